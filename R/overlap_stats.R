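## Pairwise signature similarity: rank-based Running Fisher overlap P,
## directional quadrant counts and P-values, concordance chi-square against
## the 50 percent null, and the Bonferroni significance ledger.
##
## Running Fisher scan: the first signature's ranked list is cut at its
## decile boundaries (every rank when the list is shorter than 50); at each
## cutoff the overlap of the top-k genes with the second signature is scored
## by an upper-tail hypergeometric against the common measured background,
## and the minimum P is Bonferroni-multiplied by the number of cutoffs.
## Extreme tails are handled in log space.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(population, successes, draws)`:
#' the chance of at least `k` marked genes in a draw of `draws` from a
#' population containing `successes` marked genes. Computed in log space so
#' extreme tails (below 1e-300) remain meaningful through the `log10`
#' argument.
#'
#' @param k observed overlap count.
#' @param draws number of genes drawn (size of the query list).
#' @param successes number of marked genes in the population.
#' @param population background size.
#' @param log10 return log10 of the tail probability.
#' @return Numeric scalar; exactly 1 when `k = 0`. On the natural scale the
#'   value is floored at the smallest positive double so it remains in
#'   (0, 1].
#' @examples
#' hypergeomUpper(4, 5, 6, 20)
#' @export
hypergeomUpper <- function(k, draws, successes, population, log10 = FALSE) {
    if (any(c(k, draws, successes, population) < 0) ||
        k > min(draws, successes) || draws > population ||
        successes > population)
        stop("inconsistent hypergeometric arguments: k=", k, " draws=", draws,
             " successes=", successes, " population=", population)
    if (k == 0)
        return(if (log10) 0 else 1)
    lp <- phyper(k - 1, successes, population - successes, draws,
                 lower.tail = FALSE, log.p = TRUE)
    if (log10) lp / log(10) else max(exp(lp), .Machine$double.xmin)
}

#' Restrict two signatures to a common measured background
#'
#' Filters both signatures to genes present in `background` (re-ranking the
#' survivors) and records the background size — the population for the
#' overlap tests. Typically `background` is the intersection of the two
#' platforms' measured gene universes.
#'
#' @param sigA,sigB [GeneSignature-class] objects sharing an id namespace.
#' @param background non-empty character vector of background gene ids, or a
#'   single count when the identity of background genes is not tracked (then
#'   no filtering occurs).
#' @return list with `sigA`, `sigB` (filtered, re-ranked) and
#'   `backgroundSize`.
#' @export
restrictToBackground <- function(sigA, sigB, background) {
    stopifnot(is(sigA, "GeneSignature"), is(sigB, "GeneSignature"))
    if (is.numeric(background)) {
        if (length(background) != 1L || background < 1)
            stop("numeric 'background' must be a single positive count")
        return(list(sigA = sigA, sigB = sigB,
                    backgroundSize = as.integer(background)))
    }
    background <- unique(as.character(background))
    if (length(background) == 0L)
        stop("empty background")
    filterSig <- function(sig) {
        e <- signatureEntries(sig)
        keep <- e$gene_id %in% background
        if (all(keep) && length(backgroundIds(sig)) == 0L) {
            ## still need the new background recorded on the signature
        }
        e <- e[keep, , drop = FALSE]
        if (nrow(e) == 0L)
            return(.emptySignature(length(background), background,
                                   sig@fcCut, sig@pCut, sig@name))
        extraCols <- setdiff(colnames(e), .SIG_COLS)
        GeneSignature(e$gene_id, e$linear_fc, e$p_value,
                      backgroundIds = background,
                      fcCut = sig@fcCut, pCut = sig@pCut, name = sig@name,
                      extra = e[, extraCols, drop = FALSE])
    }
    list(sigA = filterSig(sigA), sigB = filterSig(sigB),
         backgroundSize = length(background))
}

#' Directional quadrant partition of two signatures
#'
#' Assigns every shared gene to exactly one of uu, dd, ud, du by its
#' direction pair (first letter = direction in `sigA`).
#'
#' @param sigA,sigB [GeneSignature-class] objects sharing an id namespace.
#' @return list with `counts` (named integer uu/dd/ud/du) and `genes`
#'   (data.frame of shared genes with both studies' statistics).
#' @examples
#' a <- GeneSignature(c("G1", "G2"), c(2, 0.5), c(0.01, 0.02))
#' b <- GeneSignature(c("G1", "G2"), c(3, 2),  c(0.03, 0.04))
#' quadrantPartition(a, b)$counts
#' @export
quadrantPartition <- function(sigA, sigB) {
    ea <- signatureEntries(sigA)
    eb <- signatureEntries(sigB)
    shared <- intersect(ea$gene_id, eb$gene_id)
    ia <- match(shared, ea$gene_id)
    ib <- match(shared, eb$gene_id)
    dirA <- ea$direction[ia]
    dirB <- eb$direction[ib]
    quad <- paste0(substr(dirA, 1, 1), substr(dirB, 1, 1))
    quad <- chartr("ud", "ud", quad)  # "uu","ud","du","dd"
    counts <- stats::setNames(integer(4L), .QUADRANTS)
    tb <- table(factor(quad, levels = .QUADRANTS))
    counts[names(tb)] <- as.integer(tb)
    genes <- data.frame(
        gene_id = shared,
        direction_a = dirA, direction_b = dirB,
        quadrant = quad,
        display_fc_a = ea$display_fc[ia], display_fc_b = eb$display_fc[ib],
        linear_fc_a = ea$linear_fc[ia], linear_fc_b = eb$linear_fc[ib],
        p_a = ea$p_value[ia], p_b = eb$p_value[ib],
        stringsAsFactors = FALSE)
    list(counts = counts, genes = genes)
}

#' Rank cutoffs of the Running Fisher scan
#' @noRd
.runningCutoffs <- function(nA) {
    if (nA < 50L) seq_len(nA) else unique(ceiling(nA * (1:10) / 10))
}

#' Running Fisher overlap test
#'
#' Scans cumulative cutoffs of `sigA`'s ranked gene list (decile boundaries,
#' or every rank when the list has fewer than 50 genes); at each cutoff `k`
#' the overlap of the top-k genes with `sigB` is scored by
#' [hypergeomUpper()] against the common background, and the summary P is the
#' minimum over cutoffs multiplied by the number of cutoffs (Bonferroni over
#' the scan), capped at 1.
#'
#' @param sigA,sigB [GeneSignature-class] objects sharing an id namespace and
#'   background.
#' @param backgroundSize common measured background (>= union of the two
#'   signatures).
#' @return list with `p`, `log10p` (stable for extreme tails), `nCutoffs`,
#'   and `bestCutoff` (the rank minimising the scan). Empty signatures give
#'   `p = 1` with a warning.
#' @examples
#' a <- GeneSignature(paste0("G", 1:20), rep(2, 20), (1:20) / 100)
#' b <- GeneSignature(paste0("G", 1:5), rep(2, 5), rep(0.01, 5))
#' runningFisher(a, b, backgroundSize = 1000)$p
#' @export
runningFisher <- function(sigA, sigB, backgroundSize) {
    nA <- signatureSize(sigA)
    nB <- signatureSize(sigB)
    if (nA == 0L || nB == 0L) {
        warning("empty signature: running Fisher P set to 1")
        return(list(p = 1, log10p = 0, nCutoffs = 0L, bestCutoff = NA_integer_))
    }
    union_n <- length(union(geneIds(sigA), geneIds(sigB)))
    if (backgroundSize < union_n)
        stop("backgroundSize smaller than the union of the signatures")
    rankedA <- geneIds(sigA)  # entries are stored in rank order
    inB <- rankedA %in% geneIds(sigB)
    cum <- cumsum(inB)
    cutoffs <- .runningCutoffs(nA)
    logps <- vapply(cutoffs, function(k)
        hypergeomUpper(cum[k], k, nB, backgroundSize, log10 = TRUE),
        numeric(1))
    best <- which.min(logps)
    log10p <- min(logps[best] + log10(length(cutoffs)), 0)
    list(p = max(10^log10p, .Machine$double.xmin),
         log10p = log10p,
         nCutoffs = length(cutoffs),
         bestCutoff = cutoffs[best])
}

#' Subset a signature to one direction, re-ranking
#' @noRd
.directionSubset <- function(sig, direction) {
    e <- signatureEntries(sig)
    e <- e[e$direction == direction, , drop = FALSE]
    if (nrow(e) == 0L)
        return(.emptySignature(backgroundSize(sig), backgroundIds(sig),
                               sig@fcCut, sig@pCut, sig@name))
    GeneSignature(e$gene_id, e$linear_fc, e$p_value,
                  backgroundSize = backgroundSize(sig),
                  backgroundIds = backgroundIds(sig),
                  fcCut = sig@fcCut, pCut = sig@pCut,
                  name = paste0(sig@name, ".", direction))
}

#' Direction-restricted overlap P-value
#'
#' The Running Fisher test applied to the sub-signatures restricted to one
#' direction in each study (e.g. up in A vs down in B) against the same
#' background — the per-arrow bar heights of the figure-style quadrant
#' report.
#'
#' @param sigA,sigB [GeneSignature-class] objects.
#' @param directionA,directionB `"up"` or `"down"`.
#' @param backgroundSize common measured background.
#' @return The overlap P-value (1, with a warning, when a restricted set is
#'   empty).
#' @export
directionalOverlapP <- function(sigA, sigB, directionA, directionB,
                                backgroundSize) {
    stopifnot(directionA %in% .DIRECTIONS, directionB %in% .DIRECTIONS)
    subA <- .directionSubset(sigA, directionA)
    subB <- .directionSubset(sigB, directionB)
    runningFisher(subA, subB, backgroundSize)$p
}

#' Direction-concordance chi-square against the 50 percent null
#'
#' Pearson chi-square (1 df, no continuity correction) comparing the counts
#' of positively and negatively correlated genes with the expected 50/50
#' split: `chi2 = (c - d)^2 / (c + d)`.
#'
#' @param concordant count of same-direction shared genes (uu + dd).
#' @param discordant count of opposite-direction shared genes (ud + du).
#' @return list with `chi2` and `p`.
#' @examples
#' concordanceChiSquare(654, 232)  # chi2 = 201.00
#' @export
concordanceChiSquare <- function(concordant, discordant) {
    total <- concordant + discordant
    if (length(total) != 1L || is.na(total) || total < 1)
        stop("concordant + discordant must be >= 1")
    if (concordant < 0 || discordant < 0)
        stop("negative count")
    chi2 <- (concordant - discordant)^2 / total
    list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni significance-level ledger
#'
#' The per-comparison significance level is 0.05 divided by the number of
#' dataset pairs in the study; the per-direction level is fixed at
#' 0.05 / 4 = 0.0125 (four direction pairs: uu, dd, ud, du).
#'
#' @param nDatasetPairs number of dataset pairs compared (>= 1).
#' @return list with `alphaPairs` and `alphaDirections`.
#' @examples
#' bonferroniLedger(5)
#' @export
bonferroniLedger <- function(nDatasetPairs) {
    if (length(nDatasetPairs) != 1L || is.na(nDatasetPairs) ||
        nDatasetPairs < 1)
        stop("'nDatasetPairs' must be a single count >= 1")
    list(alphaPairs = 0.05 / nDatasetPairs, alphaDirections = 0.05 / 4)
}

#' Full pairwise signature comparison
#'
#' Restricts both signatures to a common background, partitions the shared
#' genes into direction quadrants, computes the joint and the four
#' direction-restricted Running Fisher P-values, the concordance chi-square
#' (NA when the overlap is empty), and attaches the Bonferroni ledger.
#'
#' @param sigA,sigB [GeneSignature-class] objects sharing an id namespace
#'   (translate first for cross-species pairs).
#' @param background character vector of common background gene ids, a
#'   single count, or `NULL` to use the intersection of the signatures'
#'   tracked background ids (an error if neither carries them).
#' @param nDatasetPairs dataset-pair count for the Bonferroni ledger.
#' @return An [OverlapResult-class].
#' @examples
#' sim <- generatePairedStudies(syntheticConfig(nGenes = 500, seed = 1))
#' a <- extractSignature(sim$studyA, name = "A")
#' b <- extractSignature(sim$studyB, name = "B")
#' compareSignatures(a, b)
#' @export
compareSignatures <- function(sigA, sigB, background = NULL,
                              nDatasetPairs = 1) {
    if (is.null(background)) {
        if (length(backgroundIds(sigA)) && length(backgroundIds(sigB))) {
            background <- intersect(backgroundIds(sigA), backgroundIds(sigB))
        } else {
            stop("'background' required when signatures do not carry ",
                 "background ids")
        }
    }
    r <- restrictToBackground(sigA, sigB, background)
    bg <- r$backgroundSize
    qp <- quadrantPartition(r$sigA, r$sigB)
    run <- if (signatureSize(r$sigA) && signatureSize(r$sigB)) {
        runningFisher(r$sigA, r$sigB, bg)
    } else list(p = 1, log10p = 0)
    dirP <- vapply(.QUADRANTS, function(q) {
        dA <- if (substr(q, 1, 1) == "u") "up" else "down"
        dB <- if (substr(q, 2, 2) == "u") "up" else "down"
        suppressWarnings(
            directionalOverlapP(r$sigA, r$sigB, dA, dB, bg))
    }, numeric(1))
    conc <- unname(qp$counts["uu"] + qp$counts["dd"])
    disc <- unname(qp$counts["ud"] + qp$counts["du"])
    if (conc + disc >= 1L) {
        cs <- concordanceChiSquare(conc, disc)
    } else {
        cs <- list(chi2 = NA_real_, p = NA_real_)
    }
    ledger <- bonferroniLedger(nDatasetPairs)
    new("OverlapResult",
        nameA = r$sigA@name, nameB = r$sigB@name,
        nA = signatureSize(r$sigA), nB = signatureSize(r$sigB),
        backgroundSize = as.integer(bg),
        quadrants = qp$counts,
        quadrantP = dirP,
        runningP = run$p, runningLog10P = run$log10p,
        chi2 = cs$chi2, chi2P = cs$p,
        alphaPairs = ledger$alphaPairs,
        alphaDirections = ledger$alphaDirections,
        genes = qp$genes)
}
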