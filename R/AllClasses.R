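#' @import methods
#' @importFrom stats pchisq phyper pt rgamma rnorm runif p.adjust setNames
#'   rbinom qbinom
#' @importFrom utils read.delim write.table packageVersion
NULL

.DIRECTIONS <- c("up", "down")
.QUADRANTS <- c("uu", "dd", "ud", "du")

## ---------------------------------------------------------------------------
## SyntheticConfig
## ---------------------------------------------------------------------------

#' Configuration for the paired-study synthetic generator
#'
#' Holds the knobs of the simulated two-study design: number of genes and
#' samples, the fraction of genes truly differential in study A, the fraction
#' of those carrying a same-direction effect in study B, the mean absolute
#' log2 effect, the per-sample Gaussian noise SD (log2 units), the fraction of
#' true effects that are negative, and the RNG seed.
#'
#' @slot nGenes integer, number of genes (>= 10).
#' @slot nPerGroup integer, samples per group per study (>= 3).
#' @slot fracDE fraction in [0,1] of genes truly differential in study A.
#' @slot concordance fraction in [0,1] of study-A DE genes with a
#'   same-direction effect in study B (the remainder carry an opposite-sign
#'   effect).
#' @slot effectSize positive mean absolute log2 effect.
#' @slot noiseSd positive per-sample Gaussian SD in log2 units.
#' @slot downBias fraction in [0,1] of true effects that are negative.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
    representation(
        nGenes = "integer",
        nPerGroup = "integer",
        fracDE = "numeric",
        concordance = "numeric",
        effectSize = "numeric",
        noiseSd = "numeric",
        downBias = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticConfig", function(object) {
    chkFrac <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("'%s' must be a single value in [0, 1]", nm)
        else TRUE
    }
    msgs <- character()
    if (length(object@nGenes) != 1L || is.na(object@nGenes) ||
        object@nGenes < 10L)
        msgs <- c(msgs, "'nGenes' must be a single integer >= 10")
    if (length(object@nPerGroup) != 1L || is.na(object@nPerGroup) ||
        object@nPerGroup < 3L)
        msgs <- c(msgs, "'nPerGroup' must be a single integer >= 3")
    for (nm in c("fracDE", "concordance", "downBias")) {
        r <- chkFrac(slot(object, nm), nm)
        if (!isTRUE(r)) msgs <- c(msgs, r)
    }
    if (length(object@effectSize) != 1L || is.na(object@effectSize) ||
        object@effectSize <= 0)
        msgs <- c(msgs, "'effectSize' must be a single positive value")
    if (length(object@noiseSd) != 1L || is.na(object@noiseSd) ||
        object@noiseSd <= 0)
        msgs <- c(msgs, "'noiseSd' must be a single positive value")
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, "'seed' must be a single integer")
    if (length(msgs)) msgs else TRUE
})

#' Create a synthetic-study configuration
#'
#' Defaults describe a moderately powered paired microarray design: 2000
#' genes, 10 samples per group, 20 percent of genes differential in study A,
#' 80 percent of those concordant in study B, mean absolute log2 effect 1,
#' noise SD 0.5, and 70 percent of effects negative (down-regulation
#' dominated, as in cortical maturation signatures).
#'
#' @param nGenes,nPerGroup,fracDE,concordance,effectSize,noiseSd,downBias,seed
#'   see the slot documentation of [SyntheticConfig-class].
#' @return A validated `SyntheticConfig` object.
#' @examples
#' syntheticConfig(nGenes = 500, seed = 42)
#' @export
syntheticConfig <- function(nGenes = 2000, nPerGroup = 10, fracDE = 0.2,
                            concordance = 0.8, effectSize = 1.0,
                            noiseSd = 0.5, downBias = 0.7, seed = 1) {
    new("SyntheticConfig",
        nGenes = as.integer(nGenes), nPerGroup = as.integer(nPerGroup),
        fracDE = as.numeric(fracDE), concordance = as.numeric(concordance),
        effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
        downBias = as.numeric(downBias), seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nGenes, "genes,",
        object@nPerGroup, "samples/group/study\n")
    cat(sprintf("  fracDE=%.3g concordance=%.3g effectSize=%.3g noiseSd=%.3g downBias=%.3g seed=%d\n",
        object@fracDE, object@concordance, object@effectSize,
        object@noiseSd, object@downBias, object@seed))
})

## ---------------------------------------------------------------------------
## GeneSignature
## ---------------------------------------------------------------------------

.SIG_COLS <- c("gene_id", "linear_fc", "display_fc", "p_value",
               "direction", "rank")

#' Differential-expression gene signature ("bioset")
#'
#' A ranked list of differentially expressed genes, each with a linear fold
#' change (group1/group2 ratio of anti-logged means), its signed display form
#' (negative reciprocal, -1/FC when FC < 1), a P-value, a direction, and a
#' rank.  The signature carries the size of the measured background (all
#' genes tested), which is the population of every hypergeometric overlap
#' test downstream, and optionally the background gene identifiers
#' themselves, which enable exact background recomputation after ortholog
#' translation and background intersection.
#'
#' Ranking policy: ascending P-value, ties broken by descending absolute
#' display fold change, then lexicographic gene id.
#'
#' @slot entries data.frame with columns `gene_id`, `linear_fc`,
#'   `display_fc`, `p_value`, `direction`, `rank` (extra columns are carried
#'   through untouched).
#' @slot backgroundSize integer count of genes tested.
#' @slot backgroundIds optional character vector of all tested gene ids
#'   (length 0 when unknown).
#' @slot fcCut numeric, the |display FC| > fcCut threshold in force.
#' @slot pCut numeric, the P < pCut threshold in force.
#' @slot name character label for reports.
#' @export
setClass("GeneSignature",
    representation(
        entries = "data.frame",
        backgroundSize = "integer",
        backgroundIds = "character",
        fcCut = "numeric",
        pCut = "numeric",
        name = "character"
    )
)

setValidity("GeneSignature", function(object) {
    e <- object@entries
    msgs <- character()
    missing <- setdiff(.SIG_COLS, colnames(e))
    if (length(missing))
        return(sprintf("entries lacks column(s): %s",
                       paste(missing, collapse = ", ")))
    n <- nrow(e)
    if (anyDuplicated(e$gene_id))
        msgs <- c(msgs, "duplicate gene ids in signature")
    if (n > 0) {
        if (any(!is.finite(e$linear_fc)) || any(e$linear_fc <= 0))
            msgs <- c(msgs, "linear_fc must be finite and positive")
        if (any(e$p_value <= 0) || any(e$p_value > 1))
            msgs <- c(msgs, "p_value must be in (0, 1]")
        if (!all(e$direction %in% .DIRECTIONS))
            msgs <- c(msgs, "direction must be 'up' or 'down'")
        up <- e$linear_fc > 1
        if (!all((e$direction == "up") == up))
            msgs <- c(msgs, "direction inconsistent with linear_fc")
        expDisp <- ifelse(up, e$linear_fc, -1 / e$linear_fc)
        if (any(abs(e$display_fc - expDisp) > 1e-8))
            msgs <- c(msgs, "display_fc is not the negative reciprocal form")
        if (!identical(sort(as.integer(e$rank)), seq_len(n)))
            msgs <- c(msgs, "ranks must be a permutation of 1..n")
    }
    if (object@backgroundSize < n)
        msgs <- c(msgs, "backgroundSize smaller than signature size")
    if (length(object@backgroundIds) &&
        length(object@backgroundIds) != object@backgroundSize)
        msgs <- c(msgs, "backgroundIds length != backgroundSize")
    if (length(object@backgroundIds) &&
        !all(e$gene_id %in% object@backgroundIds))
        msgs <- c(msgs, "signature genes absent from backgroundIds")
    if (length(msgs)) msgs else TRUE
})

#' Rank signature entries by the significance-then-magnitude policy
#' @noRd
.signatureOrder <- function(entries) {
    order(entries$p_value, -abs(entries$display_fc), entries$gene_id)
}

#' Construct a GeneSignature
#'
#' Directions and display fold changes are derived from the linear fold
#' change; ranks are assigned by ascending P, then descending |display FC|,
#' then gene id.
#'
#' @param geneIds character vector of gene identifiers.
#' @param linearFC positive linear fold changes (group1/group2).
#' @param pValue P-values in (0, 1].
#' @param backgroundSize number of genes tested (defaults to
#'   `length(backgroundIds)` when given, else to the number of entries).
#' @param backgroundIds optional character vector of all tested gene ids.
#' @param fcCut,pCut thresholds the signature was extracted with.
#' @param name label used in reports.
#' @param extra optional data.frame of extra per-gene columns to carry.
#' @return A `GeneSignature`.
#' @examples
#' GeneSignature(c("G1", "G2"), c(2, 0.5), c(0.01, 0.02), backgroundSize = 100)
#' @export
GeneSignature <- function(geneIds, linearFC, pValue,
                          backgroundSize = NULL,
                          backgroundIds = character(),
                          fcCut = 1.2, pCut = 0.05,
                          name = "signature", extra = NULL) {
    geneIds <- as.character(geneIds)
    linearFC <- as.numeric(linearFC)
    pValue <- as.numeric(pValue)
    stopifnot(length(geneIds) == length(linearFC),
              length(geneIds) == length(pValue))
    if (any(linearFC == 1))
        stop("linear fold change of exactly 1 has no direction")
    up <- linearFC > 1
    entries <- data.frame(
        gene_id = geneIds,
        linear_fc = linearFC,
        display_fc = ifelse(up, linearFC, -1 / linearFC),
        p_value = pValue,
        direction = ifelse(up, "up", "down"),
        stringsAsFactors = FALSE)
    if (!is.null(extra)) {
        stopifnot(nrow(extra) == nrow(entries))
        entries <- cbind(entries, extra)
    }
    entries <- entries[.signatureOrder(entries), , drop = FALSE]
    entries$rank <- seq_len(nrow(entries))
    rownames(entries) <- NULL
    if (is.null(backgroundSize)) {
        backgroundSize <- if (length(backgroundIds)) length(backgroundIds)
                          else nrow(entries)
    }
    new("GeneSignature", entries = entries,
        backgroundSize = as.integer(backgroundSize),
        backgroundIds = as.character(backgroundIds),
        fcCut = as.numeric(fcCut), pCut = as.numeric(pCut),
        name = as.character(name))
}

#' Empty signature helper
#' @noRd
.emptySignature <- function(backgroundSize = 0L, backgroundIds = character(),
                            fcCut = 1.2, pCut = 0.05, name = "signature") {
    entries <- data.frame(gene_id = character(), linear_fc = numeric(),
                          display_fc = numeric(), p_value = numeric(),
                          direction = character(), rank = integer(),
                          stringsAsFactors = FALSE)
    new("GeneSignature", entries = entries,
        backgroundSize = as.integer(backgroundSize),
        backgroundIds = backgroundIds,
        fcCut = fcCut, pCut = pCut, name = name)
}

setMethod("show", "GeneSignature", function(object) {
    e <- object@entries
    cat(sprintf("GeneSignature '%s': %d genes (%d up, %d down), background %d\n",
        object@name, nrow(e), sum(e$direction == "up"),
        sum(e$direction == "down"), object@backgroundSize))
    cat(sprintf("  thresholds: |FC| > %g, P < %g\n", object@fcCut,
        object@pCut))
    if (nrow(e)) {
        print(utils::head(e[, .SIG_COLS], 5L))
        if (nrow(e) > 5L) cat("  ...", nrow(e) - 5L, "more\n")
    }
})

## ---------------------------------------------------------------------------
## OrthologMap
## ---------------------------------------------------------------------------

#' Source-to-target gene identifier map
#'
#' Two-column mapping between gene identifier namespaces (e.g. mouse symbols
#' to human symbols). Exact duplicate pairs are disallowed; 1:many and many:1
#' relations are permitted and resolved deterministically by
#' [translateSignature()].
#'
#' @slot pairs data.frame with character columns `source` and `target`.
#' @export
setClass("OrthologMap", representation(pairs = "data.frame"))

setValidity("OrthologMap", function(object) {
    p <- object@pairs
    if (!all(c("source", "target") %in% colnames(p)))
        return("pairs must have columns 'source' and 'target'")
    if (anyDuplicated(p))
        return("duplicate (source, target) pairs")
    TRUE
})

#' Construct an OrthologMap
#' @param source,target character vectors of equal length.
#' @return An `OrthologMap`.
#' @examples
#' OrthologMap(c("Mm1", "Mm2"), c("G1", "G2"))
#' @export
OrthologMap <- function(source, target) {
    stopifnot(length(source) == length(target))
    new("OrthologMap", pairs = unique(data.frame(
        source = as.character(source), target = as.character(target),
        stringsAsFactors = FALSE)))
}

setMethod("show", "OrthologMap", function(object) {
    cat(sprintf("OrthologMap: %d pairs, %d source genes -> %d target genes\n",
        nrow(object@pairs), length(unique(object@pairs$source)),
        length(unique(object@pairs$target))))
})

## ---------------------------------------------------------------------------
## GeneSetCollection
## ---------------------------------------------------------------------------

#' Named collection of gene sets
#'
#' Carrier for GMT-style gene-set collections used by [enrichSignature()].
#'
#' @slot sets named list of character vectors (unique names, non-empty sets).
#' @slot descriptions character vector parallel to `sets`.
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msgs <- character()
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msgs <- c(msgs, "set names must be present and unique")
        if (any(lengths(object@sets) == 0L))
            msgs <- c(msgs, "empty gene set")
        if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
            msgs <- c(msgs, "duplicated member within a set")
    }
    if (length(object@descriptions) != length(object@sets))
        msgs <- c(msgs, "descriptions length != number of sets")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A `GeneSetCollection`.
#' @examples
#' GeneSetCollection(list(a = c("G1", "G2"), b = "G3"))
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, as.character)
    if (is.null(descriptions)) descriptions <- rep("", length(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = as.character(descriptions))
}

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets, sizes %s\n",
        length(object@sets),
        if (length(object@sets))
            paste(range(lengths(object@sets)), collapse = "-") else "-"))
})

## ---------------------------------------------------------------------------
## OverlapResult
## ---------------------------------------------------------------------------

#' Result of a pairwise signature overlap comparison
#'
#' Holds quadrant counts (uu/dd/ud/du), per-quadrant Running Fisher
#' P-values, the joint Running Fisher overlap P-value (with a log10 form that
#' stays informative below the double-precision floor), the direction
#' concordance chi-square against the 50 percent null, the Bonferroni
#' significance levels in force, and the per-gene overlap table.
#'
#' @slot nameA,nameB labels of the two signatures.
#' @slot nA,nB signature sizes after background restriction.
#' @slot backgroundSize common measured background size.
#' @slot quadrants named integer vector (uu, dd, ud, du).
#' @slot quadrantP named numeric vector of direction-restricted Running
#'   Fisher P-values.
#' @slot runningP joint Running Fisher overlap P-value.
#' @slot runningLog10P its log10, computed in log space.
#' @slot chi2,chi2P Pearson concordance chi-square (1 df) and its P-value
#'   (`NA` when the overlap is empty).
#' @slot alphaPairs,alphaDirections Bonferroni-adjusted significance levels.
#' @slot genes data.frame of shared genes with per-study statistics and
#'   quadrant assignment.
#' @export
setClass("OverlapResult",
    representation(
        nameA = "character", nameB = "character",
        nA = "integer", nB = "integer",
        backgroundSize = "integer",
        quadrants = "integer",
        quadrantP = "numeric",
        runningP = "numeric",
        runningLog10P = "numeric",
        chi2 = "numeric", chi2P = "numeric",
        alphaPairs = "numeric", alphaDirections = "numeric",
        genes = "data.frame"
    )
)

setValidity("OverlapResult", function(object) {
    msgs <- character()
    q <- object@quadrants
    if (!identical(names(q), .QUADRANTS))
        return("quadrants must be named uu, dd, ud, du")
    if (any(q < 0)) msgs <- c(msgs, "negative quadrant count")
    if (sum(q) > min(object@nA, object@nB))
        msgs <- c(msgs, "overlap exceeds min(nA, nB)")
    if (!identical(names(object@quadrantP), .QUADRANTS))
        msgs <- c(msgs, "quadrantP must be named uu, dd, ud, du")
    ps <- c(object@quadrantP, object@runningP)
    if (any(ps <= 0 | ps > 1))
        msgs <- c(msgs, "P-values must lie in (0, 1]")
    if (!is.na(object@chi2) && object@chi2 < 0)
        msgs <- c(msgs, "chi2 must be >= 0")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "OverlapResult", function(object) {
    q <- object@quadrants
    cat(sprintf("OverlapResult: '%s' (n=%d) vs '%s' (n=%d), background %d\n",
        object@nameA, object@nA, object@nameB, object@nB,
        object@backgroundSize))
    cat(sprintf("  overlap %d | uu=%d dd=%d ud=%d du=%d\n", sum(q),
        q["uu"], q["dd"], q["ud"], q["du"]))
    cat(sprintf("  running Fisher P = %.3g (log10 = %.2f)\n",
        object@runningP, object@runningLog10P))
    cat(sprintf("  concordance chi2(1) = %s, P = %s\n",
        format(round(object@chi2, 2)), format(signif(object@chi2P, 3))))
    cat(sprintf("  alpha (dataset pairs) = %.4g, alpha (directions) = %.4g\n",
        object@alphaPairs, object@alphaDirections))
})

## ---------------------------------------------------------------------------
## VennPartition
## ---------------------------------------------------------------------------

#' Venn decomposition of a bioset over reference signatures
#'
#' Counts of the bioset's genes across every non-empty membership region of
#' up to three reference signatures, the unexplained remainder, and the
#' per-reference direction agreement tallies. Membership is by gene identity;
#' direction agreement is reported alongside but does not gate membership.
#'
#' @slot biosetName label of the decomposed signature.
#' @slot biosetSize total bioset size.
#' @slot refNames reference signature labels (region names are `&`-joined
#'   subsets of these).
#' @slot regionCounts named integer over the 2^k - 1 non-empty membership
#'   patterns.
#' @slot unexplained count of bioset genes in no reference.
#' @slot agreement data.frame with per-reference `overlap`, `concordant`,
#'   `discordant` counts.
#' @export
setClass("VennPartition",
    representation(
        biosetName = "character",
        biosetSize = "integer",
        refNames = "character",
        regionCounts = "integer",
        unexplained = "integer",
        agreement = "data.frame"
    )
)

setValidity("VennPartition", function(object) {
    msgs <- character()
    k <- length(object@refNames)
    if (k < 1L || k > 3L)
        msgs <- c(msgs, "between 1 and 3 references required")
    if (length(object@regionCounts) != 2^k - 1L)
        msgs <- c(msgs, "regionCounts must cover the 2^k - 1 patterns")
    if (sum(object@regionCounts) + object@unexplained != object@biosetSize)
        msgs <- c(msgs, "region counts + unexplained != bioset size")
    a <- object@agreement
    if (!all(c("reference", "overlap", "concordant", "discordant") %in%
             colnames(a)))
        msgs <- c(msgs, "agreement table lacks required columns")
    else if (nrow(a) && any(a$concordant + a$discordant != a$overlap))
        msgs <- c(msgs, "concordant + discordant != overlap for a reference")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "VennPartition", function(object) {
    cat(sprintf("VennPartition of '%s' (%d genes) over: %s\n",
        object@biosetName, object@biosetSize,
        paste(object@refNames, collapse = ", ")))
    for (nm in names(object@regionCounts))
        cat(sprintf("  %-20s %5d\n", nm, object@regionCounts[[nm]]))
    cat(sprintf("  %-20s %5d\n", "(unexplained)", object@unexplained))
    expl <- object@biosetSize - object@unexplained
    cat(sprintf("  explained: %d/%d (%s%%)\n", expl, object@biosetSize,
        format(roundHalfUp(100 * expl / object@biosetSize, 1))))
})

## ---------------------------------------------------------------------------
## EnrichmentResult
## ---------------------------------------------------------------------------

#' Gene-set over-representation result
#'
#' One row per gene set: overlap count, in-background set size, one-sided
#' Fisher (hypergeometric upper-tail) P, and Benjamini-Hochberg adjusted P,
#' sorted by raw P.
#'
#' @slot table data.frame with columns `set`, `set_size`, `overlap`,
#'   `p_value`, `p_adjust`.
#' @slot backgroundSize hypergeometric population size.
#' @slot biosetSize number of query genes in the background.
#' @export
setClass("EnrichmentResult",
    representation(table = "data.frame", backgroundSize = "integer",
                   biosetSize = "integer"))

setValidity("EnrichmentResult", function(object) {
    t <- object@table
    need <- c("set", "set_size", "overlap", "p_value", "p_adjust")
    if (!all(need %in% colnames(t)))
        return("table lacks required columns")
    msgs <- character()
    if (nrow(t)) {
        if (any(t$p_adjust < t$p_value - 1e-12))
            msgs <- c(msgs, "adjusted P below raw P")
        if (any(t$overlap > pmin(t$set_size, object@biosetSize)))
            msgs <- c(msgs, "overlap exceeds min(set size, bioset size)")
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult: %d sets, bioset %d of background %d\n",
        nrow(object@table), object@biosetSize, object@backgroundSize))
    print(utils::head(object@table, 5L))
})

## ---------------------------------------------------------------------------
## shared small helpers
## ---------------------------------------------------------------------------

#' Round half away from zero to a number of decimals
#'
#' Report-style rounding (0.05 -> 0.1) rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(37.35, 1)
#' @export
roundHalfUp <- function(x, digits = 1) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}
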