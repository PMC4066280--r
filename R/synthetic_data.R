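## Synthetic paired two-group studies sharing a latent "maturation" axis.
##
## The generator emulates the statistical skeleton of a cross-study
## comparison: a fraction of genes carries a true log2 effect in study A; of
## those, a configurable fraction carries a same-direction effect in study B
## and the remainder an opposite-direction effect, so the concordant fraction
## among genes differential in both studies targets the configured value.
## Effect magnitudes are Gamma(shape 4) with mean `effectSize`; signs are
## negative with probability `downBias`.

#' Generate a pair of two-group expression studies with shared effects
#'
#' Produces two log2-scale gene-by-sample matrices over the same gene
#' universe (`G000001`, ...), each with `2 * nPerGroup` samples split into
#' `group1` (the "young/disease" side, the fold-change numerator) and
#' `group2`, plus the per-gene ground truth. Identical config and seed give
#' byte-identical output.
#'
#' @param config a [SyntheticConfig-class] from [syntheticConfig()].
#' @return A list with elements:
#'   \describe{
#'     \item{studyA, studyB}{`SummarizedExperiment` objects with assay
#'       `exprs` (log2 units) and colData column `group`.}
#'     \item{truth}{data.frame with `gene_id`, signed true effects
#'       `effect_a`, `effect_b` (log2 units) and `label` in
#'       concordant/discordant/A-only/B-only/null.}
#'   }
#' @examples
#' sim <- generatePairedStudies(syntheticConfig(nGenes = 200, seed = 3))
#' table(sim$truth$label)
#' @export
generatePairedStudies <- function(config) {
    if (!is(config, "SyntheticConfig"))
        stop("'config' must be a SyntheticConfig")
    validObject(config)
    set.seed(config@seed)
    n <- config@nGenes
    m <- config@nPerGroup
    ids <- sprintf("G%06d", seq_len(n))

    nDE <- round(config@fracDE * n)
    nConc <- round(config@concordance * nDE)
    effA <- numeric(n)
    effB <- numeric(n)
    label <- rep("null", n)
    if (nDE > 0) {
        deIdx <- sort(sample.int(n, nDE))
        magA <- rgamma(nDE, shape = 4, scale = config@effectSize / 4)
        sgn <- ifelse(runif(nDE) < config@downBias, -1, 1)
        effA[deIdx] <- sgn * magA
        concIdx <- if (nConc > 0) sort(sample(deIdx, nConc)) else integer()
        discIdx <- setdiff(deIdx, concIdx)
        magB <- rgamma(nDE, shape = 4, scale = config@effectSize / 4)
        names(magB) <- as.character(deIdx)
        effB[concIdx] <- sign(effA[concIdx]) * magB[as.character(concIdx)]
        effB[discIdx] <- -sign(effA[discIdx]) * magB[as.character(discIdx)]
        label[concIdx] <- "concordant"
        label[discIdx] <- "discordant"
    }

    makeStudy <- function(effect, prefix) {
        base <- rnorm(n, mean = 7, sd = 1)
        vals <- base + matrix(rnorm(n * 2L * m, sd = config@noiseSd),
                              nrow = n)
        vals[, seq_len(m)] <- vals[, seq_len(m)] + effect
        dimnames(vals) <- list(ids,
            paste0(prefix, "_s", sprintf("%02d", seq_len(2L * m))))
        groups <- rep(c("group1", "group2"), each = m)
        makeExpressionMatrix(vals, groups)
    }
    list(
        studyA = makeStudy(effA, "A"),
        studyB = makeStudy(effB, "B"),
        truth = data.frame(gene_id = ids, effect_a = effA, effect_b = effB,
                           label = label, stringsAsFactors = FALSE)
    )
}

#' Mouse-style identifier transform
#'
#' Deterministic suffix transform turning a synthetic human-style id
#' (`G000123`) into its mouse-style counterpart (`Mm000123`), used to
#' exercise ortholog translation without real nomenclature.
#'
#' @param ids character vector of `G`-prefixed ids.
#' @return Character vector of `Mm`-prefixed ids.
#' @examples
#' mouseStyleIds(c("G000001", "G000002"))
#' @export
mouseStyleIds <- function(ids) sub("^G", "Mm", ids)

#' Generate an ortholog map for synthetic gene ids
#'
#' Builds the 1:1 mouse-to-human map implied by [mouseStyleIds()], optionally
#' dropping a fraction of genes (unmapped orthologs) and fanning out a
#' fraction of sources to a second target (1:many relations).
#'
#' @param geneIds human-style gene ids (the targets).
#' @param dropFrac fraction of genes without any mapping.
#' @param fanoutFrac fraction of mapped sources given a second, duplicated
#'   target id (`<id>x`).
#' @param seed RNG seed used when `dropFrac` or `fanoutFrac` is positive.
#' @return An [OrthologMap-class] with mouse-style sources.
#' @examples
#' generateOrthologMap(sprintf("G%06d", 1:5), dropFrac = 0.2, seed = 1)
#' @export
generateOrthologMap <- function(geneIds, dropFrac = 0, fanoutFrac = 0,
                                seed = 1) {
    stopifnot(dropFrac >= 0, dropFrac <= 1, fanoutFrac >= 0, fanoutFrac <= 1)
    set.seed(seed)
    keep <- if (dropFrac > 0) {
        runif(length(geneIds)) >= dropFrac
    } else rep(TRUE, length(geneIds))
    tgt <- geneIds[keep]
    src <- mouseStyleIds(tgt)
    if (fanoutFrac > 0 && length(tgt)) {
        extra <- runif(length(tgt)) < fanoutFrac
        src <- c(src, src[extra])
        tgt <- c(tgt, paste0(tgt[extra], "x"))
    }
    OrthologMap(src, tgt)
}

#' Generate a reference signature overlapping a bioset
#'
#' Stands in for cell-type developmental signatures: each bioset gene is
#' included in the reference independently with probability `overlapFrac`
#' (so the expected overlap is `overlapFrac * signatureSize(bioset)` with
#' binomial error), agrees in direction with the bioset with probability
#' `agreement`, and the reference is padded with `nExtra` background genes
#' outside the bioset. With `targetIds = TRUE` the reference is emitted under
#' mouse-style identifiers together with the matching [OrthologMap-class].
#'
#' @param bioset the designated [GeneSignature-class].
#' @param overlapFrac inclusion probability in [0, 1] per bioset gene.
#' @param agreement probability in [0, 1] that an included gene keeps the
#'   bioset's direction.
#' @param nExtra number of non-bioset background genes added.
#' @param targetIds emit mouse-style identifiers plus an ortholog map.
#' @param fcCut,pCut thresholds stamped on the reference (magnitude of its
#'   simulated fold changes and P-values respect them).
#' @param name label for the reference.
#' @param seed RNG seed.
#' @return A list with `signature` (a `GeneSignature`) and `map` (an
#'   `OrthologMap` when `targetIds`, otherwise `NULL`).
#' @examples
#' sig <- GeneSignature(sprintf("G%06d", 1:20), rep(2, 20),
#'                      runif(20, 0, 0.05),
#'                      backgroundIds = sprintf("G%06d", 1:100))
#' ref <- generateReferenceSignature(sig, overlapFrac = 0.5, seed = 2)
#' signatureSize(ref$signature)
#' @export
generateReferenceSignature <- function(bioset, overlapFrac, agreement = 1,
                                       nExtra = NULL, targetIds = FALSE,
                                       fcCut = 1.5, pCut = 0.05,
                                       name = "reference", seed = 1) {
    stopifnot(is(bioset, "GeneSignature"))
    if (!is.numeric(overlapFrac) || overlapFrac < 0 || overlapFrac > 1)
        stop("'overlapFrac' must be in [0, 1]")
    if (!is.numeric(agreement) || agreement < 0 || agreement > 1)
        stop("'agreement' must be in [0, 1]")
    set.seed(seed)
    e <- signatureEntries(bioset)
    inRef <- runif(nrow(e)) < overlapFrac
    shared <- e$gene_id[inRef]
    sharedDir <- e$direction[inRef]
    flip <- runif(length(shared)) >= agreement
    sharedDir[flip] <- ifelse(sharedDir[flip] == "up", "down", "up")

    bg <- backgroundIds(bioset)
    if (!length(bg))
        bg <- e$gene_id
    pool <- setdiff(bg, e$gene_id)
    if (is.null(nExtra))
        nExtra <- min(length(pool), nrow(e))
    nExtra <- min(nExtra, length(pool))
    extraIds <- if (nExtra > 0) sample(pool, nExtra) else character()
    extraDir <- if (nExtra > 0)
        sample(.DIRECTIONS, nExtra, replace = TRUE) else character()

    ids <- c(shared, extraIds)
    dir <- c(sharedDir, extraDir)
    k <- length(ids)
    map <- NULL
    refBg <- bg
    if (targetIds) {
        map <- OrthologMap(mouseStyleIds(bg), bg)
        ids <- mouseStyleIds(ids)
        refBg <- mouseStyleIds(bg)
    }
    if (k == 0)
        return(list(signature = .emptySignature(length(refBg), refBg,
                                                fcCut, pCut, name),
                    map = map))
    mag <- fcCut * 2^runif(k, 0.05, 1.5)
    lfc <- ifelse(dir == "up", mag, 1 / mag)
    p <- runif(k, 1e-8, pCut * 0.999)
    list(signature = GeneSignature(ids, lfc, p,
                                   backgroundIds = refBg,
                                   fcCut = fcCut, pCut = pCut, name = name),
         map = map)
}
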