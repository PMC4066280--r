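## Venn decomposition of a concordant bioset across up to three cell-type
## developmental reference signatures. Region membership is by gene identity;
## direction agreement with each reference is tallied alongside but does not
## gate membership (a gene shared with a reference counts toward that
## reference's region whichever way it moves).

#' Partition a bioset across reference signatures
#'
#' Assigns every bioset gene to exactly one membership region of the
#' `k <= 3` references (the `2^k - 1` non-empty patterns, named by
#' `&`-joined reference labels) or to the unexplained remainder, and records
#' per-reference direction agreement counts.
#'
#' @param bioset a non-empty [GeneSignature-class].
#' @param refs a named list of 1-3 [GeneSignature-class] references (list
#'   names label the Venn regions; unnamed lists use the signatures' own
#'   names).
#' @param map optional [OrthologMap-class] translating each reference into
#'   the bioset's id namespace (applied via [translateSignature()]).
#' @return A [VennPartition-class].
#' @examples
#' bio <- GeneSignature(paste0("G", 1:10), rep(2, 10), rep(0.01, 10))
#' fs <- GeneSignature(paste0("G", 1:4), rep(2, 4), rep(0.01, 4))
#' ol <- GeneSignature(paste0("G", 3:6), rep(0.5, 4), rep(0.01, 4))
#' regionCounts(partitionBioset(bio, list(FS = fs, OL = ol)))
#' @export
partitionBioset <- function(bioset, refs, map = NULL) {
    stopifnot(is(bioset, "GeneSignature"))
    if (signatureSize(bioset) == 0L)
        stop("empty bioset")
    if (!is.list(refs)) refs <- list(refs)
    k <- length(refs)
    if (k < 1L || k > 3L)
        stop("between 1 and 3 reference signatures supported, got ", k)
    refNames <- names(refs)
    if (is.null(refNames) || any(!nzchar(refNames)))
        refNames <- vapply(refs, function(r) r@name, "")
    if (anyDuplicated(refNames))
        stop("reference names must be unique")
    if (!is.null(map))
        refs <- lapply(refs, function(r)
            suppressMessages(translateSignature(r, map)))
    for (i in seq_len(k)) {
        if (signatureSize(refs[[i]]) == 0L)
            warning("reference '", refNames[i],
                    "' is empty; it contributes only empty regions")
    }

    bioGenes <- geneIds(bioset)
    bioDir <- directions(bioset)
    membership <- vapply(refs, function(r) bioGenes %in% geneIds(r),
                         logical(length(bioGenes)))
    membership <- matrix(membership, nrow = length(bioGenes))

    ## region labels for all non-empty patterns, singletons first
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
    patterns <- patterns[order(rowSums(patterns)), , drop = FALSE]
    regionName <- apply(patterns, 1L, function(p)
        paste(refNames[as.logical(p)], collapse = "&"))
    counts <- stats::setNames(integer(nrow(patterns)), regionName)
    geneKey <- apply(membership, 1L, function(m)
        paste(refNames[m], collapse = "&"))
    tb <- table(geneKey[nzchar(geneKey)])
    counts[names(tb)] <- as.integer(tb)
    unexplained <- sum(!nzchar(geneKey))

    agreement <- do.call(rbind, lapply(seq_len(k), function(i) {
        shared <- membership[, i]
        refDir <- directions(refs[[i]])
        agree <- sum(bioDir[shared] == refDir[bioGenes[shared]])
        data.frame(reference = refNames[i],
                   overlap = sum(shared),
                   concordant = agree,
                   discordant = sum(shared) - agree,
                   stringsAsFactors = FALSE)
    }))

    new("VennPartition",
        biosetName = bioset@name,
        biosetSize = signatureSize(bioset),
        refNames = refNames,
        regionCounts = counts,
        unexplained = as.integer(unexplained),
        agreement = agreement)
}

#' Contribution percentage report
#'
#' Per-reference total overlap (membership regions summed), each exclusive
#' and shared region, and the explained total, as counts and percentages of
#' the bioset size rounded half-up to one decimal — the pie-chart table.
#'
#' @param partition a [VennPartition-class].
#' @return data.frame with columns `region`, `count`, `percent`. Rows are
#'   the per-reference totals (`total:<ref>`), the Venn regions, the
#'   unexplained remainder, and the explained total.
#' @examples
#' bio <- GeneSignature(paste0("G", 1:10), rep(2, 10), rep(0.01, 10))
#' fs <- GeneSignature(paste0("G", 1:4), rep(2, 4), rep(0.01, 4))
#' contributionPercentages(partitionBioset(bio, list(FS = fs)))
#' @export
contributionPercentages <- function(partition) {
    stopifnot(is(partition, "VennPartition"))
    n <- partition@biosetSize
    a <- partition@agreement
    rows <- data.frame(
        region = c(paste0("total:", a$reference),
                   names(partition@regionCounts),
                   "unexplained", "explained"),
        count = c(a$overlap,
                  unname(partition@regionCounts),
                  partition@unexplained,
                  n - partition@unexplained),
        stringsAsFactors = FALSE)
    rows$percent <- roundHalfUp(100 * rows$count / n, 1)
    rows
}
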