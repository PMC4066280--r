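## Accessor generics; slot access from user code is discouraged.

#' Gene identifiers of an object
#' @param x a `GeneSignature` or `GeneSetCollection`.
#' @return Character vector of gene ids (for collections, a named list).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn geneIds genes of a signature, in rank order.
#' @export
setMethod("geneIds", "GeneSignature", function(x) x@entries$gene_id)

#' @describeIn geneIds member lists of a collection.
#' @export
setMethod("geneIds", "GeneSetCollection", function(x) x@sets)

#' Number of genes in a signature
#' @param x a `GeneSignature`.
#' @return Integer count.
#' @export
setGeneric("signatureSize", function(x) standardGeneric("signatureSize"))

#' @describeIn signatureSize entry count.
#' @export
setMethod("signatureSize", "GeneSignature", function(x) nrow(x@entries))

#' Measured-background size
#' @param x a `GeneSignature`, `OverlapResult` or `EnrichmentResult`.
#' @return Integer count of genes tested (the hypergeometric population).
#' @export
setGeneric("backgroundSize", function(x) standardGeneric("backgroundSize"))

#' @describeIn backgroundSize background of a signature.
#' @export
setMethod("backgroundSize", "GeneSignature", function(x) x@backgroundSize)

#' @describeIn backgroundSize common background of a comparison.
#' @export
setMethod("backgroundSize", "OverlapResult", function(x) x@backgroundSize)

#' @describeIn backgroundSize population of an enrichment run.
#' @export
setMethod("backgroundSize", "EnrichmentResult", function(x) x@backgroundSize)

#' Background gene identifiers of a signature
#' @param x a `GeneSignature`.
#' @return Character vector (length 0 when the ids are not tracked).
#' @export
setGeneric("backgroundIds", function(x) standardGeneric("backgroundIds"))

#' @describeIn backgroundIds ids of all tested genes.
#' @export
setMethod("backgroundIds", "GeneSignature", function(x) x@backgroundIds)

#' Per-gene entry table of a signature
#' @param x a `GeneSignature`.
#' @return data.frame in rank order.
#' @export
setGeneric("signatureEntries", function(x) standardGeneric("signatureEntries"))

#' @describeIn signatureEntries the ranked entry table.
#' @export
setMethod("signatureEntries", "GeneSignature", function(x) x@entries)

#' Directions of signature genes
#' @param x a `GeneSignature`.
#' @return Named character vector ("up"/"down") keyed by gene id.
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @describeIn directions named direction vector.
#' @export
setMethod("directions", "GeneSignature",
    function(x) stats::setNames(x@entries$direction, x@entries$gene_id))

#' Quadrant counts of an overlap
#' @param x an `OverlapResult`.
#' @return Named integer vector (uu, dd, ud, du).
#' @export
setGeneric("quadrantCounts", function(x) standardGeneric("quadrantCounts"))

#' @describeIn quadrantCounts the four direction-pair counts.
#' @export
setMethod("quadrantCounts", "OverlapResult", function(x) x@quadrants)

#' Total, concordant and discordant overlap counts
#' @param x an `OverlapResult`.
#' @return Integer count.
#' @export
setGeneric("overlapCount", function(x) standardGeneric("overlapCount"))

#' @describeIn overlapCount total shared genes.
#' @export
setMethod("overlapCount", "OverlapResult", function(x) sum(x@quadrants))

#' @rdname overlapCount
#' @export
setGeneric("concordantCount", function(x) standardGeneric("concordantCount"))

#' @describeIn overlapCount same-direction (uu + dd) genes.
#' @export
setMethod("concordantCount", "OverlapResult",
    function(x) unname(x@quadrants["uu"] + x@quadrants["dd"]))

#' @rdname overlapCount
#' @export
setGeneric("discordantCount", function(x) standardGeneric("discordantCount"))

#' @describeIn overlapCount opposite-direction (ud + du) genes.
#' @export
setMethod("discordantCount", "OverlapResult",
    function(x) unname(x@quadrants["ud"] + x@quadrants["du"]))

#' Running Fisher P-value of an overlap
#' @param x an `OverlapResult`.
#' @param log10 return the log10 P (stable below 1e-300) instead.
#' @return Numeric scalar.
#' @export
setGeneric("runningP", function(x, log10 = FALSE) standardGeneric("runningP"))

#' @describeIn runningP the min-scan corrected overlap P.
#' @export
setMethod("runningP", "OverlapResult", function(x, log10 = FALSE)
    if (log10) x@runningLog10P else x@runningP)

#' Direction-restricted overlap P-values
#' @param x an `OverlapResult`.
#' @return Named numeric vector (uu, dd, ud, du).
#' @export
setGeneric("quadrantP", function(x) standardGeneric("quadrantP"))

#' @describeIn quadrantP the four directional Running Fisher P-values.
#' @export
setMethod("quadrantP", "OverlapResult", function(x) x@quadrantP)

#' Concordance chi-square of an overlap
#' @param x an `OverlapResult`.
#' @return Named numeric vector `c(chi2 = , p = )`.
#' @export
setGeneric("chiSquare", function(x) standardGeneric("chiSquare"))

#' @describeIn chiSquare Pearson statistic and P against the 50 percent null.
#' @export
setMethod("chiSquare", "OverlapResult",
    function(x) c(chi2 = x@chi2, p = x@chi2P))

#' Shared-gene table of an overlap
#' @param x an `OverlapResult`.
#' @return data.frame with per-study statistics and quadrant assignment.
#' @export
setGeneric("overlapGenes", function(x) standardGeneric("overlapGenes"))

#' @describeIn overlapGenes the per-gene overlap table.
#' @export
setMethod("overlapGenes", "OverlapResult", function(x) x@genes)

#' Region counts of a Venn partition
#' @param x a `VennPartition`.
#' @return Named integer vector over the non-empty membership patterns.
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @describeIn regionCounts the 2^k - 1 region counts.
#' @export
setMethod("regionCounts", "VennPartition", function(x) x@regionCounts)

#' Unexplained remainder of a Venn partition
#' @param x a `VennPartition`.
#' @return Integer count of bioset genes in no reference.
#' @export
setGeneric("unexplainedCount", function(x) standardGeneric("unexplainedCount"))

#' @describeIn unexplainedCount genes outside every reference.
#' @export
setMethod("unexplainedCount", "VennPartition", function(x) x@unexplained)

#' Per-reference direction agreement of a Venn partition
#' @param x a `VennPartition`.
#' @return data.frame with `reference`, `overlap`, `concordant`, `discordant`.
#' @export
setGeneric("agreementTable", function(x) standardGeneric("agreementTable"))

#' @describeIn agreementTable the agreement tallies.
#' @export
setMethod("agreementTable", "VennPartition", function(x) x@agreement)

#' Result table of an enrichment run
#' @param x an `EnrichmentResult`.
#' @return data.frame sorted by raw P.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @describeIn enrichmentTable the per-set rows.
#' @export
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)
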