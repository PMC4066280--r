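## Gene-set over-representation: one-sided Fisher exact (hypergeometric
## upper tail) per set against the measured background, Benjamini-Hochberg
## adjusted across the collection. The background is the signature's tested
## universe, not the genome.

#' Gene-set over-representation of a bioset
#'
#' For each set in the collection, tests whether the bioset over-represents
#' the set's in-background members with the one-sided Fisher exact test
#' (equivalently the hypergeometric upper tail on the 2x2 membership table),
#' then adjusts across all tested sets with Benjamini-Hochberg. Sets with no
#' member in the background are skipped with a warning.
#'
#' @param bioset a [GeneSignature-class]; its background (ids when tracked,
#'   else `backgroundSize`) is the population.
#' @param collection a [GeneSetCollection-class].
#' @param backgroundSize override for the population size (required when the
#'   bioset does not track background ids and its `backgroundSize` should
#'   not be used). Must be at least the bioset size.
#' @return An [EnrichmentResult-class], rows sorted by raw P (ties by set
#'   name).
#' @examples
#' bio <- GeneSignature(paste0("G", 1:10), rep(2, 10), rep(0.01, 10),
#'                      backgroundIds = paste0("G", 1:100))
#' coll <- GeneSetCollection(list(hit = paste0("G", 1:8),
#'                                miss = paste0("G", 90:99)))
#' enrichmentTable(enrichSignature(bio, coll))
#' @export
enrichSignature <- function(bioset, collection, backgroundSize = NULL) {
    stopifnot(is(bioset, "GeneSignature"),
              is(collection, "GeneSetCollection"))
    if (length(collection@sets) == 0L)
        stop("empty gene-set collection")
    bgIds <- backgroundIds(bioset)
    if (is.null(backgroundSize))
        backgroundSize <- backgroundSize(bioset)
    n <- signatureSize(bioset)
    if (backgroundSize < n)
        stop("backgroundSize must be >= bioset size")
    bio <- geneIds(bioset)

    rows <- lapply(names(collection@sets), function(nm) {
        members <- collection@sets[[nm]]
        inBg <- if (length(bgIds)) intersect(members, bgIds) else members
        if (length(inBg) == 0L)
            return(NULL)
        k <- length(intersect(bio, inBg))
        m <- length(inBg)
        data.frame(set = nm, set_size = m, overlap = k,
                   p_value = hypergeomUpper(k, n, m, backgroundSize),
                   stringsAsFactors = FALSE)
    })
    skipped <- names(collection@sets)[vapply(rows, is.null, TRUE)]
    if (length(skipped))
        warning("set(s) with no background members skipped: ",
                paste(skipped, collapse = ", "))
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        stop("no gene set has members in the background")
    tab$p_adjust <- p.adjust(tab$p_value, method = "BH")
    tab <- tab[order(tab$p_value, tab$set), , drop = FALSE]
    rownames(tab) <- NULL
    new("EnrichmentResult", table = tab,
        backgroundSize = as.integer(backgroundSize),
        biosetSize = as.integer(n))
}
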