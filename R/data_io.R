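## Tabular IO (TSV matrices, signature tables, ortholog maps, GMT) and
## cross-species signature translation. All text formats are UTF-8,
## tab-delimited, with '#' comment lines ignored.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## Expression matrices
## ---------------------------------------------------------------------------

#' Build a two-group expression container
#'
#' Wraps a log2-scale gene-by-sample matrix and its two-group labeling into a
#' `SummarizedExperiment` (assay `exprs`, colData column `group`). The first
#' factor level of `groups` is the fold-change numerator downstream
#' ("young/disease" in the maturity analyses this package targets).
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required), log2 units, finite.
#' @param groups character or factor of length `ncol(values)` with exactly
#'   two levels; level order (or first appearance) fixes the numerator.
#' @return A `SummarizedExperiment`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("s", 1:4)))
#' makeExpressionMatrix(m, c("group1", "group1", "group2", "group2"))
#' @export
makeExpressionMatrix <- function(values, groups) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have row (gene) and column (sample) names")
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene id: ",
             rownames(values)[duplicated(rownames(values))][1L])
    if (anyDuplicated(colnames(values)))
        stop("duplicate sample id: ",
             colnames(values)[duplicated(colnames(values))][1L])
    if (!all(is.finite(values)))
        stop("non-finite expression values")
    if (!is.factor(groups))
        groups <- factor(groups, levels = unique(groups))
    if (length(groups) != ncol(values))
        stop("'groups' must label every sample column")
    if (nlevels(droplevels(groups)) != 2L)
        stop("exactly two non-empty groups required, got: ",
             paste(levels(droplevels(groups)), collapse = ", "))
    SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(group = groups, row.names = colnames(values)))
}

#' Read a log2 expression matrix and its sample labels
#'
#' The matrix TSV has gene ids in the first column and a header of sample
#' ids; the labels TSV has two columns, sample id and group. Errors name the
#' offending row/column.
#'
#' @param path matrix TSV path.
#' @param labelsPath two-column sample-label TSV path.
#' @return A `SummarizedExperiment` as from [makeExpressionMatrix()], row
#'   order preserved.
#' @export
readExpressionMatrix <- function(path, labelsPath) {
    tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L)
        stop("matrix file needs a gene-id column plus sample columns: ", path)
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate gene id in ", path, ": ", ids[duplicated(ids)][1L])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals),
                                       dimnames = list(ids, colnames(vals))))
    if (anyNA(storage)) {
        bad <- which(is.na(storage), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell in %s at gene '%s', sample '%s'",
                     path, ids[bad[1L]], colnames(storage)[bad[2L]]))
    }
    lab <- read.delim(labelsPath, header = TRUE, sep = "\t",
                      comment.char = "#", colClasses = "character")
    if (ncol(lab) < 2L)
        stop("labels file needs columns sample id, group: ", labelsPath)
    labMap <- stats::setNames(lab[[2L]], lab[[1L]])
    miss <- setdiff(colnames(storage), names(labMap))
    if (length(miss))
        stop("unlabeled sample column(s): ", paste(miss, collapse = ", "))
    groups <- labMap[colnames(storage)]
    makeExpressionMatrix(storage, factor(groups, levels = unique(lab[[2L]])))
}

#' Write an expression matrix and its labels as TSV
#'
#' Inverse of [readExpressionMatrix()]; values are written at full
#' double precision so a round trip is value-identical.
#'
#' @param se a `SummarizedExperiment` with assay `exprs` and colData `group`.
#' @param path matrix TSV destination.
#' @param labelsPath labels TSV destination.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(se, path, labelsPath) {
    vals <- assay(se, "exprs")
    tab <- data.frame(gene_id = rownames(vals),
                      format(vals, digits = 17, trim = TRUE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(tab) <- c("gene_id", colnames(vals))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    lab <- data.frame(sample_id = colnames(vals),
                      group = as.character(colData(se)$group))
    write.table(lab, labelsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Signature tables
## ---------------------------------------------------------------------------

#' Read a gene signature table
#'
#' Expects tab-separated columns `gene_id`, a fold-change column, and
#' `p_value`. The fold-change column name declares its dialect:
#' `fold_change_linear` for positive ratios (0.5 means 2-fold down) or
#' `fold_change_signed` for the negative-reciprocal display convention
#' (-2.0 means 2-fold down). Comment lines starting `#` may carry
#' `key=value` metadata; `background_size`, `fc_cut` and `p_cut` are honored.
#'
#' @param path signature TSV path.
#' @param name signature label (defaults to the file name).
#' @return A [GeneSignature-class]; an empty table yields a valid empty
#'   signature.
#' @export
readSignatureTable <- function(path, name = NULL) {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, encoding = "UTF-8")
    meta <- list()
    for (cl in grep("^#", lines, value = TRUE)) {
        m <- regmatches(cl, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", cl))[[1L]]
        if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
    }
    tab <- read.delim(text = lines, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    fcCut <- if (!is.null(meta$fc_cut)) as.numeric(meta$fc_cut) else 1.2
    pCut <- if (!is.null(meta$p_cut)) as.numeric(meta$p_cut) else 0.05
    bg <- if (!is.null(meta$background_size))
        as.integer(meta$background_size) else NULL
    if (!("gene_id" %in% colnames(tab)))
        stop("missing column 'gene_id' in ", path)
    if (!("p_value" %in% colnames(tab)))
        stop("missing column 'p_value' in ", path)
    dialect <- intersect(c("fold_change_linear", "fold_change_signed"),
                         colnames(tab))
    if (length(dialect) != 1L)
        stop("signature table must declare exactly one fold-change dialect ",
             "column (fold_change_linear or fold_change_signed): ", path)
    if (nrow(tab) == 0L)
        return(.emptySignature(if (is.null(bg)) 0L else bg,
                               fcCut = fcCut, pCut = pCut, name = name))
    p <- as.numeric(tab$p_value)
    if (anyNA(p) || any(p <= 0) || any(p > 1))
        stop("p_value outside (0, 1] in ", path)
    fc <- as.numeric(tab[[dialect]])
    if (dialect == "fold_change_linear") {
        if (anyNA(fc) || any(fc <= 0))
            stop("linear fold change must be positive in ", path)
        lfc <- fc
    } else {
        if (anyNA(fc) || any(abs(fc) < 1))
            stop("signed display fold change must have |FC| >= 1 in ", path)
        lfc <- ifelse(fc >= 0, fc, -1 / fc)
    }
    GeneSignature(tab$gene_id, lfc, p,
                  backgroundSize = if (is.null(bg)) nrow(tab) else bg,
                  fcCut = fcCut, pCut = pCut, name = name)
}

#' Write a gene signature table
#'
#' @param sig a [GeneSignature-class].
#' @param path destination TSV.
#' @param dialect `"signed"` (negative-reciprocal display, the default) or
#'   `"linear"`.
#' @return Invisibly, `path`.
#' @export
writeSignatureTable <- function(sig, path,
                                dialect = c("signed", "linear")) {
    dialect <- match.arg(dialect)
    e <- signatureEntries(sig)
    hdr <- c(sprintf("# background_size=%d", backgroundSize(sig)),
             sprintf("# fc_cut=%g", sig@fcCut),
             sprintf("# p_cut=%g", sig@pCut))
    tab <- data.frame(gene_id = e$gene_id, stringsAsFactors = FALSE)
    if (dialect == "signed") {
        tab$fold_change_signed <- e$display_fc
    } else {
        tab$fold_change_linear <- e$linear_fc
    }
    tab$p_value <- e$p_value
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    suppressWarnings(write.table(
        format(tab, digits = 17, trim = TRUE), con, sep = "\t",
        quote = FALSE, row.names = FALSE, append = TRUE))
    invisible(path)
}

## ---------------------------------------------------------------------------
## Ortholog maps
## ---------------------------------------------------------------------------

#' Read / write a two-column ortholog map
#'
#' @param path TSV with header columns `source`, `target`.
#' @return An [OrthologMap-class].
#' @export
readOrthologMap <- function(path) {
    tab <- read.delim(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% colnames(tab)))
        stop("ortholog map needs columns 'source' and 'target': ", path)
    OrthologMap(tab$source, tab$target)
}

#' @rdname readOrthologMap
#' @param map an [OrthologMap-class].
#' @export
writeOrthologMap <- function(map, path) {
    write.table(map@pairs, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Translate a signature across species via an ortholog map
#'
#' Each source gene with at least one target mapping is emitted under the
#' target id; unmapped genes are dropped (reported via a message, not an
#' error). 1:many fan-outs keep a single deterministic target (lexicographic
#' smallest, since per-gene statistics are identical across a fan-out);
#' many:1 collisions keep the source entry with the smallest P, ties broken
#' by larger |display FC|, then lexicographic source id. Per-gene statistics
#' are carried unchanged. The background becomes the distinct target ids
#' reachable from the mapped background (target-namespace population), so the
#' translated background never exceeds the original.
#'
#' @param sig a [GeneSignature-class].
#' @param map an [OrthologMap-class] (non-empty).
#' @return The translated `GeneSignature`.
#' @export
translateSignature <- function(sig, map) {
    stopifnot(is(sig, "GeneSignature"), is(map, "OrthologMap"))
    pairs <- map@pairs
    if (nrow(pairs) == 0L)
        stop("empty ortholog map")
    ## 1:many policy: one deterministic target per source
    pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
    first <- !duplicated(pairs$source)
    lookup <- stats::setNames(pairs$target[first], pairs$source[first])

    e <- signatureEntries(sig)
    nIn <- nrow(e)
    mapped <- e$gene_id %in% names(lookup)
    nDropped <- sum(!mapped)
    e <- e[mapped, , drop = FALSE]
    e$source_id <- e$gene_id
    e$gene_id <- unname(lookup[e$gene_id])
    ## many:1 policy: best evidence (smallest P, then |FC|, then source id)
    if (anyDuplicated(e$gene_id)) {
        e <- e[order(e$p_value, -abs(e$display_fc), e$source_id), ,
               drop = FALSE]
        e <- e[!duplicated(e$gene_id), , drop = FALSE]
    }

    bgIds <- backgroundIds(sig)
    if (length(bgIds)) {
        newBg <- sort(unique(unname(lookup[intersect(bgIds,
                                                     names(lookup))])))
        newBgSize <- length(newBg)
    } else {
        newBg <- character()
        newBgSize <- min(backgroundSize(sig),
                         length(unique(pairs$target[first])))
    }
    message(sprintf(
        "translate[%s]: in=%d out=%d dropped=%d collapsed=%d background %d -> %d",
        sig@name, nIn, nrow(e), nDropped, nIn - nDropped - nrow(e),
        backgroundSize(sig), newBgSize))
    if (nrow(e) == 0L)
        return(.emptySignature(newBgSize, newBg, sig@fcCut, sig@pCut,
                               sig@name))
    extraCols <- setdiff(colnames(e), .SIG_COLS)
    GeneSignature(e$gene_id, e$linear_fc, e$p_value,
                  backgroundSize = newBgSize, backgroundIds = newBg,
                  fcCut = sig@fcCut, pCut = sig@pCut, name = sig@name,
                  extra = e[, extraCols, drop = FALSE])
}

## ---------------------------------------------------------------------------
## GMT
## ---------------------------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Broad-convention GMT: per line a set name, a description, then
#' tab-separated members. Repeated members within a set are de-duplicated
#' with a warning; duplicate set names or member-less sets are errors.
#'
#' @param path GMT path.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate set name in ", path, ": ", nm[duplicated(nm)][1L])
    desc <- vapply(fields, function(f)
        if (length(f) >= 2L) f[2L] else "", "")
    sets <- lapply(fields, function(f) {
        members <- f[-(1:2)]
        members[nzchar(members)]
    })
    if (any(lengths(sets) == 0L))
        stop("set with empty member list in ", path, ": ",
             nm[lengths(sets) == 0L][1L])
    dup <- vapply(sets, anyDuplicated, 1L) > 0L
    if (any(dup)) {
        warning("de-duplicated repeated members in set(s): ",
                paste(nm[dup], collapse = ", "))
        sets <- lapply(sets, unique)
    }
    names(sets) <- nm
    GeneSetCollection(sets, desc)
}

#' Write a GMT gene-set collection
#'
#' @param collection a [GeneSetCollection-class].
#' @param path destination.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(collection, path) {
    lines <- vapply(seq_along(collection@sets), function(i)
        paste(c(names(collection@sets)[i], collection@descriptions[i],
                collection@sets[[i]]), collapse = "\t"), "")
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
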