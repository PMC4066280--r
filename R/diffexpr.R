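## Signature extraction from a two-group log2 expression matrix: per-gene
## pooled-variance Student t and fold change on anti-logged group means,
## filtered at |display FC| > fcCut and P < pCut (strict inequalities, no
## multiple-testing correction at this stage).

#' Row-wise pooled-variance two-sample t statistics
#'
#' Vectorised Student t (equal-variance, two-sided) over a matrix split into
#' two sample groups. Degenerate rows (zero pooled variance) get P = 1 when
#' the group means are equal, otherwise the smallest representable positive
#' double, with a `degenerate` flag.
#'
#' @noRd
.rowTTest <- function(vals, idx1, idx2) {
    n1 <- length(idx1); n2 <- length(idx2)
    m1 <- rowMeans(vals[, idx1, drop = FALSE])
    m2 <- rowMeans(vals[, idx2, drop = FALSE])
    ss1 <- rowSums((vals[, idx1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((vals[, idx2, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    s2p <- (ss1 + ss2) / df
    se <- sqrt(s2p * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    p <- 2 * pt(-abs(tstat), df)
    degenerate <- se == 0
    p[degenerate & m1 == m2] <- 1
    p[degenerate & m1 != m2] <- .Machine$double.xmin
    p[p == 0] <- .Machine$double.xmin  # continuous-case underflow guard
    data.frame(fold_change = 2^(m1 - m2), p_value = p,
               mean_diff = m1 - m2, degenerate = degenerate,
               stringsAsFactors = FALSE)
}

#' Two-group fold change and t-test
#'
#' Computes, per gene, the linear fold change `2^(mean log2 group1 - mean
#' log2 group2)` and the two-sided pooled-variance Student t-test P-value.
#' The numerator group is the first factor level of the matrix's `group`
#' column.
#'
#' @param se a `SummarizedExperiment` from [makeExpressionMatrix()] /
#'   [readExpressionMatrix()]; both groups need at least 2 samples.
#' @param gene optional single gene id; when given, a list
#'   `(foldChange, pValue)` for that gene is returned instead of the full
#'   table.
#' @return data.frame with `gene_id`, `fold_change` (linear), `p_value`,
#'   `mean_diff` (log2), and a `degenerate` flag for zero-variance rows; or
#'   the per-gene list when `gene` is supplied.
#' @examples
#' sim <- generatePairedStudies(syntheticConfig(nGenes = 50, seed = 1))
#' head(twoGroupTest(sim$studyA))
#' @export
twoGroupTest <- function(se, gene = NULL) {
    vals <- assay(se, "exprs")
    groups <- colData(se)$group
    idx1 <- which(groups == levels(groups)[1L])
    idx2 <- which(groups == levels(groups)[2L])
    if (length(idx1) < 2L || length(idx2) < 2L)
        stop("each group needs at least 2 samples")
    res <- .rowTTest(vals, idx1, idx2)
    res <- cbind(gene_id = rownames(vals), res, stringsAsFactors = FALSE)
    rownames(res) <- NULL
    if (!is.null(gene)) {
        row <- res[res$gene_id == gene, ]
        if (nrow(row) != 1L) stop("unknown gene: ", gene)
        return(list(foldChange = row$fold_change, pValue = row$p_value,
                    degenerate = row$degenerate))
    }
    res
}

#' Extract a differential-expression signature
#'
#' Applies the joint filter |display fold change| > `fcCut` and P < `pCut`
#' (both strict) to the two-group test table and returns the passing genes as
#' a ranked [GeneSignature-class] whose background is the full set of tested
#' genes.
#'
#' @param se a two-group `SummarizedExperiment`.
#' @param fcCut fold-change threshold (> 1), e.g. 1.2 for whole-tissue or
#'   1.5 for sorted-cell-type comparisons.
#' @param pCut P-value threshold in (0, 1).
#' @param name signature label.
#' @return A [GeneSignature-class].
#' @examples
#' sim <- generatePairedStudies(syntheticConfig(nGenes = 200, seed = 1))
#' extractSignature(sim$studyA, name = "studyA")
#' @export
extractSignature <- function(se, fcCut = 1.2, pCut = 0.05,
                             name = "signature") {
    if (!is.numeric(fcCut) || fcCut <= 1)
        stop("'fcCut' must be > 1")
    if (!is.numeric(pCut) || pCut <= 0 || pCut >= 1)
        stop("'pCut' must be in (0, 1)")
    tab <- twoGroupTest(se)
    disp <- ifelse(tab$fold_change >= 1, tab$fold_change,
                   -1 / tab$fold_change)
    pass <- abs(disp) > fcCut & tab$p_value < pCut
    bg <- tab$gene_id
    if (!any(pass))
        return(.emptySignature(length(bg), bg, fcCut, pCut, name))
    GeneSignature(tab$gene_id[pass], tab$fold_change[pass],
                  tab$p_value[pass],
                  backgroundIds = bg, fcCut = fcCut, pCut = pCut,
                  name = name)
}
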