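## End-to-end orchestration from a declarative YAML config: signature
## extraction or loading, optional ortholog translation, all declared pair
## comparisons, bioset construction, cell-type Venn decomposition, gene-set
## enrichment, and a machine-readable JSON report plus a line-oriented log.

#' Build the positive-correlation bioset of an overlap
#'
#' The genes that changed in the same direction in both compared conditions
#' (the uu and dd quadrants), carrying both studies' statistics; study-A
#' statistics define the ranks. This is the gene set fed to the cell-type
#' contribution and enrichment stages.
#'
#' @param overlap an [OverlapResult-class].
#' @param name label for the bioset (defaults to
#'   `"bioset:<nameA>|<nameB>"`).
#' @return A [GeneSignature-class] over the comparison's common background
#'   (empty, with a warning, when there are no concordant genes).
#' @examples
#' sim <- generatePairedStudies(syntheticConfig(nGenes = 500, seed = 1))
#' ov <- compareSignatures(extractSignature(sim$studyA, name = "A"),
#'                         extractSignature(sim$studyB, name = "B"))
#' makeBioset(ov)
#' @export
makeBioset <- function(overlap, name = NULL) {
    stopifnot(is(overlap, "OverlapResult"))
    if (is.null(name))
        name <- paste0("bioset:", overlap@nameA, "|", overlap@nameB)
    g <- overlapGenes(overlap)
    g <- g[g$quadrant %in% c("uu", "dd"), , drop = FALSE]
    if (nrow(g) == 0L) {
        warning("no concordant genes; bioset is empty")
        return(.emptySignature(backgroundSize(overlap), name = name))
    }
    GeneSignature(g$gene_id, g$linear_fc_a, g$p_a,
                  backgroundSize = backgroundSize(overlap),
                  name = name,
                  extra = data.frame(linear_fc_b = g$linear_fc_b,
                                     p_b = g$p_b,
                                     stringsAsFactors = FALSE))
}

#' Read and validate a pipeline run configuration
#'
#' YAML schema:
#' \preformatted{
#' studies:
#'   - name: devDLFC
#'     matrix: dev_matrix.tsv      # with labels:, or
#'     labels: dev_labels.tsv
#'     fc_cut: 1.2                 # optional, default 1.2
#'     p_cut: 0.05                 # optional, default 0.05
#'   - name: sz
#'     signature: sz_signature.tsv # precomputed table
#' comparisons:
#'   - [devDLFC, sz]
#' ortholog_map: map.tsv           # optional
#' translate: [sz]                 # studies translated through the map
#' references:                     # optional, <= 3
#'   FS: fs_signature.tsv
#' gmt: pathways.gmt               # optional
#' out_dir: results
#' seed: 1
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param path YAML config path.
#' @return The validated config as a list (paths resolved, defaults filled).
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    resolve <- function(p)
        if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    if (is.null(cfg$studies) || length(cfg$studies) == 0L)
        stop("config: no studies declared")
    names(cfg$studies) <- vapply(cfg$studies, function(s) {
        if (is.null(s$name)) stop("config: study without a name")
        s$name
    }, "")
    if (anyDuplicated(names(cfg$studies)))
        stop("config: duplicate study names")
    cfg$studies <- lapply(cfg$studies, function(s) {
        if (!is.null(s$matrix)) {
            if (is.null(s$labels))
                stop("config: study '", s$name, "' has a matrix but no labels")
            s$matrix <- resolve(s$matrix); s$labels <- resolve(s$labels)
        } else if (!is.null(s$signature)) {
            s$signature <- resolve(s$signature)
        } else {
            stop("config: study '", s$name,
                 "' needs either matrix+labels or signature")
        }
        if (is.null(s$fc_cut)) s$fc_cut <- 1.2
        if (is.null(s$p_cut)) s$p_cut <- 0.05
        s
    })
    if (is.null(cfg$comparisons) || length(cfg$comparisons) == 0L)
        stop("config: no comparison pairs declared")
    for (pair in cfg$comparisons) {
        if (length(pair) != 2L || !all(unlist(pair) %in% names(cfg$studies)))
            stop("config: comparison pair must name two declared studies: ",
                 paste(unlist(pair), collapse = ", "))
    }
    for (field in c("ortholog_map", "gmt"))
        if (!is.null(cfg[[field]])) cfg[[field]] <- resolve(cfg[[field]])
    if (!is.null(cfg$references)) {
        if (length(cfg$references) > 3L)
            stop("config: at most 3 reference signatures")
        cfg$references <- lapply(cfg$references, resolve)
    }
    declared <- c(unlist(lapply(cfg$studies, function(s)
                      c(s$matrix, s$labels, s$signature))),
                  cfg$ortholog_map, cfg$gmt, unlist(cfg$references))
    missing <- declared[!file.exists(declared)]
    if (length(missing))
        stop("config: missing input file(s): ",
             paste(missing, collapse = ", "))
    if (is.null(cfg$seed)) cfg$seed <- 1L
    if (is.null(cfg$out_dir)) cfg$out_dir <- "pipeline_out"
    if (!grepl("^(/|[A-Za-z]:)", cfg$out_dir))
        cfg$out_dir <- file.path(base, cfg$out_dir)
    cfg
}

#' @noRd
.pipelineLog <- function(con, stage, msg) {
    line <- sprintf("%s [%s] %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), stage, msg)
    writeLines(line, con)
}

#' Run the full comparison pipeline
#'
#' Executes every declared pair comparison (extraction or loading,
#' optional ortholog translation, background intersection, overlap and
#' concordance statistics, bioset construction), then — when configured —
#' the cell-type Venn decomposition and gene-set enrichment of each bioset.
#' Writes `report.json` (deterministic: re-running the same config and
#' inputs reproduces it byte-for-byte) and a timestamped `run.log` to the
#' output directory; any stage error removes partial outputs and aborts with
#' a stage-tagged message.
#'
#' @param config a config path or the list returned by [readRunConfig()].
#' @param outDir optional override of the config's output directory.
#' @return Invisibly, the report list (per-pair overlap summaries, Venn
#'   partitions, enrichment tables, the Bonferroni ledger, software version
#'   and config echo).
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config))
        config <- readRunConfig(config)
    if (!is.null(outDir)) config$out_dir <- outDir
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    reportPath <- file.path(config$out_dir, "report.json")
    logPath <- file.path(config$out_dir, "run.log")
    logCon <- file(logPath, "w")
    failed <- TRUE
    on.exit({
        close(logCon)
        if (failed) unlink(c(reportPath, logPath))
    })
    set.seed(config$seed)

    runStage <- function(stage, expr) {
        tryCatch(expr, error = function(e) {
            .pipelineLog(logCon, stage, paste("ERROR:", conditionMessage(e)))
            stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
        })
    }

    sigs <- runStage("extract", {
        lapply(config$studies, function(s) {
            if (!is.null(s$matrix)) {
                se <- readExpressionMatrix(s$matrix, s$labels)
                sig <- extractSignature(se, s$fc_cut, s$p_cut, name = s$name)
                .pipelineLog(logCon, "extract", sprintf(
                    "%s: in=%d out=%d dropped=%d",
                    s$name, backgroundSize(sig), signatureSize(sig),
                    backgroundSize(sig) - signatureSize(sig)))
            } else {
                sig <- readSignatureTable(s$signature, name = s$name)
                .pipelineLog(logCon, "load", sprintf(
                    "%s: %d entries, background %d", s$name,
                    signatureSize(sig), backgroundSize(sig)))
            }
            sig
        })
    })

    map <- NULL
    if (!is.null(config$ortholog_map)) {
        map <- runStage("orthologs", readOrthologMap(config$ortholog_map))
        for (nm in config$translate %||% character()) {
            sigs[[nm]] <- runStage("translate", withCallingHandlers(
                translateSignature(sigs[[nm]], map),
                message = function(m) {
                    .pipelineLog(logCon, "translate",
                                 sub("\n$", "", conditionMessage(m)))
                    invokeRestart("muffleMessage")
                }))
        }
    }

    refs <- NULL
    if (!is.null(config$references))
        refs <- runStage("references", {
            r <- lapply(config$references, readSignatureTable)
            for (i in seq_along(r)) r[[i]]@name <- names(config$references)[i]
            r
        })
    gmt <- if (!is.null(config$gmt)) runStage("gmt", readGmt(config$gmt))

    ledger <- bonferroniLedger(length(config$comparisons))
    pairReports <- list()
    for (pair in config$comparisons) {
        a <- pair[[1L]]; b <- pair[[2L]]
        key <- paste0(a, "|", b)
        ov <- runStage("overlap",
                       suppressWarnings(compareSignatures(
                           sigs[[a]], sigs[[b]],
                           nDatasetPairs = length(config$comparisons))))
        .pipelineLog(logCon, "overlap", sprintf(
            "%s: overlap=%d concordant=%d discordant=%d runningP=%.3g",
            key, overlapCount(ov), concordantCount(ov), discordantCount(ov),
            runningP(ov)))
        bio <- runStage("bioset", suppressWarnings(makeBioset(ov)))
        .pipelineLog(logCon, "bioset", sprintf(
            "%s: in=%d out=%d dropped=%d", key, overlapCount(ov),
            signatureSize(bio), overlapCount(ov) - signatureSize(bio)))
        rep <- list(
            pair = c(a, b),
            n_a = ov@nA, n_b = ov@nB,
            background = backgroundSize(ov),
            quadrants = as.list(quadrantCounts(ov)),
            quadrant_p = as.list(quadrantP(ov)),
            running_p = runningP(ov),
            running_log10p = runningP(ov, log10 = TRUE),
            concordant = concordantCount(ov),
            discordant = discordantCount(ov),
            chi2 = ov@chi2, chi2_p = ov@chi2P,
            bioset_size = signatureSize(bio))
        if (!is.null(refs) && signatureSize(bio) > 0L) {
            part <- runStage("contribute", withCallingHandlers(
                partitionBioset(bio, refs, map = map),
                warning = function(w) {
                    .pipelineLog(logCon, "contribute",
                                 paste("WARN:", conditionMessage(w)))
                    invokeRestart("muffleWarning")
                }))
            rep$venn <- list(
                regions = as.list(regionCounts(part)),
                unexplained = unexplainedCount(part),
                agreement = agreementTable(part),
                percentages = contributionPercentages(part))
        }
        if (!is.null(gmt) && signatureSize(bio) > 0L) {
            enr <- runStage("enrich", suppressWarnings(
                enrichSignature(bio, gmt)))
            rep$enrichment <- enrichmentTable(enr)
        }
        pairReports[[key]] <- rep
    }

    report <- list(
        software = paste0("SignatureOverlap ",
                          as.character(packageVersion("SignatureOverlap"))),
        seed = config$seed,
        bonferroni = list(n_dataset_pairs = length(config$comparisons),
                          alpha_pairs = ledger$alphaPairs,
                          alpha_directions = ledger$alphaDirections),
        comparisons = pairReports,
        ## config echo: inputs only — the output location is not part of
        ## the reproducibility contract
        config = config[setdiff(names(config), "out_dir")])
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    .pipelineLog(logCon, "report", paste("written", reportPath))
    failed <- FALSE
    invisible(report)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
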