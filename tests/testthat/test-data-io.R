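test_that("expression matrices round-trip through TSV", {
    sim <- generatePairedStudies(syntheticConfig(nGenes = 40, nPerGroup = 3,
                                                 seed = 4))
    f <- tmpfile(); l <- tmpfile()
    writeExpressionMatrix(sim$studyA, f, l)
    back <- readExpressionMatrix(f, l)
    expect_equal(SummarizedExperiment::assay(back),
                 SummarizedExperiment::assay(sim$studyA))
    expect_identical(as.character(SummarizedExperiment::colData(back)$group),
                     as.character(SummarizedExperiment::colData(sim$studyA)$group))
})

test_that("matrix reader reports duplicate ids, unlabeled samples and bad cells", {
    f <- tmpfile(); l <- tmpfile()
    writeLines(c("gene_id\ts1\ts2\ts3\ts4",
                 "G1\t1\t2\t3\t4", "G1\t5\t6\t7\t8"), f)
    writeLines(c("sample_id\tgroup", "s1\tg1", "s2\tg1", "s3\tg2", "s4\tg2"),
               l)
    expect_error(readExpressionMatrix(f, l), "G1")
    writeLines(c("gene_id\ts1\ts2\ts3\ts4",
                 "G1\t1\t2\t3\t4", "G2\t5\tok\t7\t8"), f)
    expect_error(readExpressionMatrix(f, l), "gene 'G2', sample 's2'")
    writeLines(c("gene_id\ts1\ts2\ts3\ts4",
                 "G1\t1\t2\t3\t4", "G2\t5\t6\t7\t8"), f)
    writeLines(c("sample_id\tgroup", "s1\tg1", "s2\tg1", "s3\tg2"), l)
    expect_error(readExpressionMatrix(f, l), "s4")
    writeLines(c("sample_id\tgroup", "s1\tg1", "s2\tg1", "s3\tg1", "s4\tg1"),
               l)
    expect_error(readExpressionMatrix(f, l), "two")
    ## 3 x 4 fixture parses with groups {2, 2}
    writeLines(c("sample_id\tgroup", "s1\tg1", "s2\tg1", "s3\tg2", "s4\tg2"),
               l)
    writeLines(c("# a comment", "gene_id\ts1\ts2\ts3\ts4",
                 "G1\t1\t2\t3\t4", "G2\t5\t6\t7\t8", "G3\t1\t1\t1\t1"), f)
    se <- readExpressionMatrix(f, l)
    expect_identical(dim(se), c(3L, 4L))
    expect_identical(as.integer(table(SummarizedExperiment::colData(se)$group)),
                     c(2L, 2L))
})

test_that("signature tables honor both fold-change dialects", {
    f <- tmpfile()
    writeLines(c("gene_id\tfold_change_linear\tp_value",
                 "G1\t0.5\t0.01", "G2\t2.0\t0.02"), f)
    sig <- readSignatureTable(f)
    e <- signatureEntries(sig)
    expect_equal(e$display_fc[e$gene_id == "G1"], -2.0)
    expect_identical(e$direction[e$gene_id == "G1"], "down")
    writeLines(c("gene_id\tfold_change_signed\tp_value",
                 "G1\t-2.0\t0.01", "G2\t2.0\t0.02"), f)
    sig2 <- readSignatureTable(f)
    e2 <- signatureEntries(sig2)
    expect_equal(e2$linear_fc[e2$gene_id == "G1"], 0.5)
    expect_identical(e2$direction[e2$gene_id == "G1"], "down")
    ## round trip in each dialect preserves values
    for (d in c("signed", "linear")) {
        g <- tmpfile()
        writeSignatureTable(sig, g, dialect = d)
        back <- readSignatureTable(g)
        expect_equal(signatureEntries(back)$linear_fc, e$linear_fc)
        expect_equal(signatureEntries(back)$p_value, e$p_value)
        expect_identical(backgroundSize(back), backgroundSize(sig))
    }
})

test_that("signature reader rejects malformed tables and accepts empty ones", {
    f <- tmpfile()
    writeLines(c("gene_id\tp_value", "G1\t0.01"), f)
    expect_error(readSignatureTable(f), "dialect")
    writeLines(c("gene_id\tfold_change_linear\tp_value", "G1\t-0.5\t0.01"), f)
    expect_error(readSignatureTable(f), "positive")
    writeLines(c("gene_id\tfold_change_linear\tp_value", "G1\t0.5\t1.5"), f)
    expect_error(readSignatureTable(f), "p_value")
    writeLines("gene_id\tfold_change_linear\tp_value", f)
    expect_identical(signatureSize(readSignatureTable(f)), 0L)
})

test_that("ortholog translation follows the deterministic collapse policy", {
    bg <- paste0("S", 1:12)
    sig <- GeneSignature(paste0("S", 1:10),
                         c(2, 0.5, 3, 2, 0.25, 2, 2, 0.5, 4, 2),
                         c(0.001, 0.002, 0.003, 0.004, 0.005,
                           0.006, 0.007, 0.008, 0.009, 0.010),
                         backgroundIds = bg, name = "src")
    ## identity map: unchanged gene set, idempotent
    idMap <- OrthologMap(bg, bg)
    t1 <- suppressMessages(translateSignature(sig, idMap))
    expect_setequal(geneIds(t1), geneIds(sig))
    expect_equal(signatureEntries(t1)$p_value, signatureEntries(sig)$p_value)
    t2 <- suppressMessages(translateSignature(t1, idMap))
    expect_identical(signatureEntries(t2), signatureEntries(t1))
    ## missing gene dropped, reported in the translation log
    noS3 <- OrthologMap(setdiff(bg, "S3"), paste0("T", seq_len(11)))
    expect_message(tr <- translateSignature(sig, noS3), "dropped=1")
    expect_false(any(grepl("S3", geneIds(tr))))
    expect_identical(signatureSize(tr), 9L)
    ## 1:2 fan-out keeps one deterministic target (hand enumeration):
    ## S1 -> {T1a, T1b}; lexicographically T1a wins; other genes map 1:1.
    fan <- OrthologMap(c("S1", bg), c("T1b", paste0("T", 1:12)))
    tf <- suppressMessages(translateSignature(sig, fan))
    expect_identical(signatureSize(tf), 10L)
    expect_true("T1" %in% geneIds(tf))
    expect_false("T1b" %in% geneIds(tf))
    ## many:1 collision keeps the smallest-P source: S1 (p=.001) vs S2 (.002)
    coll <- OrthologMap(bg, c("T", "T", paste0("T", 3:12)))
    tc <- suppressMessages(translateSignature(sig, coll))
    eT <- signatureEntries(tc)
    expect_equal(eT$p_value[eT$gene_id == "T"], 0.001)
    expect_identical(signatureSize(tc), 9L)
    ## background size never grows under translation
    expect_lte(backgroundSize(tc), backgroundSize(sig))
    expect_lte(backgroundSize(tr), backgroundSize(sig))
    ## inverse of a 1:1 map recovers the original gene set
    inv <- OrthologMap(paste0("T", 1:11), setdiff(bg, "S3"))
    rec <- suppressMessages(translateSignature(tr, inv))
    expect_setequal(geneIds(rec), setdiff(geneIds(sig), "S3"))
})

test_that("GMT collections parse, validate and round-trip", {
    f <- tmpfile(".gmt")
    writeLines(c("setA\tdesc A\tG1\tG2\tG3", "setB\t\tG4\tG5"), f)
    coll <- readGmt(f)
    expect_length(geneIds(coll), 2)
    expect_identical(geneIds(coll)$setA, c("G1", "G2", "G3"))
    g <- tmpfile(".gmt")
    writeGmt(coll, g)
    expect_identical(geneIds(readGmt(g)), geneIds(coll))
    ## repeated member de-duplicated with a warning
    writeLines(c("setA\td\tG1\tG1\tG2"), f)
    expect_warning(collDup <- readGmt(f), "setA")
    expect_identical(collDup@sets$setA, c("G1", "G2"))
    ## duplicate set name / empty member list are errors
    writeLines(c("setA\td\tG1", "setA\td\tG2"), f)
    expect_error(readGmt(f), "duplicate")
    writeLines(c("setA\td"), f)
    expect_error(readGmt(f), "empty")
})
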