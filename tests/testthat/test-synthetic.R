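test_that("invalid configurations are rejected naming the field", {
    expect_error(syntheticConfig(nGenes = 5), "nGenes")
    expect_error(syntheticConfig(nPerGroup = 2), "nPerGroup")
    expect_error(syntheticConfig(fracDE = 1.2), "fracDE")
    expect_error(syntheticConfig(concordance = -0.1), "concordance")
    expect_error(syntheticConfig(effectSize = 0), "effectSize")
    expect_error(syntheticConfig(noiseSd = -1), "noiseSd")
    expect_error(syntheticConfig(downBias = 2), "downBias")
})

test_that("identical seed and config give byte-identical serialized output", {
    cfg <- syntheticConfig(nGenes = 100, nPerGroup = 4, seed = 11)
    s1 <- generatePairedStudies(cfg)
    s2 <- generatePairedStudies(cfg)
    f1 <- tmpfile(); f2 <- tmpfile(); l1 <- tmpfile(); l2 <- tmpfile()
    writeExpressionMatrix(s1$studyA, f1, l1)
    writeExpressionMatrix(s2$studyA, f2, l2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(s1$truth, s2$truth)
    s3 <- generatePairedStudies(syntheticConfig(nGenes = 100, nPerGroup = 4,
                                                seed = 12))
    expect_false(identical(
        SummarizedExperiment::assay(s1$studyA),
        SummarizedExperiment::assay(s3$studyA)))
})

test_that("full concordance with strong effects makes every A-DE gene B-DE with the same sign", {
    cfg <- syntheticConfig(nGenes = 300, concordance = 1, effectSize = 2,
                           noiseSd = 0.01, seed = 5)
    sim <- generatePairedStudies(cfg)
    tr <- sim$truth
    de <- tr$effect_a != 0
    expect_true(all(tr$label[de] == "concordant"))
    expect_true(all(sign(tr$effect_b[de]) == sign(tr$effect_a[de])))
    expect_true(all(tr$effect_b[de] != 0))
})

test_that("fracDE = 0 yields an all-null ground truth and empty signatures", {
    cfg <- syntheticConfig(nGenes = 200, fracDE = 0, noiseSd = 0.01, seed = 2)
    sim <- generatePairedStudies(cfg)
    expect_true(all(sim$truth$label == "null"))
    expect_identical(signatureSize(extractSignature(sim$studyA)), 0L)
})

test_that("ground-truth concordant fraction matches the config within rounding", {
    for (conc in c(0.3, 0.5, 0.8)) {
        cfg <- syntheticConfig(nGenes = 1000, concordance = conc, seed = 9)
        tr <- generatePairedStudies(cfg)$truth
        nDE <- sum(tr$effect_a != 0)
        expect_lte(abs(sum(tr$label == "concordant") / nDE - conc), 1 / nDE)
    }
})

test_that("recovered DE genes show the configured concordant fraction (binomial band)", {
    cfg <- syntheticConfig(nGenes = 2000, nPerGroup = 10, fracDE = 0.2,
                           concordance = 0.8, effectSize = 1.0, noiseSd = 0.5,
                           seed = 7)
    sim <- generatePairedStudies(cfg)
    a <- extractSignature(sim$studyA, name = "A")
    b <- extractSignature(sim$studyB, name = "B")
    ov <- compareSignatures(a, b)
    n <- overlapCount(ov)
    k <- concordantCount(ov)
    expect_gte(k, qbinom(0.025, n, 0.8))
    expect_lte(k, qbinom(0.975, n, 0.8))
    ## oracle: the ground-truth labels of the recovered overlap agree
    lab <- sim$truth$label[match(overlapGenes(ov)$gene_id,
                                 sim$truth$gene_id)]
    sameDir <- overlapGenes(ov)$quadrant %in% c("uu", "dd")
    trueDE <- lab %in% c("concordant", "discordant")
    expect_gt(mean((lab == "concordant")[trueDE] == sameDir[trueDE]), 0.95)
})

test_that("concordance estimate bias shrinks as group size grows", {
    biasAt <- function(m) {
        est <- vapply(1:8, function(s) {
            cfg <- syntheticConfig(nGenes = 1000, nPerGroup = m,
                                   concordance = 0.7, seed = 100 + s)
            sim <- generatePairedStudies(cfg)
            ov <- compareSignatures(extractSignature(sim$studyA),
                                    extractSignature(sim$studyB))
            concordantCount(ov) / overlapCount(ov)
        }, numeric(1))
        abs(mean(est) - 0.7)
    }
    b <- vapply(c(3L, 10L, 30L), biasAt, numeric(1))
    expect_true(b[3] <= b[1])
    expect_lt(b[3], 0.05)
})

test_that("reference signatures overlap the bioset at the requested fraction", {
    bg <- sprintf("G%06d", 1:3000)
    bio <- randomSignature(561, bg, seed = 3, name = "bioset")
    ## disjoint reference: everything unexplained
    r0 <- generateReferenceSignature(bio, overlapFrac = 0, seed = 1)
    expect_length(intersect(geneIds(r0$signature), geneIds(bio)), 0)
    part <- partitionBioset(bio, list(ref = r0$signature))
    expect_identical(unexplainedCount(part), 561L)
    ## complete overlap with full agreement: all uu/dd
    r1 <- generateReferenceSignature(bio, overlapFrac = 1, agreement = 1,
                                     nExtra = 0, seed = 1)
    q <- quadrantPartition(bio, r1$signature)$counts
    expect_identical(sum(q), 561L)
    expect_identical(unname(q["ud"] + q["du"]), 0L)
    ## fixture-scale check: 0.374 of 561 ~ 210 within binomial error
    r <- generateReferenceSignature(bio, overlapFrac = 0.374, seed = 4)
    k <- length(intersect(geneIds(r$signature), geneIds(bio)))
    expect_gte(k, qbinom(0.0025, 561, 0.374))
    expect_lte(k, qbinom(0.9975, 561, 0.374))
})

test_that("mouse-style references come with a consistent ortholog map", {
    bg <- sprintf("G%06d", 1:500)
    bio <- randomSignature(60, bg, seed = 8)
    r <- generateReferenceSignature(bio, overlapFrac = 0.5, targetIds = TRUE,
                                    seed = 2)
    expect_s4_class(r$map, "OrthologMap")
    expect_true(all(startsWith(geneIds(r$signature), "Mm")))
    back <- suppressMessages(translateSignature(r$signature, r$map))
    expect_true(all(geneIds(back) %in% bg))
})
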