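test_that("upper-tail hypergeometric matches direct PMF summation", {
    expect_identical(hypergeomUpper(0, 5, 6, 20), 1)
    expect_identical(hypergeomUpper(5, 5, 5, 5), 1)
    direct <- sum(dhyper(4:5, 6, 14, 5))
    expect_equal(hypergeomUpper(4, 5, 6, 20), direct, tolerance = 1e-12)
    expect_equal(10^hypergeomUpper(4, 5, 6, 20, log10 = TRUE), direct,
                 tolerance = 1e-12)
    ## extreme tail stays finite and meaningful in log10 space
    lp <- hypergeomUpper(500, 500, 500, 20000, log10 = TRUE)
    expect_lt(lp, -700)
    expect_true(is.finite(lp))
    expect_error(hypergeomUpper(6, 5, 6, 20), "inconsistent")
    expect_error(hypergeomUpper(2, 5, 6, 4), "inconsistent")
})

test_that("background restriction matches brute-force set algebra", {
    bg <- paste0("G", 1:200)
    a <- randomSignature(40, bg, seed = 1, name = "A")
    b <- randomSignature(30, bg, seed = 2, name = "B")
    ## identical background: no-op on the gene sets
    r <- restrictToBackground(a, b, bg)
    expect_setequal(geneIds(r$sigA), geneIds(a))
    expect_identical(r$backgroundSize, 200L)
    ## restricted universe drops out-of-platform genes
    sub <- paste0("G", 1:120)
    r2 <- restrictToBackground(a, b, sub)
    expect_setequal(geneIds(r2$sigA), intersect(geneIds(a), sub))
    expect_setequal(geneIds(r2$sigB), intersect(geneIds(b), sub))
    expect_identical(r2$backgroundSize, 120L)
    ## ranks are recomputed to 1..n after filtering
    expect_identical(sort(signatureEntries(r2$sigA)$rank),
                     seq_len(signatureSize(r2$sigA)))
    expect_error(restrictToBackground(a, b, character()), "empty background")
})

test_that("quadrant partition matches manual enumeration and printed sums", {
    a <- toySignature(paste0("G", 1:6), c("up", "up", "down", "down", "up",
                                          "down"))
    b <- toySignature(paste0("G", c(1, 2, 3, 4, 7, 8)),
                      c("up", "down", "down", "up", "up", "down"))
    q <- quadrantPartition(a, b)$counts
    expect_identical(q, c(uu = 1L, dd = 1L, ud = 1L, du = 1L))
    ## disjoint signatures
    c0 <- toySignature(paste0("H", 1:4), rep("up", 4))
    expect_identical(sum(quadrantPartition(a, c0)$counts), 0L)
    ## the partition sums to the printed overlap: 91+563+193+39 = 886
    expect_identical(91L + 563L + 193L + 39L, 886L)
})

test_that("quadrant counts transpose when the signatures swap", {
    bg <- paste0("G", 1:300)
    for (s in 1:5) {
        a <- randomSignature(50, bg, seed = s, name = "A")
        b <- randomSignature(60, bg, seed = s + 100, name = "B")
        q1 <- quadrantPartition(a, b)$counts
        q2 <- quadrantPartition(b, a)$counts
        expect_identical(q1[c("uu", "dd")], q2[c("uu", "dd")])
        expect_identical(unname(q1["ud"]), unname(q2["du"]))
        expect_identical(unname(q1["du"]), unname(q2["ud"]))
    }
})

test_that("running Fisher equals the exhaustive brute-force oracle for short lists", {
    set.seed(99)
    bg <- paste0("G", 1:60)
    for (rep in 1:50) {
        nA <- sample(1:12, 1)
        nB <- sample(1:20, 1)
        a <- randomSignature(nA, bg, seed = rep, name = "A")
        b <- randomSignature(nB, bg, seed = rep + 500, name = "B")
        got <- runningFisher(a, b, 60)
        want <- runningFisherOracle(geneIds(a), geneIds(b), 60)
        expect_equal(got$p, want, tolerance = 1e-12)
    }
})

test_that("running Fisher rewards rank concentration of the shared genes", {
    bg <- paste0("G", 1:1000)
    n <- 100
    ids <- paste0("G", 1:n)
    p <- (1:n) / (n * 21)
    top <- GeneSignature(ids, rep(2, n), p, backgroundIds = bg)
    bTop <- toySignature(geneIds(top)[1:10], rep("up", 10), bgIds = bg)
    spread <- toySignature(geneIds(top)[seq(10, 100, by = 10)],
                           rep("up", 10), bgIds = bg)
    pTop <- runningFisher(top, bTop, 1000)$p
    pSpread <- runningFisher(top, spread, 1000)$p
    expect_lt(pTop, pSpread)
    ## and beats the single full-list cutoff for a top-decile match
    single <- hypergeomUpper(10, 100, 10, 1000)
    expect_lt(pTop, single)
})

test_that("running Fisher handles disjoint and empty signatures", {
    bg <- paste0("G", 1:100)
    a <- randomSignature(10, bg, seed = 1)
    b <- toySignature(paste0("H", 1:5), rep("up", 5),
                      bgIds = c(bg, paste0("H", 1:5)))
    expect_identical(runningFisher(a, b, 200)$p, 1)
    e <- GeneSignature(character(), numeric(), numeric(),
                       backgroundSize = 100)
    expect_warning(r <- runningFisher(a, e, 100), "empty")
    expect_identical(r$p, 1)
    expect_error(runningFisher(a, randomSignature(10, bg, seed = 2), 5),
                 "smaller than the union")
})

test_that("adding a shared gene at rank 1 never increases the running P", {
    bg <- paste0("G", 1:500)
    for (s in 1:10) {
        a <- randomSignature(30, bg, seed = s)
        b <- randomSignature(40, bg, seed = s + 50)
        before <- runningFisher(a, b, 500)$p
        ## plant a new shared top gene
        newId <- setdiff(bg, union(geneIds(a), geneIds(b)))[1]
        ea <- signatureEntries(a)
        a2 <- GeneSignature(c(newId, ea$gene_id), c(9, ea$linear_fc),
                            c(1e-12, ea$p_value), backgroundIds = bg)
        eb <- signatureEntries(b)
        b2 <- GeneSignature(c(newId, eb$gene_id), c(9, eb$linear_fc),
                            c(1e-12, eb$p_value), backgroundIds = bg)
        after <- runningFisher(a2, b2, 500)$p
        expect_lte(after, before)
    }
})

test_that("directional overlap P-values are calibrated on concordant pairs", {
    cfg <- syntheticConfig(nGenes = 1500, concordance = 1, effectSize = 2,
                           noiseSd = 0.3, seed = 17)
    sim <- generatePairedStudies(cfg)
    ov <- compareSignatures(extractSignature(sim$studyA),
                            extractSignature(sim$studyB))
    qp <- quadrantP(ov)
    expect_lt(qp["uu"], 1e-4)
    expect_lt(qp["dd"], 1e-4)
    expect_gt(qp["ud"], 0.5)
    expect_gt(qp["du"], 0.5)
    ## empty direction-restricted sets give P = 1
    allUp <- toySignature(paste0("G", 1:5), rep("up", 5),
                          bgIds = paste0("G", 1:100))
    expect_warning(
        p <- directionalOverlapP(allUp, allUp, "down", "down", 100), "empty")
    expect_identical(p, 1)
})

test_that("concordance chi-square reproduces the printed statistics", {
    r <- concordanceChiSquare(654, 232)
    expect_equal(round(r$chi2, 2), 201.00)
    r2 <- concordanceChiSquare(57, 11)
    expect_equal(round(r2$chi2, 2), 31.12)
    expect_identical(concordanceChiSquare(50, 50)$chi2, 0)
    expect_identical(concordanceChiSquare(50, 50)$p, 1)
    ## symmetry and error cases
    a <- concordanceChiSquare(13, 37); b <- concordanceChiSquare(37, 13)
    expect_identical(a$chi2, b$chi2)
    expect_error(concordanceChiSquare(0, 0), ">= 1")
})

test_that("the Bonferroni ledger follows the dataset-pair and direction counts", {
    l1 <- bonferroniLedger(1)
    expect_identical(l1$alphaPairs, 0.05)
    expect_identical(l1$alphaDirections, 0.0125)
    expect_identical(bonferroniLedger(5)$alphaPairs, 0.01)
    expect_error(bonferroniLedger(0), ">= 1")
})

test_that("compareSignatures assembles a consistent overlap result", {
    bg <- paste0("G", 1:400)
    a <- randomSignature(60, bg, seed = 3, name = "A")
    b <- randomSignature(70, bg, seed = 4, name = "B")
    ov <- compareSignatures(a, b, nDatasetPairs = 3)
    expect_s4_class(ov, "OverlapResult")
    expect_identical(overlapCount(ov),
                     length(intersect(geneIds(a), geneIds(b))))
    expect_identical(concordantCount(ov) + discordantCount(ov),
                     overlapCount(ov))
    expect_equal(ov@alphaPairs, 0.05 / 3)
    ## chi-square symmetric in the pair order
    ov2 <- compareSignatures(b, a, nDatasetPairs = 3)
    expect_equal(chiSquare(ov), chiSquare(ov2))
})
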