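## Shared fixtures built in code.

## A signature of n genes drawn from a background universe of bg ids.
randomSignature <- function(n, bgIds, seed = 1, name = "sig",
                            fcCut = 1.2, pCut = 0.05) {
    set.seed(seed)
    ids <- sample(bgIds, n)
    mag <- fcCut * 2^runif(n, 0.05, 1.5)
    up <- runif(n) < 0.5
    GeneSignature(ids, ifelse(up, mag, 1 / mag),
                  runif(n, 1e-8, pCut * 0.999),
                  backgroundIds = bgIds, fcCut = fcCut, pCut = pCut,
                  name = name)
}

## Tiny signature with hand-set directions (fc +/- 2) and evenly spaced P.
toySignature <- function(ids, dirs, bgIds = ids, name = "toy") {
    GeneSignature(ids, ifelse(dirs == "up", 2, 0.5),
                  seq_along(ids) / (2 * length(ids) + 1) * 0.05,
                  backgroundIds = bgIds, name = name)
}

## Independent step-up BH oracle (textbook definition).
bhStepUp <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

## Independent pooled-variance two-sample t oracle (scalar, textbook form).
pooledTOracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
    2 * stats::pt(-abs(tt), n1 + n2 - 2)
}

## Exhaustive-cutoff Running Fisher oracle: every rank of A is a cutoff and
## each tail is a direct PMF sum.
runningFisherOracle <- function(rankedA, bGenes, backgroundSize) {
    nB <- length(bGenes)
    ps <- vapply(seq_along(rankedA), function(k) {
        x <- sum(rankedA[seq_len(k)] %in% bGenes)
        if (x == 0) return(1)
        sum(stats::dhyper(x:min(k, nB), nB, backgroundSize - nB, k))
    }, numeric(1))
    min(min(ps) * length(ps), 1)
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
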