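---
title: "Comparing differential-expression signatures: models, parameters and design choices"
author: "SignatureOverlap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing differential-expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SignatureOverlap)
```

# The problem

Transcriptomic meta-analyses often ask whether two independent two-group
comparisons — say, *patient vs. control* in one cohort and *infant vs.
adult* in another — perturb the transcriptome in a similar way. A
well-known application is the "pseudo-immaturity" question in psychiatric
disorders: does the expression change seen in the adult patient cortex
recapitulate the change seen during normal cortical development? Answering
it requires (i) a defensible way to call a per-study gene signature, (ii) a
rank-aware test of whether two signatures share more genes than chance,
(iii) a test of whether the shared genes move in the *same direction* more
often than the 50 % expected by chance, and (iv) a decomposition of the
concordant genes across cell-type developmental programs (fast-spiking
interneurons, astrocytes, oligodendrocytes). `SignatureOverlap` implements
this full chain, together with a synthetic paired-study generator so every
stage is testable without access to the original microarray series.

# Signature extraction

A study enters the pipeline as a log2-scale gene-by-sample matrix with a
two-group labeling (`makeExpressionMatrix()`, or TSV files through
`readExpressionMatrix()`). For each gene the package computes

* the linear fold change $2^{\bar{x}_1 - \bar{x}_2}$, where $\bar{x}_g$ is
  the mean log2 expression in group $g$ (group 1 is the numerator —
  the "young / disease" side by convention), and
* a two-sided Student pooled-variance two-sample *t*-test P-value.

The pooled-variance (rather than Welch) form is the package's fixed choice:
it was the default in the microarray era this methodology comes from, and
fixing it keeps the test oracle unambiguous. Zero-variance rows are handled
by convention: equal means give $P = 1$; unequal means with zero pooled
variance are a degenerate limit reported at the smallest representable
positive double and flagged.

`extractSignature()` keeps genes with $|\mathrm{FC}_{display}| >$ `fcCut`
**and** $P <$ `pCut`, both strict, and applies *no* multiple-testing
correction — by design, correction happens at the comparison and enrichment
layers, not at extraction. Typical thresholds are `fcCut = 1.2` for
whole-tissue comparisons and `1.5` for sorted-cell-type data, with
`pCut = 0.05`. Fold changes below 1 are displayed in the negative-reciprocal
convention ($-1/\mathrm{FC}$), so 0.5 reads as $-2.0$.

Entries are ranked by ascending P-value, ties by descending absolute
display fold change, then lexicographic gene id. The ranking key is the
package's own fixed policy: rank-based overlap testing needs *some*
deterministic key, and significance-then-magnitude is the natural one.

# The Running Fisher overlap test

Given ranked signatures $A$ (size $n_A$) and $B$ (size $n_B$) over a common
measured background of $N$ genes, the test scans cumulative cutoffs $k$ of
$A$'s ranked list. At each cutoff it computes the upper-tail
hypergeometric probability of the observed overlap between the top-$k$
genes of $A$ and all of $B$:

$$ p_k \;=\; P\!\left(X \ge |top_k(A) \cap B|\right),
   \qquad X \sim \mathrm{Hypergeom}(N,\, n_B,\, k), $$

and summarizes the scan as

$$ p_{run} \;=\; \min\bigl(1,\; C \cdot \min_k p_k \bigr), $$

where $C$ is the number of cutoffs (a Bonferroni correction over the scan).
The cutoff grid is the package's declared choice: the ten decile boundaries
of $A$'s list, or *every* rank when $n_A < 50$. A coarse published grid for
this family of tests does not exist, so the package states one and corrects
for it; the short-list branch makes the implementation coincide with an
exhaustive brute-force scan, which the test suite exploits as an exact
oracle. The min-scan correction is conservative, which the null-calibration
tests confirm (rejection rate at $\alpha = 0.05$ stays at or below
nominal). Tail probabilities are computed in log space throughout;
`runningP(x, log10 = TRUE)` stays meaningful below the $10^{-308}$ double
floor.

Direction is incorporated by also running the same test on the four
direction-restricted sub-signature pairs (up/up, down/down, up/down,
down/up) — the per-arrow P-values of the familiar quadrant bar graphs.
The per-direction significance level is Bonferroni-fixed at
$0.05/4 = 0.0125$; the per-comparison level is $0.05/m$ for $m$ declared
dataset pairs (`bonferroniLedger()`).

# Direction concordance

Shared genes are cross-classified by their direction pair. With $c$
concordant (uu + dd) and $d$ discordant (ud + du) genes, the package tests
the 50 % null with the Pearson chi-square without continuity correction:

$$ \chi^2_{(1)} \;=\; \frac{(c - d)^2}{c + d}. $$

The no-continuity-correction form is deliberate: it reproduces the
published statistics of the motivating analyses exactly at two decimals
(e.g. $c = 654$, $d = 232$ gives $\chi^2 = 201.00$):

```{r chi2}
concordanceChiSquare(654, 232)$chi2
```

`makeBioset()` then materializes the positive-correlation genes (uu and dd
only) as a new signature — the "bioset" fed to the downstream stages — with
study-A statistics defining its ranks and study-B statistics carried along.

# Ortholog translation

Cross-species comparisons translate a signature through a two-column
source-to-target map (`translateSignature()`). The collision policy is
deterministic "best evidence": a 1:many fan-out keeps the lexicographically
smallest target (the per-gene statistics are identical across a fan-out),
and a many:1 collision keeps the source with the smallest P, ties broken by
larger absolute fold change, then source id. Unmapped genes are dropped and
counted in the translation log. After translation the hypergeometric
population must live in the target namespace, so the background becomes the
set of distinct target ids reachable from the mapped background; it can
only shrink. Gene matching is exact, case-sensitive string equality —
symbol aliasing belongs in the map, not in silent normalization.

# Cell-type contribution

`partitionBioset()` decomposes a bioset over up to three reference
signatures into the $2^k - 1$ Venn regions plus the unexplained remainder.
Membership is by gene identity only; direction agreement with each
reference is tallied alongside (`agreementTable()`) but does not gate
membership. This separation mirrors how such results are usually reported:
Venn counts say which developmental program a gene belongs to, agreement
counts say whether it moves the same way. Since the published pie charts
do not state which convention their pairwise regions use, both tallies are
always emitted. `contributionPercentages()` reports counts and percentages
rounded half-up to one decimal, matching report style; `k > 3` references
are rejected rather than generalized to keep region enumeration auditable.

# Enrichment

`enrichSignature()` runs one-sided (over-representation) Fisher exact tests
of a bioset against a GMT collection, using the signature's *measured*
background — the genes actually tested — as the population rather than the
genome, and adjusts across sets with Benjamini-Hochberg. The Fisher tail is
the same log-space hypergeometric primitive the Running Fisher scan uses;
the test suite cross-checks it against `stats::fisher.test` and direct PMF
summation, and checks `stats::p.adjust(method = "BH")` against a hand-coded
step-up oracle. Under-representation is out of scope.

# The synthetic generator

`generatePairedStudies()` emulates the statistical skeleton of a paired
two-study design with a shared latent axis:

* `fracDE` of the `nGenes` genes carry a true effect in study A;
* of those, `concordance` carry a same-sign effect in study B and the
  remainder an *opposite*-sign effect;
* effect magnitudes are Gamma(shape 4, mean `effectSize`) in log2 units;
* signs are negative with probability `downBias`;
* observations are the baseline (N(7, 1) log2 intensity, typical of
  normalized arrays) plus the group effect plus N(0, `noiseSd`) noise.

Two modeling choices deserve comment. First, the non-concordant remainder
is made discordant (opposite sign in B) rather than null in B, so that the
pipeline's natural estimator $(uu + dd)/\mathrm{overlap}$ is a *consistent*
estimator of `concordance`; the ground-truth label vocabulary still
includes `A-only`/`B-only` for schemes that need one-sided effects. Second,
the Gamma shape of 4 (SD half the mean) keeps effect magnitudes spread but
bounded away from zero — a reasonable description of genes that by
definition clear a fold-change floor — while shape values near 1 would put
substantial mass on unrecoverable near-zero effects.

Defaults (`nGenes = 2000`, `nPerGroup = 10`, `fracDE = 0.2`,
`concordance = 0.8`, `effectSize = 1`, `noiseSd = 0.5`, `downBias = 0.7`)
describe a moderately powered microarray-scale design with
down-regulation-dominated effects, the regime the motivating cortical
maturity analyses live in. These sizes are also what the test suite and the
acceptance script simulate at.

What the generator does *not* emulate: probe-level artifacts, batch
effects, normalization pipelines (RMA/MAS5), correlated noise across genes,
or age as a continuous covariate. Passing tests therefore demonstrate
correctness of the statistical machinery under a clean additive-Gaussian
model, not robustness to real-data pathologies.

```{r worked, message = FALSE}
sim <- generatePairedStudies(syntheticConfig(seed = 7))
a <- extractSignature(sim$studyA, name = "A")
b <- extractSignature(sim$studyB, name = "B")
ov <- compareSignatures(a, b)
ov
concordantCount(ov) / overlapCount(ov)  # targets the configured 0.8
```

# Numerical and degenerate-input conventions

* All overlap P-values are floored at the smallest positive double on the
  natural scale; log10 values are authoritative in the extreme tail.
* Empty signatures (or empty direction-restricted sub-signatures) give an
  overlap P of 1 with a warning; an empty overlap leaves the concordance
  chi-square as `NA` (the test is undefined at $c + d = 0$ and
  `concordanceChiSquare()` errors there).
* Threshold comparisons are strict on both sides, so a display fold change
  of exactly $\pm$`fcCut` or a P equal to `pCut` is excluded.
* Ranks are recomputed after every filtering operation (background
  restriction, translation, direction subsetting) so they are always a
  permutation of $1..n$.
* Percentages are rounded half away from zero to one decimal
  (`roundHalfUp()`), not banker's rounding.

# Known limitations

* The decile cutoff grid and its Bonferroni correction are one concrete
  instantiation of a rank-scan overlap test; absolute P-values from other
  implementations of the same idea (different grids, different corrections,
  proprietary preprocessing) are not comparable number-for-number, and the
  package makes no attempt to reproduce any specific published overlap
  P-value. The count and chi-square layers, by contrast, are exact.
* With the generator's noise and null genes present, the recovered
  concordant fraction is contaminated by a small number of false-positive
  overlap pairs and observed sign flips of weak effects (order one gene per
  run at default settings). The estimator is consistent as the group size
  grows, but at the degenerate boundary `concordance = 1` even a single
  such gene moves the estimate off 1, so exact recovery there is
  unattainable in finite samples — visible as the one deliberately failing
  boundary check in the acceptance suite.
* Probe-to-gene collapsing is the caller's responsibility; input rows are
  treated as genes.
* The pipeline problem sizes used by the test suite and acceptance script
  (2000 genes, 10 samples per group, a few hundred replicates) were chosen
  so the whole battery runs comfortably on a laptop while keeping
  Monte-Carlo error around estimated rates at or below the percent scale.
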