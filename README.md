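# SignatureOverlap

Rank-based overlap and directional concordance of differential-expression
signatures.

`SignatureOverlap` is for researchers who need to ask, quantitatively,
whether two independent two-group transcriptomic comparisons perturb the
same genes in the same directions — the kind of question behind
"pseudo-immaturity" analyses of the psychiatric cortex, where the
*patient vs. control* signature of the prefrontal cortex is compared with
the *infant vs. adult* signature of normal development, and the shared
concordant genes are decomposed across cell-type developmental programs
(fast-spiking interneurons, astrocytes, oligodendrocytes).

The package implements the full chain:

* **Signature extraction** — per-gene linear fold change
  `2^(mean log2 group1 − mean log2 group2)` and two-sided pooled-variance
  Student *t*, filtered at `|FC| > fcCut` and `P < pCut` (strict, no
  multiple-testing correction at extraction); negative-reciprocal display
  convention (`0.5 → −2.0`).
* **Running Fisher overlap** — a rank-based scan over cumulative cutoffs
  `k` of the first signature's ranked list, scoring each cutoff with the
  upper-tail hypergeometric `P(X ≥ |top_k(A) ∩ B|)`,
  `X ~ Hypergeom(N, n_B, k)`, and reporting
  `p_run = min(1, C · min_k p_k)` with `C` the number of cutoffs. Computed
  in log space; exact brute-force semantics for short lists.
* **Directional statistics** — uu/dd/ud/du quadrant counts, per-quadrant
  overlap P-values, and the direction-concordance Pearson chi-square
  against the 50 % null, `χ²(1) = (c − d)² / (c + d)` (no continuity
  correction), with Bonferroni ledgers over dataset pairs (0.05/m) and
  direction pairs (0.05/4 = 0.0125).
* **Ortholog translation** of signatures with a deterministic best-evidence
  collision policy, **Venn decomposition** of a concordant bioset over up
  to three cell-type reference signatures, and **Fisher/BH gene-set
  over-representation** against the measured background.
* A **synthetic paired-study generator** with a controllable latent
  concordance fraction, so the whole pipeline is testable end-to-end
  without external data.

## Worked example

```r
library(SignatureOverlap)

# two synthetic studies sharing 80% direction-concordant effects
sim <- generatePairedStudies(syntheticConfig(seed = 7))
a <- extractSignature(sim$studyA, name = "A")
b <- extractSignature(sim$studyB, name = "B")
ov <- compareSignatures(a, b)
ov
#> OverlapResult: 'A' (n=424) vs 'B' (n=402), background 2000
#>   overlap 289 | uu=63 dd=162 ud=25 du=39
#>   running Fisher P = 5.61e-148 (log10 = -147.25)
#>   concordance chi2(1) = 89.69, P = 2.78e-21
#>   alpha (dataset pairs) = 0.05, alpha (directions) = 0.0125

concordantCount(ov) / overlapCount(ov)
#> [1] 0.7785467
```

Reading: each study's signature holds ~400 genes of the 2000-gene
background; 289 genes are shared, far more than chance (the Running Fisher
P), and 225 of them (77.9 %, close to the configured 0.8) move in the same
direction in both studies — overwhelmingly down (dd = 162), as configured
through the generator's down-bias. The published-count layer reproduces
report-style numbers exactly:

```r
concordanceChiSquare(654, 232)$chi2   # 201.00 at 2 d.p.
#> [1] 200.9977
roundHalfUp(100 * 210 / 561, 1)       # FS-neuron contribution, percent
#> [1] 37.4
```

Concordant genes can then be decomposed and annotated:

```r
bio <- makeBioset(ov)
ref <- generateReferenceSignature(bio, overlapFrac = 0.4, name = "FS")
contributionPercentages(partitionBioset(bio, list(FS = ref$signature)))
```

Full end-to-end runs (extraction → translation → overlap → contribution →
enrichment) are driven by a YAML config through `runPipeline()` (schema in
`?readRunConfig`; a thin shell wrapper lives at
`inst/scripts/run-pipeline.R`). Reports are deterministic JSON: the same
config and inputs reproduce the report byte-for-byte.

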