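---
title: "Openness-weighted association scans: model, simulation design, and numerical conventions"
author: "openwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Openness-weighted association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openwas)
```

## The model and its assumptions

`openwas` tests genomic *segments* — fixed windows tiled over regulatory
regions around transcription start sites — for association with a
phenotype, after collapsing each segment's SNPs into a single
individual-level quantity, the openness score

$$O_{i,s} = \sum_{j \in \Omega_s} w_j X_{ij},$$

where $X_{ij}$ is the effect-allele dosage and $w_j$ the predicted allelic
effect of SNP $j$ on chromatin accessibility in a chosen cell type (such
weights come from sequence-based predictors trained on DNase I
hypersensitivity; predicting them is upstream of this package). The
association model is linear,

$$Y = \alpha + O_s \gamma_s + \epsilon, \qquad
  Z_s = \hat\gamma_s / \mathrm{se}(\hat\gamma_s),$$

with a two-sided p-value from the standard normal reference. The
assumptions worth stating:

* **Additivity.** Openness contributes additively across SNPs with fixed
  per-allele effects; dominance and interaction are not modeled.
* **Linear model also for binary traits.** Case/control status is fitted
  as 0/1 in the same linear model. At GWAS sample sizes the linear-model
  Z is essentially equivalent for association testing, and the
  summary-statistic approximation below is derived for the linear model;
  a logistic variant would break the correspondence between the two
  routes.
* **Normal reference.** $Z_s$ is compared to $N(0,1)$ rather than a t
  reference; `owasIndividual()` therefore requires $n \ge 30$. The type-I
  harness (below) verifies the calibration empirically.
* **Covariates** are residualized out of both $Y$ and $O_s$
  (Frisch–Waugh), with degrees of freedom adjusted, so the reported Z
  equals the joint-regression Z exactly.

### Summary-statistic mode

When only GWAS summary statistics are available, the same statistic is
approximated from per-SNP z-scores $z_j$ and an LD reference panel:

$$Z_s \approx \sum_{j\in\Omega_s} \frac{w_j\,\hat\sigma_j}{\hat\sigma_s}\, z_j,
\qquad
\hat\sigma_s^2 = \sum_{j,k\in\Omega_s} w_j w_k\, \hat\sigma_j \hat\sigma_k R_{jk},$$

with $\hat\sigma_j$ the per-SNP dosage standard deviation and $R$ the
segment LD (correlation) matrix, both estimated from the panel. The
identity for $\hat\sigma_s$ is exact (it is the variance of a linear
combination); the approximation lies in replacing
$\widehat{\mathrm{cov}}(X_j, Y)$-type terms with their z-score
equivalents, which is accurate to the order of the squared effect sizes.
With LD computed *in-sample* the two routes agree to numerical noise
(tested: Pearson r > 0.999, median |ΔZ| ≈ 0.002 at n = 2000); with an
external panel the agreement degrades with panel mismatch — the usual
caveat for any summary-statistic method. Note that no LD matrix is ever
inverted, so the method has no ridge/regularization parameter.

When all weights are set to 1 the same pipeline gives the *unweighted*
baseline (every SNP in a segment counted equally), which is the
comparison point for the heritability-enrichment evaluation.

## Coordinates, harmonization, and degenerate cases

* **Coordinates.** Variant positions are 1-based (as in `.bim` files);
  segments are reported in BED-style 0-based half-open intervals
  $[a, b)$. A variant at position $p$ belongs to $[a,b)$ iff
  $a < p \le b$ — equivalently its 0-based coordinate $p-1$ lies in
  $[a, b)$. Every boundary base therefore has exactly one owner.
* **Merged windows.** Overlapping TSS windows are merged before tiling so
  no SNP is tested twice; a segment is attributed afterwards to the gene
  with the nearest TSS (ties broken by lexicographically smallest gene
  id). Terminal windows shorter than the segment length are kept and
  flagged rather than dropped, preserving coverage.
* **Allele harmonization.** Weights and GWAS z-scores are both aligned to
  the dosage effect allele: a weight (or z) stated for the other allele
  has its sign flipped; alleles matching neither are dropped;
  strand-ambiguous SNPs (A/T, C/G) are dropped by default
  (`allowAmbiguous = TRUE` overrides) because their orientation cannot be
  verified. Every flip and drop is counted and surfaced in the pipeline
  manifest, which asserts `read = used + dropped-by-reason`.
* **Missing dosages** are mean-imputed per SNP before the openness sum,
  which keeps the per-SNP variance entering $\hat\sigma_s$ consistent
  with the dosages actually summed. SNPs without a harmonized weight
  contribute 0 (the additive form makes this the natural treatment);
  segments where *no* SNP carries a weight, or with zero openness
  variance, are skipped with an explicit reason rather than reported.
* **Numerical floors.** LD entries are defensively clipped to $[-1,1]$; a
  numerically perfect individual-level fit is reported at the smallest
  positive double and flagged `saturated`; p-values are floored at the
  same value so $p \in (0,1]$ always holds.
* **Multiple testing** defaults to Bonferroni across tested segments
  (the convention for declaring "significant segments"), with
  Benjamini–Hochberg available.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `flank` | 100000 bp | half-width of the TSS-centered regulatory window |
| `segLen` | 5000 bp | segment length (2500 / 10000 are sensitivity settings) |
| `snpCountK` | 20 SNPs | fixed-SNP-count segmentation (≈ median SNPs per 5 kb) |
| HLA region | chr6:28,477,797–33,448,354 (hg19) | excluded from heritability analyses of real data |
| `alpha` | 0.05 | significance level after adjustment |
| `prioritizeP` | 5e-8 | segment p-value defining "prioritized" SNPs in replication analysis |
| `replicateP` | 0.05 | relaxed replication threshold |
| `nResample` | 10000 | draws in the peak-resampling enrichment test |

## The synthetic world

The simulator reproduces the published generative design at a
configurable number of SNPs. Among $m$ SNPs, 90% are null ($C_0$); the
associated SNPs are stratified *by rank of openness weight* into
$C_1$ (top 0.5% of $|w|$), $C_2$ (next 1.5%) and $C_3$ (next 8%), with
group heritabilities $h^2(C_k) = 0.5, 0.2, 0.1$. Within group $k$ each
effect is drawn $\beta_j \sim N(0, \tau_k)$ with
$\tau_k = h^2(C_k)/M(C_k)$, so $\tau_k M(C_k) = h^2(C_k)$ holds exactly.
GWAS z-scores are then drawn from the standard LD-aware model

$$z \mid R, \beta \sim N(\sqrt{n}\, R\beta,\; R), \qquad n = 10000
  \text{ by default},$$

sampled block-by-block via Cholesky factors so memory stays linear in
block size. Choices that the source design leaves open, decided here once:

* **Ranking by $|w|$.** The sign of a weight encodes direction (opening
  vs closing chromatin); magnitude encodes regulatory impact. "Rank of
  openness score" is therefore read as rank of $|w_j|$, with ties broken
  by SNP index.
* **Weight distribution.** Synthetic weights are $N(0,1)$ — the same
  choice the type-I design prescribes. Real deltaSVM scores are more
  heavy-tailed; the tails affect how sharply the weighted test
  concentrates on top SNPs but not the calibration of any test.
* **Total heritability.** The group values sum to 0.8 and no separate
  trait total is stated; `h2Total` is exposed with default
  $0.5+0.2+0.1 = 0.8$.
* **LD stand-in.** The full-scale design estimated $R$ from reference
  chromosome 22 genotypes (141,123 SNPs). The desk default is AR(1)
  blocks of 50 SNPs with $\rho = 0.5$ at $m = 2000$; the full-size
  configuration remains expressible, and `ldFromGenotypes()` estimates
  $R$ from any genotype panel instead.
* **Genotypes** (needed for individual-mode tests; the published type-I
  study used a real cohort) are simulated by thresholding two latent
  Gaussian haplotypes at the allele-frequency quantile. Realized dosage
  LD is the tetrachoric-attenuated latent correlation; the test suite
  checks it against a numerically integrated oracle.
* **Null phenotypes** in the type-I harness are drawn independently of
  the genotypes (the published study does not state its null generator;
  with a truly null $\beta$ the two constructions coincide in
  distribution). The cohort size is exposed (`n`, default 1000) because
  null calibration of the regression Z does not depend on it at these
  scales.

### What the synthetic world does and does not establish

The generator emulates: LD-blocked z-scores with openness-stratified
heritability, allele-coding inconsistencies (via harmonization tests),
missing dosages, and internally consistent gene/variant/weight/summary
files. It does **not** emulate: realistic minor-allele-frequency spectra
coupled to effect sizes, population stratification, imputation error,
case/control ascertainment, or real LD beyond AR(1) blocks. A green test
therefore establishes correctness of the statistical machinery under the
stated model, not robustness to the artifacts of real cohorts.

### Scaling caveat: why the weighted-vs-unweighted contrast needs matched power

Scaling the chromosome-wide design from $m = 141{,}123$ to $m = 2000$
SNPs *without* touching $n$ multiplies every per-SNP non-centrality
$\sqrt{n\,\tau_k}$ by $\sqrt{141123/2000} \approx 8.4$: all associated
segments then reach astronomically small p-values under *both* the
weighted and the unweighted test, the 5%-of-SNPs selection picks among
equally saturated segments, and the comparison between the two rankings
degenerates into noise. Matching the full-scale per-SNP power instead —
scaling $n$ by the same factor as $m$, i.e. $n = 142$ at $m = 2000$ —
restores the regime the full-scale design operates in, and there the
openness-weighted ranking explains clearly more true heritability than
the unweighted ranking at the 5% SNP proportion (the test suite asserts
the paired Monte-Carlo difference exceeds twice its standard error). A
second consequence of desk scale: with 100 segments, the 5% cutoff
selects only 5, so the per-replicate win/loss indicator stays noisy even
when the mean advantage is large — per-replicate win rates near 100%
would require hundreds of segments, as in the chromosome-wide design.

## Evaluation conventions

* **Heritability explained** by a selected SNP set $S$ is computed from
  simulation truth as $\beta_S' \Sigma_S \beta_S / \mathrm{Var}(Y)$ with
  $\Sigma = D R D$ ($D$ = per-SNP sds), and
  $\mathrm{Var}(Y) = \beta'\Sigma\beta / h^2_{\mathrm{total}}$, so
  selecting everything explains exactly $h^2_{\mathrm{total}}$.
  (REML-based estimation on real cohorts is deliberately out of scope;
  truth-based evaluation removes the external-data dependence while
  preserving the comparison being made.) The x-axis "proportion of SNPs"
  counts unique SNPs in selected segments over all analyzed SNPs.
  Rankings sort by ascending p, ties by $|Z|$ descending, then segment
  id; the curve is non-decreasing whenever selected contributions are
  non-negatively correlated (exact under independent LD — with mixed-sign
  effects in strong LD small dips are possible, which is a property of
  the quantity, not a bug).
* **Replication analysis** bins discovery SNPs by GWAS p into
  (0, 1e-6), [1e-6, 1e-5), [1e-5, 1e-4), [1e-4, 1e-3), [1e-3, 1e-2),
  splits each bin by membership in prioritized segments, and compares
  replication rates with a one-sided binomial test (prioritized rate
  greater than the non-prioritized rate as null probability) — one-sided
  because the claim under evaluation is directional.
* **Peak enrichment** uses the empirical estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{resample}}+1)$,
  which is never zero and uniform under the null up to the $1/(n+1)$
  grid.

## Known limitations

* Results inherit the accuracy of the upstream openness-effect
  predictions; weights are inputs, never re-estimated.
* Summary mode needs an LD panel matching the GWAS cohort; panel mismatch
  biases $\hat\sigma_s$ and the Z-scores.
* Association is marginal per segment; no conditional or fine-mapping
  analysis across segments, and no causal interpretation.
* PLINK binary `.bed` genotypes are not parsed; use a dosage TSV (plus
  `.bim`-style variant records, which are supported).
* Strand-ambiguous SNPs are lost under the default policy; with weights
  and GWAS on the same strand convention `allowAmbiguous = TRUE` recovers
  them at the user's risk.
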