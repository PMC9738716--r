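---
title: "Methods: linking taste ratings, questionnaires, brain activity, and fruit composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking taste ratings, questionnaires, brain activity, and fruit composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tastecca)
```

## The study design this package models

A tasting study in which `P = 19` participants each eat four strawberries
(two cultivars, Skyberry and Tochiotome, in a large and a small size each)
produces four blocks of data on the same `n = 4P = 76`
(participant, strawberry) samples:

* **Taste**: a visual analog scale (VAS) score in millimetres, 0–100, per
  sample. This is the quantity everything else is related to.
* **Questionnaires**: 19 five-point Likert items grouped into reward,
  cultural, information, and appearance factors.
* **Brain activity**: 20-channel temporal-lobe fNIRS oxy-/deoxy-hemoglobin
  traces recorded while the participant bites and swallows, reduced to five
  epoch statistics (mean, sd, RMS, max, min) per channel and chromophore —
  a 200-dimensional feature vector per sample.
* **Individual information**: per-fruit sugar content (%), titratable
  acidity (%), their ratio (the standard sweetness–sourness balance index),
  and a large/small size indicator.

Every stacked vector uses one fixed row order: strawberry blocks s1..s4
concatenated, participants 1..P within each block (`sample_key()`). The VAS
scores, the composition table, and the questionnaire catalogue of the
original study are packaged as fixtures (`study_fixtures()`); the raw fNIRS
recordings and questionnaire responses were never released, which is why the
package ships a synthetic-study generator (below).

## Analysis 1: the correlation screen

`correlate_taste_vs_all()` computes the Pearson correlation

$$\eta_{ab} = \frac{\sum_j (a_j - \bar a)(b_j - \bar b)}
  {\sqrt{\sum_j (a_j - \bar a)^2}\sqrt{\sum_j (b_j - \bar b)^2}}$$

between the stacked VAS vector and every questionnaire item, every retained
brain PCA score, and every individual-information variable, with a two-sided
p-value from the exact t statistic $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
degrees of freedom. Design choices:

* The t-test is used because it is the standard exact test for a single
  product-moment correlation; with the packaged fixtures it reproduces the
  study's printed p-values for the four individual-information variables
  (including the point-biserial size row), which is the package's check that
  the convention matches.
* The ratio variable is the *printed* table column, not recomputed from
  sugar/acidity, so the screen runs on the same inputs the original analysis
  used. (The fixture validator still checks the column against
  sugar/acidity within ±0.15, covering one-decimal printed rounding.)
* p-values are reported raw, with no multiple-testing correction, matching
  the screen's descriptive role; interpretation is left to the caller.
* Constant inputs raise an error rather than returning `NaN`.

## fNIRS features and PCA

`build_feature_matrix()` computes the five statistics over the closed
epoch interval `[bite_onset_s, swallow_end_s]`. Epoch lengths may differ
across samples — the statistics are length-invariant summaries, which is
precisely why they are used. The interval is closed for determinism; at
10 Hz and above, endpoint inclusion is immaterial. No filtering or
detrending is applied before the statistics: PCA is the pipeline's only
noise-handling step, applied to features rather than to raw traces.
Standard deviations use the sample (n−1) denominator throughout the
package; with the VAS table this reproduces the printed summary row
(the population denominator does not).

`fit_pca()` performs a column-centered (not rescaled) eigendecomposition,
`select_dimension()` keeps the fewest leading components whose cumulative
explained-variance fraction reaches the threshold (default 0.90, read as
“≥ 90%”), and `pca_transform()` yields the brain scores `d1..dk`. Centering
without scaling is the default because the five statistics share units
within a chromophore; `scale = TRUE` is available. Component signs are fixed
by making each component's largest-magnitude loading positive, so results
are reproducible across platforms. In the original study the 90% rule
retained 9 dimensions; on synthetic data the retained dimension depends on
the noise configuration and is reported, not assumed.

## Analysis 2: CCA with cross-loadings

For two blocks $A \in \mathbb{R}^{n \times D_a}$, $B \in \mathbb{R}^{n
\times D_b}$, CCA seeks weight vectors maximizing
$\phi_a^\top C_{AB}\phi_b$ subject to $\phi_a^\top C_{AA}\phi_a =
\phi_b^\top C_{BB}\phi_b = 1$, solved as the eigenproblem
$C_{AA}^{-1} C_{AB} C_{BB}^{-1} C_{AB}^\top \phi_a = \lambda^2 \phi_a$
with $\lambda_k$ the k-th canonical correlation. Implementation decisions:

* **Centering.** Columns are mean-centered before forming the
  cross-products. Uncentered products conflate means with covariance and
  cannot reproduce correlation semantics, so centering is not optional.
* **Ridge.** Both within-block covariances are stabilized as
  $C + \text{ridge}\cdot(\mathrm{tr}(C)/D)\, I$ with default ridge
  `1e-8`. Likert items can be collinear at small n; a pure pseudo-inverse
  would silently drop directions, whereas the relative ridge perturbs
  correlations by a controlled, negligible amount in the full-rank case.
* **Dimensions.** `D_cca = min(rank(A), rank(B))`, so the three study
  pairs (taste 1, questionnaire 19, individual 4 against 9 brain scores)
  give 1, 9, and 4 canonical dimensions.
* **Whitening.** The eigenproblem is solved in the symmetric whitened form
  $W_a C_{AB} C_{BB}^{-1} C_{AB}^\top W_a$ with $W_a = C_{AA}^{-1/2}$,
  which keeps eigenvalues real and eigenvectors orthogonal under the
  $C_{AA}$ metric.
* **Signs.** Each pair is oriented so the canonical pair correlates
  positively and the largest-magnitude weight in $\phi_a$ is positive —
  cross-loadings are then reproducible across runs and platforms.
* **Cross-loadings.** `cross_loadings()` correlates each raw variable of
  one block with a canonical feature of the *opposite* block; the headline
  analysis uses dimension 1, the API exposes all. This is the device that
  identifies which questionnaire item or composition variable drives the
  brain-linked canonical pair.

### Significance

The sequential test reported by default is Bartlett's chi-square
approximation on Wilks' lambda: for dimension k,
$\Lambda_k = \prod_{j\ge k}(1-\lambda_j^2)$, statistic
$-(n - 1 - (D_a + D_b + 1)/2)\ln\Lambda_k$ on $(D_a-k+1)(D_b-k+1)$ degrees
of freedom. The original study does not name its test; Bartlett–Wilks is
the standard default and is labelled in the output metadata. A seeded
permutation alternative (`permutation_significance()`, rows of one block
permuted, add-one p-values) is provided for small samples where the
chi-square approximation is doubtful. The test suite checks the Bartlett
first-dimension type-I rate at $\alpha = 0.05$ on independent Gaussian
blocks of the study's geometry (n = 76, 9 × 4).

## The synthetic-study generator

`generate_study()` emulates the study for validation by parameter
recovery. A standardized latent taste value $z$ per sample drives:

* **VAS**: $65 + 15\,(\rho_{vas} z + \sqrt{1-\rho_{vas}^2}\,\varepsilon)$,
  clipped to [0, 100] (clipping affects ~1% of draws and attenuates the
  planted correlation negligibly);
* **sugar-to-acid ratio**: mean 16, sd 2.5 around a latent mixed with $z$
  at `link_ratio`; sugar is drawn near the packaged table's means
  (9.9 ± 1.2%) and acidity is derived as sugar/ratio, so the three columns
  are exactly consistent and acidity lands near the table's ~0.6%;
* **questionnaire items**: reward items mix with the VAS at `link_reward`,
  cultural items with the brain latent (identified with $z$) at
  `link_cultural`, other items are independent; all are discretized to
  1..5 by equal-probability thresholds on the latent Gaussian, which
  approximately preserves the planted correlation;
* **fNIRS traces**: responsive channels (default 1–6) carry a smooth
  gamma-shaped epoch-locked bump with peak amplitude
  `brain_gain × latent` (sign flipped for deoxy, mimicking the usual
  oxy/deoxy anti-correlation), plus white noise (`noise_sd`, default 0.3)
  and a 60 s-period sinusoidal drift (`drift_amp`, default 0.2) with
  random phase. The epoch is the nominal `epoch_seconds` (default 6 s)
  jittered ±20% per sample, reflecting per-participant eating-time
  differences; traces include 4 s of pre- and post-epoch baseline.

Default link strengths (`link_vas = 0.6`, `link_reward = 0.6`,
`link_cultural = 0.5`, `link_ratio = 0`) are moderate effect sizes typical
of sensory studies; the original study reports no effect sizes for brain
responses, so recovery tests are self-referential by design — they validate
the pipeline's estimating machinery, not the field data. The implied
correlation matrix over (latent, VAS, ratio, cultural, reward) is assembled
and checked for positive semi-definiteness; infeasible combinations are
rejected, not repaired. With the default signal-to-noise ratio the epoch
statistics recover the latent nearly noiselessly across the 12 responsive
traces, so the planted brain–taste canonical correlation equals `link_vas`.

A single integer seed determines the whole study; per-recording streams are
derived from it by counter-based splitting, so any subset of recordings is
reproducible independently of generation order.

### What the generator does not emulate

No cardiac or Mayer-wave bands, no motion artifacts, no spatial correlation
across channels, no participant-level random effects, and no modified
Beer–Lambert conversion (traces are already concentration-like). Passing
recovery tests therefore demonstrates correctness of the statistical
machinery under a clean hemodynamic model, not robustness to real fNIRS
noise.

## Problem sizes used in validation

The test and acceptance workloads fix their scales as follows: parameter
recovery uses 125 participants (500 samples) over 20 seeds with a planted
brain–taste correlation of 0.6 and a ±0.1 tolerance on the recovered
median; the cross-loading identification check plants only the ratio link
and requires the ratio to top the absolute cross-loadings in at least 90%
of 20 seeds; null calibration uses 1000 independent-Gaussian replicates of
the 76 × (9, 4) study geometry; oracle comparisons use 50 random instances
each for the reference-implementation route (n = 50, up to 5 columns,
tolerance 1e-6 on canonical correlations) and the 1°-grid-search route
(n = 30, up to 3 columns per block excluding the 3 × 3 shape, whose
direction-pair grid is infeasible to enumerate; tolerance 1e-3).

## Numerical edge cases

* Constant blocks/columns: `pearson()` and `fit_pca()` error explicitly;
  `fit_cca()` errors on rank-0 blocks and handles collinear (but not
  all-constant) blocks via the ridge.
* Canonical correlations are clipped to [0, 1] after the eigensolve;
  $\lambda = 1$ maps to p = 0 by convention in both significance methods.
* Eigenvalue ties in PCA keep the solver's stable order; signs are fixed
  as described, so ties cannot flip results between runs.
* `select_dimension()` treats threshold comparisons with a 1e-12 slack so
  exact-boundary cumulative ratios (e.g. 0.95 at threshold 0.95) select
  the intended dimension.

## Known limitations

* The questionnaire and brain rows of the original screen, and the printed
  canonical correlations, depend on the unreleased fNIRS/questionnaire
  data and cannot be reproduced numerically; the package reproduces the
  printed VAS/composition summaries and individual-information p-values,
  and validates everything else by oracle agreement and synthetic
  parameter recovery.
* Bartlett's test is asymptotic; at n = 76 with 9 × 19 blocks it is
  approximate, which is why the permutation alternative exists.
* The ridge default (1e-8) is a numerical stabilizer, not a tuned
  regularizer; genuinely regularized, sparse, kernel, or multi-view CCA is
  out of scope.
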