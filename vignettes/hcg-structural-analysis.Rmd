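---
title: "Quantifying the structure of hyperchromatic crowded cell groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the structure of hyperchromatic crowded cell groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcgtexture)
```

## The measurement problem

Liquid-based cervical cytology frequently presents densely packed,
darkly staining three-dimensional cell clusters — hyperchromatic crowded
cell groups (HCGs). Under transmitted light a thick, cell-dense cluster
absorbs more light than a thin, sparse one, so the *structure* of the
cluster is encoded in its gray-level distribution even when individual
nuclei cannot be resolved. `hcgtexture` measures that encoding with four
per-cluster statistics:

* **8-bit gray-scale value** — the mode of the 256-bin gray-level
  histogram inside the trimmed cluster region. Low values mean a dark,
  heavily absorbing cluster.
* **Skewness and kurtosis** of the same masked pixel-value distribution,
  in the bias-corrected spreadsheet (`SKEW`/`KURT`) definitions:
  for a sample of size $n$ with mean $\bar x$ and $(n-1)$-denominator
  standard deviation $s$,
  $$\mathrm{skew} = \frac{n}{(n-1)(n-2)} \sum_i \left(\frac{x_i - \bar x}{s}\right)^3,
  \qquad
  \mathrm{kurt} = \frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum_i \left(\frac{x_i - \bar x}{s}\right)^4
  - \frac{3(n-1)^2}{(n-2)(n-3)}.$$
  Positive skewness means mass piled toward gray level 0 with a long
  bright tail; high kurtosis means a sharply peaked distribution. Both
  act as proxies for cellular density.
* **Thickness** — the focal span of the cluster in a Z-stack (40 planes
  at 1 µm in the reference design), from the deepest in-focus layer to
  the topmost in-focus layer.

These are per-cluster records; the group-level battery (Kruskal–Wallis,
Steel–Dwass all-pairs, ROC with Youden cut-offs, Pearson correlation,
interaction regression) operates on the resulting tibble.

## Conventions that make results bit-reproducible

Several small numerical decisions are fixed and documented because they
change digits:

* **Colour-to-gray.** Two conversions are offered: Rec. 601 luma
  (`0.299R + 0.587G + 0.114B`, the default) and the plain channel mean.
  Imaging software differs on this point and the original measurement
  protocol does not pin it down, so the choice is an explicit config
  entry and is recorded in the run log. Rounding is half-up, stated
  explicitly so conversions are identical across platforms.
* **Histogram mode ties** break toward the smallest gray level.
* **Polygon masks** use the pixel-centre-inside rule with centres
  exactly on the boundary excluded — deterministic and easy to test.
* **Quantiles.** All medians/IQRs use the linear-interpolation (type 7)
  convention.
* **Degenerate regions.** A constant masked region has no defined
  skewness or kurtosis; the record is flagged `degenerate` and excluded
  from those summaries rather than silently contributing zeros, which
  would bias group comparisons toward symmetry.

## Thickness from focus

Visual focus judgement is operationalised as the variance of the
4-neighbour discrete Laplacian over member pixels, a standard
parameter-free sharpness score. A layer counts as "in focus" when its
score reaches half the profile maximum (`rel_threshold = 0.5`, exposed
in the config). Thickness is the *exclusive* span
`(top - bottom) * spacing`: a cluster confined to one plane reads 0 µm.
Whether a thickness "distance" should include one terminal layer is
genuinely ambiguous; the exclusive convention was chosen and is stated
wherever thickness is reported. Both the focus operator and the 0.5
threshold are artifact decisions — the reference measurement was a human
looking through an eyepiece — so they are validated against simulator
ground truth (within ±2 µm on noiseless stacks) rather than asserted as
"the" definition.

## The statistical battery

* **Kruskal–Wallis** with mid-ranks and the tie correction
  $1 - \sum(t^3 - t)/(N^3 - N)$, referred to $\chi^2_{k-1}$. A fully
  tied sample returns $H = 0$, $p = 1$.
* **Steel–Dwass** all-pairs comparisons: each pair is mid-ranked in
  isolation, the standardized rank-sum statistic $z$ uses the
  tie-corrected variance, and the two-sided p-value is the upper tail of
  the studentized range for $k$ groups at infinite degrees of freedom at
  $\sqrt 2 |z|$. This is the large-sample approximation; no exact
  small-sample tables are used. Its approximation error is bounded in
  the test suite against a family-wise permutation null: at $n = 30$ per
  group the absolute error is a few times $10^{-2}$ at most, but at very
  small samples ($n = 4$ per group) the discreteness of the rank
  distribution makes the continuous tail deviate by up to ~0.1 — the
  asymptotic p-values should not be trusted at such sizes, and the test
  suite records this fact rather than hiding it.
* **ROC.** Thresholds sit at midpoints between adjacent distinct pooled
  marker values (plus infinite sentinels), which is why cut-offs on
  integer gray levels end in ".5". AUC uses the exact rank/concordance
  identity with ties counting one half. The operating point maximizes
  the Youden index, ties resolved toward higher specificity. The
  positive class is the *lower*-valued (darker) group by default,
  matching the direction of clinical interest; the orientation is a
  config entry, not an assumption.
* **Regression.** OLS of the gray mode on thickness, skewness, kurtosis
  and their three pairwise products, on raw (uncentered) covariates so
  coefficients refer to measurement scales. Mean-centering before
  forming products is available behind a flag for collinearity
  diagnostics. Two-sided t-tests with $n - 7$ degrees of freedom.

## What the simulator emulates — and what it does not

No public image set accompanies the study design this package
implements, so validation runs on a synthetic brightfield simulator with
known ground truth. Its physics is deliberately minimal:

* **Multiplicative absorbance.** Each stained cell traversal multiplies
  transmitted intensity by a transmittance in (0, 1] (nuclei darker than
  cytoplasm). This Beer–Lambert-style compounding is the mechanism that
  makes stacked, dense clusters dark, and it reproduces the long-tailed,
  high-kurtosis histograms the texture metrics are designed to detect.
* **Defocus** is Gaussian blur of each occupied plane's transmittance
  map, with sigma proportional to focal distance (1.5 µm of blur scale
  per µm of defocus by default). This is the minimal model under which a
  focus-variance thickness estimator is meaningful.
* **Populations.** Three presets differ in occupied layer count
  (HSIL-like 11–23, AGC-like 8–14, NILM-like 8–13 planes at 1 µm),
  packing density (10–16, 6–10 and 5–8 cells per plane), cell geometry
  (scant cytoplasm for the squamous-lesion-like preset, generous
  cytoplasm for the glandular-lesion-like one) and nuclear darkness.
  Layer ranges pin the ground-truth thickness ordering; the remaining
  values were chosen once so that the *orderings* of the group medians
  and of the pairwise AUCs match the clinical pattern (the dark, thick,
  dense population is separable from the other two; the two thin
  populations are nearly exchangeable on the gray mode). No attempt is
  made to match clinical medians numerically — those depend on staining
  chemistry, optics and case mix the simulator does not model.
* **Determinism.** Every cluster renders from an explicit seed;
  study-level sampling derives per-cluster seeds from the study seed by
  a fixed counter scheme, so any single cluster can be re-rendered in
  isolation and a study is reproducible byte-for-byte at the CSV level.

Not modelled: chromatin texture within nuclei, stain spectra beyond a
fixed per-channel cast, optical aberrations, overlapping clusters,
within-case correlation between clusters from the same specimen. Passing
tests on this simulator therefore demonstrate that the *measurement
chain and statistics* behave correctly on images whose generative truth
is known — not that any clinical accuracy figure transfers to real
slides.

## Problem sizes used in validation

The shipped validation battery uses 1,000 fuzzed samples for the
formula oracles, 200 datasets for the rank-test and ROC oracles, 50
noiseless stacks for thickness recovery, a 100-cluster-per-group study
for the end-to-end directional checks, and 2,000 null simulations for
the Kruskal–Wallis type-I calibration — sizes at which the Monte-Carlo
error of each check is far below the tolerance it asserts.

## A worked example

```{r example, eval = FALSE}
library(hcgtexture)

report <- run_study(study_config(
  synthetic = list(n_per_group = 30),
  output_dir = "hcg_demo",
  seed = 1
))

report$group_summaries   # median/IQR per metric per group
report$roc_summary       # pairwise AUCs and Youden cut-offs
tidy(report$regression)  # interaction-model coefficient table
```

The output directory then holds `records.csv` (one row per cluster),
the statistical tables, the run log, and the box-plot, gray-density and
ROC figures.

## Known limitations

* The simulator's thin-cluster histograms concentrate near the
  single-traversal gray level, so their modes sit higher than typical
  clinical values; only orderings across groups are meaningful.
* Steel–Dwass p-values rely on the large-sample studentized-range tail
  and are anti-conservative for group sizes below roughly 10.
* Thickness requires the in-focus span to be resolvable: with defocus
  blur much weaker than the layer spacing, neighbouring empty planes can
  score above threshold and widen the span by a layer or two (the ±2 µm
  validation bound).
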