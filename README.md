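# hcgtexture

Quantitative structural analysis of hyperchromatic crowded cell groups
(HCGs) in cervical cytology.

HCGs are densely packed, darkly staining three-dimensional cell clusters
that are notoriously hard to call benign or malignant from morphology
alone. Because a thick, cell-dense cluster absorbs more transmitted
light than a thin sparse one, its structure is encoded in the gray-level
distribution of the trimmed cluster region. `hcgtexture` measures that
encoding and runs the group-comparison statistics a screening study
needs, for cytopathology researchers and image-analysis developers.

Per cluster it computes:

* the **8-bit gray-scale value** — the mode of the 256-bin masked
  gray-level histogram (lower = darker cluster);
* **skewness** and **kurtosis** of the masked pixel distribution in the
  bias-corrected spreadsheet definitions
  (`skew = n/((n-1)(n-2)) * sum(((x-x̄)/s)^3)`, and the matching
  excess-kurtosis form), used as cellular-density proxies;
* **thickness** from a Z-stack, as the span from the deepest to the
  topmost in-focus layer, scored by variance of the Laplacian.

At the study level it provides tie-corrected Kruskal–Wallis tests,
Steel–Dwass all-pairs post hoc comparisons (studentized-range
approximation), ROC curves with Youden-index cut-offs on midpoint
thresholds, Pearson correlation matrices, and an OLS regression of the
gray mode on thickness, skewness, kurtosis and their pairwise
interactions. A seeded synthetic brightfield simulator (multiplicative
Beer–Lambert-style absorbance, distance-proportional defocus) generates
three-group studies with known ground truth for validation.

## Worked example

```r
library(hcgtexture)

report <- run_study(study_config(
  synthetic = list(n_per_group = 100),
  output_dir = "hcg_demo",
  seed = 1
))

dplyr::filter(report$group_summaries, metric %in% c("gray_mode", "thickness_um"))
#> # A tibble: 6 × 6
#>   metric       group         n median   q25   q75
#>   <chr>        <chr>     <int>  <dbl> <dbl> <dbl>
#> 1 gray_mode    AGC-like    100  218   217     218
#> 2 gray_mode    HSIL-like   100    4     2       6
#> 3 gray_mode    NILM-like   100  218   217     218
#> 4 thickness_um AGC-like    100   10     8      12
#> 5 thickness_um HSIL-like   100   15.5  12.8    19
#> 6 thickness_um NILM-like   100   10     8      11
```

The dark, thick, dense HSIL-like population separates cleanly on the
gray mode (its median sits near gray level 4, against ~218 for the two
thin populations) and is the thickest group (median 15.5 µm vs 10 µm),
while the two thin populations are nearly exchangeable — their pairwise
AUC is ~0.47 against ~0.98 for either comparison with the HSIL-like
group. Skewness and kurtosis are strongly positively correlated
(r ≈ 0.95), as expected when both track the same density mechanism.
`report$roc_summary`, `tidy(report$regression)` and the CSV tables in
the output directory hold the full battery; `records.csv` has one row
per cluster.

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/hcgstudy.R simulate --n 10 --seed 1 --out clusters/
Rscript inst/exec/hcgstudy.R run --config study.json
```

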