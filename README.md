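# clusterflim

Fitting-free analysis of TCSPC FLIM images by decay-histogram clustering.

## The problem

Fluorescence lifetime imaging microscopy (FLIM) distinguishes molecular
binding states and microenvironments by the *shape* of each pixel's photon
arrival-time histogram, independent of brightness. Quantifying that shape by
per-pixel curve fitting needs ~10⁴ photons per pixel for a biexponential
decay — far more than live-cell imaging at subcellular resolution can afford
without phototoxicity. `clusterflim` implements the fitting-free alternative:
pixels are grouped by k-means on the Euclidean distance between their
normalized, rebinned decay histograms, and the photons of each group are
accumulated into one high signal-to-noise **fluorescence lifetime signature
(FLS)** per cluster,

D(x, c) = sqrt( Σⱼ (xⱼ − cⱼ)² ),   FLSₖ = Σ_{pixels i in cluster k} xᵢ' ,

so a handful of cluster-level curves — fitted once with
I(t) = Σᵢ αᵢ exp(−t/τᵢ) deconvolved from the IRF, if lifetimes are wanted at
all — replace hundreds of thousands of per-pixel fits. The package targets
the screening use case: tracing where a labelled drug carrier goes inside
cells (receptor-bound → caveolae → lysosomes) and turning that into an
automated verdict.

It is written for microscopists and image analysts: tidyverse-style
data-frame outputs, `tidy()`/`glance()` summaries and `autoplot()` figures
for every result type.

## What is in the box

- `decay_cube()` / `read_cube()` / `write_cube()` — TCSPC decay cubes
  (row × col × 1024 time channels of 19.97 ps by default), multi-page TIFF
  with JSON sidecar on disk.
- `cluster_flim()` — the core pipeline: masking (< 10 counts/px), feature
  rebinning, k-means++ with restarts, FLS accumulation, lifetime-ordered
  false-color maps.
- `simulate_image()`, `validation_panel()` — a synthetic FLIM generator
  (multi-exponential species, Gaussian IRF convolution, Poisson noise) for
  ground-truth validation.
- `titration_curve()`, `confusion_rates()` — sensitivity/specificity scoring
  against ground truth versus photon budget.
- `fit_multiexp()` — per-FLS multi-exponential fitting by Poisson maximum
  likelihood with IRF deconvolution; τ_m,a, β_i, τ_m.
- `simulate_kinetics()`, `fit_kinetics()` — the four-pool first-order model
  of receptor-mediated endocytosis; `fit_saturation()`,
  `fit_displacement_hill()` for uptake and competition curves.
- `manders()`, `costes_threshold()` — Manders colocalization with automatic
  threshold search.
- `run_workflow()` / `write_report()` — the automated image-series pipeline
  with threshold-based assessment verdicts; a thin CLI lives in
  `inst/scripts/clusterflim`.

## Worked example

Simulate a five-species validation image at 170 counts/pixel and cluster it:

```r
library(clusterflim)

panel  <- validation_panel(5)                    # 5 biexponential species,
                                                 # mean lifetimes 0.20-1.53 ns
layout <- scene_layout(block_layout(128, 128, 5), mean_counts = 170)
sim    <- simulate_image(panel, layout, seed = 42)

res <- cluster_flim(sim$cube, k = 5, seed = 42)
res
#> <cluster_flim> k = 5 on 128 x 128 pixels (0 masked)
#> # A tibble: 5 × 6
#>   cluster n_pixels photons fraction tau_mean_ns color
#>     <int>    <int>   <dbl>    <dbl>       <dbl> <chr>
#> 1       1     3200  542805    0.195       0.194 #00FFFF
#> 2       2     3199  544524    0.195       0.859 #FFFF00
#> 3       3     3231  549802    0.197       1.46  #FF0000
#> 4       4     3431  583836    0.209       1.53  #00FF00
#> 5       5     3323  566199    0.203       3.14  #FF00FF
```

Each row is one cluster: its pixel count, accumulated photons, share of the
total signal, a moment estimate of its FLS mean lifetime (used only for
ordering — cluster 1 is always the fastest decay), and its display color.
`autoplot(res)` draws the false-color map, `autoplot(res, "fls")` the five
accumulated decay curves. Scoring against the known ground truth:

```r
keep <- !is.na(res$labels)
cm <- confusion_rates(res$labels[keep], sim$truth[keep],
                      match_labels(res$labels[keep], sim$truth[keep], 5))
round(macro_rates(cm), 3)
#> sensitivity specificity
#>       0.976       0.994
```

i.e. at 170 counts per pixel the clustering assigns 97.6% of pixels to the
correct species — with histograms far too sparse to fit individually.

Fitting the transport model to a cluster-fraction time series (here a
noiseless trajectory from the model itself):

```r
tr  <- simulate_kinetics(c(8, 28, 88, 107), times = c(15, 45, 90, 180, 270))
obs <- tibble::tibble(time_min = tr$time_min, cyan = tr$c_pm,
                      yellow = tr$y_pm + tr$y_cp, red = tr$r_cp)
fit_kinetics(obs)
#> <kinetic_fit> time constants (min):
#>          tau1 tau_m1 tau2 tau3
#> estimate    8     28   88  107
#> se          0      0    0    0
```

`tau1`/`tau_m1` are the forward/backward constants of caveolar capture at the
membrane, `tau2` the internalization and `tau3` the lysosomal accumulation
time, in minutes.

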