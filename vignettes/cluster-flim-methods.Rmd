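---
title: "Cluster-FLIM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-FLIM: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterflim)
```

## The problem

Time-correlated single-photon counting (TCSPC) FLIM records, for every pixel
of an image, a histogram of photon arrival times — the fluorescence decay of
whatever fluorophore population occupies that pixel. The decay shape encodes
the fluorophore's microenvironment (binding state, viscosity, pH), so a
labelled drug carrier changes its *fluorescence lifetime signature* (FLS) as
it moves from receptor binding at the membrane through caveolar vesicles into
lysosomes. The catch is photon statistics: a reliable biexponential fit needs
on the order of 10^4 photons, while a live-cell pixel at useful magnification
and acquisition time holds tens to a few hundred.

Cluster-FLIM sidesteps per-pixel fitting. Pixels whose decays have the same
*shape* are grouped by k-means on the Euclidean distance between their
(normalized, rebinned) decay histograms, and all photons of a group are
accumulated into one high signal-to-noise FLS per cluster. Fitting, when
wanted at all, happens once per cluster instead of once per pixel, and the
cluster label map itself is the segmentation.

## The clustering pipeline

`cluster_flim()` composes three steps:

1. **Features** (`build_features()`): pixels below `min_counts` photons are
   masked (default 10 counts/px — below that a histogram carries essentially
   no shape information and would only add noise to the clusters). Remaining
   histograms are rebinned from the instrument's 1024 channels to `b`
   contiguous bins and normalized to unit area, so that clustering is driven
   by decay shape rather than brightness. A `normalize = FALSE` escape hatch
   clusters raw counts for users who want brightness to participate.
2. **Partitioning** (`kmeans_partition()`): Lloyd iterations from kmeans++
   seeding, best of 10 restarts by within-cluster sum of squares,
   deterministic given a seed. Assignment ties break toward the lower cluster
   index; an emptied cluster is reseeded with the point farthest from its
   center. Tiny two-cluster instances (n ≤ 12) are solved by exhaustive
   enumeration of the same objective, since restarts cannot guarantee the
   optimum that the package's own invariants promise there.
3. **Accumulation** (`accumulate_fls()`): per-cluster, channel-wise integer
   sums at full 1024-channel resolution. Photon conservation is exact and is
   asserted as an integer identity in the tests.

Clusters are re-indexed by ascending mean lifetime of their FLS before colors
are assigned, so cluster 1 is always the fastest decay (cyan), then yellow,
then red. The ranking uses a background-corrected first-moment estimate
(`tau_moment`), which is monotone in the true mean lifetime and costs nothing
— only the *order* matters for display, not the value.

### Why `b = 16` feature bins

The feature dimension trades shape resolution against shot noise per bin. At
the photon budgets this method targets (40–170 counts/px), Euclidean distance
on unit-area features is shot-noise limited: with 1024 raw channels almost
every channel holds 0 or 1 photons and distances are dominated by noise; with
very few bins the decay shape is lost. A sweep over `b` on simulated
five-species images showed classification accuracy peaking around 16 bins
(64 channels, ~1.3 ns per bin) across 40–170 counts/px, with 8 and 32 close
behind and 64+ clearly worse at the low end. `b = 16` is therefore the
default; it is a plain argument for users with different time ranges.

### Choosing k

The number of clusters is user-supplied, as the method itself provides no
selection rule. `scan_k()` reports, per candidate k, the inertia, the mean
silhouette width, and the adjusted Rand index between partitions from two
seeds — in practice the partition is seed-stable (ARI ≈ 1) up to the number
of genuinely distinct signatures and degrades beyond it.

## The synthetic-data generator

Because no raw FLIM data are publicly deposited, every quantitative claim is
validated in silico. The generator draws, per pixel, independent Poisson
counts around an expected curve built as: multi-exponential decay
`I(t) = Σ α_i exp(-t/τ_i)` sampled at channel midpoints → linear convolution
with the instrument response function (IRF) → rescaled to the requested decay
photons → plus constant background. Defaults mirror the instrument the
package emulates: 1024 channels × 19.97 ps, Gaussian IRF of 100 ps FWHM.
Poisson-per-channel sampling (rather than multinomial at fixed total) is the
physically correct photon-counting model; per-pixel totals then fluctuate
around the nominal mean counts. Repetition-period wrap-around of slow tails
is not modelled: at lifetimes ≤ ~2.4 ns and a ~51 ns laser period the folded
tail is negligible, and keeping the convolution linear keeps the closed-form
oracles exact.

### The validation panel

`validation_panel(k)` builds the stand-in for a dye measured in k = 4 or 5
microenvironments: biexponential species whose amplitude-weighted mean
lifetimes are evenly spaced on 0.20–1.53 ns, the span of the environments the
method was validated against. The per-environment decay compositions are not
publicly tabulated, so the panel is a documented construction, not a claim
about the real samples: species alternate between near-monoexponential
(lifetime ratios 0.97/1.05 of the mean, amplitudes 0.625/0.375) and strongly
biexponential character (ratios 0.22/3.10, amplitudes 0.729/0.271). The
alternation is deliberate. Real microenvironments differ in their full decay
signature, not merely in mean lifetime — distinct environments can even share
a mean lifetime and still be separable by shape. A panel whose species differ
*only* by mean lifetime is strictly harder than that: a known-curve Poisson
maximum-likelihood classifier (the Bayes ceiling, which no clustering method
can beat) already misclassifies more than 5% of pixels at the documented
photon budgets for such a panel, so it cannot represent samples that were in
fact discriminated at the 95% level. With the alternating panel the Bayes
ceiling sits comfortably above 95% at all four operating points and the
unsupervised pipeline's margin below that ceiling is what the validation
measures.

What the generator does **not** emulate: detector afterpulsing, dead-time and
pile-up, autofluorescence mixtures within a pixel, spatially correlated
species (real cells have structured layouts, which if anything helps a
human but not this pixel-independent analysis), and measured (non-Gaussian)
IRF shapes, although `irf_model()` accepts a measured vector. Passing the
in-silico titration therefore demonstrates the statistical behaviour of the
algorithm under the stated noise model, not robustness to every instrument
artefact.

### Validation scale

The titration reproduced by `scripts/acceptance.R` and the acceptance tests
uses 128 × 128 pixel images (16 384 pixels, ~3 300 per species at k = 5),
balanced equal-area block layouts, five replicate images per photon-budget
level in the script (two in the test suite), and scores macro-averaged
one-vs-rest sensitivity and specificity after optimal (exhaustive) matching
of cluster labels to ground truth. Balanced layouts make per-class
sensitivity and specificity prevalence-free, which is also why macro
averaging is the honest aggregate.

## Decay fitting

`fit_multiexp()` fits 1–4 exponential components, convolved with the IRF,
plus a flat background, by Poisson maximum likelihood. FLS channels span four
or more decades of counts; unweighted least squares over-weights the peak and
Neyman-weighted χ² biases the low-count tail, while the Poisson likelihood is
correct at any count level. The reduced Pearson χ² is still reported for
comparability with the FLIM literature.

Parameterization: each component carries a lifetime and a component photon
count, both fitted on the log scale (positivity for free); the decay
amplitudes `α_i` then follow from the identity that component photons are
proportional to `α_i τ_i`. Lifetimes are bounded to [0.01, 20] ns; a
parameter landing on a bound sets an `at_bound` flag rather than failing.
Multi-start over a decade-spaced lifetime grid (capped at 10 starts) guards
against the well-known multi-exponential local minima. The background is
estimated from the pre-pulse window — the channels strictly before the IRF
rise, located from the IRF's own cumulative sum — and held fixed; a
user-supplied value overrides. Derived quantities follow the standard
definitions: amplitude-weighted mean `τ_m,a = Σ α_i τ_i`, intensity fractions
`β_i = α_i τ_i / Σ α_j τ_j`, component-weighted mean `τ_m = Σ β_i τ_i`, with
`τ_m,a ≤ τ_m` by Cauchy–Schwarz (equality only for a single component).
Standard errors come from the numeric Hessian of the negative log-likelihood,
delta-transformed to natural scale. `scan_components()` reports BIC across
n = 1..4 for users deciding the component count.

## The four-pool transport model

The endocytosis scheme — membrane receptor binding ⇌ caveolae capture →
vesicle internalization → lysosomal accumulation — is the unique first-order
ODE realization of the reaction chain, with time constants `tau1`, `tau_m1`
(back reaction), `tau2`, `tau3` in minutes. The printed forms of the original
differential equations are not recoverable from the source material, so the
implementation states the realization explicitly in `kinetic_rhs()` and
treats it as the model. The system is closed (derivatives sum to zero;
fractions sum to one along every trajectory) and linear, so
`simulate_kinetics()` evaluates the matrix exponential exactly by default,
with `deSolve::ode` available as an independent numerical check (the two
agree to 1e-8 in the tests).

`fit_kinetics()` fits the three *observable* cluster fractions — cyan,
yellow, red, where observed yellow is the sum of the membrane and cytoplasmic
caveolar pools, since intensity imaging cannot separate them without a
membrane segmentation — by least squares over the log time constants, from a
deterministic 16-point start grid. The initial state defaults to all
receptor-bound, `(1, 0, 0, 0)`, matching the earliest observation. Fractions
rather than absolute intensities are fitted, which removes photobleaching and
excitation-power drift from the problem. With five time points and three
observables the back-transition constant `tau_m1` is weakly identified; the
reported standard errors reflect this, and the recovery study in the
acceptance suite uses the *median* over 50 noisy replicates for that reason.
The recovery study applies 5% *relative* Gaussian noise to the fractions —
the natural reading for intensity-derived quantities; additive noise of 0.05
would swamp the small early-time lysosomal fraction entirely.

`fit_saturation()` (Michaelis–Menten-like uptake, `I = I_max·c/(K50 + c)`)
and `fit_displacement_hill()` (modified Hill displacement,
`A = A_max + (A_min − A_max)·c^n/(K50^n + c^n)`) are ordinary
Levenberg–Marquardt fits with data-driven starts and positivity bounds on
`K50` and `n`.

## Colocalization

`manders()` computes thresholded Manders coefficients with a Costes-style
automatic threshold: a major-axis (orthogonal) regression through the joint
intensity distribution, thresholds walked down one intensity quantile at a
time until the Pearson correlation of pixels below both thresholds is ≤ 0.
The coefficient convention is `M1 = Σ A over {A > T_A and B > T_B} / Σ A over
{A > T_A}` (and symmetrically for M2): the denominator is channel A's
above-threshold intensity and the numerator additionally requires the partner
channel above its threshold. This is the convention that keeps both
coefficients in [0, 1] and makes channel swapping exchange M1 and M2 exactly.
Costes randomization significance testing is not implemented.

## The automated workflow

`run_workflow()` chains clustering over an image series, matches clusters
across images to a reference image by minimal Euclidean distance between
unit-area FLSs (a one-to-one assignment, solved exhaustively for k ≤ 8) so
colors and fraction traces stay consistent over time, quantifies
photon-weighted cluster fractions, and applies an `assessment_rule()` — e.g.
"at least 90% of the signal in the red cluster" as a lysosomal-trapping
read-out. Fractions are photon-weighted because the biological quantity of
interest is the share of carrier *material* in each state, and photons track
material at fixed brightness; a pixel-weighted alternative is available.
Reports carry the seed, a config digest and the package version, and
identical config plus seed reproduces byte-identical CSV/JSON output.

## File formats

The on-disk interchange format is a multi-page 16-bit TIFF (one page per time
channel) with a JSON sidecar for the channel width and metadata. Counts above
65535 are rejected with advice to rebin rather than silently truncated.

## Known limitations

- k-means with Euclidean distance on normalized features is not the Bayes
  classifier for Poisson data; at very low counts a likelihood-based
  assignment would do better. The gap is the price of the method's speed and
  model-freeness.
- Cluster-count selection is left to the user (with `scan_k()` as a guide).
- Per-pixel lifetime *values* are never estimated — only cluster membership
  and per-cluster FLS fits. That is the point of the method, but it means
  sub-cluster heterogeneity is invisible.
- The Becker & Hickl SDT container and HDF5 are not read by this build; data
  arrive via TIFF (or are simulated).
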