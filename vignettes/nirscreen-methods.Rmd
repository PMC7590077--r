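---
title: "Multistage NIR screening for cocaine: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage NIR screening for cocaine: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscreen)
```

## The screening problem

Handheld near-infrared (NIR) spectrometers covering only 740–1070 nm are
cheap and fast enough for on-scene presumptive drug testing, but their
spectra are information poor: vibrational overtone and combination bands in
this window are broad and weak, and diffuse-reflectance measurements of
powders add large additive baseline shifts (vial positioning, per-device
response) and multiplicative scatter (particle size). `nirscreen`
implements a multistage chemometric model that, from a library of labelled
scans, decides whether an unknown powder contains cocaine, estimates its
concentration in weight percent, and suggests a sample identity — while
*abstaining* rather than guessing when the spectrum resembles nothing in the
library.

A scan is 331 reflectance values on a fixed 1 nm grid; a sample is scanned
several times on several devices, and decisions are taken per sample by
majority voting over its replicate scans.

## Preprocessing

Every model consumes spectra preprocessed scan-wise in a fixed order:

1. **SNV (standard normal variate)** — centre each spectrum to mean 0 and
   scale to unit standard deviation (sample, n−1 denominator by default).
   SNV removes exactly the additive offset and multiplicative scatter terms
   of the measurement model: `snv(a·x + b) = snv(x)` for any `a > 0`.
   A flat-line (zero-variance) scan cannot be normalised and is a hard
   error, named by scan id.
2. **Savitzky–Golay derivative** — a fused smoothing + differentiation
   filter: a degree-3 polynomial is fitted in a 19-point window around each
   interior grid point and the derivative of that fit (first or second
   order, in units per nm) is returned. We deliberately use one fused
   convolution rather than smoothing followed by finite differences; the
   filter is linear and exact on polynomials up to the fit degree. The 9
   edge points on each side are dropped rather than extrapolated, so a
   331-point spectrum yields 313 derivative values (749–1061 nm). The
   19-point window is the package default; whether such a window is best
   read as the smoothing span or the full fused filter is ambiguous in the
   chemometrics literature, so both the window and the polynomial order are
   configurable.
3. **Region of interest (optional)** — restrict to the cocaine-selective
   window: 839–939 nm for first-derivative spectra (101 points on the 1 nm
   grid) and 839–914 nm for second-derivative spectra (76 points), bounds
   inclusive. ROI selection increases sensitivity to cocaine at some cost
   in selectivity for identifying non-cocaine compounds, so the full
   spectrum is the default.

## Submodel A: abstaining dual kNN

The first and more reliable submodel matches a preprocessed query spectrum
against every library scan by two measures: Euclidean distance and Pearson
correlation. Up to 9 neighbours with the smallest distances **at most
0.1**, and up to 9 neighbours with the highest correlations **at least
0.98**, are accepted (inclusive comparisons; ties broken by library row
order). The two lists form one multiset of at most 18 votes — a scan
accepted by both metrics deliberately counts twice. The predicted identity
is the modal identity of the multiset (ties broken by smallest mean
neighbour distance), and the predicted concentration is the arithmetic mean
of the neighbours' known cocaine weight percentages.

If **no** neighbour passes either threshold the submodel returns `no_match`
— the mechanism by which novel compounds, absent from the library, produce
no spurious identification. The 0.1/0.98 defaults are tuned for
SNV + first-derivative full spectra and are configurable for other
preprocessing variants.

Before any training, replicate-scan outliers are flagged by a PCA score
rule: a PCA (mean-centred, unscaled) is fitted on the whole preprocessed
library, and each scan's mean Euclidean distance to the other scans of its
sample is computed in the space of score components 1–3. Scans whose mean
distance lies strictly above the 99% empirical quantile (linear
interpolation between order statistics) are flagged and excluded from all
training sets; incoming query scans are never silently dropped. The
reference distribution for the quantile is **pooled over the library** by
default: a per-sample quantile of n replicate values flags the per-sample
maximum almost surely (about 1/n of all scans regardless of quality),
whereas the pooled rule flags only scans extreme relative to the
library-wide replicate spread. `scope = "per_sample"` is available for the
stricter local reading. Note the pooled rule caps the flagged fraction near
1% by construction; if more than ~1% of scans are corrupted, the excess
necessarily survives.

## Submodel B: gated form classifier + bagged-tree regressors

Scans the kNN submodel abstains on fall through to an ensemble path:

* **PCA prescaling** — a PCA on the training spectra, keeping the smallest
  number of components whose cumulative explained variance reaches 99%.
* **Neural-network form classifier** — a single-hidden-layer network
  (8 hidden units, logistic output, cross-entropy loss, weight decay 1e−4)
  trained on the PC scores of cocaine-containing scans only, targets
  HCl → 0, base → 1. The two cocaine forms (protonated salt vs free base)
  are spectrally distinct and modelled as separate classes. At prediction
  time every scan is scored; probabilities ≤ 0.05 are called `hcl`, ≥ 0.95
  `base`, and anything between is **unassigned** — the gate through which
  non-cocaine scans are expected to fall. The topology, epochs and decay
  are package choices (the smallest standard binary scorer adequate for
  ~19-dimensional inputs); all are configurable and all fits are seeded and
  bit-reproducible.
* **Per-form bagged regression trees** — for each form, 25 regression trees
  (CART, minimum leaf 5, grown without a complexity penalty), each fitted
  on a bootstrap resample of that form's scans; the prediction is the
  ensemble mean, clipped to [0, 100] wt%. Trees consume the preprocessed
  spectra directly rather than PC scores (configurable); the prescaling is
  attached to the classifier only. Samples with 0 wt% cocaine have form
  `none` by the metadata invariant and never enter regressor training.

## Decision hierarchy and voting

Per scan: if the kNN submodel returned a result, the scan is **positive iff
its kNN concentration exceeds the threshold** (default 20 wt%, strict `>`;
a prediction exactly at the threshold is negative) and submodel B is
ignored. If the kNN abstained, the scan is positive iff the gated form call
is `hcl` or `base` **and** the submodel-B concentration exceeds the
threshold. Everything else is negative.

Per sample: strict majority over the replicate verdicts; an even split
resolves **negative**, because false positives are the costlier error in a
screening test that triggers judicial action. The sample identity is the
modal kNN identity among kNN-decided scans.

The threshold is a tunable operating point: `threshold_curve()` re-applies
the decision rule over a grid of thresholds to predictions computed once
(ground-truth labels held fixed at the evaluation convention) and reports
the smallest zero-false-positive threshold, the maximum-accuracy threshold,
and the largest threshold keeping false negatives at or below a tolerance.
Both rates are weakly decreasing in the threshold by construction.

## Cross-validation

Replicate scans are never split between training and validation:

* the kNN submodel is validated **leave-one-sample-out** — all scans of the
  query's sample are removed from the candidate pool before ranking;
* submodel B is validated on **grouped 10-fold** splits, samples assigned
  whole to folds (seeded, near-equal sizes).

Outlier-flagged scans are excluded from every training set and receive no
verdict. The library PCA and outlier mask are computed once on the full
library rather than refit inside each fold, matching the model-building
sequence the method describes; at the library sizes used here the
difference is negligible because the mask is driven by within-sample
replicate spread.

Ground truth for confusion tallies: a sample is positive iff it contains
cocaine **above** the threshold. Cocaine-containing samples at or below the
threshold are deliberate false negatives of the screening rule and are
excluded from the tally by default (reportable separately via
`include_subthreshold = TRUE`).

## The synthetic benchmark

No public scan library exists for this instrument class, so the package
ships a seeded generator. A scan is simulated as

```
a · Σ_c fraction_c · signature_c(λ) + b_scanner + b_scan + noise(λ)
```

with `a = exp(N(0, 0.08²))` per-scan multiplicative scatter, additive
offsets `b_scanner ~ N(0, 0.06²)` (drawn once per device) and
`b_scan ~ N(0, 0.04²)`, and i.i.d. `N(0, 0.002²)` noise per wavelength.
Component signatures are smooth Gaussian band sets on a sloped baseline —
synthetic stand-ins labelled as such, not measured spectra. Linear mixing
is a simulation convention (Beer–Lambert-like), adequate for exercising the
model. Spike corruption for outlier tests adds a fixed offset to a random
20-point window, drawn in a post-pass so the clean scan values of a design
are identical whether or not injection is on.

The frozen benchmark (`benchmark_design()`, seed 20) has 72 samples × 5
scanners × 5 replicates = 1800 scans: cocaine HCl dilution ladders in
caffeine (42/34/30/25/20/19/10/5/0 wt%), lactose, acetaminophen and
inositol; cocaine base ladders in caffeine and lactose; the eight pure
adulterant components; and eight equal-weight adulterant mixtures. Two
deliberate design features:

* **Noise calibration.** Band widths (22–45 nm) and noise levels were
  calibrated once so that, after SNV + first derivative, replicate scans of
  one sample sit well inside the 0.1 distance threshold, all pure
  components sit well outside it (minimum pairwise distance ≈ 0.27), and
  ladder steps of ≤ 10 wt% remain matchable mainly through the correlation
  metric — so both kNN metrics and the submodel-B fallback are genuinely
  exercised. The parameters were then frozen.
* **Recurring negatives.** Every negative composition occurs in two
  independent samples, because common cutting agents recur across seizures.
  Leave-one-sample-out removes a sample's own scans, so a negative without
  a compositional twin would be matched by nothing and land in the
  neural-net path, whose gates are not reliable for inputs far from the
  training manifold. The twin structure reproduces the behaviour of a
  mature library, where negatives match other negatives at ~0 wt% and are
  decided by the kNN path.

What passing the benchmark does **not** show: robustness to real instrument
drift, non-linear mixing, particle-size effects beyond a scalar scatter
factor, coloured or packaged samples, or the spectral diversity of real
seizures. The benchmark's separation is also cleaner than real data — its
negatives are predicted at exactly 0 wt%, so the zero-false-positive
threshold of the sweep sits at 0 rather than at a mid-range value.

Problem sizes throughout the test suite (1800-scan benchmark, 200 random
libraries for the ranking oracle, 200 replicates for the convergence check)
were chosen to exercise every decision path at desk scale.

## Numerical and degenerate-input choices

* Empirical quantiles use R's default linear interpolation (type 7);
  outlier flagging uses strict `>`.
* kNN ties (equal distance or correlation) break by library row order, so
  results are permutation-stable given a fixed library ordering and
  reproducible across runs.
* Identity-vote ties break by smallest mean neighbour distance.
* Zero-variance (flat-line) scans are hard errors at SNV; zero-variance
  inputs to `concentration_fit_metrics()` raise an undefined-R² error
  rather than returning `NaN`.
* All stochastic fits (fold assignment, network initialisation, bootstrap
  resampling, simulation) take explicit seeds and save/restore the caller's
  RNG state; identical (data, config, seed) gives bit-identical artifacts.

## Known limitations

* The neural-net gate is only trustworthy near the cocaine training
  manifold; compounds far outside it can receive saturated probabilities.
  The library must therefore carry representative negatives — the same
  operational requirement the underlying screening approach has.
* The pooled outlier quantile caps the flagged fraction near 1 − q of the
  library.
* Signatures are synthetic; no conclusions about real NIR selectivity for
  any specific adulterant follow from this package's tests.
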