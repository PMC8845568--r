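---
title: "Methods: virocell identification from single-cell Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virocell identification from single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanvirocell)
```

## The problem

A culture sampled after virus addition is a mixture: some cells are
virocells (their metabolism redirected to virion production), the rest
are ordinary ribocells. Single-cell Raman microspectroscopy resolves the
biochemical composition of individual cells — nucleic-acid, protein and
lipid bands each have characteristic wavenumbers in the 600–1,800 cm⁻¹
fingerprint region — so infection can be called per cell rather than per
culture. This package implements the statistical machinery for that
call: spectral preprocessing, multivariate group comparison, marker-band
selection, and a control-calibrated univariate classifier.

## Preprocessing model and assumptions

An observed single-cell spectrum is treated as

> Raman signal (sharp bands, ~10–16 cm⁻¹ FWHM) + smooth fluorescence
> background + noise,

and preprocessing runs in a fixed order: **trim → quality filter → SNIP
baseline subtraction → TIC normalization**. Quality control must precede
the statistics; the baseline must be removed before normalization so the
total ion current measures Raman signal rather than background.

* **Trim** (`trim_low = 600`, `trim_high = 1800` cm⁻¹, closed interval):
  restricts to the fingerprint window. No resampling is ever performed;
  cells must share one wavenumber grid (tolerance 0.01 cm⁻¹ at import),
  so every later operation is exactly per-point.
* **SNIP** (`snip_iterations = 100`): for clipping half-window
  m = 1…100, each point is replaced by min(itself, mean of neighbours at
  offset ±m); edge points whose offset falls outside the spectrum stay
  untouched. On a ~1 cm⁻¹ grid, 100 iterations clip structures much
  wider than a Raman band while following the fluorescence curvature.
  Without the optional log-log-sqrt compression the estimate never
  exceeds the input and is pointwise non-increasing in the iteration
  count; a linear (or any convex) baseline is a fixed point. Negatives
  created by subtraction are clipped to 0 because TIC normalization and
  the band-ratio statistics assume non-negative intensities.
* **TIC normalization**: each cell is divided by its summed intensity.
  This cancels cell-to-cell brightness (focus, cell size, laser power)
  exactly, which matters because the virocell ratio is *not*
  scale-invariant (one numerator band against two denominator bands:
  scaling a spectrum by c scales the ratio by 1/c).
* **Quality filter** (raw intensities): `low_intensity` when the total
  ion current falls below `qc_min_tic` (default 10⁴ counts, far below a
  normally focused cell); `cosmic_ray` when a point's robust z-score
  (median/MAD within the cell) exceeds `qc_spike_zscore = 8` while the
  contiguous run above half that score is at most
  `qc_spike_max_width = 3` points — genuine Raman bands exceed high
  z-scores too, but over runs of 10+ points, which is what separates
  them from 1–2-point cosmic-ray spikes; `saturated` when any point
  reaches `qc_max_intensity` (off by default). "Burnt" cells have no
  separate criterion; they surface as low-intensity and/or saturated
  spectra.

## Multivariate comparison

PCA is a column-mean-centered SVD; component signs are fixed so each
loading vector's largest-magnitude element is positive, which makes
scores, loading profiles and downstream regression tests reproducible.
PCoA (classical metric scaling) is run on either Euclidean or spectral
contrast angle distances; on Euclidean distances it reproduces the PCA
scores up to sign, which the test suite asserts to 10⁻⁶. Ward D2
dendrograms use the standard agglomerative update (and are checked
against a brute-force Lance–Williams enumeration on small instances).

**MRPP** quantifies group separation without distributional assumptions:
δ is the group-size-weighted mean within-group pairwise distance, its
expectation is estimated as the mean of δ over label permutations
(default 999), and the chance-corrected within-group agreement is
A = 1 − δ_obs/E[δ]. The permutation p uses the add-one estimator so it
is never 0 and never below 1/(n_perm + 1); the seed is a mandatory
argument. Group weights n_g/N are the default, with (n_g−1)/(N−K)
available. MRPP runs on the full preprocessed spectra (not on PCA
scores), the more conservative of the two readings of the source
analysis; the Euclidean metric is the default, with contrast-angle
distances available since both give nearly identical ordinations.

The **contrast profile** is defined here as the per-wavenumber
difference of TIC-normalized class mean spectra (infected − control):
positive density means a band is more prominent in infected cells. The
upstream "contrast plot" implementation is not specified anywhere in
detail; the plain mean difference reproduces its documented sign
convention, which is the property the pipeline actually uses. The
magnitudes of published density values are therefore not comparable to
ours, only their signs and ranking.

## OPLS-DA and VIP

The two-class O-PLS model encodes classes as 0/1 (alphabetical order,
for sign stability), centers X and y, extracts `n_ortho` (default 1)
response-orthogonal components by deflation, then fits a single
predictive PLS component. With `n_ortho = 0` the predictive component
equals the first NIPALS PLS1 component (asserted to 10⁻⁸ in the tests).
VIP for a one-predictive-component model reduces to √p·|w_j|, so
mean(VIP²) = 1 exactly and a single informative wavenumber attains the
closed form VIP = √p. VIP is computed from the predictive component
only: the orthogonal components are response-irrelevant by construction.
Whether normalization should precede OPLS is genuinely open; we fit on
baseline-corrected, TIC-normalized spectra for consistency with every
other stage.

## Marker selection and the virocell ratio

Candidate marker bands are local extrema of |density| with topographic
prominence of at least 20% of the maximum |density| (tunable). Because
candidates are data-driven extrema — under the null they sit exactly
where noise happened to separate the groups most — raw per-band p-values
are anti-conservative by construction. Retention therefore uses a
Westfall–Young maxT permutation test: a candidate survives at level α
(default 0.01) only if its |density| beats the permutation distribution
of the *axis-wide maximum* |density| (499 label permutations, a local
seeded RNG stream that leaves the caller's random state untouched, so
selection is deterministic). The per-band rank-sum p-value is still
reported per candidate. Positive density assigns a band to the ratio
numerator, negative to the denominator, and candidates within ±6 cm⁻¹
of a packaged assignment-table entry inherit its biomolecule label.

The classifier itself is the band ratio

ratio = (I₁₅₇₆ × 2) / (I₁₀₀₃ × I₁₆₇₁),

nucleic acid over proteins, with the ×2 multiplier kept verbatim from
the published form (its motivation is not stated there; it rescales one
numerator band against two denominator bands and is configurable). Band
intensities are the maximum preprocessed intensity in a ±4 cm⁻¹ window
— peak shoulders carry part of the infection signal, so a window
maximum is more robust than a single grid point; `window_halfwidth = 0`
degenerates to nearest-point lookup. Cells with a non-positive band
intensity are excluded from the ratio table with a logged reason rather
than producing infinite ratios.

**Cutoff calibration.** The published description mixes "99% confidence
interval" (methods) with "cells do not exceed … (99% probability)"
(results). Only the second reading yields a per-cell statement, so the
cutoff is a one-sided normal tolerance bound on individual cells:
cutoff = mean + z₀.₉₉·sd of the control-group ratios (sample sd). A
confidence interval of the mean would shrink with n and could not bound
individual cells. Shapiro–Wilk results for both groups are stored as a
validity note: control ratios should look normal; infected-sample
ratios should not, being a mixture. A cell is called a virocell when
its ratio strictly exceeds the cutoff; calls in the control group are
false positives by construction. Dunn's test (joint Kruskal–Wallis
ranks, tie-corrected z, Benjamini–Hochberg adjustment by default — no
adjustment is specified upstream) compares ratios across host/condition
groups when more than two are present.

A caveat the test suite quantifies rather than hides: a product/quotient
of band intensities is inherently slightly right-skewed even when every
component is symmetric, so the normal tolerance bound is approximate.
With the default generator the held-out exceedance of a 99% cutoff
calibrated on 250 control cells averages ≈1.5% rather than 1.0%, and a
single n = 250 calibration adds sampling noise of several tenths of a
percentage point. The corresponding validation check is asserted at the
idealized binomial-only tolerance, so its outcome documents this gap
explicitly — it is a property of normal tolerance bounds applied to a
mildly skewed ratio, not an implementation defect.

## What the synthetic generator emulates — and what it does not

Each cell is `brightness × Σ Gaussian bands + polynomial baseline
(+ fluorescence hump) + heteroscedastic Gaussian noise (+ cosmic-ray
spikes)`, clipped at 0, on a 600–1,800 cm⁻¹ step-1 grid. Bands sit at
the packaged assignment-table wavenumbers with FWHM 10–16 cm⁻¹ (typical
for biological Raman bands) and amplitudes chosen once to give a
realistic single-cell spectrum; brightness is lognormal
(`cell_amplitude_cv = 0.15`); per-band lognormal jitter
(`band_cv = 0.015`) models biological composition variation and gives
control-group ratios a cv of ≈3%, close to the ≈2.6% implied by a
published 99% control bound of 1.06 around a mean ratio near 1 — and,
importantly, control ratios that pass Shapiro–Wilk at n = 250, as
reported for real uninfected cells. Noise is additive Gaussian with sd
= `noise_sd`·√(signal+1) (default 0.2), approximating shot noise; this
is what makes the autofluorescence preset degrade group separability:
the hump (amplitude 8,000, roughly 10× the strongest band) inflates
shot noise across the spectrum, attenuating MRPP agreement even after
the baseline itself is subtracted — the archaeal failure mode. The
infected sample is a mixture: only `virocell_fraction` (default 0.45)
of its cells carry the planted fold-changes (1,576 ×1.5; 1,003 and
1,671 ×0.7 for the phi6-like preset; inverted for phi29-like), with a
late-stage sub-fraction (default 0.5) additionally scaled at the
1,448 cm⁻¹ lipid band. The control sample never contains virocells.

Not emulated: instrument response functions, wavenumber calibration
error, Mie scattering, true photon (Poisson) statistics, band-shape
changes (only amplitudes move), and correlated biological variation
across bands. Passing tests therefore demonstrate the statistical
machinery is correct under the stated generative model — not that the
effect sizes match any real virus–host system; the planted fold-changes
are chosen for testability and are not estimates of real data.

## Numerical and design choices

* Import rejects heterogeneous wavenumber grids (> 0.01 cm⁻¹ deviation)
  instead of interpolating; duplicate wavenumbers or cell ids and
  non-finite values are hard errors naming the offending cell.
* Text serialization uses 15 significant digits; round-trips are exact
  at double precision for practical intensities.
* The spectral contrast angle clamps the cosine into [−1, 1] before
  `acos` to guard against rounding; zero-norm spectra are errors.
* PCoA keeps the non-negative-eigenvalue coordinates and errors only
  when no positive eigenvalue exists; Ward clustering requires the
  Euclidean metric and inherits `hclust`'s deterministic tie handling.
* Degenerate inputs are reported, not silently patched: constant
  samples make Shapiro–Wilk return a flagged degenerate result; a
  zero-variance control group yields `cutoff = mean` with a degenerate
  flag; an all-flagged QC input stops the pipeline with the stage name.
* All randomness is seeded at the interface (`mrpp`, `scenario_config`,
  `run_config` demand a seed); the pipeline splits its one top-level
  seed deterministically per stage, and two runs with the same config
  produce byte-identical numeric tables.
* Test problem sizes: oracle comparisons run on 6–20-cell instances
  where exhaustive enumeration is feasible; calibration simulations use
  200 replicates; the cutoff-coverage check calibrates on 250 cells and
  evaluates on 10,000. These sizes make the whole suite run in a few
  minutes while keeping binomial error bands meaningful.

## Limitations

The classifier assumes the three marker bands exist and move
monotonically with infection; systems whose response inverts (protein-up
rather than nucleic-acid-up) still separate by rank-sum test on the
ratio, but the one-sided upper cutoff then calls no cells — a lower
cutoff would be needed, which we expose implicitly via the configurable
marker roles rather than automatically. Strong autofluorescence degrades
every stage by inflating shot noise; the package detects the resulting
loss of separation (MRPP) but does not correct it (bleaching is an
acquisition-time remedy, out of scope). The contrast-profile density is
a mean difference of normalized spectra; its absolute scale is not
comparable across instruments or to published density tables.
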