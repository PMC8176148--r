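---
title: "Resting-state MEG band power, envelope connectomes and group classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megconn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`megconn` implements a complete resting-state MEG group-study pipeline at
the source level: a synthetic cohort generator with plantable group
effects, sensor-space cleaning and epoching, LCMV beamforming over a
spherical head model, Welch band power, leakage-corrected
amplitude-envelope-correlation (AEC) connectomes, covariate-adjusted
permutation statistics with FDR control, and a nested feature-selection /
classification workflow that compares regional power against functional
connectivity as discriminative markers. The emulated study design is a
paediatric two-group comparison (16 cases with chronic mild traumatic
brain injury vs 20 typically developing controls), five minutes of
eyes-open rest on a 151-channel axial system at 600 Hz, with 90
atlas-centroid seeds.

# The synthetic cohort generator

No real recordings ship with the package; the generator is first-class,
tested code whose defaults encode the emulated study conditions.

**Signal model.** Each seed's continuous signal is a sum over the seven
canonical bands — delta (1–3 Hz), theta (4–7), alpha (8–14), beta
(15–30), low gamma1 (30–55), low gamma2 (65–80), high gamma (80–150) — of
a *carrier* (4th-order Butterworth band-passed Gaussian noise, unit RMS)
multiplied by a slow positive *envelope*. Envelopes are rectified
low-pass-filtered Gaussian noise plus a positive offset
(`|LP(0.25 Hz) noise| + 0.5`), generated on a 4 Hz grid and linearly
interpolated; this produces realistic slow amplitude dynamics whose mixing
maps smoothly onto measured AEC. Baseline band amplitudes fall with
frequency, with an alpha prominence (1.0, 0.9, 1.1, 0.7, 0.4, 0.3, 0.25);
they set relative band power only and are otherwise arbitrary.

**Covariates.** Age is truncated-normal within 6–18 years (means 12.46 vs
13.14, SDs 3.24 vs 2.69 per group); head motion is log-normal matched to
mean/SD 1.83/1.79 mm (cases) and 0.64/0.51 mm (controls). Motion is
deliberately group-dependent so that covariate adjustment in the
statistics is genuinely exercised, not decorative.

**Planted power effects** multiply a band's carrier amplitude for one
group on a seed set; measured band power then scales with the square of
the factor. The default plants delta × 1.5 in all occipital seeds of the
case group. Note that the analysis pipeline z-scores each seed's series
before spectral analysis, so the *measured* ratio on z-scored data is
smaller than the square law (the planted band inflates the total variance
that the z-score divides out); `measure_cohort(..., zscore = FALSE)`
exposes raw generator output where the square law holds exactly.

**Planted coupling effects** add a shared low-pass Gaussian component to
the envelope precursors of both endpoints of an edge, with Gaussian
correlation `rho` (the squared mixing weight). Because the measured AEC
depends non-analytically on the rectification, the band filter, the
10-sample-per-epoch envelope correlation and the epoch averaging, the
`rho -> measured AEC` map is built empirically once per band
(`build_aec_calibration()`, isotonic-smoothed, shipped as
`inst/extdata/aec_calibration.csv`) and inverted at generation time. A
negative target shift plants coupling in the control group, a positive one
in the case group, so the group difference equals the target. Planted
edges must be pairwise disjoint within a band — the calibration assumes
each endpoint participates in one shared component.

**Leakage-correction shrinkage.** Symmetric orthogonalization forces all
seed series to be exactly orthogonal within each epoch. For the delta band
a 10 s epoch holds only ~40 degrees of freedom against 90 seeds, so the
constraint binds hard and shrinks envelope correlations; we measured the
ratio of the leakage-corrected planted group difference to the requested
shift on full 90-seed calibration cohorts and ship the per-band factor
(`inst/extdata/aec_orth_attenuation.csv`; it also absorbs the residual
imperfection of the pairwise calibration in the multiband, 90-seed
setting). Planting divides its target by this factor, interpolated
between no attenuation at ≤ 20 seeds (where it is negligible) and the
90-seed reference value, so that the *measured, leakage-corrected* group
difference lands on the requested shift. This is
a property of the measurement, not a free dial: the factor was estimated
once from dedicated calibration cohorts and is not adjusted per run.

**Artifacts and sensors.** The forward model is a homogeneous conducting
sphere (Sarvas closed form; radius 9 cm, 151 radial sensors on a helmet
cap at 11 cm). Seed dipoles have fixed tangential orientations — radial
moments are magnetically silent in a sphere, so tangential orientations
avoid silent sources by construction. Artifacts comprise frontal blink
bumps (Poisson events), a ~1.2 Hz biphasic cardiac train with a fixed
random topography, smooth head-position excursions drawn from 6–15 mm (so
they straddle the 10 mm rejection threshold), and step jumps (default
2500 fT) in random channels. Head-position traces are slow (< 0.05 Hz)
three-axis wander, self-scaled so the mean per-epoch maximum displacement
matches the subject's drawn motion covariate.

**What the generator does not emulate:** anatomically realistic head
geometry and cortical meshes, 1/f aperiodic spectra beyond the band
mixture, non-stationary band power beyond the slow envelopes, and
physiological correlation structure between artifacts and brain signals.
Passing tests therefore demonstrate correctness of the algorithms under a
controlled model, not performance on real MEG.

# Preprocessing

The cleaning chain is: 4th-order Butterworth band-pass 1–150 Hz applied
forward–backward (zero phase; the magnitude response is squared, which we
accept in exchange for undistorted envelopes), an FFT notch that zeroes
bins within ±1 Hz of 60 and 120 Hz, ICA artifact attenuation, 10 s
epoching (floor rule, trailing remainder dropped) and epoch rejection.
An epoch is rejected when any within-epoch head displacement from the
whole-recording median position exceeds 10 mm — the recording-wide median
was chosen over per-epoch medians, which would hide slow drifts — or when
any channel's absolute first difference exceeds 2000 fT (one detector
covers both step-like sensor jumps and physiological jumps, since a single
numeric criterion defines both). The per-subject head-motion covariate is
the mean over retained epochs of the per-epoch maximum displacement.

ICA is a symmetric fixed-point FastICA (tanh contrast) on a 30-component
PCA subspace, written in-package. Component removal is automated: any
component whose time course correlates with a supplied artifact template
above |r| = 0.5 is zeroed before back-projection — a deterministic,
testable stand-in for manual component inspection. Directions without
independent non-Gaussian structure have no ICA contrast and can rotate
freely between iterations, so (as is standard for this algorithm) the
decomposition after the iteration cap is used even when the strict
tolerance was not met; pass-through with a warning is reserved for
numerical failure.

# Source reconstruction

Leadfields use the closed-form field of a current dipole in a homogeneous
conducting sphere, evaluated for two tangential unit moments per seed.
The spherical model replaces a template-based single-shell model: it is
closed-form and exactly testable (the radial field of the sphere equals
the radial free-space field of the primary dipole, which the tests
exploit), and template-based localization is itself an approximation.

The LCMV beamformer pools the sensor covariance over retained epochs,
loads it with `lambda = 0.05 * trace(C)/n_channels` (the "5%" is scaled to
the mean sensor variance; the scale base is a design choice, as is the
scalar rather than vector formulation), picks per seed the tangential
orientation maximizing output power, and applies unit-gain
minimum-variance weights. Virtual-sensor series are then z-scored over
concatenated retained epochs. Output variance is minimized at zero
loading by construction; regularization trades that optimality for
robustness.

# Spectral power

Welch's method with 2 s Hann windows and 50% overlap inside each 10 s
epoch (0.5 Hz resolution — fine enough for the 1–3 Hz delta band, nine
windows per epoch), averaged over epochs. Band summaries are the *mean*
density over in-band bins (not the integral), comparable across bands of
unequal width. Lobe spectra are unweighted means over member seeds per
lobe and hemisphere; peak alpha is the maximum density and its frequency
within 8–14 Hz of a lobe-averaged spectrum.

# Connectivity

The per-epoch order is fixed: band-pass FIR → symmetric orthogonalization
→ Hilbert envelope → block-mean downsampling to 1 Hz → Pearson
correlation; per-epoch matrices are averaged (raw mean, no Fisher z — the
averaging convention is "mean of per-epoch r") into the static connectome.
The FIR is a windowed-sinc design of order
`max(3 * rate/f_lo rounded even, 66)` (at least three cycles of the lowest
band frequency), applied as one symmetric two-pass kernel via
zero-padded FFT convolution — exactly zero phase.

Symmetric orthogonalization finds the closest set of mutually orthogonal
time series (Frobenius norm) by alternating a polar decomposition with
per-row scale fitting; the objective is non-increasing and iteration
stops at a relative change below 1e-8 (cap 200, flagged). All iterations
run in the k-dimensional row-space basis, so the per-iteration cost is
O(k^3) regardless of epoch length; rank-deficient inputs (e.g. duplicated
rows) are handled by SVD basis completion. Orthogonalization is applied
jointly over all seeds per epoch — the multivariate, symmetric variant —
not pairwise.

# Group statistics

Per unit (seed, or upper-triangle edge — 4005 edges for 90 seeds) we test
the group factor with a one-way ANCOVA adjusted for age and head motion:
`F = (RSS_reduced - RSS_full) / (RSS_full / (n - 4))`. Inference is by
Freedman–Lane permutation: residualize on the covariates, permute the
residuals (the same seeded permutation sequence for every unit within a
band, so the map is coherent), add back the covariate fit and recompute F;
`p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` with 10 000 permutations by
default. Raw label permutation would not be exchangeable under
group-correlated motion, which the cohort deliberately has.
Benjamini–Hochberg FDR is applied within band across the 90 seeds or 4005
edges (matching per-band reporting; pooling across bands is the stated
alternative), with significance at adjusted p < 0.05. The implementation
vectorizes all units and permutations into a handful of matrix products;
p-values are never zero and are reproducible bit-for-bit from the seed.

# Classification

Features are per-band seed powers (90) or vectorized upper-triangle edges
(4005, deterministic `i < j` ordering with a round-trippable edge↔index
map). The nested selection runs 10 stratified outer folds; inside each
fold only the 9 training folds are touched by (a) an optional univariate
rank-sum filter (p < 0.05 uncorrected) — gated globally by a PCA
separation check (silhouette of the group labels in the first two PCs
> 0.2, the quantitative stand-in for visual cluster judgement) and used
for connectivity features only — and (b) recursive random-forest feature
selection: 10 repetitions with fresh RF seeds of an elimination ladder
(500-tree forests, impurity importance, drop the bottom 20% per step down
to two features), each repetition keeping the smallest set whose
out-of-bag accuracy is within 2 points of the ladder's best (a parsimony
rule in the spirit of the 1-SE rule; OOB noise at n = 36 makes a strict
early-stopping rule degenerate), and a feature surviving in at least half
the repetitions being selected. Features selected in ≥ 4 of 10 folds
(connectivity) or ≥ 2 of 10 (power — no pre-filter there) form the
consensus list.

The final RBF SVM (C = 1, gamma at its scale default, features z-scored
with training-fold statistics only) is evaluated by stratified 10-fold CV
(mean ± SD, in percent). Significance uses the add-one label-permutation
test (default 1000 permutations; reduced counts are used in bounded
acceptance runs); generalizability is checked the same way with a
2-component PLS-DA (class = argmax of the one-hot prediction). The
training-set ROC-AUC is documented as an optimistic, comparative-only
metric. A leakage canary utility injects, per fold, a feature that is
label-revealing only on held-out rows; any CV-accuracy gain beyond one
subject's worth flags leakage.

# Numerical and design notes

- IIR filters run through a compiled direct-form-II-transposed kernel;
  narrow band-passes at 600 Hz are numerically delicate in any direct
  form, and implementations may differ at rounding-amplified level while
  sharing the spectral response (the tests assert responses, not bit
  patterns).
- Degenerate inputs: constant series fail z-scoring; constant envelopes
  produce missing AEC pairs with a warning; a constant feature is dropped
  by the univariate filter; all-equal classifier scores give AUC 0.5.
- Ties in the rank-sum test use the tie-corrected normal approximation
  without continuity correction.
- The pipeline orchestrator caches stages by a content hash of the stage
  config and its upstream hashes; a single master seed fans out to
  per-stage and per-subject substreams.

# Problem sizes used in bounded runs

The default generator emulates 300 s recordings. Bounded verification
runs (the acceptance script and the acceptance test file) use 200 s per
subject (20 epochs) at the full n = 16/20, 90-seed, 600 Hz design for the
effect-recovery and classification checks; null-calibration checks run
200 synthetic null cohorts at 20 units × 1000 permutations and one
500-unit cohort for p-value uniformity. These sizes were chosen once as
the smallest designs at which the planted effects are comfortably
identifiable; the planted effect sizes, thresholds and seeds themselves
are fixed by the emulated study conditions and are not tuned to test
outcomes.

# Known limitations

- The spherical forward model and quasi-uniform seed layout are
  geometric idealizations; no claim is made about anatomical accuracy.
- AEC planting is calibrated for the default envelope parameters, 10 s
  epochs and 1 Hz envelope sampling; changing those re-requires
  `build_aec_calibration()`.
- The orthogonalization-shrinkage compensation is measured at the
  90-seed reference and interpolated for intermediate seed counts;
  planted shifts at unusual seed counts land within, but not exactly on,
  the requested value.
- With 36 subjects, 10-fold CV folds hold 3–4 subjects; accuracy SDs are
  correspondingly coarse (one subject ≈ 2.8 points).
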