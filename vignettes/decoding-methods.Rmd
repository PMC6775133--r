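---
title: "Decoding articulator movements from high-density ECoG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding articulator movements from high-density ECoG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfbdecode)
```

## The problem

High-density electrocorticography (HD-ECoG) grids over sensorimotor cortex
record field potentials whose high-frequency-band power (HFB, 60–130 Hz)
tracks local population activity. During cued movements of the speech
articulators — lips, jaw, tongue, larynx — or of the tongue in different
directions, HFB power rises on spatially clustered subsets of electrodes,
and the spatial pattern of that rise differs between movements. `hfbdecode`
implements the full analysis chain that turns such a recording into:

* a per-electrode, per-movement responsiveness map (permutation-tested
  r²) with FDR control,
* a cross-validated template-matching classification accuracy (spatial and
  spatio-temporal variants),
* an electrode-importance map from a random-search procedure,
* a searchlight estimate of the smallest cortical patch that supports
  accurate classification, and
* winner-takes-all topographic maps of movement preference.

Because clinical ECoG is not freely shareable, the package ships a
synthetic generator that reproduces the statistical structure this chain
assumes, so every stage is testable end to end without any external data.

## The task design and generator

A run consists of `4 × 20` movement trials plus 20 rest trials in one
pseudorandom order. Each trial is a 1.5 s cue followed by a 1.5 s (or 2 s)
inter-trial interval; sampling is 512 Hz or 2000 Hz; electrodes sit on an
8 × 8 or 8 × 16 grid with 4 or 3 mm spacing. These defaults are fixed in
`sim_config()` and are the conditions under which all calibration claims
are made.

The generator (`generate_run()`) synthesizes, per channel,

1. **background**: Gaussian noise with a $1/f^{\alpha}$ power spectrum
   (`noise_exponent`, default $\alpha = 2$, a typical broadband ECoG
   slope). The spectrum is flattened below 1 Hz, as a recording chain's
   high-pass would do; the slope is therefore well-defined over the 5–200
   Hz range where it is asserted by test.
2. **line noise**: a 50 Hz sinusoid plus harmonics at half and quarter
   amplitude, with random phase, *shared across channels* (`line_amp`, in
   units of the background SD). 50 Hz is a configurable default; the
   protocol this package models never states the mains frequency.
3. **class effect**: during each active trial, additive band-limited
   (60–130 Hz) noise, independent across channels, whose spectral shape
   matches the background inside the band. Because the shapes match, the
   per-frequency power ratio during a trial is flat across the band, and
   the amplitude can be calibrated exactly so the center channel's HFB
   log-power rises by `effect_db` decibels in expectation. The amplitude
   falls off as a spatial Gaussian (`effect_sigma_mm`) around the class
   center. Movement onset jitters uniformly 0–200 ms after the cue
   (`onset_jitter_s`), which is what makes the spatio-temporal and spatial
   classifiers behave differently on synthetic data, mirroring onset
   variability in real recordings.

The effect size in dB is a free parameter of the generator: the protocol
the package models reports no effect sizes in physical units, so the
default (5 dB) was chosen once to land mid-range between chance and
ceiling for the default geometry, and the calibration tests sweep it
explicitly (0 dB for chance, 12 dB for ceiling). What the generator does
*not* model: cortical geometry and volume conduction, non-stationary
artifacts, electrode drift, or any forward model — passing tests on
synthetic runs validates the analysis machinery, not the neurophysiology.

## Preprocessing

`detect_bad_channels()` flags *flat* channels (variance below an absolute
tolerance) and *noisy* channels (variance above 10× the median, or
line-band power ratio above 10× the median ratio). The exclusion criteria
for clinical recordings are lab lore rather than published constants, so
these rules are this package's own reproducible definition, with all
thresholds exposed. `common_average_rereference()` subtracts the mean of
the *included* channels at every sample — whether excluded channels should
contribute to the average is ambiguous in the protocol; here they do not.

`notch_filter()` removes 50 Hz and harmonics with a second-order
Butterworth band-stop (1 Hz wide) designed by `signal::butter()` and
applied as its forward-backward squared-magnitude response via FFT on the
zero-padded recording. This is the textbook zero-phase realization; the
test suite verifies it against `signal::filtfilt()` to ~1e-3 in the
interior, ≥ 40 dB attenuation at the notch centers, and a flat (±1 dB)
passband.

## HFB envelope

`gabor_power()` convolves each channel with complex Gabor atoms at 1 Hz
spacing over 60–130 Hz. "FWHM of 4 cycles" is read as: the Gaussian
envelope's full width at half maximum equals 4 periods of the atom's
center frequency — the standard Morlet-family parameterization (a 4-second
FWHM at 60–130 Hz would smear entire trials and is physically
implausible). Per-bin power is converted to dB (`10*log10`) *first* and
then averaged over bins; a test asserts this order against the
dB-of-mean alternative, which is not the same function. Atoms are
L2-normalized; since every downstream statistic is a correlation, a
z-score or an r², the absolute dB offset this choice fixes is
inconsequential, and a test asserts that affine per-electrode transforms
do not move any downstream result.

Numerics: the convolution runs in the frequency domain on a 5-smooth
padded length; each atom's Gaussian frequency response is truncated at
±4σ. The `hop` argument returns the envelope at every `hop`-th sample by
alias-free spectral folding — an exact subsample of the `hop = 1` series
(asserted to 1e-10), not an approximation. The HFB power envelope carries
only a few tens of Hz of bandwidth, so a 128 Hz envelope rate preserves
it; decimation only trades resolution of the later 0.5 s smoothing, which
is insensitive at these rates. ε-floors inside the logarithm (relative,
1e-12) keep silent channels finite.

## Responsiveness and electrode selection

For each movement, the per-trial mean envelope (cue onset to cue offset;
"end of a trial" is read as cue offset, since the inter-trial interval is
task-free) is correlated with a binary movement-vs-rest design; r² is the
squared Pearson correlation, with r² ≡ 0 for degenerate zero-variance
electrodes. Significance uses label permutations (default 10000) with the
add-one convention p = (1 + #{r²_perm ≥ r²_obs}) / (n_perm + 1), so p can
never be zero, followed by Benjamini–Hochberg FDR at α = 0.05.

Two open choices are fixed as follows:

* **Shuffling** is per movement contrast (active-vs-rest labels within
  that contrast), not joint across movements.
* **FDR family** defaults to electrodes *within one movement*
  (`fdr_family = "within_movement"`), which matches treating each
  movement's map as its own analysis. The joint family
  (`"global"`) is available, and it is the variant whose whole-map
  selection rate under a global null is bounded by α — the calibration
  test uses it for exactly that reason. With four within-movement
  families the whole-map rate under a global null is ≈ 1 − 0.95⁴ ≈ 0.19
  by construction, which is a property of the family choice, not an
  error.

During cross-validation, selection runs on training trials (plus all rest
trials, which are never classified) only — a leakage-guard test corrupts
held-out trials and asserts bitwise-identical masks and templates. If no
electrode is significant in a fold (routine on null data), the fold falls
back to all candidate electrodes, which keeps the classifier defined and
at chance under the null.

## Template-matching classification

The envelope is smoothed with a centered 0.5 s moving average (truncated
at the run edges), z-scored per electrode *over the full run* (the
protocol z-scores before epoching; an all-constant electrode becomes all
zeros rather than NaN), and epoched into 2 s windows from cue onset —
deliberately 0.5 s past the cue, as specified. Spatial templates average
each electrode over the trial period; spatio-temporal templates keep the
electrode × time matrix. A held-out trial is assigned to the class with
the highest Pearson correlation (winner-takes-all); exact ties, including
the all-zero degenerate case, go to the lowest class index. 10-fold
cross-validation uses stratified folds — 8 trials, 2 per class — assigned
by a seeded permutation within class; the reported accuracy is the mean
over folds and the SD is taken over folds. Leave-one-trial-out variants
(`loocv()`) serve the localization procedures, which were designed for
small windows of data and take their electrode set as given.

The significance of an observed accuracy is assessed by permuting class
labels among movement trials and re-running the *entire*
cross-validation, selection included (`accuracy_significance()`); a
binomial test against chance is provided for reference only, since
cross-validated trials are not independent.

## Localization

`random_search_importance()` draws random electrode subsets (size uniform
on 1..N, then a uniform subset — the subset-size law is this package's
choice and is configurable), scores each with spatial-mode
leave-one-trial-out decoding, credits every member with the subset's
accuracy, and z-scores the per-electrode means. The convergence
diagnostic correlates the running importance pattern at iteration i with
all later patterns; before an electrode's first inclusion its running
mean is taken as 0, and undefined (zero-variance) correlations are
skipped and counted. The curve is computed on the raw mean-accuracy
patterns; correlation is invariant to the z-scoring, so the choice is
cosmetic.

`searchlight()` slides k × k windows (k = 1, 2, …) one electrode at a
time and records the spatial-mode leave-one-out accuracy per position;
excluded electrodes inside a window are omitted, and an empty window is
`NA`. A 1 × 1 window yields a scalar feature, for which a correlation
across electrodes is undefined; such windows are classified by nearest
template (smallest absolute distance), so the smallest grid size remains
informative rather than pinned at chance. A window of size k covers `(k × spacing / 10)²` cm² — the convention
under which a 3 × 3 window at 4 mm spacing is 12 × 12 mm —
and `min_area_for_accuracy()` reports the smallest area whose best
position exceeds a threshold, strictly.

`winner_takes_all()` labels each electrode with its highest-r² movement,
but only when that maximum exceeds 0.2 *strictly*; ties go to the lowest
class index. Maps live on the electrode grid of the run: normalizing to a
common cortical coordinate system requires subject anatomy, which is out
of scope here, so the grid map is the exported product.

## Problem sizes used by the shipped checks

The calibration studies that the test suite and `scripts/acceptance.R`
run use a reduced geometry chosen to keep a full 100-seed study of the
entire chain (synthesis → preprocessing → wavelets → selection →
classification) comfortably on one CPU: a 4 × 4 grid at 512 Hz, 2 Hz
wavelet bins, envelope decimated to 128 Hz, and 1000 selection
permutations per fold (the `"test"` profile of `pipeline_config()`).
Chance level, ceiling behaviour, fold structure, null calibration and the
oracle equivalences are all invariant to these sizes; analyses of real
recordings should use the full defaults (1 Hz bins, per-sample envelope,
10000 permutations, 5000 random-search iterations).

The null-calibration and localization-recovery studies simulate at the
trial-feature level (Gaussian per-trial means and tensors) rather than
re-synthesizing hundreds of full recordings; those checks target the
selection and importance machinery, whose inputs are exactly such
matrices.

## Known limitations

* The generator's class effect is stationary within a trial (up to onset
  jitter and 20 ms ramps); it cannot expose failure modes tied to
  within-trial dynamics, e.g. movement-offset rebounds.
* Electrode "area" conventions treat a k × k window as `(k·spacing)²`;
  physical electrode diameter is ignored.
* The permutation test of accuracy re-permutes labels but keeps the fold
  geometry; with very few trials its p-values are coarse
  (minimum 1/(n_perm+1)).
* Bad-channel detection assumes corruption is rare (medians are robust up
  to ~50% contamination) and that line noise is common-mode across the
  grid.
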