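---
title: "Analysing auditory mismatch fields with mmfpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing auditory mismatch fields with mmfpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In an auditory oddball experiment a frequent *standard* tone is
interleaved with rarer *deviant* tones. Averaging the magnetoencephalographic
(MEG) response per condition and subtracting standard from deviant yields
the **mismatch field (MMF)** — the magnetic counterpart of the mismatch
negativity, widely read as a cortical prediction-error signal. `mmfpipe`
implements a complete, reproducible analysis chain for a *multi-feature*
(Optimum-1 style) oddball design in which standards and deviants strictly
alternate and deviants differ from the standard in one of four acoustic
features (frequency, intensity, duration, or a silent gap):

1. **Paradigm generation** — seeded stimulus sequences and tone synthesis.
2. **Synthetic cohorts** — continuous multichannel recordings for two age
   groups with a known, injected mismatch effect.
3. **Preprocessing** — zero-phase FIR filtering, epoching, artifact
   rejection, channel interpolation, ERF averaging.
4. **Sensor-level statistics** — cross-validated effect-matched spatial
   (EMS) filtering, one-sample cluster-based permutation tests, and group
   estimation statistics (permutation test, Cohen's *d* with a bootstrap
   interval, Pearson correlation with age).
5. **Source-level statistics** — LCMV beamformer reconstruction at six
   regions of interest (bilateral A1, STG, IFG) with paired and
   independent-samples cluster tests.

Because no public raw data accompany the study design the pipeline targets,
the package ships a first-class synthetic-data generator with known ground
truth; every inferential component is validated against that truth, against
closed-form oracles, or against simulation-based calibration.

## The paradigm module

A block opens with 15 standards and then alternates standard and deviant
tones at a 0.5 s stimulus-onset asynchrony; a default block holds 495
stimuli, so a session of three blocks presents 1,485. Deviant slots are
filled by a seeded pseudorandom draw over the four feature dimensions under
three hard constraints: each dimension fills exactly a quarter of the
deviant slots, frequency and intensity deviants split exactly half up /
half down, and the same dimension never occupies two successive deviant
slots. The generator draws dimensions sequentially with probability
proportional to their remaining counts and restarts on the (rare) dead
ends; feasibility is checked up front.

The standard tone is one harmonic complex with partials at 550, 1,000 and
1,500 Hz, 75 ms long with 5 ms linear ramps. The frequency deviants scale
every partial by 1.1 or 0.9 (yielding the 605/1,100/1,650 Hz and
495/900/1,350 Hz complexes), the intensity deviants scale the amplitude by
1.1 or 0.9 (implemented as linear amplitude, the most direct reading of
"10% louder/softer"), the duration deviant truncates tone-on time to 25 ms
(ramps preserved, zero-padded to the standard length) and the gap deviant
silences 7 ms at the waveform midpoint. We place the 1 ms fall/rise ramps
*outside* the silent span, so the fully silent portion is exactly 7 ms; the
source description is ambiguous on this point and the alternative (ramps
inside, 5 ms of true silence) is a one-line change.

## Geometry and forward model

The conductor is a homogeneous sphere (radius 0.09 m). Sensors are 125
first-order axial gradiometers (50 mm baseline) on a Fibonacci lattice
covering a 75° polar cap at 0.11 m radius, with radial orientations —
a deliberate idealization of a pediatric whole-head system. Fields are
computed with the closed-form Sarvas solution; an axial gradiometer reads
the difference of the radial field at its two coils. Because radial
current dipoles are silent in a spherically symmetric conductor, each
source vertex carries a 2-column tangential leadfield; the beamformer's
"free orientation" is free within that tangential plane. The radial
component of the external field is independent of volume currents, which
gives an exact independent oracle for the forward model: the test suite
checks the Sarvas radial component against the infinite-medium dipole
formula.

The source grid is cubic (10 mm spacing) clipped to the sphere interior.
Six ROIs (left/right A1, STG, IFG) are spheres of 13 mm radius around
mirror-symmetric template coordinates. The ROI centers are a configuration
choice for the synthetic geometry, not a co-registered atlas; all
source-level conclusions in the tests are about recovery of *injected*
effects under the same forward model.

## The synthetic cohort

`sim_config()` defines the study conditions: 18 younger (age 4.1 ± 0.9 y)
and 19 older (6.2 ± 0.4 y) simulated children, three blocks of 495 stimuli
at 1,000 Hz, 125 channels. Every stimulus evokes a Gaussian-windowed
8 Hz transient (peak 0.1 s, SD 30 ms, 40 nAm) in bilateral A1. Deviants
additionally receive a Gaussian mismatch component (SD 30 ms, 25 nAm) in
right A1, STG and IFG whose peak latency progresses 0.25 → 0.29 → 0.33 s
across the hierarchy, mimicking feed-forward propagation of prediction
errors; the right-IFG amplitude is doubled in the older group
(`group_gain_ifg = 2`). All kernels are truncated at 0.4 s post-onset so
no component bleeds into the next epoch's baseline.

The noise model has four components, each of which matters for honest
source-level behaviour:

- white sensor noise (300 fT per sample);
- optional AR(1) sensor noise;
- **ongoing background brain activity**: 30 dipoles at random grid
  locations per participant with AR(1) dynamics (50 ms time constant,
  15 nAm rms). Without spatially correlated background, an adaptive
  beamformer behaves unrealistically well, and tiny cross-ROI leakage
  terms become statistically visible;
- **trial-to-trial variability**: every stimulus × source draws an
  independent mean-one lognormal amplitude gain (σ = 1.0). Real evoked
  generators are far from deterministic, and this variability is what
  decorrelates the mismatch sources; perfectly coherent sources would
  put the simulation in the one regime where LCMV beamformers are known
  to fail (correlated-source cancellation).

A per-participant lognormal scale (σ = 0.2) creates realistic
between-subject amplitude spread. Setting `noise_sd`, `trial_jitter_sd`
and `background_dipoles` to zero gives the noiseless limit used by the
support and recovery tests. The amplitudes (tens of nAm, hundreds of fT)
sit in the range reported for auditory evoked fields and produce
single-trial SNR well below 1, as in real recordings.

What the generator deliberately does **not** emulate: eyeblinks, SQUID
jumps, head motion, environmental interference, realistic cortical
geometry, or per-subtype mismatch differences (the analysis pools the four
deviant subtypes, so the generator injects a common mismatch). Passing
end-to-end tests therefore show that the *statistical pipeline* recovers
known effects through a realistic forward model and noise structure — not
that it would survive every artifact class of a real pediatric session.

## Preprocessing

Filtering uses a windowed-sinc FIR (Blackman window): a 0.1–40 Hz
band-pass convolved with a 50 Hz band-stop (harmonics are already inside
the stop-band of the 40 Hz low-pass). The filter is applied in a single
pass with group-delay compensation — linear phase, zero net delay — via
FFT convolution. The order is transition-limited (≈ 5.5·fs / transition
width) and capped at 10% of the recording length. The high-pass is built by
spectral inversion of a unit-DC-gain low-pass, so the DC response of the
composite is identically zero at any order.

Epochs are half-open windows [onset − 0.1 s, onset + 0.4 s) and the first
15 epochs of each block are excluded. Artifact screening is a peak-to-peak
threshold (default 5 pT) — an automated, reproducible stand-in for visual
inspection. Bad channels (listed or auto-detected by a robust z-score on
median log peak-to-peak amplitude) are replaced by inverse-distance
weighted averages of their four nearest good neighbours. No baseline
correction is applied by default. Epoch bookkeeping
(`n_input = n_kept + n_dropped`) is asserted per run.

## EMS filtering and the sensor-level test

The EMS spatial filter at each (channel, time) is the deviant-minus-
standard difference of z-scored training means, unit-normalized per time
slice. Z-scoring statistics (per channel, pooled over training epochs ×
samples) are estimated on the training folds only and applied to the held-
out fold — the cross-validation is what protects the later tests from
selection circularity, and a dedicated property test verifies that
held-out null data produce unbiased traces while the same-data variant is
strongly positively biased.

The whole-cohort test feeds each participant's deviant-minus-standard EMS
trace to a one-sample cluster-based permutation test: pointwise t tests,
clusters of temporally contiguous same-sign samples with |t| above the
two-tailed critical value at α = 0.05, **mean** of t values as the cluster
statistic (as specified by the method this package follows — unusual, since
it does not reward long clusters; the sum is available via
`cluster_stat = "sum"`), and a max-statistic permutation null from
per-participant sign flips with the +1 Monte-Carlo correction. The time
window of the winning cluster (lowest p, then largest |statistic|) becomes
the TOI; per-participant TOI mean amplitudes go into the estimation step
(5,000 label reshuffles, 5,000 BCa bootstraps, Pearson correlation with
age). The TOI is *derived* from the data, never hard-coded.

## Beamforming and the source-level tests

The spatial filter per vertex is the unit-gain LCMV solution built from
the conditions-combined covariance (diagonal regularization
λ = 0.05 of the mean diagonal). The free orientation is the pseudo-Z
optimal direction — the generalized eigenvector of t(L)C⁻¹L against
t(L)C⁻²L with the largest eigenvalue. The simpler minimum-eigenvalue rule
maximizes raw output power and is biased toward the tangential direction
with the weaker leadfield norm; in simulation it mis-orients a noticeable
fraction of participants and destroys group comparability, which is why
the noise-normalized orientation is the default here. Each ROI filter is
the proximity-weighted sum of its vertex filters (Gaussian kernel around
the ROI centroid, σ defaulting to the median centroid distance), with two
polarity conventions enforced: vertex filters are sign-aligned to the
centroid orientation before summation, and the centroid orientation itself
is aligned to a geometry-fixed reference so that trace polarity is
comparable *across participants*.

Paired (deviant vs standard) cluster tests run per ROI with 2,000
permutations. The union of significant right-hemisphere paired clusters
defines the source window, and the age-group contrasts (MMF, standard and
deviant amplitudes) are restricted to the right-hemisphere ROIs and that
window, mirroring the study logic the pipeline reproduces. The MMF group
contrast is one-sided by default (`group_tail = "pos"`): the developmental
hypothesis is directional (larger mismatch amplitudes in the older group),
and the per-participant adaptive filters carry a small negative-going
artifact — participants with a stronger right-IFG source have their
neighbouring-ROI filters suppress that source more deeply, which depresses
the older group's rSTG traces and can produce an anti-hypothesis rSTG
cluster under a two-sided test. The standard- and deviant-amplitude group
contrasts, for which no direction is hypothesized, stay two-sided, as does
the sensor-level estimation test. For the group
contrasts the permutation null pools the maximum cluster statistic across
the tested ROIs, controlling the family-wise error over ROIs × time; with
per-ROI α = 0.05 the chance of *some* false ROI would approach 15% per
run and a specificity requirement of "no spurious ROI in ≥ 90% of runs"
would be unattainable by construction. Per-ROI nulls remain available
(`fwer_across_rois = FALSE`).

## Numerical choices and degenerate inputs

- Monte-Carlo p values always use (1 + #{null ≥ observed}) / (1 + n_perm).
- Zero-variance timepoints give t = 0 with a warning (conservative).
- Zero-variance channels floor the z-score SD at machine epsilon.
- The BCa bootstrap falls back to percentile endpoints when the bias
  correction or acceleration is degenerate, and records which method was
  used.
- Cluster-forming thresholds come from the t distribution at the
  appropriate degrees of freedom; "free" orientation sign ambiguities are
  resolved as described above; ties in the centroid definition go to the
  lowest voxel index.
- Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; cohort members, analysis stages and bootstrap /
  permutation draws use sub-seeds derived deterministically from one
  master seed.

## Problem sizes used by the test suite

The package defaults describe the full study (three 495-stimulus blocks at
1,000 Hz, 125 channels, 18 + 19 participants). The property tests and the
acceptance checks exercise the identical code paths at reduced problem
sizes chosen to keep a complete run on a single CPU comfortable: one
191-stimulus block at 250 Hz for the ten end-to-end cohort runs (88
deviants per participant instead of 720), 500–2,000 resamples instead of
1,000–5,000, and 200–500 replicates for the calibration and coverage
properties. These sizes are a package choice: they keep every inferential
property measurable (type-I calibration within binomial error, ≥ 90%
end-to-end detection) while making the whole suite cheap to re-run.
At the reduced trial counts the per-participant source estimates are
noisier than at full scale, so the end-to-end detection margins reported
by the tests are conservative relative to the full-size conditions.

## Known limitations

- The single-sphere conductor and point-magnetometer coils idealize the
  real sensor array; absolute source amplitudes are nominal (A·m up to
  leadfield scaling) and are not treated as a scientific surface.
- ROI geometry is synthetic; cross-ROI beamformer leakage in the
  simulation (adjacent A1/STG spheres, partially correlated sources) is
  physically genuine and visible in the recovery tables — the specificity
  statements the tests make are about *statistical* detections under
  family-wise control, not about zero leakage.
- The manual artifact screening of a real analyst cannot be codified; the
  peak-to-peak criterion is a reproducible substitute with a free
  threshold.
- EMS reduces space to one dimension before inference, so no
  channel-space cluster topography is produced (by design, matching the
  method implemented).
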