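---
title: "Gait-related brain-body connectivity: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-related brain-body connectivity: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During walking, oscillatory activity in sensorimotor cortex is modulated
within each gait cycle: alpha (8-13 Hz) and beta (13-30 Hz) power typically
decreases around the swing phase of the contralateral leg and rebounds
afterwards, while gamma (30-50 Hz) shows weaker modulations of opposite
sign. *Neurokinematic connectivity* (NKC) and *neuromuscular connectivity*
(NMC) quantify how strongly these gait-locked neural power modulations
co-vary with limb-velocity envelopes and EMG envelopes, respectively, as
correlations computed over the gait-percentage axis. `mobigait` implements
the full analysis chain for mobile brain/body imaging (MoBI) recordings --
high-density EEG walking data plus wireless body sensors (3-axis
acceleration and EMG per site) -- together with a synthetic MoBI generator
whose ground truth makes every stage testable without human recordings.

## Pipeline stages and their models

### Synchronization (`align_streams`)

The EEG amplifier and the body-sensor base run on different clocks; both
record a shared square synchronization pulse. Both pulse channels are
resampled to a common 1 kHz grid and the lag maximizing their normalized
cross-correlation is searched within a +/-30 s window (the window is a
package choice; it comfortably covers manual start offsets). The lag is then
refined on matched rising edges, and the residual standard deviation across
edges is reported as jitter. On clean square pulses the recovered lag is
exact to one common-rate sample and jitter tracks planted edge noise;
hardware-grade recordings synchronize to a few milliseconds.

### Gait events (`detect_events`)

Velocity is estimated as the cumulative trapezoidal integral of the
mean-removed total-acceleration norm, high-pass filtered at 0.3 Hz
(zero-phase) both before and after integration to suppress drift; the
0.3 Hz edge is a documented package decision, as is taking the norm before
removing the mean. Heel strikes are the dominant impact peaks of each ankle's total
acceleration (prominence-based, refractory period 0.4 cycles, cycle period
estimated from the envelope autocorrelation); toe offs are the onset of the
push-off/swing burst, detected as the first sustained crossing of the
smoothed (50 ms RMS) envelope at 30% of the burst peak measured above the
quiet-stance baseline. The baseline correction matters in practice: without
it, sensor noise during stance sits above a fixed 30%-of-peak threshold and
onsets fire spuriously. Detection is restricted to stable-velocity segments
(envelope RMS within +/-20% of its running median, segments >= 5 s). Cycles
are left-heel-strike referenced (LHS 0%, next LHS 100%) and cycles violating
the event ordering LHS < RTO < RHS < LTO < next LHS or the 0.5-2.5 s
duration bounds are discarded and counted.

### Body envelopes (`preprocess_emg`, `envelope`, `standardize_to_cycle`)

EMG is zero-phase band-passed to 1-500 Hz and rectified; envelopes are the
magnitude of the analytic (Hilbert) signal, anti-alias resampled to 200 Hz.
"Velocity envelope" is likewise the Hilbert magnitude of the velocity
signal; velocity is already slow, so this is close to a rectification, but
the definition is kept uniform across signal types. Each cycle is warped to
the 0-100% grid by a piecewise-linear map anchored at LHS = 0%, next
LHS = 100% and the participant-median percentages of RTO, RHS and LTO. The
anchor warping is the simplest event-respecting normalization; with
identical cycles it reduces to the identity, and a template replayed with
+/-10% duration jitter is recovered with RMSE below 1% of its range.
Trial-averaged curves (not per-cycle curves) enter the correlation
analyses; per-cycle curves remain available in the `CycleEnvelope`
container.

Cross-sensor inter-dependence uses Pearson correlations between
trial-averaged curves (Spearman available), Fisher z transformed, with
|r| capped at 1 - 1e-7 so degenerate perfect correlations stay finite.
Group inference is a one-sample t-test on z per pair with
Benjamini-Hochberg FDR over the off-diagonal family; group correlation
displays are the back-transformed mean z.

### EEG cleaning (`repair_bad_channels`, `filter_resample`, `attenuate_artifacts`)

Channels whose robust neighbour correlation falls below 0.4 or whose
variance deviates more than 5 MADs from the montage median are replaced by
the mean of their 4 nearest neighbours (spatial neighbours when electrode
positions are available, otherwise the most-correlated channels); more than
25% bad channels aborts with a quality error. Data are band-passed 1-80 Hz
(zero-phase FIR, Hamming windowed-sinc; ~1 Hz lower and ~10 Hz upper
transition bands) and resampled to 200 Hz.

Artifact attenuation runs three blind-source-separation stages strictly in
order, each decomposing the current data, zeroing components that fail the
stage criterion, and reconstructing:

* **ocular** -- maximum excess kurtosis over non-overlapping 5-s windows
  above 12 (blink trains are sparse and heavy-tailed);
* **movement** -- mean sample entropy (m = 2, r = 0.2 x window SD) over
  non-overlapping 20-s windows below 0.8 (step-locked components are
  near-periodic, hence highly regular);
* **myogenic** -- Welch band power in 30-80 Hz exceeding that in 1-30 Hz.

Kurtosis is excess (Fisher) kurtosis; blink components exceed the threshold
under either convention. Windows are non-overlapping, the simplest choice.
Decomposition backends are pluggable:
`backend_fastica()` (deflation or symmetric, tanh contrast) for production
data, and `backend_oracle()` -- regression on the known artifact
topographies plus residual PCA -- in validation, so that the tests verify
the screening rules themselves rather than ICA convergence.

### Source reconstruction (`eloreta_fit`, `apply_inverse`, `collapse_dipole`, `extract_roi`)

The inverse operator is eLORETA: source-wise 3x3 weight blocks iterated on
the regularized resolution kernel (tolerance 1e-6, at most 100 iterations),
with the gain average-referenced to match average-referenced data. Its
defining property -- exact localization of noiseless point sources -- holds
on the synthetic grids for every source and is the module's primary
acceptance surface. The default regularization, 1e-3 times the mean
eigenvalue of the gain Gram matrix, is appropriate for that noiseless
setting; for data with realistic sensor and background noise the pipeline
uses `pipeline_inverse()` with 0.1 times the mean Gram eigenvalue.
The stronger value leaves point-source localization untouched but limits
the noise amplification that otherwise dominates voxel time courses (with
the noiseless default, the weight rows amplify channel noise by three
orders of magnitude, and the first principal component of the three
orientation signals can lock onto a noise orientation rather than the
source). The 3-D dipole signal at each voxel is collapsed to its first
principal component; ROI signals are the first principal component across
the voxels of a 6-mm sphere. PCA signs are fixed by requiring a positive
loading sum (positive first nonzero element on ties) for reproducibility;
note that all downstream connectivity uses spectral *power*, which is
invariant to this sign.

### Connectivity (`gait_spectrogram`, `connectivity_profile`, `band_aggregate`, statistics)

Spectrograms use an analytic Morlet continuous wavelet transform with the
6-octave, 8-voices-per-octave geometric frequency grid, masked to 1-50 Hz
(the wavelet family beyond the octave/voice discretization is a package
choice; the Morlet centre parameter is 6). Magnitude-squared power at each
frequency is warped and trial-averaged exactly like the body envelopes and
then z-scored across the percentage grid per frequency; correlation is
invariant to this affine standardization, which is why the precise
standardization formula is safe to choose. NKC/NMC profiles are Pearson
correlations between the standardized power curve and a body envelope, one
value per frequency; band values are means over in-band frequencies with
half-open edges alpha [8,13), beta [13,30), gamma [30,50).

Group statistics: Fisher z per cell, one-sample t-tests across
participants, Benjamini-Hochberg FDR within one declared family per
results table (and per effect across voxels for images). ANOVAs are
balanced fixed-effects linear models with sum-to-zero coding; the four-way
analysis (sensor x ROI x band x signal type) fits main effects only,
matching factor-wise reporting, while two-way analyses include the
interaction. Voxel-wise two-way ANOVA maps are FDR-thresholded at
q < 0.001; group-average connectivity images apply the display threshold
r > 0.2 only when rendering.

## The synthetic MoBI generator

The generator emulates the study conditions: walking blocks at cadence
around 1 cycle/s (durations gamma-distributed with CV 0.03 by default,
within-cycle event fractions RTO 12%, RHS 50%, LTO 62%), eight EMG sensors
(bilateral vastus medialis, biceps femoris, tibialis anterior,
gastrocnemius) at 2 kHz, 3-axis acceleration at 148 Hz at every sensor site
plus both ankles, EEG (32 channels by default for desk-scale validation,
128 available) and a shared square synchronization pulse. Muscle activation
windows follow the classical phasing of level walking -- vastus around the
ipsilateral heel strike, biceps femoris in terminal swing through double
support, tibialis across swing and the following double support,
gastrocnemius in stance, right-side templates shifted by half a cycle --
and EMG is amplitude-modulated broadband (20-450 Hz) noise. Ankle
acceleration is the analytic derivative of a smooth swing-velocity bump
plus a sharp Gaussian heel-strike impact (sigma 15 ms) and a sharp-onset
biexponential push-off burst at toe off; the sharp onset is what a 30%
envelope-crossing detector can time accurately, mirroring the fast
transients of real push-off.

EEG sources are band-limited Gaussian noise carriers (not sinusoids, so
wavelet band power behaves like real rhythms) with instantaneous amplitude
following gait-phase modulation curves. The default bilateral "M1" sources
couple alpha/beta amplitude negatively to the contralateral leg's flexor
composite (modulation depth 0.4) and gamma weakly with opposite sign
(depth 0.15), which yields contralateral-negative / ipsilateral-positive
alpha-beta NMC with the gastrocnemius reversed -- the planted analogue of
the connectivity sign structure the pipeline is meant to recover. Source
amplitudes are set so alpha/beta form a clear spectral bump above the
background, as real sensorimotor rhythms do. Background activity is 64
broadband 1/f dipoles across the grid; sensor noise is per-channel 1/f
electrode noise (2 uV) plus small white amplifier noise (0.5 uV). The noise
colour matters: purely white sensor noise would make the low-variance
decomposition components flat-spectrum and trip the myogenic band-ratio
rule wholesale, which contradicts how that rule behaves on real recordings.
Artifacts are topography x waveform: sparse biexponential blinks (0.25 Hz,
frontal topography), a step-frequency-locked sinusoid with slow amplitude
drift (broad gradient topography), and 30-80 Hz broadband myogenic noise
(rim topography). Their default amplitudes are deliberately chosen to
exceed the screening thresholds by a safe margin -- the generator documents
detectability, it does not calibrate detector sensitivity.

The head model is a homogeneous conducting sphere (radius 90 mm,
conductivity 0.33 S/m) with electrodes on a Fibonacci lattice over the
upper surface and sources on a regular grid at cortical depth (grid centre
45 mm above the sphere centre). Dipole gains are the analytic gradient of
the closed-form monopole surface kernel; the closed form agrees with an
independent Legendre-series evaluation and with two-monopole finite
differences. What the generator does *not* emulate: realistic
volume-conductor geometry (skull/CSF layers), biomechanically exact limb
dynamics, electrode motion artifacts coupled to the gait kinematics, or
inter-participant anatomical variability. Passing tests therefore
demonstrate the correctness of the analysis chain and its statistical
calibration under known ground truth -- not field performance on human
recordings.

## Numerical choices

* FIR filters are Hamming windowed-sinc designs with -6 dB cutoffs at the
  band edges, applied by FFT convolution with reflected edges and exact
  delay compensation; Butterworth `filtfilt` (order 2) is used only for the
  0.3 Hz integration high-pass where a short IIR is preferable.
* Resampling low-passes at 0.45 of the target rate before linear
  interpolation onto the new grid.
* Analytic signals and noise synthesis pad to 2-3-5-smooth FFT lengths and
  truncate, keeping mixed-radix FFTs fast without changing results beyond
  edge effects.
* Sample entropy uses Chebyshev distance with matches at distance <= r,
  self-matches excluded, in a compiled O(N^2) kernel verified to 1e-10
  against a brute-force R implementation.
* Gamma-distributed cycle durations degenerate exactly to constants at
  CV = 0; all generators draw from a locally seeded RNG and restore the
  global seed state.
* Degenerate statistics are defined explicitly: an exactly-null group cell
  reports t = 0, p = 1; a flat ANOVA response reports F = 0, p = 1;
  constant envelopes are excluded from correlation summaries.

## Validation problem sizes

The test-suite and the acceptance script run at desk scale: 32-channel
montages, 100-140-voxel grids (6-7 mm spacing), 40-120 gait cycles per
simulated participant, 24 simulated participants for group-level checks,
20-50 seeds for detection and screening properties. These sizes give stable
statistics for every property tested while keeping a full run in minutes;
the same code paths run unchanged at 128 channels and denser grids.

## Known limitations

* The spherical homogeneous head model understates the spatial blurring a
  real skull causes; absolute localization accuracy on human data will be
  lower than on the synthetic fixtures.
* The FastICA backend is a compact reference implementation; for large
  production montages a mature ICA/IVA library may converge faster and
  should be wrapped behind the same backend contract.
* NKC from muscle-site velocity and ankle velocity are both supported;
  lag-resolved (trial-level) brain-body modelling is out of scope.
* The EDF writer quantizes to 16 bits and pads the final record with zeros;
  files store whole records by design.
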