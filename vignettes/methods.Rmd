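---
title: "Beta bursts and spiral kinematics: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta bursts and spiral kinematics: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the scientific model behind `spiralburst`, the
parameters that matter, what the synthetic cohort does and does not
emulate, and the numerical decisions taken where the underlying method
left the design open.

## 1. The measurement model

### LFP conditioning

Subthalamic LFP enters at its native rate (2048 Hz in the synthetic
world) and passes a fixed chain: 4th-order Butterworth high-pass at 4 Hz,
anti-aliased resampling to 200 Hz, demeaning, linear detrending, and
per-epoch DFT notches at 50 and 100 Hz. All IIR filtering is zero-phase
(forward–backward with steady-state initial conditions and odd-reflection
padding sized to the slowest pole), because burst *onset timing* feeds
the peri-burst analysis and must not be delayed by filter group delay.

Numerical choices:

* **Resampling** is a Butterworth low-pass at the target Nyquist followed
  by Fourier-domain resampling (spectrum truncation). A rational
  polyphase FIR cascade would be the other standard route; the Fourier
  route is exact for band-limited signals, shorter to state, and meets
  the same contracts (in-band correlation > 0.999, out-of-band
  attenuation > 20×), which is why it was chosen.
* **DFT notch** = least-squares fit-and-subtract of the sine/cosine pair
  at the target frequency (exact for a stationary tone regardless of
  epoch length, and immune to spectral leakage) followed by zeroing the
  Fourier coefficients in a 1 Hz bin around the target (catches slow
  drift of the line frequency). Centred regressors keep the epoch mean
  untouched.
* **Stimulation artifacts.** At the 200 Hz analysis rate the 130 Hz
  stimulation frequency is above Nyquist; its narrowband residue aliases
  to |round(130/200)·200 − 130| = 70 Hz, so the extra stim-on notch is
  applied there. Broadband transients that survive the anti-alias filter
  are caught by the 10 µV absolute-amplitude threshold (applied after
  the notch by default; a switch exposes the pre-notch reading) and
  replaced by linear interpolation between flanking clean samples; an
  epoch losing more than half its samples is flagged unusable.

### Bursts

The subject's beta peak is the frequency with the deepest
movement-related desynchronization within 13–30 Hz in the warped,
baseline-normalized map; when the two deepest frequencies sit within 5%
relative of each other ("similar levels"), or nothing desynchronizes,
the rest-spectrum peak is used instead. The envelope is the rectified
f_peak ± 2 Hz band-pass, smoothed with a *centred* 200 ms moving
average; the burst threshold is the pooled (per condition, per subject)
75th percentile of rest-interval envelope samples, with the
linear-interpolation percentile definition (R type 7). Bursts are
strict threshold exceedances (ties count as subthreshold) lasting
≥ 100 ms; bursts are assigned to the interval containing their onset
and truncated at the interval boundary for duration accounting
(configurable).

Two measurement biases are inherent to this operationalization and are
left in place deliberately (they are properties of the method, not
bugs):

* the centred 200 ms smoothing makes detected onsets *anticipate* true
  envelope onsets (median ≈ −40 ms in the synthetic cohort) and biases
  detected durations long by roughly the smoothing window;
* with a 75th-percentile threshold, the suprathreshold fraction of the
  defining rest pool is 25% by construction, so rest-interval burst
  statistics are threshold-referenced, not absolute.

### Kinematics

Positions are low-pass filtered (10 Hz, 4th-order Butterworth, zero
phase; jittery timestamps are first resampled to the median interval).
Tangential velocity uses central differences and is smoothed with a
Gaussian kernel (σ = 25 ms, configurable — the underlying description
of the velocity smoothing is ambiguous, and this is our documented
interpretation). Acceleration is the central difference of smoothed
velocity, so the mean acceleration over a window equals
(v_end − v_start)/window — the identity the peri-burst windows rely on.

The radius–angle transform centres the trace on the centroid of the
first 0.5 s (the drawing starts at the spiral centre by task design;
an explicit centre can be supplied), unwraps the angle, maps both
drawing directions to increasing θ, and fixes θ(start) = −π/2 so the
excluded "first revolution" is exactly (−π/2, 1.5π]. The spiral fit is
OLS of radius on θ beyond 1.5π; residuals are reported for *all*
samples (line extrapolated into the excluded region) for the
trace-deviation analysis. Self-intersection (the accuracy flag) is an
exact orientation test over all non-adjacent polyline segment pairs.

### Peri-burst windows and controls

For each onset with a full ±0.25 s margin inside the draw interval,
Δa = a_post − a_pre with a_• = (v(edge) − v(edge'))/0.25 via
nearest-sample lookups on the shared clock (kinematics and LFP both use
draw onset = 0). Onsets too close to the boundary are excluded and
counted; overlapping windows are kept (a minimum-spacing switch
exists). The linear control places onsets every 50 ms across the
eligible draw span (half-open at the end; the rest interval has no
velocity signal, so restricting the grid to the draw interval is
forced); the shuffled control draws as many onsets as there are real
bursts, uniformly over the eligible span.

Because of the velocity smoothing and the 10 Hz position filter, a
rectangular deceleration pulse of amplitude c is recovered as ≈ 0.92 c
(kink smearing at the window edges); the recovery criterion's ±0.1
tolerance absorbs this. At cohort level two further dilutions apply:
detected (rather than true) onsets jitter by the smoothing
anticipation, and closely spaced bursts put earlier decelerations into
later pre-windows. Both affect real recordings identically.

### Spectral statistics

Morlet maps (width 7 cycles, 4–100 Hz at 1 Hz, 20 ms centres) mark
edge columns without full wavelet support and ±100 ms around draw onset
invalid. Time-warping linearly interpolates each frequency row onto 50
equispaced midpoints over the rest interval and 100 over the draw
interval — the draw segment is *always* exactly 100 samples, asserted in
tests. Band power uses DPSS multitapers (1 s windows, 2 Hz smoothing →
3 tapers, computed from the tridiagonal commuting matrix) averaged over
non-overlapping windows. The per-bin spectrum is scaled so its sum over
[0, Nyquist] is the signal variance (Parseval); `band_power()` averages
band bins by default ("average power of frequencies") and exposes
`aggregate = "sum"` for integrated power — the two conventions differ
by the bin count and are both used in the tests.

The cluster test is the standard paired within-subject construction:
per-bin paired t across subjects, one-sided cluster-forming threshold at
the α = 0.05 t-quantile, 4-connectivity over the time–frequency grid,
cluster mass = summed t, null = maximal |mass| over random sign flips
(5000 by default; full enumeration when 2^n is affordable, where the
sampled +1 correction is dropped because the identity flip is included).
Early (warped samples 1–50) and late (51–100) draw segments are tested
against rest separately. Permutation is at the level of subject-average
maps, since the per-subject averaged warped response is the unit of the
underlying analysis.

### Mixed models

`fit_mixed_model()` is a disciplined wrapper around `lme4::lmer` (REML):
factor fixed effects with interactions, subject random intercepts,
optional subject random slope for a continuous covariate (dropped with a
flag when the fit is singular). Because no Satterthwaite backend is
available in the target environment, fixed-effect p-values use the Wald
normal approximation, and post hoc pairwise contrasts are built directly
from the fixed-effect covariance (cell means on the model matrix,
averaged over the remaining factors, Bonferroni-adjusted). At the
design sizes here (hundreds of trials, ≥ 5 subjects) the normal
approximation's anti-conservatism is small; the 95% CI coverage of a
known stimulation effect measured over 100 synthetic cohorts is ~94%,
inside the [90%, 99%] acceptance band.

## 2. The synthetic world

The generator emulates the stated experimental conditions: 19 subjects,
four conditions (free/template × stim off/on), up to 12 trials each;
five-loop spirals with 1.5 cm spacing and 7.5 cm maximal radius; a fixed
5 s rest interval preceding each draw; 7/19 subjects flagged
tremor-dominant; 130 Hz stimulation.

Key modelling decisions, each chosen once for realism:

* **LFP** = 1/f^1.5 background (RMS 1 µV) + 50 Hz line (0.3 µV) + beta
  bursts: sinusoids at the subject's beta peak under a Hann envelope
  with log-normal duration (median 0.3 s) and envelope-peak amplitude
  (median 5 µV — STN beta bursts stand well out of the background, and
  detectability at the 75th-percentile threshold requires it). During
  drawing, rate (0.8 → 0.6 /s), duration (×0.7) and amplitude (×0.8)
  multiply down; stimulation multiplies amplitudes by 0.7 in both
  intervals. Overlapping injected events are merged in the ground truth.
* **Stim artifacts** = a 2 µV 130 Hz carrier (removed by the notch) plus
  broadband double-exponential transients (median 50 µV, τ = 18 ms,
  1.5 /s) — narrowband 130 Hz content cannot survive the anti-alias
  brickwall at 100 Hz, so what the 10 µV threshold catches in practice
  is broadband saturation residue. Rates were calibrated once so the
  cleaning stage removes ≈ 6% of stim-on samples.
* **Drawing** = r = bθ with b = 1.5/(2π), traced at a tangential speed
  linear in time (constant base acceleration, start at 40% of the
  trial-mean speed) — velocity grows with the radius, and the
  acceleration profile is stationary, which is the premise the
  control-onset analyses certify. The trace starts at θ₀ = 2.5 rad
  (r ≈ 0.6 cm): the exact centre point cannot be drawn from standstill.
  Nominal durations: free 15 s, template 25 s (free is faster; the
  duration distribution is not specified anywhere, so these are exposed
  as configuration, not claimed as fidelity). Position noise is
  band-limited (~8 Hz) Gaussian with SD 0.005 cm free / 0.003 cm
  template; white noise at tablet resolution would fold sample-scale
  zigzags into the slow near-centre trace and produce spurious
  self-intersections no human trace contains.
* **Burst–kinematics coupling**: in free drawing only, each burst onset
  triggers a deceleration pulse of −0.8 cm/s² for 0.25 s (scaled by the
  stimulation amplitude factor when stim is on — DBS weakens the
  burst's kinematic consequence), after which the standing velocity
  decrement decays with τ = 6 s. The decay starts only after the pulse,
  so the injected Δa over the measurement windows is exactly the pulse
  amplitude; without it, repeated bursts would accumulate an unbounded
  slow-down and could stall the pen, which no real trace does.
* **Inaccurate trials**: with probability 0.25 (free) / 0.10 (template)
  an inward radial perturbation of 1.2 × spacing makes the trace cross
  the previous loop, mirroring the observed exclusion fractions.
* **Subject effects**: log₁₀-velocity intercepts (SD 0.15), multiplicative
  burst-amplitude factors (log-normal, SD 0.2), per-subject beta peaks
  uniform on 15–28 Hz, trial-level velocity jitter SD 0.1.

What the generator does **not** emulate — and what a green test therefore
does not establish: volume conduction and electrode geometry, real DBS
pulse waveforms (only their spectral/saturation signature), non-beta
oscillatory structure (no tremor-band LFP, no gamma bursts),
pen pressure, corrective sub-movements on the template, manual trial
alignment error (the synthetic clocks are exactly aligned), and any
clinical-score generating process. Statistical conclusions about the
pipeline's calibration transfer to real data only insofar as real noise
resembles 1/f + line noise.

## 3. Determinism and budgets

A single integer seed determines an entire cohort bit-exactly
(per-trial seeds are derived arithmetically and stay below 2^31). The
pipeline driver seeds each stage from its master seed, stamps each stage
with a hash of its parameters plus the upstream stamp, and skips stages
whose stamp is unchanged — so a parameter change reruns exactly the
affected suffix of the chain, and two runs with one seed produce
byte-identical outputs (asserted over file hashes in the acceptance
suite). Simulation sizes in the test suite are scaled down where a
criterion permits (cluster-test calibration uses 500 permutations per
simulated dataset; the determinism check runs a reduced cohort at
512 Hz); thresholds and tolerances are never scaled.

## 4. Known limitations

* Wald (normal) p-values for mixed models; small-sample dfs are not
  approximated. CIs are slightly anti-conservative at few subjects.
* The peri-burst deceleration estimate is attenuated ~8% by the
  measurement chain (velocity smoothing and position filtering); the
  package reports what the chain measures, not the latent pulse.
* `find_beta_peak` assumes a desynchronization exists; flat or
  synchronizing spectra fall back to the rest peak with a warning.
* The 10 µV artifact threshold is applied after the stim-frequency
  notch by default; the pre-notch reading is a switch, and with heavy
  artifacts the two differ.
* Draw intervals shorter than 10 native TFR bins (200 ms) cannot be
  warped and error out rather than extrapolate.
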