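---
title: "Online EEG source reconstruction with calibration-derived spatial filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online EEG source reconstruction with calibration-derived spatial filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstream)
```

## The problem

Scalp EEG mixes every active cortical source into every electrode, together
with ocular and muscular artifacts and sensor noise. Source-space analyses
undo this mixing by solving the inverse problem, but the classical workflow
(artifact rejection by independent component analysis, head modelling,
regularized inverse operators) is an offline batch computation. For
brain-computer interfaces and neurofeedback the reconstruction must instead be
available within milliseconds of each acquired sample.

`eegstream` follows the calibration-filter strategy: every expensive,
data-dependent estimation step is done once, on a resting *calibration
recording* acquired before the experiment, and condensed into a set of fixed
matrices. The live loop then consists only of small matrix products per
buffer, cheap enough to run at the sampling rate.

## The model

**Forward model.** Scalp potentials are linear in the source currents,
`theta(t) = L J(t)`, with `L` the `[n_E x 3 n_V]` leadfield over a regular
volumetric grid (three columns per voxel, one per dipole axis). `L` is
computed analytically for three concentric spherical shells (brain, skull,
scalp; conductivities 0.33, 0.01, 0.43 S/m by default) with an insulating
exterior. Per spherical-harmonic degree the radial transfer across the shells
is a 5-unknown boundary-value problem, solved with row/column equilibration
so the `r^(+-n)` terms cannot destroy conditioning at high degree; the
angular sums are evaluated with Legendre recurrences. Truncation is adaptive:
starting from `order` (default 60) terms, the series is extended until the
geometric tail bound at the most superficial grid voxel falls below `tol`
(default 1e-8), and it is an error if `maxOrder` (default 300) cannot achieve
that. In the equal-conductivity limit the solution must coincide with the
single homogeneous sphere, for which the package carries an independent
closed form (`homogeneousSpherePotential`, a generating-function summation of
the same series); the two agree to about 1e-12 in the tests. Electrodes are
co-registered by a closed-form least-squares rigid fit over the three
fiducials followed by radial projection onto the scalp sphere (for a sphere
the radial projection plays the role a surface-ICP refinement would play for
a realistic mesh). When no head model is available, a least-squares sphere is
fitted to the electrode cloud and the inner radii set by fixed ratios (0.92
and 0.87 of the scalp radius).

**Calibration filters.** From the calibration recording the package
estimates, in order:

* **Bad channels** — a channel is rejected when its minimum in-band Pearson
  correlation against all other channels is an outlier *below* the channel
  distribution (mean − 4 sd), or its 200–250 Hz noise variance an outlier
  *above* (mean + 4 sd). The two directions matter: low correlation and high
  noise are the pathological tails. The noise parameter is defined only at
  acquisition-grade sampling rates (≥ 500 Hz) and is skipped otherwise. A
  constant channel has no defined correlation and receives the sentinel −1.
* **Repair matrix `C`** — bad channels are replaced by the mean of their good
  neighbours (adjacency by Euclidean distance ≤ 40 mm; the threshold is a
  configuration key), all other rows are canonical unit rows.
* **Average reference `R = I − (1/n_E) 11ᵀ`** — a symmetric idempotent
  projector; all downstream operators live in its range.
* **ICA** — deflation FastICA with the `tanh` contrast on the filtered,
  repaired, re-referenced data, after whitening to the effective rank
  (average referencing and each repaired channel reduce rank by one).
  Initial vectors come from a seeded RNG and each component's sign is fixed
  by its largest unmixing weight, so the decomposition is bit-reproducible.
* **Artifact components** — a component is artifactual if at least one of
  three features exceeds its threshold: maximum absolute correlation between
  its power envelope (squared signal, 1 s moving average) and the identically
  processed vEOG/hEOG/EMG auxiliaries (default 0.3); the R² of a log-log
  linear fit of its Welch spectrum against frequency, counted only for
  negative slopes, i.e. a 1/f shape (default 0.8); and its excess kurtosis
  (default 10). The thresholds are configuration keys; the envelope
  correlation feature needs a few minutes of calibration to keep its null
  distribution narrow, which is why the standard calibration length is 4
  minutes.
* **Artifact attenuation filter**
  `F0 = I − X S_Aᵀ (S_A S_Aᵀ)⁻¹ W_A`, the regression of the data on the
  artifact component time courses `S_A = W_A X`. By substitution,
  `W_A F0 X = 0`: the artifact subspace is annihilated exactly on the data
  that built the filter. If `S_A S_Aᵀ` is ill-conditioned (condition number
  above 1e12) a relative ridge of `1e-8 · trace/n_A` is added.
* **Noise covariance `H`** — by default the sample covariance of the cleaned
  calibration data, symmetrized, projected as `R H R` and trace-normalized to
  `n_E`; alternatively (`hEstimator = "reference"`) the trace-normalized
  projector `R` itself, the white-noise model in average-reference space.
  The choice matters in simulation: when the calibration deliberately
  carries very strong rhythms, their covariance is signal, not noise, and
  using it as `H` penalizes exactly the sources being imaged; the validation
  studies therefore use the reference model, and real-data users whose
  calibration contains prominent idling rhythms face the same trade-off.
* **Inverse operator** `K = G⁻¹ Lᵀ (L G⁻¹ Lᵀ + λH)⁺`, with `λ = alpha ·
  trace(L G⁻¹ Lᵀ)/n_E` so that `alpha` (default 0.05) is dimensionless.
  eLORETA (default) iterates the per-voxel 3×3 weights
  `W_v = sqrtm(L_vᵀ M L_v)` with `M` the bracketed pseudoinverse,
  renormalizing the weights to mean trace one per pass, until the largest
  relative block change drops below 1e-6 (cap 100 iterations); with small
  `alpha` it localizes noiseless point sources with zero error, which the
  tests verify exactly on the study grid. MNE uses `G = I`; sLORETA uses
  `G = I` and returns the per-voxel resolution blocks for standardized power.
  The pseudoinverse truncates singular values below 1e-10 of the maximum
  (average referencing makes rank `n_E − 1` structural).

**Online loop.** Samples enter a rolling buffer (default 500 ms). Per sample:
band-pass within the buffer, apply `C R`, estimate the buffer's artifact
activity `S_A(τ) = W_A X̃_q(τ)`, re-fit the regression on this buffer alone —
`F(τ) = I − X̃_q(τ) S_Aᵀ(τ) (S_A(τ) S_Aᵀ(τ))⁻¹ W_A` — clean, extract the
newest column as `Y(t)`, and project `B(t) = K Y(t)`. Re-estimating the
regression per buffer tracks the non-stationary gain of artifact processes
(a blink is not scaled like the last one), while the subspace `W_A` itself
stays fixed from calibration. One `(Y, B)` pair is emitted per input sample
once the buffer has filled; warm-up produces no output.

## Numerical choices

* **Band-pass design.** The band-pass is realized as a cascade of 4th-order
  Butterworth high-pass and low-pass sections, each applied forward-backward
  (zero phase). A single direct-form band-pass of the same total order is
  numerically fragile for narrow normalized bands (beta at 1 kHz); the
  cascade is not. Filtering uses odd-reflection padding *and* steady-state
  initial conditions on both passes — without the latter, a 1 Hz high-pass
  pole (time constant of seconds) rings across any window it touches. An
  upper edge at or above 99% of Nyquist drops the low-pass section, so the
  paper-style configuration "1–50 Hz at 100 Hz" runs as a pure 1 Hz
  high-pass.
* **High-pass inside a short buffer.** A zero-phase high-pass at 1 Hz is
  meaningless on a 500 ms window — the window holds half a period. The
  online engine therefore applies the high-pass section only when the buffer
  spans at least two periods of the edge frequency, and falls back to window
  demeaning otherwise (all the window can say about its low frequencies).
  This rule is what makes the streamed output agree with offline cleaning to
  r > 0.95 per channel on stationary data; applying the 1 Hz section to the
  window verbatim drives the agreement below 0.4.
* **ERD estimator.** Band power is band-pass → squaring → 250 ms moving
  average for time courses; windowed ERD values
  (`100 · (P_task − P_base)/P_base`, task [0, 2] s, baseline [−1, 0] s) use
  the *unsmoothed* instantaneous power, because a centered smoother bleeds
  baseline power across the onset boundary. The across-trial map divides
  pooled task power by pooled baseline power (ratio of means): averaging
  per-trial ratios inherits the small-sample bias of dividing by a noisy
  one-second baseline estimate, which at 20 trials shifts a true −75%
  modulation visibly toward zero.
* **EMG onsets.** Rectified EMG, causal 200 ms moving average, threshold at
  mean + 3 sd of the *below-median* half of the envelope (the rest-dominated
  part for duty cycles up to 50%; whole-signal statistics would place the
  threshold above the bursts for the 6 s/6 s task), 3 s refractory period.
  Each supra-threshold crossing is backdated to where the envelope first
  left the baseline band (mean + 1 sd), the usual double-threshold scheme:
  the high threshold confirms a burst, the low one dates it.
* **Degenerate inputs.** Empty artifact subspace → `F0 = I` with a warning;
  silent artifact subspace in a buffer → that buffer passes through; fewer
  samples than channels in the covariance → diagonal shrinkage; a grid voxel
  at the exact sphere center uses the analytic `n = 1` limit of the series.

## The simulator, and what it does and does not show

`simulateRecording` realizes the generative model the pipeline assumes:
band-limited dipolar sources mixed through the leadfield, a 6 s move / 6 s
rest trial structure in which task sources are scaled by the modulation
depth `a` during movement (so the expected ERD is `(a² − 1)·100%`; amplitude
ramps of 100 ms make the transition physiological rather than instantaneous),
distributed broadband background dipoles (`backgroundSources`), blink events
(300 ms biphasic template, Poisson times, stylized frontal topography built
from the most frontal-superior leadfield column plus an exponential fall-off
from the nasion), muscle bursts (20–50 Hz filtered noise with an
edge-electrode topography, deliberately inside the analysis band so band-pass
filtering alone cannot remove them), and white sensor noise. Auxiliary
channels carry the artifact generators' reference signals plus independent
noise, and a fourth EMG channel carries bursts aligned to the true movement
onsets. Everything is drawn from a single seed; identical specifications give
bit-identical recordings.

The background dipoles matter for validity: ERD is a *ratio* map, normalized
by each voxel's own baseline power. If the baseline were sensor noise alone,
its source-space projection would be strongly depth-dependent and the ratio
map would peak away from the true source no matter how strong the planted
rhythm — physiological baselines are dominated by distributed brain activity,
and so must simulated ones.

What passing these studies shows: the algebra of the filters is exact, the
inverse operators localize as theory predicts, the online engine reproduces
offline cleaning on stationary data, and the whole chain recovers a known
modulation depth at the right location under realistic artifact load. What it
does not show: performance on real heads (a three-shell sphere is not an
individual BEM model), on artifact morphologies richer than the stylized
templates, or at rhythm signal-to-noise ratios much lower than the prominent
simulated one.

## The validation studies

`studyGeometry()` builds the desk-scale study setup: a 94 mm three-shell
sphere, a 64-electrode Fibonacci montage and a 20 mm grid (251 voxels).
Sixty-four channels is deliberate — it is a high-density montage (half the
128 channels of typical hdEEG systems) and the spatial resolution it buys is
what makes the ratio-normalized ERD peak land on the planted voxel; at 32
channels the peak ties with a neighbouring voxel within 2%. The grid and
montage are coarse enough that every study runs in minutes on one core:
`motorValidationStudy` uses a 4-minute calibration and 20 task trials
(4 minutes of streaming at 100 Hz), `agreementStudy` a 4-minute rest stream,
and `badChannelStudy` twenty 20-second screenings at 1 kHz.

The planted motor source uses amplitude 300 nA·m against per-voxel background
dipoles of 10 nA·m and 2 µV sensor noise — a deliberately prominent
sensorimotor rhythm whose reconstructed beta power dominates its local
baseline by more than an order of magnitude, so the ERD estimate is limited
by the estimator, not the SNR. With modulation depth 0.5 the measured ERD
comes out between about −70 and −74% across seeds (expectation −75%, minus
roughly two points for the 100 ms amplitude ramps inside the [0, 2] s window
and one to two points of residual reconstruction bias).

## Known limitations

* The spherical model is a geometric idealization; realistically computed
  leadfields can be imported through the documented archive format instead.
* The artifact subspace `W_A` is frozen at calibration; electrode drift or
  new artifact types during a long session require recalibration.
* The per-buffer regression assumes the artifact components are
  distinguishable within 500 ms; with many flagged components and few
  channels the per-buffer fit gets noisy (another reason dense montages
  help).
* Gray-matter constraints, cortical meshes, beamformers and weighted
  minimum-norm variants are out of scope.
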