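# eegstream

Real-time source reconstruction of high-density EEG in R.

Source-space EEG analysis — mapping scalp potentials back onto the cortical
currents that generated them — is normally an offline batch computation:
artifact removal by independent component analysis, head modelling, and a
regularized inverse operator. `eegstream` re-organizes that workflow for
online use, for people building brain–computer interfaces, neurofeedback
loops, or closed-loop stimulation experiments: every data-dependent
estimation step is condensed, once, from a resting **calibration recording**
into a set of fixed spatial filters, and the live loop applies only small
matrix products per acquired sample.

## The model

Scalp potentials are linear in the source currents,

```
theta(t) = L J(t)
```

with `L` the `[n_E x 3 n_V]` leadfield over a volumetric grid, computed
analytically for a three-shell spherical head (brain/skull/scalp
conductivities 0.33/0.01/0.43 S/m) via an equilibrated per-harmonic
transfer-matrix solve. Calibration estimates, in order: a bad-channel repair
matrix `C` (outlier screening on in-band correlation and 200–250 Hz noise
variance, repair by good-neighbour averaging); the average reference
`R = I − (1/n_E)11'`; deflation FastICA (tanh contrast) with automatic
artifact-component classification (EOG/EMG power-envelope correlation, 1/f
spectral fit, kurtosis); the artifact attenuation filter

```
F0 = I − X S_A' (S_A S_A')^-1 W_A ,   S_A = W_A X
```

which annihilates the artifact subspace exactly on the calibration data; a
noise covariance `H`; and the source localization filter

```
K = G^-1 L' (L G^-1 L' + alpha H)^+
```

with eLORETA per-voxel weights `G` (zero localization error for noiseless
point sources), or MNE / sLORETA alternatives. Online, a rolling buffer
(500 ms default) is band-passed, sensor-filtered, and cleaned with the
regression re-fitted on the buffer itself — tracking the non-stationary gain
of artifact processes while the subspace `W_A` stays fixed — then the newest
sample `Y(t)` is extracted and projected as `B(t) = K Y(t)`. Validation
analytics compute event-related desynchronization,

```
ERD(f, t) = 100 * (P(f, t) − P_b(f)) / P_b(f)  [%]
```

as per-voxel maps and time–frequency profiles around EMG-detected movement
onsets. A ground-truth simulator (task-modulated dipolar sources, distributed
background activity, blink and muscle artifact generators with matching
auxiliary channels) makes every stage testable without any data download.
See the vignette `vignettes/online-source-reconstruction.Rmd` for the
numerical choices and their rationale.

## Worked example

```r
library(eegstream)

model   <- sphericalHeadModel()                      # 94 mm, 3 shells
montage <- fibonacciMontage(32, model)               # synthetic cap
grid    <- buildSourceGrid(model, spacing = 20)
lf      <- computeLeadfield(model, montage, grid)
lf
#> Leadfield: 32 electrodes x 251 voxels (average reference)

spec <- simulationSpec(sources = backgroundSources(lf), duration = 240,
                       samplingRate = 100, seed = 7)
sim <- simulateRecording(spec, lf)                   # 4 min rest + artifacts
cal <- runCalibration(sim$recording, lf,
                      calibrationConfig(band = c(1, 45), seed = 7))
cal$filters
#> SpatialFilterSet (eloreta, alpha = 0.05)
#>   32 EEG channels, 2 artifact components, K: 753 x 32

cfg <- realtimeConfig(bufferMs = 500, samplingRate = 100, band = c(1, 45))
out <- runStream(sim$recording, cal$filters, cfg)
max(out$annihilation)
#> [1] 1.74e-15
```

The two flagged components are the simulated blink and muscle generators;
the annihilation residual shows the artifact subspace is removed to machine
precision in every buffer. Comparing the streamed samples against offline
cleaning of the full record:

```r
off  <- offlineClean(sim$recording, cal$filters)[, out$timestamps]
cors <- sapply(seq_len(nrow(off)), function(i) cor(out$Y[i, ], off[i, ]))
round(c(min = min(cors), median = median(cors)), 3)
#>    min median
#>  0.953  0.960
```

`motorValidationStudy()` runs the full end-to-end experiment (simulated
6 s move / 6 s rest task, calibration, streaming, ERD mapping) and is the
quickest way to see every stage working together.

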