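# Canonical synthetic validation studies: self-contained experiments
# that exercise the whole pipeline under the task design the package
# targets (6 s move / 6 s rest right-hand movement blocks). They are
# used by the test suite and the acceptance script, and serve as worked
# examples of the API.

#' Geometry and leadfield for the synthetic validation studies
#'
#' A 94 mm three-shell spherical head, a quasi-uniform Fibonacci
#' montage, a 20 mm source grid (a few hundred voxels, desk-scale) and
#' the analytic leadfield.
#'
#' @param nElectrodes montage size (default 64; a high-density montage
#'   is what makes ratio-normalized ERD maps spatially specific).
#' @param spacing grid spacing in mm (default 20).
#' @return list with `model`, `electrodes`, `grid`, `leadfield`.
#' @export
studyGeometry <- function(nElectrodes = 64, spacing = 20) {
  model <- sphericalHeadModel()
  electrodes <- fibonacciMontage(nElectrodes, model)
  grid <- buildSourceGrid(model, spacing = spacing)
  lf <- computeLeadfield(model, electrodes, grid)
  list(model = model, electrodes = electrodes, grid = grid, leadfield = lf)
}

#' End-to-end motor ERD validation study
#'
#' Simulates a calibration (rest) recording and a task recording with a
#' beta-band source of modulation depth `depth` over `nTrials` move/rest
#' cycles plus distributed background activity and blink/muscle
#' artifacts; calibrates the full spatial filter set on the rest data;
#' streams the task recording through the online engine; and computes
#' the beta ERD map, the ERD at the planted voxel, the peak-ERD voxel,
#' EMG-detected onsets and residual artifact correlations.
#'
#' @param seed study seed (drives both simulations and the ICA).
#' @param nTrials move/rest cycles (default 20).
#' @param depth modulation depth (default 0.5, expected ERD -75%).
#' @param nElectrodes montage size (default 64).
#' @param calibrationSec rest-recording length in seconds (default 240,
#'   the standard 4 min resting calibration; short calibrations inflate
#'   the false-flag rate of the envelope-correlation IC feature).
#' @param hEstimator noise-covariance estimator (default `"reference"`:
#'   the simulated calibration is dominated by deliberately strong
#'   rhythms, and treating their covariance as noise would penalize the
#'   very sources being imaged; see the vignette).
#' @param geometry optional precomputed [studyGeometry()] result (the
#'   leadfield does not depend on the seed, so it can be shared).
#' @return list of study measurements (see details in the vignette):
#'   `erdAtSource`, `peakVoxel`, `sourceVoxel`, `erdMap`,
#'   `onsetsDetected`, `onsetErrMs`, `cleanedVeogCorr`,
#'   `uncleanedVeogCorr`, `annihilationMax`, `nArtifactICs`, plus the
#'   fitted `filters`.
#' @export
motorValidationStudy <- function(seed = 1, nTrials = 20, depth = 0.5,
                                 nElectrodes = 64, calibrationSec = 240,
                                 hEstimator = "reference", geometry = NULL) {
  geo <- if (is.null(geometry)) studyGeometry(nElectrodes) else geometry
  lf <- geo$leadfield
  fs <- 100
  band <- c(1, 45)
  src <- defaultMotorSource(lf, depth = depth)
  bg <- backgroundSources(lf, seed = seed)
  calSpec <- simulationSpec(
    sources = rbind(transform(src, depth = 1, task = FALSE), bg),
    nTrials = 0L, duration = calibrationSec, samplingRate = fs, seed = seed)
  cal <- simulateRecording(calSpec, lf)
  calib <- runCalibration(cal$recording, lf,
                          calibrationConfig(band = band, seed = seed,
                                            hEstimator = hEstimator))
  filters <- calib$filters
  taskSpec <- simulationSpec(sources = rbind(src, bg), nTrials = as.integer(nTrials),
                             samplingRate = fs, seed = seed + 1L)
  task <- simulateRecording(taskSpec, lf)
  cfg <- realtimeConfig(bufferMs = 500, samplingRate = fs, band = band, seed = seed)
  out <- runStream(task$recording, filters, cfg)
  # onsets from the movement EMG channel, trimmed to the streamed range
  emg <- auxChannel(task$recording, "emgonset")
  det <- detectOnsets(emg, fs)
  trueOn <- task$groundTruth@onsets
  onsetErrMs <- if (length(det) == length(trueOn))
    max(abs(det - trueOn)) / fs * 1000 else NA_real_
  # beta ERD map over voxels from the streamed source signals; window
  # averages use instantaneous power (no envelope smoothing) so no
  # baseline power bleeds across the onset boundary
  pw <- collapseOrientations(out$B, c(13, 30), fs, smoothSec = 0)
  onStream <- trueOn - (cfg$nT - 1L)
  onStream <- onStream[onStream >= 1]
  trials <- epochTrials(pw, onStream, fs)
  erd <- computeERDFromPower(trials)
  v0 <- src$voxel
  # residual blink correlation at ROIs around the source and a control site
  ctrl <- which.max(geo$grid@positions[, 2])      # frontal-most voxel
  rois <- data.frame(name = c("source", "control"),
                     x = geo$grid@positions[c(v0, ctrl), 1],
                     y = geo$grid@positions[c(v0, ctrl), 2],
                     z = geo$grid@positions[c(v0, ctrl), 3],
                     radius = 12)
  ds <- downsampleToROIs(filters@K, geo$grid, rois)
  veog <- auxChannel(task$recording, "veog")[out$timestamps]
  cleaned <- ds$K %*% out$Y
  Xraw <- bandpassFilter(eegData(task$recording), band, fs = fs)
  uncleaned <- ds$K %*% (filters@C %*% filters@R %*% Xraw)[, out$timestamps]
  cc <- function(M) max(abs(stats::cor(t(M), veog)))
  list(erdAtSource = erd@values[v0],
       peakVoxel = which.max(abs(erd@values)),
       sourceVoxel = v0,
       erdMap = erd,
       trials = trials,
       onsetsDetected = length(det), onsetsTrue = length(trueOn),
       onsetErrMs = onsetErrMs,
       cleanedVeogCorr = cc(cleaned),
       uncleanedVeogCorr = cc(uncleaned),
       annihilationMax = max(out$annihilation),
       nArtifactICs = nrow(filters@WA),
       filters = filters, geometry = geo, stream = out,
       groundTruth = task$groundTruth, config = cfg)
}

#' Online/offline agreement study
#'
#' Streams a stationary rest recording through the online engine and
#' compares each cleaned sensor channel with the offline-cleaned
#' full-record output ([offlineClean()] with the same calibration
#' filters); returns the per-channel Pearson correlations.
#'
#' @param seed study seed.
#' @param nElectrodes montage size (default 64).
#' @param durationSec recording length (default 240 s, the standard
#'   resting calibration length).
#' @param geometry optional shared [studyGeometry()] result.
#' @return list with `correlations`, `minCorrelation`, `filters`.
#' @export
agreementStudy <- function(seed = 1, nElectrodes = 64, durationSec = 240,
                           geometry = NULL) {
  geo <- if (is.null(geometry)) studyGeometry(nElectrodes) else geometry
  lf <- geo$leadfield
  fs <- 100; band <- c(1, 45)
  spec <- simulationSpec(sources = backgroundSources(lf, seed = seed),
                         nTrials = 0L, duration = durationSec,
                         samplingRate = fs, seed = seed)
  sim <- simulateRecording(spec, lf)
  calib <- runCalibration(sim$recording, lf, calibrationConfig(band = band, seed = seed))
  cfg <- realtimeConfig(bufferMs = 500, samplingRate = fs, band = band, seed = seed)
  out <- runStream(sim$recording, calib$filters, cfg)
  off <- offlineClean(sim$recording, calib$filters)[, out$timestamps]
  cors <- vapply(seq_len(nrow(off)),
                 function(i) stats::cor(out$Y[i, ], off[i, ]), numeric(1))
  list(correlations = cors, minCorrelation = min(cors), filters = calib$filters)
}

#' Bad-channel detection study
#'
#' Simulates short 1 kHz recordings (the acquisition-grade sampling rate
#' at which the 200-250 Hz noise parameter is defined), injects one flat
#' and one high-frequency-noise channel, and screens a set of clean
#' replicates for false positives.
#'
#' @param seed study seed.
#' @param nClean number of clean replicate simulations (default 20).
#' @param durationSec per-recording length (default 20).
#' @return list with `flatDetected`, `hfDetected`, `falsePositives`.
#' @export
badChannelStudy <- function(seed = 1, nClean = 20, durationSec = 20) {
  geo <- studyGeometry(32)
  lf <- geo$leadfield
  fs <- 1000
  mk <- function(s, bad = NULL) {
    spec <- simulationSpec(sources = backgroundSources(lf, seed = s),
                           nTrials = 0L, duration = durationSec,
                           samplingRate = fs, blinkRate = 0, emgRate = 0,
                           badChannels = bad, seed = s)
    simulateRecording(spec, lf)$recording
  }
  rec <- mk(seed, data.frame(channel = c("E05", "E17"),
                             mode = c("flat", "hf-noise")))
  rep1 <- detectBadChannels(rec, band = c(1, 45))
  fp <- 0L
  for (k in seq_len(nClean)) {
    r <- detectBadChannels(mk(seed + k), band = c(1, 45))
    fp <- fp + length(r$bad)
  }
  list(flatDetected = "E05" %in% rep1$bad,
       hfDetected = "E17" %in% rep1$bad,
       detected = rep1$bad,
       falsePositives = fp)
}
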