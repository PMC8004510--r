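#' @import methods
NULL

.checkFinite <- function(x, what) {
  if (length(x) && !all(is.finite(x))) sprintf("%s contains non-finite values", what) else NULL
}

#' Electrode montage with fiducial landmarks
#'
#' Holds electrode labels, their 3-D positions (mm) and the three anatomical
#' fiducials (nasion, left/right preauricular points) used for rigid
#' co-registration into head-model space.
#'
#' @slot labels character vector of unique channel names.
#' @slot positions numeric matrix `[n_E x 3]` of coordinates in mm
#'   (+x right, +y anterior, +z superior).
#' @slot fiducials numeric matrix `[3 x 3]` with rownames `nz`, `lpa`, `rpa`.
#' @slot referenceLabel optional name of the physical reference channel.
#' @export
setClass("ElectrodeSet",
  representation(labels = "character", positions = "matrix",
                 fiducials = "matrix", referenceLabel = "character"),
  prototype(referenceLabel = character(0)))

setValidity("ElectrodeSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@labels)) msg <- c(msg, "electrode labels must be unique")
  if (nrow(object@positions) != length(object@labels))
    msg <- c(msg, "positions must have one row per label")
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be [n x 3]")
  msg <- c(msg, .checkFinite(object@positions, "positions"))
  if (!identical(dim(object@fiducials), c(3L, 3L)) ||
      !setequal(rownames(object@fiducials), c("nz", "lpa", "rpa")))
    msg <- c(msg, "fiducials must be a 3x3 matrix with rows nz, lpa, rpa")
  else {
    msg <- c(msg, .checkFinite(object@fiducials, "fiducials"))
    v1 <- object@fiducials["lpa", ] - object@fiducials["nz", ]
    v2 <- object@fiducials["rpa", ] - object@fiducials["nz", ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(cr^2)) < 1e-6) msg <- c(msg, "fiducials are collinear")
  }
  if (length(msg)) msg else TRUE
})

#' Three-shell spherical volume conductor
#'
#' Concentric spheres for brain, skull and scalp with isotropic
#' conductivities (S/m). Defaults follow the standard literature values
#' 0.33 / 0.01 / 0.43.
#'
#' @slot center numeric length-3, sphere center in mm.
#' @slot radii named numeric `(brain, skull, scalp)` in mm, strictly increasing.
#' @slot conductivities named numeric `(brain, skull, scalp)` in S/m.
#' @export
setClass("SphericalHeadModel",
  representation(center = "numeric", radii = "numeric", conductivities = "numeric"))

setValidity("SphericalHeadModel", function(object) {
  msg <- character(0)
  if (length(object@center) != 3 || !all(is.finite(object@center)))
    msg <- c(msg, "center must be a finite length-3 vector")
  r <- object@radii
  if (length(r) != 3 || !all(is.finite(r)) || !(0 < r[1] && r[1] < r[2] && r[2] < r[3]))
    msg <- c(msg, "radii must satisfy 0 < brain < skull < scalp")
  s <- object@conductivities
  if (length(s) != 3 || !all(is.finite(s)) || any(s <= 0))
    msg <- c(msg, "conductivities must be three positive values")
  if (length(msg)) msg else TRUE
})

#' Regular volumetric source grid
#'
#' Lattice of candidate dipole positions inside the brain shell, ordered
#' x-fastest, then y, then z, so that leadfield column `3(v-1)+d` is
#' unambiguous across the package.
#'
#' @slot positions numeric matrix `[n_V x 3]` in mm.
#' @slot spacing scalar lattice spacing in mm.
#' @slot maskRadius radius (mm, about the model center) inside which voxels lie.
#' @slot center model center the mask refers to.
#' @export
setClass("SourceGrid",
  representation(positions = "matrix", spacing = "numeric",
                 maskRadius = "numeric", center = "numeric"))

setValidity("SourceGrid", function(object) {
  msg <- character(0)
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be [n x 3]")
  msg <- c(msg, .checkFinite(object@positions, "positions"))
  if (length(object@spacing) != 1 || object@spacing <= 0)
    msg <- c(msg, "spacing must be a positive scalar")
  if (nrow(object@positions) == 0) msg <- c(msg, "grid is empty")
  if (length(msg)) msg else TRUE
})

#' Leadfield (forward gain) matrix
#'
#' Linear map from unit dipole moments on the source grid to scalp
#' potentials: `gain[e, 3(v-1)+d]` is the potential (microvolt per nA m) at
#' electrode `e` for a unit dipole at voxel `v` along axis `d`.
#'
#' @slot gain numeric matrix `[n_E x 3 n_V]`.
#' @slot electrodes the co-registered [ElectrodeSet-class] the rows refer to.
#' @slot grid the [SourceGrid-class] the columns refer to.
#' @slot model the [SphericalHeadModel-class] used.
#' @slot referenced logical; `TRUE` when columns are in average reference.
#' @export
setClass("Leadfield",
  representation(gain = "matrix", electrodes = "ElectrodeSet",
                 grid = "SourceGrid", model = "SphericalHeadModel",
                 referenced = "logical"))

setValidity("Leadfield", function(object) {
  msg <- character(0)
  msg <- c(msg, .checkFinite(object@gain, "gain"))
  if (nrow(object@gain) != length(object@electrodes@labels))
    msg <- c(msg, "gain rows must match electrode count")
  if (ncol(object@gain) != 3 * nrow(object@grid@positions))
    msg <- c(msg, "gain must have 3 columns per grid voxel")
  if (isTRUE(object@referenced) && ncol(object@gain)) {
    colm <- colMeans(object@gain)
    rel <- max(abs(colm)) / max(abs(object@gain), 1e-300)
    if (rel > 1e-10) msg <- c(msg, "referenced leadfield columns must have zero mean")
  }
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' Sensor time series in microvolt, rows are channels. Auxiliary
#' electrophysiology channels (vEOG, hEOG, EMG) live in the same matrix and
#' are indexed by `auxMap`; all other rows are EEG.
#'
#' @slot data numeric matrix `[(n_E + n_aux) x n_T]` in microvolt.
#' @slot labels character, one per row.
#' @slot samplingRate sampling frequency in Hz.
#' @slot auxMap named integer vector mapping auxiliary roles
#'   (e.g. `veog`, `heog`, `emg1`) to row indices.
#' @slot band numeric length-2 filter provenance (Hz), or `numeric(0)` for raw.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", labels = "character",
                 samplingRate = "numeric", auxMap = "integer", band = "numeric"),
  prototype(auxMap = integer(0), band = numeric(0)))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "labels must match data rows")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  msg <- c(msg, .checkFinite(object@data, "data"))
  if (length(object@auxMap)) {
    if (is.null(names(object@auxMap)) || anyDuplicated(object@auxMap))
      msg <- c(msg, "auxMap must be named with disjoint row indices")
    if (any(object@auxMap < 1 | object@auxMap > nrow(object@data)))
      msg <- c(msg, "auxMap indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' ICA decomposition of a calibration recording
#'
#' @slot A mixing matrix `[n_E x n_S]`.
#' @slot W unmixing matrix `[n_S x n_E]` (`W %*% A` is the identity).
#' @slot S component time courses `[n_S x n_T]`, unit variance.
#' @slot artifactIndices integer indices of components classified artifactual.
#' @slot converged logical per component.
#' @export
setClass("ICADecomposition",
  representation(A = "matrix", W = "matrix", S = "matrix",
                 artifactIndices = "integer", converged = "logical"),
  prototype(artifactIndices = integer(0)))

setValidity("ICADecomposition", function(object) {
  msg <- character(0)
  nS <- nrow(object@W)
  if (ncol(object@A) != nS) msg <- c(msg, "A and W dimensions disagree")
  if (nS) {
    wa <- object@W %*% object@A
    if (max(abs(wa - diag(nS))) > 1e-6) msg <- c(msg, "W %*% A must be the identity")
  }
  if (length(object@artifactIndices) &&
      (min(object@artifactIndices) < 1 || max(object@artifactIndices) > nS))
    msg <- c(msg, "artifactIndices out of range")
  if (length(msg)) msg else TRUE
})

#' Calibration products: the full spatial filter set
#'
#' Everything the online engine needs: bad-channel repair `C`, average
#' reference `R`, artifact unmixing rows `WA`, the static artifact
#' attenuation filter `F0`, noise covariance `H`, and the source
#' localization filter `K` with its per-voxel weight blocks.
#'
#' @slot C bad-channel correction matrix `[n_E x n_E]`.
#' @slot R average-reference matrix `[n_E x n_E]`.
#' @slot WA artifact-component unmixing rows `[n_A x n_E]`.
#' @slot F0 artifact attenuation filter `[n_E x n_E]`.
#' @slot H noise covariance `[n_E x n_E]`, trace-normalized.
#' @slot K source localization filter `[3 n_V x n_E]` (or `[3 n_R x n_E]`).
#' @slot Gblocks numeric array `[3 x 3 x n_V]` of per-voxel weights
#'   (eLORETA weights, or sLORETA standardization blocks).
#' @slot method inverse operator name: `"eloreta"`, `"mne"` or `"sloreta"`.
#' @slot alpha dimensionless Tikhonov regularization parameter.
#' @slot band analysis band (Hz) used during calibration.
#' @slot samplingRate calibration sampling rate in Hz.
#' @slot badChannels labels of repaired channels.
#' @slot electrodeLabels EEG channel order the matrices refer to.
#' @slot roiNames ROI names when `K` is ROI-downsampled, else `character(0)`.
#' @export
setClass("SpatialFilterSet",
  representation(C = "matrix", R = "matrix", WA = "matrix", F0 = "matrix",
                 H = "matrix", K = "matrix", Gblocks = "array",
                 method = "character", alpha = "numeric", band = "numeric",
                 samplingRate = "numeric", badChannels = "character",
                 electrodeLabels = "character", roiNames = "character"),
  prototype(roiNames = character(0), badChannels = character(0)))

setValidity("SpatialFilterSet", function(object) {
  msg <- character(0)
  nE <- length(object@electrodeLabels)
  for (nm in c("C", "R", "F0", "H"))
    if (!identical(dim(slot(object, nm)), c(nE, nE)))
      msg <- c(msg, sprintf("%s must be [n_E x n_E]", nm))
  if (ncol(object@K) != nE) msg <- c(msg, "K must have n_E columns")
  if (nrow(object@K) %% 3 != 0) msg <- c(msg, "K rows must be a multiple of 3")
  if (length(object@alpha) != 1 || object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  msg <- c(msg, .checkFinite(object@F0, "F0"), .checkFinite(object@K, "K"))
  if (nE) {
    if (max(abs(object@H - t(object@H))) > 1e-8) msg <- c(msg, "H must be symmetric")
    ev <- eigen((object@H + t(object@H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-300)) msg <- c(msg, "H must be positive semidefinite")
  }
  if (length(msg)) msg else TRUE
})

#' Rolling acquisition buffer
#'
#' FIFO window of the most recent `nT` samples; `pushSample` is functional
#' (returns the updated buffer). The online engine mirrors this structure
#' in compiled code.
#'
#' @slot window numeric matrix `[n_chan x n_T]`, oldest to newest at read time.
#' @slot nT buffer capacity in samples.
#' @slot cursor next write position (internal, circular storage).
#' @slot samplesSeen total samples pushed since creation.
#' @export
setClass("StreamBuffer",
  representation(window = "matrix", nT = "integer", cursor = "integer",
                 samplesSeen = "numeric"))

setValidity("StreamBuffer", function(object) {
  msg <- character(0)
  if (object@nT < 4) msg <- c(msg, "buffer must hold at least 4 samples")
  if (ncol(object@window) != object@nT) msg <- c(msg, "window width must equal nT")
  if (length(msg)) msg else TRUE
})

#' Epoched trials around movement onsets
#'
#' @slot epochs numeric array `[n_signal x n_time x n_trial]`, aligned so that
#'   the onset sample sits at `time = 0`.
#' @slot onsets sample indices (in the source record) of the kept trials.
#' @slot times numeric vector of within-epoch times in seconds.
#' @slot samplingRate Hz.
#' @slot baselineWindow numeric length-2, seconds relative to onset.
#' @slot taskWindow numeric length-2, seconds relative to onset.
#' @export
setClass("TrialSet",
  representation(epochs = "array", onsets = "integer", times = "numeric",
                 samplingRate = "numeric", baselineWindow = "numeric",
                 taskWindow = "numeric"))

setValidity("TrialSet", function(object) {
  msg <- character(0)
  if (length(dim(object@epochs)) != 3) msg <- c(msg, "epochs must be a 3-D array")
  if (is.unsorted(object@onsets, strictly = TRUE)) msg <- c(msg, "onsets must be strictly increasing")
  if (length(object@times) != dim(object@epochs)[2])
    msg <- c(msg, "times must match epoch length")
  if (length(msg)) msg else TRUE
})

#' Per-signal ERD/ERS map
#'
#' Signed relative band-power change in percent (negative values are
#' desynchronization). Entries with zero baseline power are `NA` and
#' flagged in `undefined`.
#'
#' @slot values numeric vector (one entry per voxel/ROI/channel), percent.
#' @slot undefined logical, `TRUE` where baseline power was zero.
#' @slot band numeric length-2 (Hz).
#' @slot trial trial id, or `"average"`.
#' @export
setClass("ERDMap",
  representation(values = "numeric", undefined = "logical",
                 band = "numeric", trial = "character"))

setValidity("ERDMap", function(object) {
  if (length(object@undefined) != length(object@values))
    "undefined flags must match values" else TRUE
})

#' Time-frequency ERD profile for one region
#'
#' @slot values matrix `[n_freq x n_time]` of ERD percent.
#' @slot freqs bin centers in Hz.
#' @slot times bin centers in seconds relative to onset.
#' @slot roi region name.
#' @export
setClass("ERDTimeFrequency",
  representation(values = "matrix", freqs = "numeric", times = "numeric",
                 roi = "character"))

setValidity("ERDTimeFrequency", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@freqs)) msg <- c(msg, "freqs must match rows")
  if (ncol(object@values) != length(object@times)) msg <- c(msg, "times must match columns")
  if (length(msg)) msg else TRUE
})

#' Ground-truth simulation specification
#'
#' Describes the synthetic study the simulator realizes: band-limited
#' dipolar cortical sources mixed through the leadfield, a 6 s move / 6 s
#' rest task that scales source amplitude by the modulation depth `a`
#' during movement (so the expected ERD is `(a^2 - 1) * 100` percent),
#' blink and muscle artifact generators with matching auxiliary reference
#' channels, white sensor noise, and optional bad-channel injections.
#'
#' @slot sources data.frame with columns `voxel`, `ox`, `oy`, `oz`,
#'   `low`, `high` (carrier band Hz), `amplitude` (dipole moment scale,
#'   nA m), `depth` (task modulation depth in (0, 1]; 1 = no
#'   modulation), `task` (logical: modulated by the trial structure).
#' @slot moveDur,restDur move/rest durations in seconds (paper task: 6/6).
#' @slot nTrials number of move/rest cycles; 0 means rest-only for the
#'   full `duration`.
#' @slot blinkRate blink events per minute.
#' @slot blinkAmplitude peak sensor amplitude of a blink, microvolt.
#' @slot emgRate muscle-burst events per minute.
#' @slot emgAmplitude sensor amplitude of muscle bursts, microvolt.
#' @slot noiseSD white sensor-noise standard deviation, microvolt.
#' @slot badChannels data.frame with columns `channel`, `mode`
#'   (`"flat"` or `"hf-noise"`).
#' @slot samplingRate Hz.
#' @slot duration total length in seconds (rest-only mode).
#' @slot seed integer RNG seed; fixed seed gives bit-identical recordings.
#' @export
setClass("SimulationSpec",
  representation(sources = "data.frame", moveDur = "numeric", restDur = "numeric",
                 nTrials = "integer", blinkRate = "numeric", blinkAmplitude = "numeric",
                 emgRate = "numeric", emgAmplitude = "numeric", noiseSD = "numeric",
                 badChannels = "data.frame", samplingRate = "numeric",
                 duration = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  if (nrow(object@sources)) {
    if (any(object@sources$depth <= 0 | object@sources$depth > 1))
      msg <- c(msg, "modulation depth must be in (0, 1]")
  }
  if (object@blinkRate < 0 || object@emgRate < 0) msg <- c(msg, "rates must be >= 0")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth accompanying a simulated recording
#'
#' @slot sourceSignals matrix `[n_src x n_T]`, the modulated source
#'   time courses (one row per simulated dipole).
#' @slot envelopes matrix `[n_src x n_T]` of task-modulation envelopes.
#' @slot onsets sample indices of movement-block starts.
#' @slot blinkRef blink reference time course (before aux noise).
#' @slot emgRef muscle-artifact reference time course.
#' @slot blinkTopography,emgTopography sensor-space mixing columns.
#' @slot blinkTimes sample indices of blink events.
#' @slot badChannels injected bad channels (label and mode).
#' @export
setClass("GroundTruth",
  representation(sourceSignals = "matrix", envelopes = "matrix",
                 onsets = "integer", blinkRef = "numeric", emgRef = "numeric",
                 blinkTopography = "numeric", emgTopography = "numeric",
                 blinkTimes = "integer", badChannels = "data.frame"))
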