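# show() methods and small accessors for the S4 containers

#' @describeIn ElectrodeSet-class number of electrodes
#' @param x an object
#' @export
setMethod("length", "ElectrodeSet", function(x) length(x@labels))

setMethod("show", "ElectrodeSet", function(object) {
  cat(sprintf("ElectrodeSet: %d electrodes\n", length(object@labels)))
  cat(sprintf("  labels: %s%s\n", paste(utils::head(object@labels, 6), collapse = ", "),
              if (length(object@labels) > 6) ", ..." else ""))
  ctr <- colMeans(object@positions)
  cat(sprintf("  centroid (mm): [%.1f, %.1f, %.1f]\n", ctr[1], ctr[2], ctr[3]))
})

setMethod("show", "SphericalHeadModel", function(object) {
  cat("SphericalHeadModel (3 concentric shells)\n")
  cat(sprintf("  center (mm): [%.1f, %.1f, %.1f]\n",
              object@center[1], object@center[2], object@center[3]))
  cat(sprintf("  radii  (mm): brain %.1f | skull %.1f | scalp %.1f\n",
              object@radii[1], object@radii[2], object@radii[3]))
  cat(sprintf("  sigma (S/m): brain %.3g | skull %.3g | scalp %.3g\n",
              object@conductivities[1], object@conductivities[2], object@conductivities[3]))
})

setMethod("show", "SourceGrid", function(object) {
  cat(sprintf("SourceGrid: %d voxels, %.1f mm spacing (mask radius %.1f mm)\n",
              nrow(object@positions), object@spacing, object@maskRadius))
})

setMethod("show", "Leadfield", function(object) {
  cat(sprintf("Leadfield: %d electrodes x %d voxels (%s reference)\n",
              nrow(object@gain), ncol(object@gain) / 3,
              if (object@referenced) "average" else "infinite"))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels (%d auxiliary) x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), length(object@auxMap), ncol(object@data),
              object@samplingRate, ncol(object@data) / object@samplingRate))
  if (length(object@band))
    cat(sprintf("  band: %.3g-%.3g Hz\n", object@band[1], object@band[2]))
})

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition: %d components over %d channels; %d artifactual\n",
              nrow(object@W), ncol(object@W), length(object@artifactIndices)))
})

setMethod("show", "SpatialFilterSet", function(object) {
  cat(sprintf("SpatialFilterSet (%s, alpha = %g)\n", object@method, object@alpha))
  cat(sprintf("  %d EEG channels, %d artifact components, K: %d x %d\n",
              length(object@electrodeLabels), nrow(object@WA),
              nrow(object@K), ncol(object@K)))
  if (length(object@badChannels))
    cat(sprintf("  repaired channels: %s\n", paste(object@badChannels, collapse = ", ")))
  if (length(object@roiNames))
    cat(sprintf("  ROI mode: %s\n", paste(object@roiNames, collapse = ", ")))
})

setMethod("show", "StreamBuffer", function(object) {
  cat(sprintf("StreamBuffer: %d x %d, %s (%g samples seen)\n",
              nrow(object@window), object@nT,
              if (bufferFull(object)) "full" else "warming up", object@samplesSeen))
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("TrialSet: %d trials x %d signals x %d samples @ %g Hz\n",
              d[3], d[1], d[2], object@samplingRate))
  cat(sprintf("  baseline [%g, %g] s, task [%g, %g] s\n",
              object@baselineWindow[1], object@baselineWindow[2],
              object@taskWindow[1], object@taskWindow[2]))
})

setMethod("show", "ERDMap", function(object) {
  v <- object@values[!object@undefined]
  cat(sprintf("ERDMap (%s, %.3g-%.3g Hz): %d entries, range [%.1f, %.1f]%%\n",
              object@trial, object@band[1], object@band[2],
              length(object@values), min(v), max(v)))
})

setMethod("show", "ERDTimeFrequency", function(object) {
  cat(sprintf("ERDTimeFrequency [%s]: %d freqs x %d times\n",
              object@roi, length(object@freqs), length(object@times)))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d sources, fs %g Hz, seed %d\n",
              nrow(object@sources), object@samplingRate, object@seed))
  if (object@nTrials > 0)
    cat(sprintf("  task: %d trials of %g s move / %g s rest\n",
                object@nTrials, object@moveDur, object@restDur))
  else cat(sprintf("  rest-only, %g s\n", object@duration))
})

#' EEG channel rows of a recording (excluding auxiliaries)
#' @param rec an [EEGRecording-class]
#' @return integer vector of EEG row indices
#' @export
eegRows <- function(rec) {
  setdiff(seq_len(nrow(rec@data)), unname(rec@auxMap))
}

#' Extract the EEG data matrix (microvolt, channels x samples)
#' @param rec an [EEGRecording-class]
#' @export
eegData <- function(rec) rec@data[eegRows(rec), , drop = FALSE]

#' Extract one auxiliary channel by role name
#' @param rec an [EEGRecording-class]
#' @param role auxiliary role, e.g. `"veog"`, `"heog"`, `"emg1"`
#' @export
auxChannel <- function(rec, role) {
  if (!role %in% names(rec@auxMap)) stop("no auxiliary channel with role '", role, "'")
  rec@data[rec@auxMap[[role]], ]
}

#' Sampling rate accessor
#' @param rec an [EEGRecording-class]
#' @export
samplingRate <- function(rec) rec@samplingRate

#' Leadfield gain matrix accessor
#' @param lf a [Leadfield-class]
#' @export
leadfieldGain <- function(lf) lf@gain
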