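# Calibration orchestration: from a resting recording and a leadfield to
# the full spatial filter set, plus the filter archive IO.

#' Default calibration configuration
#'
#' @param band analysis band in Hz (default `c(1, 45)`).
#' @param alpha Tikhonov regularization (default 0.05).
#' @param method inverse operator (default `"eloreta"`).
#' @param seed ICA seed (default 1).
#' @param adjacencyThreshold neighbour distance in mm (default 40).
#' @param icThresholds artifact-classification thresholds (see
#'   [classifyArtifactICs()]).
#' @param rois optional data.frame of spherical ROIs (name, x, y, z,
#'   radius) to downsample `K` to.
#' @param roiMode `"nearest"` or `"average"` representative voxel rule.
#' @param hEstimator `"data"` for the sample covariance of the cleaned
#'   calibration recording, or `"reference"` for the
#'   identity-in-average-reference model `H = R` (appropriate when the
#'   calibration is dominated by strong ongoing rhythms rather than
#'   sensor noise).
#' @return a named list of calibration settings.
#' @export
calibrationConfig <- function(band = c(1, 45), alpha = 0.05,
                              method = "eloreta", seed = 1,
                              adjacencyThreshold = 40,
                              icThresholds = c(power = 0.3, spectrum = 0.8, kurtosis = 10),
                              rois = NULL, roiMode = "nearest",
                              hEstimator = c("data", "reference")) {
  list(band = band, alpha = alpha, method = method, seed = seed,
       adjacencyThreshold = adjacencyThreshold, icThresholds = icThresholds,
       rois = rois, roiMode = roiMode, hEstimator = match.arg(hEstimator))
}

#' Run the full spatial-filter calibration
#'
#' Executes the calibration chain in order: bad-channel detection,
#' adjacency and correction matrix `C`, average reference `R`, sensor
#' filtering `X_q = C R X`, zero-phase band-pass, FastICA, artifact-IC
#' classification, artifact attenuation filter `F0`, noise covariance
#' `H` from the cleaned data, and the source localization filter `K`
#' (optionally downsampled to ROIs). Deterministic given
#' `config$seed`.
#'
#' @param rec calibration [EEGRecording-class] (EEG plus auxiliaries).
#' @param lf [Leadfield-class] whose electrodes match the recording's
#'   EEG channels.
#' @param config list from [calibrationConfig()].
#' @return a list with `filters` (a [SpatialFilterSet-class]) and
#'   `report` (bad channels, IC feature table, eLORETA iterations).
#' @export
runCalibration <- function(rec, lf, config = calibrationConfig()) {
  rows <- eegRows(rec)
  labs <- rec@labels[rows]
  if (!identical(labs, lf@electrodes@labels))
    stop("recording EEG channels do not match the leadfield electrodes")
  nE <- length(rows)
  bad <- detectBadChannels(rec, band = config$band)
  D <- buildAdjacency(lf@electrodes, bad$bad, threshold = config$adjacencyThreshold)
  C <- correctionMatrix(D, bad$bad)
  R <- referenceMatrix(nE)
  dimnames(C) <- NULL
  xq <- applySensorFilters(rec, C, R)
  xqt <- bandpassFilter(xq, config$band, auxPassthrough = TRUE)
  ica <- fitICA(xqt, seed = config$seed)
  feats <- classifyArtifactICs(ica, rec, thresholds = config$icThresholds,
                               band = config$band)
  ica <- markArtifactICs(ica, feats)
  WA <- artifactUnmixing(ica)
  F0 <- if (nrow(WA)) artifactFilter(xqt, ica) else diag(nE)
  Xp <- F0 %*% eegData(xqt)
  H <- if (identical(config$hEstimator, "reference")) {
    R * (nE / (nE - 1))            # trace-normalized average-reference projector
  } else noiseCovariance(Xp)
  inv <- inverseFilter(lf, H, alpha = config$alpha, method = config$method)
  K <- inv$K
  roiNames <- character(0)
  if (!is.null(config$rois)) {
    ds <- downsampleToROIs(K, lf@grid, config$rois, mode = config$roiMode)
    K <- ds$K
    roiNames <- ds$roiNames
  }
  filters <- new(Class = "SpatialFilterSet", C = C, R = R, WA = WA, F0 = F0, H = H,
                 K = K, Gblocks = inv$Gblocks, method = config$method,
                 alpha = config$alpha, band = as.numeric(config$band),
                 samplingRate = rec@samplingRate,
                 badChannels = as.character(bad$bad), electrodeLabels = labs,
                 roiNames = as.character(roiNames))
  list(filters = filters,
       report = list(badChannels = bad, icFeatures = feats,
                     nComponents = nrow(ica@W),
                     artifactComponents = ica@artifactIndices,
                     inverseIterations = inv$iterations))
}

# ---------------------------------------------------------------------------
# filter archive: JSON header + float64 binary, same layout rules as the
# leadfield container

#' Save a spatial filter set
#'
#' @param filters a [SpatialFilterSet-class].
#' @param path header file path; matrices go to `<path>.bin`.
#' @return `path`, invisibly.
#' @export
saveSpatialFilters <- function(filters, path) {
  mats <- list(C = filters@C, R = filters@R, WA = filters@WA, F0 = filters@F0,
               H = filters@H, K = filters@K,
               Gblocks = matrix(filters@Gblocks, nrow = 9))
  sizes <- vapply(mats, length, numeric(1))
  hdr <- list(format = "eegstream-filters", version = 1L,
              method = filters@method, alpha = filters@alpha,
              band = filters@band, sampling_rate = filters@samplingRate,
              bad_channels = filters@badChannels,
              electrode_labels = filters@electrodeLabels,
              roi_names = filters@roiNames,
              matrices = lapply(mats, function(m) dim(as.matrix(m))),
              n_gblocks = dim(filters@Gblocks)[3],
              binary = paste0(basename(path), ".bin"),
              dtype = "float64", order = "column-major")
  jsonlite::write_json(hdr, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (m in mats) writeBin(as.numeric(m), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a spatial filter set
#'
#' @param path header file path written by [saveSpatialFilters()].
#' @return a [SpatialFilterSet-class]
#' @export
loadSpatialFilters <- function(path) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(hdr$format, "eegstream-filters"))
    stop("not a spatial-filter container: ", path)
  con <- file(file.path(dirname(path), hdr$binary), "rb")
  on.exit(close(con))
  mats <- list()
  for (nm in names(hdr$matrices)) {
    d <- unlist(hdr$matrices[[nm]])
    x <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
    if (length(x) < prod(d)) stop("truncated filter archive: ", path)
    mats[[nm]] <- matrix(x, d[1], d[2])
  }
  nG <- as.integer(hdr$n_gblocks)
  new(Class = "SpatialFilterSet", C = mats$C, R = mats$R, WA = mats$WA, F0 = mats$F0,
      H = mats$H, K = mats$K,
      Gblocks = array(mats$Gblocks, dim = c(3, 3, nG)),
      method = hdr$method, alpha = hdr$alpha, band = as.numeric(hdr$band),
      samplingRate = hdr$sampling_rate,
      badChannels = as.character(hdr$bad_channels),
      electrodeLabels = as.character(hdr$electrode_labels),
      roiNames = as.character(hdr$roi_names))
}
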