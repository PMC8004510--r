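# Leadfield archive: a documented two-file container, `<path>` holding a
# JSON header (labels, grid, model, layout) and `<path>.bin` the gain
# matrix as little-endian float64, column-major. Binary storage keeps the
# round trip bit-exact.

.lfBinPath <- function(path) paste0(path, ".bin")

#' Save a leadfield to a JSON + binary container
#'
#' @param lf a [Leadfield-class].
#' @param path header file path; the gain matrix goes to `<path>.bin`.
#' @return `path`, invisibly.
#' @export
saveLeadfield <- function(lf, path) {
  hdr <- list(
    format = "eegstream-leadfield", version = 1L,
    n_electrodes = nrow(lf@gain), n_voxels = nrow(lf@grid@positions),
    labels = lf@electrodes@labels,
    electrode_positions = unname(lf@electrodes@positions),
    fiducials = unname(lf@electrodes@fiducials),
    grid_positions = unname(lf@grid@positions),
    spacing = lf@grid@spacing, mask_radius = lf@grid@maskRadius,
    model = list(center = lf@model@center, radii = unname(lf@model@radii),
                 conductivities = unname(lf@model@conductivities)),
    referenced = lf@referenced,
    binary = basename(.lfBinPath(path)), dtype = "float64", order = "column-major")
  jsonlite::write_json(hdr, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  con <- file(.lfBinPath(path), "wb")
  on.exit(close(con))
  writeBin(as.numeric(lf@gain), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a leadfield container
#'
#' Reads the JSON + binary pair written by [saveLeadfield()] (or produced
#' externally to the same layout), validates the stated shape against the
#' binary payload and rebuilds the [Leadfield-class] with its invariants
#' checked.
#'
#' @param path header file path.
#' @param electrodes optional [ElectrodeSet-class]; when given, labels and
#'   count must match the archive (compatibility check for downstream use).
#' @return a [Leadfield-class]
#' @export
loadLeadfield <- function(path, electrodes = NULL) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(hdr$format, "eegstream-leadfield"))
    stop("not a leadfield container: ", path)
  nE <- as.integer(hdr$n_electrodes); nV <- as.integer(hdr$n_voxels)
  binPath <- file.path(dirname(path), hdr$binary)
  expected <- nE * 3L * nV
  sz <- file.info(binPath)$size
  if (is.na(sz) || sz != 8 * expected)
    stop(sprintf("leadfield compatibility error: binary holds %s doubles, header implies %d",
                 ifelse(is.na(sz), "no", format(sz / 8)), expected))
  con <- file(binPath, "rb")
  on.exit(close(con))
  g <- readBin(con, numeric(), n = expected, size = 8, endian = "little")
  gain <- matrix(g, nE, 3L * nV)
  fid <- matrix(unlist(hdr$fiducials), 3, 3)
  rownames(fid) <- c("nz", "lpa", "rpa")
  es <- electrodeSet(hdr$labels, matrix(unlist(hdr$electrode_positions), nE, 3), fid)
  if (!is.null(electrodes)) {
    if (length(electrodes@labels) != nE || !all(electrodes@labels == es@labels))
      stop("leadfield compatibility error: electrode labels do not match the archive")
  }
  model <- sphericalHeadModel(center = hdr$model$center,
                              radii = hdr$model$radii,
                              conductivities = hdr$model$conductivities)
  grid <- new("SourceGrid", positions = matrix(unlist(hdr$grid_positions), nV, 3),
              spacing = hdr$spacing, maskRadius = hdr$mask_radius,
              center = model@center)
  new("Leadfield", gain = gain, electrodes = es, grid = grid, model = model,
      referenced = isTRUE(hdr$referenced))
}
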