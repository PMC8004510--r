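# Electrode montages: file readers, sphere fitting and rigid
# co-registration into head-model space.

#' Construct an ElectrodeSet
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric `[n x 3]` matrix of coordinates in mm.
#' @param fiducials numeric `3 x 3` matrix (rows `nz`, `lpa`, `rpa`) in mm.
#' @param referenceLabel optional physical reference channel name.
#' @return an [ElectrodeSet-class]
#' @export
electrodeSet <- function(labels, positions, fiducials, referenceLabel = character(0)) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  fiducials <- as.matrix(fiducials)
  if (is.null(rownames(fiducials))) rownames(fiducials) <- c("nz", "lpa", "rpa")
  rownames(fiducials) <- tolower(rownames(fiducials))
  new("ElectrodeSet", labels = as.character(labels), positions = positions,
      fiducials = fiducials[c("nz", "lpa", "rpa"), , drop = FALSE],
      referenceLabel = referenceLabel)
}

.FIDUCIAL_ALIASES <- list(
  nz = c("nz", "nas", "nasion", "fidnz"),
  lpa = c("lpa", "fidt9", "leftear", "al"),
  rpa = c("rpa", "fidt10", "rightear", "ar"))

.splitFiducials <- function(labels, positions, fiducialLabels = NULL) {
  lab <- tolower(labels)
  aliases <- .FIDUCIAL_ALIASES
  if (!is.null(fiducialLabels)) {
    fl <- tolower(fiducialLabels)
    aliases <- list(nz = fl[1], lpa = fl[2], rpa = fl[3])
  }
  idx <- vapply(aliases, function(a) {
    hit <- which(lab %in% a)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stop("fiducials not found in electrode file (need ",
         paste(names(idx)[is.na(idx)], collapse = ", "), ")")
  fid <- positions[idx, , drop = FALSE]
  rownames(fid) <- names(idx)
  keep <- setdiff(seq_along(labels), idx)
  list(labels = labels[keep], positions = positions[keep, , drop = FALSE], fiducials = fid)
}

#' Read electrode positions from an SFP or ELC file
#'
#' SFP files hold one `label x y z` row per line. The ELC dialect read
#' here has a `Positions` section (`label : x y z` or bare coordinate
#' triplets) followed by an optional `Labels` section. Fiducial rows
#' (nasion and preauricular points, by default `Nz`/`LPA`/`RPA`,
#' case-insensitive with common aliases) are split off into the
#' `fiducials` slot.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sfp"` or `"elc"`.
#' @param fiducialLabels optional length-3 character overriding the
#'   fiducial label aliases, in the order nasion, LPA, RPA.
#' @return an [ElectrodeSet-class]
#' @export
readElectrodes <- function(path, format = c("auto", "sfp", "elc"), fiducialLabels = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.elc$", path, ignore.case = TRUE)) "elc" else "sfp"
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (format == "sfp") {
    parts <- strsplit(lines, "[[:space:]]+")
    ok <- lengths(parts) >= 4
    parts <- parts[ok]
    labels <- vapply(parts, `[`, character(1), 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  } else {
    posStart <- grep("^Positions", lines, ignore.case = TRUE)
    labStart <- grep("^Labels", lines, ignore.case = TRUE)
    if (!length(posStart)) stop("ELC file has no Positions section")
    end <- if (length(labStart)) labStart[1] - 1L else length(lines)
    posLines <- lines[(posStart[1] + 1L):end]
    posLines <- posLines[!grepl("^[A-Za-z]+[A-Za-z ]*=", posLines)]
    haveLabel <- grepl(":", posLines, fixed = TRUE)
    labels <- character(length(posLines))
    pos <- matrix(NA_real_, length(posLines), 3)
    for (i in seq_along(posLines)) {
      ln <- posLines[i]
      if (haveLabel[i]) {
        bits <- strsplit(ln, ":", fixed = TRUE)[[1]]
        labels[i] <- trimws(bits[1])
        ln <- bits[2]
      }
      pos[i, ] <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][1:3])
    }
    if (!all(haveLabel)) {
      if (length(labStart)) {
        labLines <- lines[(labStart[1] + 1L):length(lines)]
        labs <- unlist(strsplit(labLines, "[[:space:]]+"))
        labels <- labs[seq_len(nrow(pos))]
      } else labels <- paste0("E", seq_len(nrow(pos)))
    }
  }
  if (anyNA(pos)) stop("malformed coordinates in ", path)
  sp <- .splitFiducials(labels, pos, fiducialLabels)
  electrodeSet(sp$labels, sp$positions, sp$fiducials)
}

#' Fit a spherical head model to electrode positions
#'
#' Least-squares sphere through the electrode cloud (algebraic fit).
#' The scalp radius is the fitted radius; skull and brain radii are set
#' by fixed ratios, standing in for an MR-derived surface when none is
#' available.
#'
#' @param electrodes an [ElectrodeSet-class] (at least 4 non-coplanar positions).
#' @param skullRatio,brainRatio inner radii as fractions of the scalp radius.
#' @param conductivities brain/skull/scalp conductivities in S/m.
#' @return a [SphericalHeadModel-class]
#' @export
fitSphereToElectrodes <- function(electrodes, skullRatio = 0.92, brainRatio = 0.87,
                                  conductivities = c(0.33, 0.01, 0.43)) {
  P <- electrodes@positions
  if (nrow(P) < 4) stop("need at least 4 electrode positions for a sphere fit")
  A <- cbind(2 * P, 1)
  y <- rowSums(P^2)
  qrA <- qr(A)
  if (qrA$rank < 4) stop("degenerate sphere fit: electrode positions are coplanar")
  beta <- qr.coef(qrA, y)
  center <- beta[1:3]
  r <- sqrt(beta[4] + sum(center^2))
  if (!is.finite(r) || r <= 0) stop("degenerate sphere fit")
  sphericalHeadModel(center = center, scalpRadius = r,
                     skullRatio = skullRatio, brainRatio = brainRatio,
                     conductivities = conductivities)
}

# closed-form least-squares rigid transform (rotation + translation,
# no scaling) mapping rows of A onto rows of B (Kabsch)
.rigidFit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(A - matrix(ca, nrow(A), 3, byrow = TRUE)) %*%
       (B - matrix(cb, nrow(B), 3, byrow = TRUE))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t0 <- cb - as.numeric(R %*% ca)
  list(R = R, t = t0)
}

#' Co-register electrodes to a spherical head model
#'
#' A least-squares rigid-body transform (rotation + translation) over the
#' three fiducial landmarks maps the electrodes into model space; each
#' electrode is then orthogonally (radially) projected onto the scalp
#' sphere. For a sphere the radial projection plays the role that a
#' surface ICP refinement would play for a realistic scalp mesh.
#'
#' @param electrodes an [ElectrodeSet-class] with fiducials in electrode space.
#' @param model a [SphericalHeadModel-class].
#' @param modelFiducials optional `3 x 3` matrix (rows nz/lpa/rpa) of the
#'   landmark positions in model space. By default the electrode fiducials
#'   are assumed to already be in model coordinates (the common case after
#'   [fitSphereToElectrodes()]), i.e. the transform is fitted
#'   fiducials-to-fiducials and reduces to the identity.
#' @return the co-registered [ElectrodeSet-class]; every position satisfies
#'   `| ||p - center|| - r_scalp | < 1e-9` mm.
#' @export
coregisterElectrodes <- function(electrodes, model, modelFiducials = NULL) {
  fid <- electrodes@fiducials
  if (is.null(modelFiducials)) modelFiducials <- fid
  modelFiducials <- as.matrix(modelFiducials)
  if (!identical(dim(modelFiducials), c(3L, 3L)))
    stop("modelFiducials must be a 3 x 3 matrix")
  tr <- .rigidFit(fid, modelFiducials)
  P <- electrodes@positions %*% t(tr$R) +
    matrix(tr$t, nrow(electrodes@positions), 3, byrow = TRUE)
  Fd <- fid %*% t(tr$R) + matrix(tr$t, 3, 3, byrow = TRUE)
  rownames(Fd) <- rownames(fid)
  # radial projection onto the scalp sphere
  ctr <- model@center
  rs <- model@radii[3]
  D <- P - matrix(ctr, nrow(P), 3, byrow = TRUE)
  nr <- sqrt(rowSums(D^2))
  if (any(nr < 1e-9)) stop("cannot project: electrode at the sphere center")
  P <- matrix(ctr, nrow(P), 3, byrow = TRUE) + D * (rs / nr)
  electrodeSet(electrodes@labels, P, Fd, electrodes@referenceLabel)
}

#' Construct a three-shell spherical head model
#'
#' @param center sphere center in mm.
#' @param scalpRadius outer (scalp) radius in mm.
#' @param radii optional explicit radii `(brain, skull, scalp)` in mm,
#'   overriding the ratio construction.
#' @param skullRatio,brainRatio inner radii as fractions of `scalpRadius`.
#' @param conductivities `(brain, skull, scalp)` conductivities in S/m;
#'   defaults 0.33, 0.01, 0.43.
#' @return a [SphericalHeadModel-class]
#' @export
sphericalHeadModel <- function(center = c(0, 0, 0), scalpRadius = 94,
                               radii = NULL, skullRatio = 0.92, brainRatio = 0.87,
                               conductivities = c(0.33, 0.01, 0.43)) {
  if (is.null(radii))
    radii <- c(brainRatio * scalpRadius, skullRatio * scalpRadius, scalpRadius)
  names(radii) <- c("brain", "skull", "scalp")
  conductivities <- as.numeric(conductivities)
  names(conductivities) <- c("brain", "skull", "scalp")
  new("SphericalHeadModel", center = as.numeric(center), radii = radii,
      conductivities = conductivities)
}
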