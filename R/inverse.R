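# Source localization filters: eLORETA (default), MNE and sLORETA, plus
# ROI downsampling of the filter for region-wise streaming.

# dimensionless regularization: alpha scales the mean sensor variance of
# the model term, so the same alpha means the same relative damping
# regardless of leadfield units
.regScale <- function(M, nE) sum(diag(M)) / nE

#' Compute the source localization filter K
#'
#' `K = G^-1 %*% t(L) %*% pinv(L %*% G^-1 %*% t(L) + lambda * H)` with
#' per-voxel 3x3 weight blocks `G` depending on the method:
#' \describe{
#'   \item{eloreta}{weights from the fixed-point iteration
#'     `W_v = sqrtm(t(L_v) %*% M %*% L_v)` with
#'     `M = pinv(L G^-1 t(L) + lambda H)`, initialized at the identity and
#'     iterated to a relative block change below `tol`. Gives zero
#'     localization error for noiseless point sources.}
#'   \item{mne}{`G = I` (classical minimum-norm).}
#'   \item{sloreta}{`G = I`; the per-voxel resolution blocks
#'     `t(L_v) %*% M %*% L_v` are returned as standardization weights for
#'     [sourcePower()].}
#' }
#' `lambda = alpha * trace(L G^-1 t(L)) / n_E` makes `alpha`
#' dimensionless (default 0.05); `H` should be trace-normalized (see
#' [noiseCovariance()]).
#'
#' @param lf an average-referenced [Leadfield-class] (or plain gain matrix).
#' @param H noise covariance `[n_E x n_E]`.
#' @param alpha dimensionless Tikhonov regularization parameter (> 0).
#' @param method `"eloreta"` (default), `"mne"` or `"sloreta"`.
#' @param tol eLORETA convergence tolerance (default 1e-6).
#' @param maxIter eLORETA iteration cap (default 100).
#' @return list with `K` (`[3 n_V x n_E]`), `Gblocks`
#'   (`[3 x 3 x n_V]` weights; identity for MNE, standardization blocks
#'   for sLORETA), `method`, `alpha`, and `iterations`.
#' @export
inverseFilter <- function(lf, H, alpha = 0.05, method = c("eloreta", "mne", "sloreta"),
                          tol = 1e-6, maxIter = 100) {
  method <- match.arg(method)
  L <- if (is.matrix(lf)) lf else lf@gain
  nE <- nrow(L); nV <- ncol(L) / 3
  if (alpha <= 0) stop("alpha must be positive")
  if (nV != round(nV)) stop("leadfield must have 3 columns per voxel")
  nV <- as.integer(nV)
  vidx <- function(v) (3L * (v - 1L) + 1L):(3L * v)
  Gblocks <- array(0, dim = c(3, 3, nV))
  for (v in seq_len(nV)) Gblocks[, , v] <- diag(3)
  iterations <- 0L
  if (method == "eloreta") {
    for (it in seq_len(maxIter)) {
      # C = L G^-1 t(L): accumulate per voxel with the block inverses
      Cmat <- matrix(0, nE, nE)
      for (v in seq_len(nV)) {
        Lv <- L[, vidx(v), drop = FALSE]
        Cmat <- Cmat + Lv %*% symPinv(Gblocks[, , v]) %*% t(Lv)
      }
      lambda <- alpha * .regScale(Cmat, nE)
      M <- pinvTol(Cmat + lambda * H)
      newG <- array(0, dim = c(3, 3, nV))
      mxChange <- 0
      trsum <- 0
      for (v in seq_len(nV)) {
        Lv <- L[, vidx(v), drop = FALSE]
        Wv <- symSqrt(t(Lv) %*% M %*% Lv)
        newG[, , v] <- Wv
        trsum <- trsum + sum(diag(Wv))
      }
      newG <- newG * (3 * nV / trsum)        # scale-fix the weights
      for (v in seq_len(nV)) {
        num <- norm(newG[, , v] - Gblocks[, , v], "F")
        den <- max(norm(Gblocks[, , v], "F"), 1e-300)
        mxChange <- max(mxChange, num / den)
      }
      Gblocks <- newG
      iterations <- it
      if (mxChange < tol) break
    }
    if (iterations == maxIter)
      stop(sprintf("eLORETA weights did not converge in %d iterations", maxIter))
  }
  # final filter with the converged (or identity) weights
  Cmat <- matrix(0, nE, nE)
  Ginv <- array(0, dim = c(3, 3, nV))
  for (v in seq_len(nV)) {
    Ginv[, , v] <- symPinv(Gblocks[, , v])
    Lv <- L[, vidx(v), drop = FALSE]
    Cmat <- Cmat + Lv %*% Ginv[, , v] %*% t(Lv)
  }
  lambda <- alpha * .regScale(Cmat, nE)
  M <- pinvTol(Cmat + lambda * H)
  K <- matrix(0, 3L * nV, nE)
  for (v in seq_len(nV)) {
    Lv <- L[, vidx(v), drop = FALSE]
    K[vidx(v), ] <- Ginv[, , v] %*% t(Lv) %*% M
  }
  if (method == "sloreta") {
    for (v in seq_len(nV)) {
      Lv <- L[, vidx(v), drop = FALSE]
      Gblocks[, , v] <- t(Lv) %*% M %*% Lv   # resolution (standardization) blocks
    }
  }
  list(K = K, Gblocks = Gblocks, method = method, alpha = alpha,
       iterations = iterations)
}

#' Per-voxel source power of a localized sample or segment
#'
#' For eLORETA and MNE the power of voxel `v` is `sum(B_v^2)` over the
#' three directions; for sLORETA it is the standardized power
#' `t(B_v) %*% pinv(S_v) %*% B_v` with the stored resolution blocks.
#'
#' @param B localized vector `[3 n_V]` or matrix `[3 n_V x n_T]`.
#' @param Gblocks standardization blocks (only used for sLORETA).
#' @param method inverse method name.
#' @return numeric vector of per-voxel power (time-averaged for matrices).
#' @export
sourcePower <- function(B, Gblocks = NULL, method = "eloreta") {
  B <- as.matrix(B)
  nV <- nrow(B) / 3
  pw <- numeric(nV)
  for (v in seq_len(nV)) {
    Bv <- B[(3 * (v - 1) + 1):(3 * v), , drop = FALSE]
    if (identical(method, "sloreta") && !is.null(Gblocks)) {
      Sv <- symPinv(Gblocks[, , v])
      pw[v] <- mean(colSums(Bv * (Sv %*% Bv)))
    } else {
      pw[v] <- mean(colSums(Bv^2))
    }
  }
  pw
}

#' Downsample a localization filter to spherical ROIs
#'
#' For each ROI (center + radius, mm) the grid voxels inside the sphere
#' are found; the representative voxel is the one nearest the ROI center
#' (`mode = "nearest"`, default) or the rows are averaged over all
#' in-ROI voxels (`mode = "average"`). The three dipole directions are
#' kept separate, so the result has `3 * n_R` rows.
#'
#' @param K localization filter `[3 n_V x n_E]`.
#' @param grid the [SourceGrid-class] the rows of `K` refer to.
#' @param rois data.frame with columns `name`, `x`, `y`, `z`, `radius`
#'   (mm); radius defaults to 6 mm when absent.
#' @param mode `"nearest"` or `"average"`.
#' @return list with `K` (`[3 n_R x n_E]`), `roiNames`, and `voxel`
#'   (chosen representative voxel index per ROI, `NA` for averages).
#' @export
downsampleToROIs <- function(K, grid, rois, mode = c("nearest", "average")) {
  mode <- match.arg(mode)
  if (is.null(rois$radius)) rois$radius <- 6
  if (is.null(rois$name)) rois$name <- paste0("roi", seq_len(nrow(rois)))
  P <- grid@positions
  out <- matrix(0, 3L * nrow(rois), ncol(K))
  repVox <- rep(NA_integer_, nrow(rois))
  for (i in seq_len(nrow(rois))) {
    ctr <- c(rois$x[i], rois$y[i], rois$z[i])
    d <- sqrt(colSums((t(P) - ctr)^2))
    inside <- which(d <= rois$radius[i])
    if (!length(inside))
      stop("ROI '", rois$name[i], "' contains no grid voxel")
    rows <- function(v) (3L * (v - 1L) + 1L):(3L * v)
    if (mode == "nearest") {
      v <- inside[which.min(d[inside])]
      repVox[i] <- v
      out[rows(i), ] <- K[rows(v), , drop = FALSE]
    } else {
      acc <- matrix(0, 3, ncol(K))
      for (v in inside) acc <- acc + K[rows(v), , drop = FALSE]
      out[rows(i), ] <- acc / length(inside)
    }
  }
  list(K = out, roiNames = rois$name, voxel = repVox)
}
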