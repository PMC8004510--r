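# The static artifact attenuation filter F0 and the noise covariance H
# estimated from the cleaned calibration data.

#' Build the artifact attenuation filter F0
#'
#' Regresses the calibration data onto the artifactual component time
#' courses and removes the fitted contribution:
#' `F0 = I - X %*% t(S_A) %*% solve(S_A %*% t(S_A)) %*% W_A`
#' with `S_A = W_A %*% X`. By construction `W_A %*% F0 %*% X = 0` on the
#' calibration data. When `S_A %*% t(S_A)` has condition number above
#' `condMax`, a relative ridge (`1e-8 * trace / n_A`) is added and noted.
#'
#' @param rec the filtered, repaired, re-referenced calibration
#'   [EEGRecording-class] (or plain matrix) the ICA was fitted on.
#' @param ica an [ICADecomposition-class] with artifact flags set; with
#'   no flagged component `F0` is the identity (with a warning).
#' @param condMax ridge trigger on the condition number (default 1e12).
#' @return numeric `[n_E x n_E]` filter matrix.
#' @export
artifactFilter <- function(rec, ica, condMax = 1e12) {
  X <- if (is.matrix(rec)) rec else eegData(rec)
  nE <- nrow(X)
  WA <- artifactUnmixing(ica)
  if (!nrow(WA)) {
    warning("no artifactual components flagged: F0 is the identity")
    return(diag(nE))
  }
  SA <- WA %*% X
  G <- SA %*% t(SA)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > condMax) {
    message("artifact regression ill-conditioned: ridge added")
    G <- G + diag(1e-8 * sum(diag(G)) / nrow(WA), nrow(WA))
  }
  diag(nE) - X %*% t(SA) %*% solve(G) %*% WA
}

#' Estimate the noise covariance from cleaned calibration data
#'
#' Sample covariance of the artifact-attenuated calibration recording,
#' symmetrized, projected into average-reference space (`R %*% H %*% R`)
#' and trace-normalized to `n_E`. With fewer samples than channels a
#' diagonal shrinkage (`1e-3 * trace / n_E`) is applied before
#' projection.
#'
#' @param rec cleaned calibration [EEGRecording-class] or matrix
#'   `[n_E x n_T]`.
#' @return symmetric positive-semidefinite `[n_E x n_E]` matrix with
#'   `sum(diag(H)) == n_E`.
#' @export
noiseCovariance <- function(rec) {
  X <- if (is.matrix(rec)) rec else eegData(rec)
  nE <- nrow(X); TT <- ncol(X)
  Xc <- X - rowMeans(X)
  H <- (Xc %*% t(Xc)) / max(TT - 1, 1)
  H <- (H + t(H)) / 2
  if (TT < nE) {
    message("fewer samples than channels: diagonal shrinkage applied to H")
    H <- H + diag(1e-3 * sum(diag(H)) / nE, nE)
  }
  R <- referenceMatrix(nE)
  H <- R %*% H %*% R
  H <- (H + t(H)) / 2
  tr <- sum(diag(H))
  if (tr <= 0) stop("noise covariance has zero trace")
  H * (nE / tr)
}
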