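# Deflation FastICA with the hyperbolic-tangent contrast, the
# decomposition stage of spatial-filter calibration.

#' FastICA decomposition of a calibration recording
#'
#' Fixed-point ICA in deflation mode with the `tanh` contrast.
#' Channels are centered and whitened by eigendecomposition of the
#' sample covariance; the number of retained components defaults to the
#' effective rank of the data (relative eigenvalue cutoff 1e-8), which
#' for an average-referenced, bad-channel-repaired recording is
#' `n_E - |bad| - 1`. The extraction is deterministic given `seed`:
#' initial vectors are drawn from the seeded RNG, and each component's
#' sign is fixed so its largest-magnitude unmixing weight is positive.
#'
#' @param rec an [EEGRecording-class] (EEG rows are decomposed) or a
#'   numeric matrix `[n_E x n_T]`.
#' @param nComponents number of components, `NULL` for the effective rank.
#' @param seed RNG seed (default 1).
#' @param maxIter fixed-point iteration cap per component (default 500).
#' @param tol convergence tolerance on the weight update (default 1e-6).
#' @return an [ICADecomposition-class]; `S = W %*% X` has unit-variance rows.
#' @export
fitICA <- function(rec, nComponents = NULL, seed = 1, maxIter = 500, tol = 1e-6) {
  X <- if (is.matrix(rec)) rec else eegData(rec)
  n <- nrow(X); TT <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  Cv <- (Xc %*% t(Xc)) / TT
  e <- eigen((Cv + t(Cv)) / 2, symmetric = TRUE)
  rank <- sum(e$values > 1e-8 * max(e$values))
  nS <- if (is.null(nComponents)) rank else min(nComponents, rank)
  if (nS < 1) stop("input has no signal variance to decompose")
  Ew <- e$vectors[, seq_len(nS), drop = FALSE]
  dw <- e$values[seq_len(nS)]
  Kw <- t(Ew) / sqrt(dw)            # whitening: Z = Kw %*% Xc, unit covariance
  Z <- Kw %*% Xc
  Wh <- matrix(0, nS, nS)           # unmixing in whitened space (orthonormal rows)
  converged <- logical(nS)
  withSeed(seed, {
    for (i in seq_len(nS)) {
      w <- stats::rnorm(nS)
      w <- w / vnorm(w)
      if (i > 1) {
        prev <- Wh[seq_len(i - 1), , drop = FALSE]
        w <- w - as.numeric(t(prev) %*% (prev %*% w))
        w <- w / vnorm(w)
      }
      for (it in seq_len(maxIter)) {
        wz <- as.numeric(w %*% Z)
        g <- tanh(wz)
        gp <- 1 - g^2
        wNew <- as.numeric(Z %*% g) / TT - mean(gp) * w
        if (i > 1) {
          prev <- Wh[seq_len(i - 1), , drop = FALSE]
          wNew <- wNew - as.numeric(t(prev) %*% (prev %*% wNew))
        }
        nrm <- vnorm(wNew)
        if (nrm < 1e-12) { wNew <- w; break }
        wNew <- wNew / nrm
        delta <- abs(abs(sum(wNew * w)) - 1)
        w <- wNew
        if (delta < tol) { converged[i] <- TRUE; break }
      }
      Wh[i, ] <- w
    }
  })
  if (!all(converged))
    warning(sprintf("FastICA: %d of %d components hit the iteration cap",
                    sum(!converged), nS))
  W <- Wh %*% Kw                    # [nS x n]
  # deterministic sign: largest |weight| positive
  for (i in seq_len(nS)) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) { W[i, ] <- -W[i, ]; Wh[i, ] <- -Wh[i, ] }
  }
  A <- Ew %*% (sqrt(dw) * t(Wh))    # pinv(W) restricted to the signal subspace
  S <- W %*% Xc
  new("ICADecomposition", A = A, W = W, S = S,
      artifactIndices = integer(0), converged = converged)
}
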