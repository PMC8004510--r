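# internal numerical helpers

# Moore-Penrose pseudoinverse with relative singular-value cutoff.
# Average referencing forces rank n_E - 1, so a tolerant pinv is used
# throughout the inverse-operator algebra.
pinvTol <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# symmetric PSD square root of a small matrix (eigendecomposition,
# negative eigenvalues clamped to zero)
symSqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

# inverse of a symmetric PSD matrix through its eigendecomposition,
# with relative cutoff (used for the 3x3 eLORETA weight blocks)
symPinv <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  mx <- max(abs(e$values), 1e-300)
  d <- ifelse(e$values > tol * mx, 1 / e$values, 0)
  e$vectors %*% (d * t(e$vectors))
}

# moving average (width in samples) applied along a vector or the rows
# of a matrix; sides = 2 is centered, sides = 1 causal (trailing
# window); ends use the partial window
movingAverage <- function(x, width, sides = 2) {
  width <- max(1L, as.integer(round(width)))
  if (width == 1L) return(x)
  k <- rep(1, width)
  smooth1 <- function(v) {
    num <- stats::filter(v, k, sides = sides)
    cnt <- stats::filter(rep(1, length(v)), k, sides = sides)
    out <- as.numeric(num / cnt)
    n <- length(v)
    half <- width %/% 2
    for (i in which(is.na(out))) {
      if (sides == 2) { lo <- max(1, i - half); hi <- min(n, i + half) }
      else { lo <- max(1, i - width + 1L); hi <- i }
      out[i] <- mean(v[lo:hi])
    }
    out
  }
  if (is.matrix(x)) t(apply(x, 1, smooth1)) else smooth1(x)
}

# Welch power spectral density estimate (Hann window, 50% overlap).
# Returns list(freq, psd).
welchPSD <- function(x, fs, windowSec = 2, overlap = 0.5) {
  n <- length(x)
  nw <- min(n, max(8L, as.integer(round(windowSec * fs))))
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  u <- sum(w^2)
  nf <- nw %/% 2 + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided scaling (all bins but DC/Nyquist counted twice)
  if (nf > 2) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = (seq_len(nf) - 1) * fs / nw, psd = psd)
}

# seeded RNG scope: evaluates expr with a local, restored RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v^2))
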