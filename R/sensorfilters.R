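# Sensor-space spatial filters: bad-channel repair C, average reference
# R, their application, and the zero-phase band-pass.

#' Average-reference matrix
#'
#' `R = I - (1/n_E) * 11'`: a symmetric, idempotent projector removing
#' the instantaneous channel mean (`r_ii = (n_E - 1)/n_E`,
#' `r_ij = -1/n_E`).
#'
#' @param nE number of EEG channels (>= 2).
#' @return numeric `[n_E x n_E]` matrix.
#' @export
referenceMatrix <- function(nE) {
  if (nE < 2) stop("average referencing needs at least 2 channels")
  diag(nE) - matrix(1 / nE, nE, nE)
}

#' Channel adjacency from electrode geometry
#'
#' `d_ij = 1` when electrodes `i` and `j` are within `threshold` mm of
#' each other, `i != j`, and the donor channel `j` is not marked bad:
#' bad channels never serve as donors (their columns are zero, and no
#' good row links to them), but their own rows keep the links to good
#' neighbours so that the repair matrix can be formed. A bad channel
#' whose row is all zero has no usable neighbour.
#'
#' @param electrodes co-registered [ElectrodeSet-class].
#' @param bad character or integer vector of bad channels.
#' @param threshold neighbour distance in mm (default 40).
#' @return binary `[n_E x n_E]` matrix; bad channels have zero columns.
#' @export
buildAdjacency <- function(electrodes, bad = character(0), threshold = 40) {
  P <- electrodes@positions
  n <- nrow(P)
  D2 <- as.matrix(stats::dist(P))
  A <- (D2 <= threshold) * 1
  diag(A) <- 0
  badIdx <- if (is.character(bad)) match(bad, electrodes@labels) else as.integer(bad)
  badIdx <- badIdx[!is.na(badIdx)]
  A[, badIdx] <- 0
  dimnames(A) <- list(electrodes@labels, electrodes@labels)
  A
}

#' Bad-channel correction matrix
#'
#' Rows for good channels are canonical unit rows; the row of each bad
#' channel averages its good neighbours (`c_ij = d_ij / sum_j d_ij`), so
#' repaired signals are convex combinations of neighbouring channels.
#'
#' @param adjacency binary adjacency matrix from [buildAdjacency()]
#'   (built with the same bad-channel list).
#' @param bad character or integer vector of bad channels.
#' @return numeric `[n_E x n_E]` correction matrix `C`.
#' @export
correctionMatrix <- function(adjacency, bad = character(0)) {
  n <- nrow(adjacency)
  labs <- rownames(adjacency)
  badIdx <- if (is.character(bad)) match(bad, labs) else as.integer(bad)
  badIdx <- badIdx[!is.na(badIdx)]
  C <- diag(n)
  for (i in badIdx) {
    s <- sum(adjacency[i, ])
    if (s == 0) {
      nm <- if (!is.null(labs)) labs[i] else as.character(i)
      stop("bad channel '", nm, "' has no good neighbour to repair from")
    }
    C[i, ] <- adjacency[i, ] / s
  }
  dimnames(C) <- dimnames(adjacency)
  C
}

#' Apply sensor-space filters to a recording
#'
#' Computes `X_q = C %*% R %*% X` on the EEG rows (average reference
#' first, then bad-channel repair, in that composition order); auxiliary
#' channels pass through untouched.
#'
#' @param rec an [EEGRecording-class].
#' @param C bad-channel correction matrix.
#' @param R average-reference matrix.
#' @return the filtered [EEGRecording-class].
#' @export
applySensorFilters <- function(rec, C, R) {
  rows <- eegRows(rec)
  nE <- length(rows)
  if (!identical(dim(C), c(nE, nE)) || !identical(dim(R), c(nE, nE)))
    stop("filter dimensions do not match the EEG channel count")
  if (!is.null(rownames(C)) && !all(rownames(C) == rec@labels[rows]))
    stop("label order mismatch between correction matrix and recording")
  out <- rec@data
  out[rows, ] <- C %*% R %*% rec@data[rows, , drop = FALSE]
  new("EEGRecording", data = out, labels = rec@labels,
      samplingRate = rec@samplingRate, auxMap = rec@auxMap, band = rec@band)
}

# factor a zero/pole/gain design into second-order sections
# ([k x 6] rows of b0 b1 b2 a0 a1 a2, a0 = 1); direct high-order
# transfer functions are ill-conditioned for narrow normalized bands
.zp2sos <- function(zpg) {
  pairUp <- function(x) {
    used <- rep(FALSE, length(x))
    out <- list()
    for (i in seq_along(x)) {
      if (used[i]) next
      used[i] <- TRUE
      j <- NA_integer_
      if (abs(Im(x[i])) > 1e-9) {
        cand <- which(!used & abs(x - Conj(x[i])) < 1e-6)
        j <- if (length(cand)) cand[1] else NA_integer_
      } else {
        cand <- which(!used & abs(Im(x)) <= 1e-9)
        j <- if (length(cand)) cand[1] else NA_integer_
      }
      if (!is.na(j)) used[j] <- TRUE
      out[[length(out) + 1L]] <- if (is.na(j)) x[i] else c(x[i], x[j])
    }
    out
  }
  zz <- pairUp(zpg$zero)
  pp <- pairUp(zpg$pole)
  k <- length(pp)
  poly2 <- function(r) {
    if (length(r) == 1) Re(c(1, -r, 0)) else Re(c(1, -(r[1] + r[2]), r[1] * r[2]))
  }
  g <- Re(zpg$gain)
  gsec <- abs(g)^(1 / k) * ifelse(g < 0, NA, 1)
  if (is.na(gsec)) stop("negative section gain not supported")
  sos <- matrix(0, k, 6)
  for (i in seq_len(k)) {
    zi <- if (i <= length(zz)) zz[[i]] else complex(real = 0)
    sos[i, ] <- c(gsec * poly2(zi), poly2(pp[[i]]))
  }
  sos
}

# Butterworth band edges -> cascade of high-pass and low-pass sections,
# each represented as second-order sections and applied
# forward-backward (zero phase).
designBandpass <- function(band, fs, order = 4) {
  ny <- fs / 2
  low <- band[1]; high <- band[2]
  if (low < 0 || low >= ny) stop("band edge outside (0, Nyquist)")
  if (high <= low) stop("band must satisfy low < high")
  if (high > ny) stop("upper band edge beyond Nyquist")
  useHp <- low > 0
  useLp <- high < 0.99 * ny
  des <- list(useHp = useHp, useLp = useLp,
              sosHp = matrix(0, 0, 6), sosLp = matrix(0, 0, 6))
  if (useHp)
    des$sosHp <- .zp2sos(signal::as.Zpg(signal::butter(order, low / ny, type = "high")))
  if (useLp)
    des$sosLp <- .zp2sos(signal::as.Zpg(signal::butter(order, high / ny, type = "low")))
  if (!useHp && !useLp) stop("band covers the whole spectrum; nothing to filter")
  des
}

# zero-phase cascade of second-order sections along matrix rows
sosFiltfilt <- function(sos, X) {
  for (i in seq_len(nrow(sos)))
    X <- cpp_filtfilt_mat(sos[i, 1:3], sos[i, 4:6], X)
  X
}

#' Zero-phase band-pass filter
#'
#' Cascaded 4th-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase) to every channel. A `high` edge at or
#' above 99% of Nyquist drops the low-pass section (the band is then a
#' pure high-pass). Auxiliary channels are filtered as well unless
#' `auxPassthrough = TRUE`.
#'
#' @param rec an [EEGRecording-class] (or a plain numeric matrix with
#'   rows as channels, in which case `fs` must be given).
#' @param band numeric length-2 `(low, high)` in Hz.
#' @param fs sampling rate, only for matrix input.
#' @param auxPassthrough leave auxiliary rows untouched (default `FALSE`).
#' @return filtered object of the same kind; recordings are tagged with
#'   the band.
#' @export
bandpassFilter <- function(rec, band, fs = NULL, auxPassthrough = FALSE) {
  if (is.matrix(rec)) {
    if (is.null(fs)) stop("fs required for matrix input")
    des <- designBandpass(band, fs)
    X <- rec
    if (des$useHp) X <- sosFiltfilt(des$sosHp, X)
    if (des$useLp) X <- sosFiltfilt(des$sosLp, X)
    return(X)
  }
  des <- designBandpass(band, rec@samplingRate)
  rows <- if (auxPassthrough) eegRows(rec) else seq_len(nrow(rec@data))
  X <- rec@data
  sub <- X[rows, , drop = FALSE]
  if (des$useHp) sub <- sosFiltfilt(des$sosHp, sub)
  if (des$useLp) sub <- sosFiltfilt(des$sosLp, sub)
  X[rows, ] <- sub
  new("EEGRecording", data = X, labels = rec@labels,
      samplingRate = rec@samplingRate, auxMap = rec@auxMap, band = as.numeric(band))
}
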