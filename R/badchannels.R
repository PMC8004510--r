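# Automated bad-channel detection combining an in-band correlation
# parameter with a high-frequency noise-variance parameter.

#' Detect channels with low signal quality
#'
#' Two per-channel parameters are screened for outliers at four robust
#' standard deviations: (1) the minimum Pearson correlation of the
#' band-filtered signal against every other channel, flagged when it
#' falls below `mean - 4 sd` of the channel distribution (low correlation
#' marks a bad channel); and (2) the noise variance in the 200-250 Hz
#' band, where genuine EEG is negligible, flagged above `mean + 4 sd`.
#' The noise parameter requires a sampling rate of at least 500 Hz and is
#' skipped (with a message) otherwise. A constant (flat) channel has an
#' undefined correlation; it is assigned the sentinel -1 and excluded
#' from the outlier statistics of the correlation parameter.
#'
#' @param rec an [EEGRecording-class] (EEG rows are screened; auxiliaries
#'   ignored).
#' @param band analysis band in Hz for the correlation parameter.
#' @param nSD outlier threshold in standard deviations (default 4).
#' @return a list with elements `bad` (labels), `minCorrelation`,
#'   `noiseVariance` (per-channel vectors, `NA` when skipped), and the
#'   outlier statistics `stats` (`m` and `s` per parameter).
#' @export
detectBadChannels <- function(rec, band = c(1, 45), nSD = 4) {
  rows <- eegRows(rec)
  if (length(rows) < 3) stop("bad-channel detection needs at least 3 EEG channels")
  labs <- rec@labels[rows]
  X <- rec@data[rows, , drop = FALSE]
  fs <- rec@samplingRate
  Xb <- bandpassFilter(X, band, fs = fs)
  flat <- apply(X, 1, stats::sd) < 1e-12     # judged on the raw signal
  minCorr <- rep(NA_real_, length(rows))
  cm <- suppressWarnings(stats::cor(t(Xb)))
  diag(cm) <- NA
  minCorr <- apply(cm, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) NA_real_ else min(r)
  })
  minCorr[flat] <- -1          # degenerate-correlation sentinel
  usable <- is.finite(minCorr) & !flat
  mC <- mean(minCorr[usable]); sC <- stats::sd(minCorr[usable])
  badCorr <- minCorr < mC - nSD * sC
  badCorr[is.na(badCorr)] <- FALSE
  badCorr[flat] <- TRUE
  noiseVar <- rep(NA_real_, length(rows))
  badVar <- rep(FALSE, length(rows))
  mV <- sV <- NA_real_
  if (fs >= 500) {
    Xn <- bandpassFilter(X, c(200, 250), fs = fs)
    noiseVar <- apply(Xn, 1, stats::var)
    mV <- mean(noiseVar, na.rm = TRUE); sV <- stats::sd(noiseVar, na.rm = TRUE)
    badVar <- noiseVar > mV + nSD * sV
    badVar[is.na(badVar)] <- FALSE
  } else {
    message("sampling rate below 500 Hz: 200-250 Hz noise-variance parameter skipped")
  }
  bad <- labs[badCorr | badVar]
  list(bad = bad,
       minCorrelation = stats::setNames(minCorr, labs),
       noiseVariance = stats::setNames(noiseVar, labs),
       stats = list(correlation = c(m = mC, s = sC),
                    noise = c(m = mV, s = sV)))
}
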