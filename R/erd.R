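# Validation analytics: movement-onset detection, epoching, band power
# and event-related desynchronization (ERD/ERS).

#' Detect movement onsets from an EMG channel
#'
#' Rectified EMG smoothed with a causal (trailing) 200 ms moving
#' average, thresholded at a robust baseline level, with a refractory
#' period between onsets. The baseline statistics are taken over the
#' below-median half of the envelope (the rest-dominated part for duty
#' cycles up to 50 percent; the truncated standard deviation is
#' rescaled to the full-width equivalent), because whole-signal
#' statistics misplace the threshold when movement occupies half the
#' record. A crossing only counts as an onset when the envelope stays
#' above threshold for `minDurSec` (bursts are sustained; noise
#' excursions are not), and each confirmed crossing is backdated to
#' where the envelope first left the baseline band (double-threshold
#' onset localization). Deterministic.
#'
#' @param emg numeric EMG signal.
#' @param fs sampling rate in Hz.
#' @param smoothSec envelope smoothing window (default 0.2 s).
#' @param nSD threshold in robust SDs above baseline (default 3).
#' @param minDurSec minimum supra-threshold duration to confirm a burst
#'   (default 0.2 s).
#' @param refractorySec minimum onset separation (default 3 s).
#' @return integer vector of onset sample indices (empty, with a
#'   warning, when nothing crosses the threshold).
#' @export
detectOnsets <- function(emg, fs, smoothSec = 0.2, nSD = 3, minDurSec = 0.2,
                         refractorySec = 3) {
  if (anyNA(emg)) stop("EMG signal contains missing values")
  env <- movingAverage(abs(emg), smoothSec * fs, sides = 1)
  base <- env[env <= stats::median(env)]
  # sd of the below-median half, rescaled to the full-width equivalent
  # (a normal truncated at its median has sd 0.6028 of the original)
  sdBase <- stats::sd(base) / 0.6028
  thr <- mean(base) + nSD * sdBase
  if (!is.finite(thr)) thr <- Inf
  above <- env > thr
  if (!any(above)) {
    warning("no EMG threshold crossings: returning no onsets")
    return(integer(0))
  }
  crossings <- which(diff(c(FALSE, above)) == 1)
  md <- max(1L, round(minDurSec * fs))
  n <- length(env)
  # a burst must stay above threshold for minDurSec; then backdate the
  # confirmed crossing to where the envelope first left the baseline
  # band (double-threshold onset localization: the high threshold
  # confirms, the low one dates)
  low <- mean(base) + sdBase
  onsets <- integer(0)
  last <- -Inf
  for (cx in crossings) {
    hi <- min(n, cx + md - 1L)
    if (!all(env[cx:hi] > thr)) next
    o <- cx
    while (o > 1 && env[o - 1] > low) o <- o - 1L
    if (o - last >= refractorySec * fs) {
      onsets <- c(onsets, o)
      last <- o
    }
  }
  if (!length(onsets)) warning("no sustained EMG bursts found")
  as.integer(onsets)
}

#' Epoch signals around onsets
#'
#' Cuts one epoch per onset spanning the baseline start to the task end;
#' onsets whose epoch would leave the record are dropped with a message.
#'
#' @param signals numeric matrix `[n_signal x n_samples]`.
#' @param onsets onset sample indices.
#' @param fs sampling rate in Hz.
#' @param baselineWindow seconds relative to onset (default `c(-1, 0)`).
#' @param taskWindow seconds relative to onset (default `c(0, 2)`).
#' @return a [TrialSet-class]
#' @export
epochTrials <- function(signals, onsets, fs, baselineWindow = c(-1, 0),
                        taskWindow = c(0, 2)) {
  if (!length(onsets)) stop("no onsets to epoch around")
  signals <- as.matrix(signals)
  lo <- round(baselineWindow[1] * fs)
  hi <- round(taskWindow[2] * fs)
  keep <- onsets + lo >= 1 & onsets + hi <= ncol(signals)
  if (any(!keep)) message(sum(!keep), " trial(s) dropped: epoch outside the record")
  onsets <- onsets[keep]
  if (!length(onsets)) stop("no usable trials after bounds check")
  nt <- hi - lo + 1L
  ep <- array(0, dim = c(nrow(signals), nt, length(onsets)))
  for (k in seq_along(onsets))
    ep[, , k] <- signals[, (onsets[k] + lo):(onsets[k] + hi), drop = FALSE]
  new("TrialSet", epochs = ep, onsets = as.integer(onsets),
      times = (seq_len(nt) - 1L + lo) / fs, samplingRate = fs,
      baselineWindow = baselineWindow, taskWindow = taskWindow)
}

#' Band-power envelope of a signal
#'
#' Zero-phase band-pass, squaring, and moving-average smoothing
#' (default 250 ms): a nonnegative power time course at the signal's
#' resolution. For a unit-amplitude in-band sinusoid the mean power is
#' 1/2.
#'
#' @param x numeric vector or matrix (rows are signals).
#' @param band numeric length-2 in Hz.
#' @param fs sampling rate in Hz.
#' @param smoothSec smoothing window in seconds (default 0.25).
#' @return power envelope, same shape as `x`.
#' @export
bandPower <- function(x, band, fs, smoothSec = 0.25) {
  M <- if (is.matrix(x)) x else matrix(x, 1)
  Mf <- bandpassFilter(M, band, fs = fs)
  pw <- movingAverage(Mf^2, smoothSec * fs)
  if (is.matrix(x)) pw else as.numeric(pw)
}

.windowCols <- function(times, win) which(times >= win[1] & times <= win[2])

#' Compute ERD/ERS from epoched trials
#'
#' Relative band-power change
#' `ERD = 100 * (P - P_b) / P_b` where `P` is the power in the task
#' window and `P_b` the time-average power in the baseline window.
#' In `"map"` mode the result is one percentage per signal row (per
#' trial, or pooled across trials); signals with zero baseline power
#' are `NA` and flagged rather than silently zeroed. The across-trial
#' map divides pooled task power by pooled baseline power (ratio of
#' means): averaging per-trial ratios instead would inherit the
#' small-sample bias of dividing by a noisy single-trial baseline.
#'
#' @param trials a [TrialSet-class] (rows of `epochs` are signals:
#'   channels, voxels or ROIs; for 3-direction source signals collapse
#'   first, see [collapseOrientations()]).
#' @param band numeric length-2 in Hz (e.g. `c(13, 30)` for beta).
#' @param average average across trials (default `TRUE`); otherwise a
#'   list of per-trial maps is returned.
#' @param smoothSec power smoothing (default 0.25 s).
#' @return an [ERDMap-class], or a list of them when `average = FALSE`.
#' @export
computeERD <- function(trials, band, average = TRUE, smoothSec = 0.25) {
  d <- dim(trials@epochs)
  fs <- trials@samplingRate
  baseCols <- .windowCols(trials@times, trials@baselineWindow)
  taskCols <- .windowCols(trials@times, trials@taskWindow)
  perTrial <- matrix(NA_real_, d[1], d[3])
  basePow <- taskPow <- matrix(NA_real_, d[1], d[3])
  for (k in seq_len(d[3])) {
    pw <- bandPower(trials@epochs[, , k, drop = TRUE], band, fs, smoothSec)
    pw <- matrix(pw, d[1], d[2])
    Pb <- rowMeans(pw[, baseCols, drop = FALSE])
    Pt <- rowMeans(pw[, taskCols, drop = FALSE])
    basePow[, k] <- Pb; taskPow[, k] <- Pt
    erd <- 100 * (Pt - Pb) / Pb
    erd[Pb <= 0] <- NA_real_
    perTrial[, k] <- erd
  }
  mk <- function(vals, id) new("ERDMap", values = as.numeric(vals),
                               undefined = !is.finite(vals),
                               band = as.numeric(band), trial = id)
  if (average) {
    erd <- 100 * (rowMeans(taskPow) - rowMeans(basePow)) / rowMeans(basePow)
    erd[rowMeans(basePow) <= 0] <- NA_real_
    mk(erd, "average")
  } else lapply(seq_len(d[3]), function(k) mk(perTrial[, k], as.character(k)))
}

#' ERD from trials that already hold power envelopes
#'
#' Same relative-change definition as [computeERD()], but for a
#' [TrialSet-class] whose epoch rows are power time courses (e.g.
#' per-voxel envelopes from [collapseOrientations()] epoched
#' afterwards), so no further band-pass or squaring is applied.
#'
#' @param trials a [TrialSet-class] of power signals.
#' @param average pool across trials (ratio of mean powers, default
#'   `TRUE`); otherwise per-trial maps.
#' @return an [ERDMap-class], or a list of per-trial maps.
#' @export
computeERDFromPower <- function(trials, average = TRUE) {
  d <- dim(trials@epochs)
  baseCols <- .windowCols(trials@times, trials@baselineWindow)
  taskCols <- .windowCols(trials@times, trials@taskWindow)
  perTrial <- matrix(NA_real_, d[1], d[3])
  basePow <- taskPow <- matrix(NA_real_, d[1], d[3])
  for (k in seq_len(d[3])) {
    pw <- matrix(trials@epochs[, , k], d[1], d[2])
    Pb <- rowMeans(pw[, baseCols, drop = FALSE])
    Pt <- rowMeans(pw[, taskCols, drop = FALSE])
    basePow[, k] <- Pb; taskPow[, k] <- Pt
    erd <- 100 * (Pt - Pb) / Pb
    erd[Pb <= 0] <- NA_real_
    perTrial[, k] <- erd
  }
  mk <- function(vals, id) new("ERDMap", values = as.numeric(vals),
                               undefined = !is.finite(vals),
                               band = numeric(2), trial = id)
  if (average) {
    erd <- 100 * (rowMeans(taskPow) - rowMeans(basePow)) / rowMeans(basePow)
    erd[rowMeans(basePow) <= 0] <- NA_real_
    mk(erd, "average")
  } else lapply(seq_len(d[3]), function(k) mk(perTrial[, k], as.character(k)))
}

#' Collapse 3-direction source epochs to per-voxel power signals
#'
#' Sums the power envelopes of the three dipole directions of each
#' voxel; use before [computeERD()] on source-space trials.
#'
#' @param B matrix `[3 n_V x n_samples]` of source signals.
#' @param band,fs,smoothSec band-power parameters (see [bandPower()]).
#' @return matrix `[n_V x n_samples]` of per-voxel power envelopes.
#' @export
collapseOrientations <- function(B, band, fs, smoothSec = 0.25) {
  pw <- bandPower(B, band, fs, smoothSec)
  nV <- nrow(B) / 3
  out <- matrix(0, nV, ncol(B))
  for (d in 1:3) out <- out + pw[seq(d, 3 * nV, by = 3), , drop = FALSE]
  out
}

#' Time-frequency ERD profile for one region
#'
#' Short-time band power on a grid of frequency bins (default 2 Hz wide)
#' and time bins, averaged across trials and expressed relative to the
#' baseline-window mean of each frequency row, as percent change.
#' Baseline columns therefore average to zero by construction.
#'
#' @param trials a [TrialSet-class] whose epochs hold one signal row
#'   (or the row index given by `row`).
#' @param freqRange analysis range in Hz (default `c(2, 40)`).
#' @param binHz frequency bin width (default 2).
#' @param row signal row to analyze (default 1).
#' @param roi region name for labelling.
#' @param smoothSec power smoothing (default 0.25 s).
#' @return an [ERDTimeFrequency-class]
#' @export
erdTimeFrequency <- function(trials, freqRange = c(2, 40), binHz = 2, row = 1L,
                             roi = "roi", smoothSec = 0.25) {
  fs <- trials@samplingRate
  ny <- fs / 2
  lo <- seq(freqRange[1], min(freqRange[2], 0.95 * ny) - binHz, by = binHz)
  d <- dim(trials@epochs)
  baseCols <- .windowCols(trials@times, trials@baselineWindow)
  acc <- matrix(0, length(lo), d[2])
  for (k in seq_len(d[3])) {
    x <- trials@epochs[row, , k]
    for (f in seq_along(lo)) {
      acc[f, ] <- acc[f, ] + bandPower(x, c(lo[f], lo[f] + binHz), fs, smoothSec)
    }
  }
  acc <- acc / d[3]
  base <- rowMeans(acc[, baseCols, drop = FALSE])
  vals <- 100 * (acc - base) / base
  vals[base <= 0, ] <- NA_real_
  new("ERDTimeFrequency", values = vals, freqs = lo + binHz / 2,
      times = trials@times, roi = roi)
}

#' Mean pairwise spatial correlation of ERD maps
#'
#' Pearson correlation over map entries for every pair of maps,
#' averaged; undefined entries are excluded pairwise, and pairs with a
#' constant map are dropped with a message.
#'
#' @param maps list of [ERDMap-class] objects (or numeric vectors) on
#'   the same grid.
#' @return mean pairwise correlation (scalar).
#' @export
spatialCorrelation <- function(maps) {
  vecs <- lapply(maps, function(m) if (is(m, "ERDMap")) m@values else as.numeric(m))
  n <- length(vecs)
  if (n < 2) stop("need at least 2 maps")
  rs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- vecs[[i]]; b <- vecs[[j]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      message(sprintf("map pair (%d, %d) undefined: excluded", i, j))
      next
    }
    rs <- c(rs, stats::cor(a[ok], b[ok]))
  }
  if (!length(rs)) stop("no valid map pairs")
  mean(rs)
}

#' Residual artifact correlation between source and auxiliary signals
#'
#' Absolute Pearson correlation between each reconstructed source (ROI)
#' signal and each auxiliary channel, plus the per-ROI maximum: the
#' quantitative check that cleaned reconstructions no longer track
#' EOG/EMG activity.
#'
#' @param sourceSignals numeric matrix `[n_roi x n_samples]`.
#' @param auxSignals numeric matrix `[n_aux x n_samples]` (same length).
#' @param roiNames,auxNames optional dimension names.
#' @return list with `correlations` (`[n_roi x n_aux]` of `|r|`) and
#'   `maxPerROI`.
#' @export
residualArtifactCorrelation <- function(sourceSignals, auxSignals,
                                        roiNames = NULL, auxNames = NULL) {
  S <- as.matrix(sourceSignals); A <- as.matrix(auxSignals)
  if (ncol(S) != ncol(A)) stop("source and auxiliary signals must have equal length")
  cc <- matrix(NA_real_, nrow(S), nrow(A))
  for (i in seq_len(nrow(S))) for (j in seq_len(nrow(A))) {
    if (stats::sd(S[i, ]) == 0 || stats::sd(A[j, ]) == 0) next
    cc[i, j] <- abs(stats::cor(S[i, ], A[j, ]))
  }
  dimnames(cc) <- list(roiNames, auxNames)
  list(correlations = cc, maxPerROI = apply(cc, 1, max, na.rm = TRUE))
}
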