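# The online engine: rolling buffer, per-buffer adaptive artifact
# regression, source projection, replay sources and sinks.

#' Realtime engine configuration
#'
#' @param bufferMs buffer length in milliseconds (default 500).
#' @param samplingRate sampling rate of the stream in Hz (default 100).
#' @param band analysis band in Hz (default `c(1, 50)`; an upper edge at
#'   Nyquist degrades gracefully to a pure high-pass).
#' @param mode `"voxels"` (full `K`) or `"rois"` (ROI-downsampled `K`).
#' @param stride recompute the adaptive filter every `stride` samples
#'   (default 1: every sample, i.e. at the sampling rate).
#' @param seed seed recorded with outputs for provenance.
#' @return a named list of stream settings.
#' @export
realtimeConfig <- function(bufferMs = 500, samplingRate = 100, band = c(1, 50),
                           mode = c("voxels", "rois"), stride = 1L, seed = 1L) {
  mode <- match.arg(mode)
  nT <- as.integer(round(bufferMs * samplingRate / 1000))
  if (nT < 4) stop("buffer must span at least 4 samples")
  if (stride < 1) stop("stride must be >= 1")
  list(bufferMs = bufferMs, samplingRate = samplingRate, band = band,
       mode = mode, stride = as.integer(stride), nT = nT, seed = as.integer(seed))
}

# In-buffer band-pass design. A zero-phase high-pass is only meaningful
# when the window holds at least two periods of the edge frequency;
# below that (e.g. 1 Hz on a 500 ms buffer) the high-pass section is
# replaced by window demeaning, which is all the information the window
# carries about its low-frequency content.
.bufferBandpass <- function(cfg) {
  des <- designBandpass(cfg$band, cfg$samplingRate)
  windowSec <- cfg$nT / cfg$samplingRate
  des$demean <- FALSE
  if (des$useHp && cfg$band[1] < 2 / windowSec) {
    des$useHp <- FALSE
    des$demean <- TRUE
  }
  # sections actually applied inside the buffer, stacked
  des$sos <- rbind(if (des$useHp) des$sosHp, if (des$useLp) des$sosLp)
  if (is.null(des$sos)) des$sos <- matrix(0, 0, 6)
  des
}

#' Create an empty stream buffer
#'
#' @param nChannels rows of the incoming samples.
#' @param nT buffer capacity in samples (>= 4).
#' @return a [StreamBuffer-class]
#' @export
streamBuffer <- function(nChannels, nT) {
  new("StreamBuffer", window = matrix(0, nChannels, as.integer(nT)),
      nT = as.integer(nT), cursor = 1L, samplesSeen = 0)
}

#' Push one sample into a buffer (FIFO)
#'
#' @param buffer a [StreamBuffer-class].
#' @param sample numeric vector of length `nrow(window)`.
#' @return the updated buffer (functional update).
#' @export
pushSample <- function(buffer, sample) {
  if (length(sample) != nrow(buffer@window))
    stop("sample length does not match the buffer channel count")
  buffer@window[, buffer@cursor] <- sample
  buffer@cursor <- if (buffer@cursor == buffer@nT) 1L else buffer@cursor + 1L
  buffer@samplesSeen <- buffer@samplesSeen + 1
  buffer
}

#' Has the buffer filled once?
#' @param buffer a [StreamBuffer-class].
#' @export
bufferFull <- function(buffer) buffer@samplesSeen >= buffer@nT

#' Chronologically ordered window (oldest to newest)
#' @param buffer a full [StreamBuffer-class].
#' @export
bufferWindow <- function(buffer) {
  if (!bufferFull(buffer)) stop("buffer not yet full")
  if (buffer@cursor == 1L) buffer@window
  else buffer@window[, c(buffer@cursor:buffer@nT, 1L:(buffer@cursor - 1L)), drop = FALSE]
}

#' Clean one buffer with the adaptive artifact filter
#'
#' The per-buffer pipeline: zero-phase band-pass within the window,
#' sensor filters `X_q = C R X`, artifact estimate `S_A = W_A X_q`,
#' adaptive regression
#' `F = I - X_q t(S_A) solve(S_A t(S_A)) W_A`, and the cleaned window
#' `X_p = F X_q` (so `W_A X_p = 0` on this buffer). Returns the cleaned
#' window; feed it to [extractLatest()] and [localizeSample()].
#'
#' @param buffer a full [StreamBuffer-class] holding raw EEG samples.
#' @param filters a [SpatialFilterSet-class].
#' @param cfg list from [realtimeConfig()].
#' @return numeric matrix `[n_E x n_T]`, the cleaned buffer.
#' @export
processBuffer <- function(buffer, filters, cfg) {
  W <- bufferWindow(buffer)
  des <- .bufferBandpass(cfg)
  if (des$demean) W <- W - rowMeans(W)
  if (nrow(des$sos)) W <- sosFiltfilt(des$sos, W)
  Xq <- filters@C %*% filters@R %*% W
  WA <- filters@WA
  if (!nrow(WA)) return(Xq)
  SA <- WA %*% Xq
  G <- SA %*% t(SA)
  tr <- sum(diag(G))
  # artifact subspace numerically silent in this buffer: nothing to fit
  if (tr <= 1e-12 * sum(Xq^2)) return(Xq)
  if (rcond(G) < 1e-12) G <- G + diag(1e-8 * tr / nrow(WA), nrow(WA))
  coef <- Xq %*% t(SA) %*% solve(G)
  Xq - coef %*% SA
}

#' Newest cleaned sensor sample of a processed buffer
#'
#' @param cleaned matrix from [processBuffer()].
#' @return numeric vector `Y`, the last column.
#' @export
extractLatest <- function(cleaned) cleaned[, ncol(cleaned)]

#' Project a cleaned sensor sample into source space
#'
#' `B = K %*% Y`.
#'
#' @param Y cleaned sensor vector (length `n_E`).
#' @param K localization filter `[3 n_V x n_E]` or a
#'   [SpatialFilterSet-class].
#' @return numeric vector of length `3 n_V` (or `3 n_R`).
#' @export
localizeSample <- function(Y, K) {
  if (is(K, "SpatialFilterSet")) K <- K@K
  if (ncol(K) != length(Y)) stop("K column count does not match the sample length")
  as.numeric(K %*% Y)
}

#' Replay a recorded file (or recording) as a sample iterator
#'
#' Test and offline stand-in for a live acquisition link: yields one
#' sample vector per call, `NULL` on exhaustion. With `paced = TRUE` the
#' iterator sleeps `1/fs` between yields.
#'
#' @param source file path (fixture/EDF/BrainVision) or an
#'   [EEGRecording-class].
#' @param paced sleep to approximate the real sampling cadence.
#' @return a function; calling it yields the next sample or `NULL`.
#' @export
replayRecording <- function(source, paced = FALSE) {
  rec <- if (is(source, "EEGRecording")) source else readRecording(source)
  X <- rec@data
  fs <- rec@samplingRate
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > ncol(X)) return(NULL)
    if (paced) Sys.sleep(1 / fs)
    X[, i]
  }
}

#' Run the online reconstruction over a stream
#'
#' Per-sample pipeline (push, band-pass within buffer, sensor filters,
#' adaptive artifact regression, extract newest sample, localize),
#' executed in compiled code over the whole replayed stream. Emits one
#' `(Y, B)` pair per input sample once the buffer has filled; no output
#' during warm-up. Deterministic in replay mode.
#'
#' @param source an [EEGRecording-class], a recording file path, or a
#'   numeric matrix of raw EEG `[n_E x n_samples]`.
#' @param filters a [SpatialFilterSet-class] from [runCalibration()].
#' @param cfg list from [realtimeConfig()]; `cfg$mode` must match the
#'   `K` stored in `filters`.
#' @param sink optional function called as `sink(Y, B, t)` per output
#'   sample (errors in the sink are logged, the stream continues).
#' @param outDir optional directory; cleaned sensor and source streams
#'   are persisted there as float32 matrices with a JSON sidecar.
#' @return list with `Y` (`[n_E x n_out]`), `B` (`[rows(K) x n_out]`),
#'   `annihilation` (per-buffer residual ratio of the artifact subspace),
#'   `timestamps` (1-based sample indices), and `latencySamples`
#'   (`nT - 1`, the buffer warm-up).
#' @export
runStream <- function(source, filters, cfg = realtimeConfig(), sink = NULL,
                      outDir = NULL) {
  X <- if (is.matrix(source)) source
  else if (is(source, "EEGRecording")) eegData(source)
  else eegData(readRecording(source))
  nE <- nrow(X)
  if (nE != length(filters@electrodeLabels))
    stop("stream channel count does not match the calibration filters")
  des <- .bufferBandpass(cfg)
  CR <- filters@C %*% filters@R
  res <- cpp_stream_loop(X, des$sos, des$demean,
                         CR, filters@WA, filters@K, cfg$nT,
                         1e-8, 1e12, cfg$stride)
  ts <- seq.int(cfg$nT, ncol(X))
  if (!is.null(sink)) {
    for (o in seq_along(ts)) {
      ok <- try(sink(res$Y[, o], res$B[, o], ts[o]), silent = TRUE)
      if (inherits(ok, "try-error")) message("sink failed at sample ", ts[o])
    }
  }
  out <- list(Y = res$Y, B = res$B, annihilation = as.numeric(res$annihilation),
              timestamps = ts, latencySamples = cfg$nT - 1L)
  if (!is.null(outDir)) .writeStreamOutput(out, filters, cfg, outDir)
  out
}

.writeStreamOutput <- function(out, filters, cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeStream <- function(M, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(M), con, size = 4, endian = "little")
  }
  writeStream(out$Y, file.path(outDir, "sensor.bin"))
  writeStream(out$B, file.path(outDir, "source.bin"))
  side <- list(format = "eegstream-stream", version = 1L,
               labels = filters@electrodeLabels, roi_names = filters@roiNames,
               n_out = length(out$timestamps), first_timestamp = out$timestamps[1],
               n_sensor_rows = nrow(out$Y), n_source_rows = nrow(out$B),
               sampling_rate = cfg$samplingRate, band = cfg$band,
               buffer_ms = cfg$bufferMs, stride = cfg$stride, seed = cfg$seed,
               dtype = "float32", order = "column-major")
  jsonlite::write_json(side, file.path(outDir, "stream.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Offline cleaning of a full recording with calibration filters
#'
#' The calibration pipeline applied to an entire record at once:
#' zero-phase band-pass, `C R`, then the static artifact filter `F0`.
#' Serves as the offline benchmark the streamed output is compared
#' against.
#'
#' @param rec an [EEGRecording-class].
#' @param filters a [SpatialFilterSet-class].
#' @param band analysis band (defaults to the calibration band).
#' @param useArtifactFilter apply `F0` (set `FALSE` to benchmark the
#'   no-artifact-removal condition).
#' @return numeric matrix `[n_E x n_T]` of cleaned sensor signals.
#' @export
offlineClean <- function(rec, filters, band = filters@band, useArtifactFilter = TRUE) {
  X <- bandpassFilter(eegData(rec), band, fs = rec@samplingRate)
  X <- filters@C %*% filters@R %*% X
  if (useArtifactFilter) X <- filters@F0 %*% X
  X
}
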