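# The online engine: buffer mechanics, per-buffer adaptive cleaning,
# localization and replay determinism.

makeFilters <- function(nE, WA = matrix(0, 0, nE), K = diag(nE)[1:3, , drop = FALSE]) {
  new(Class = "SpatialFilterSet", C = diag(nE), R = referenceMatrix(nE),
      WA = WA, F0 = diag(nE), H = referenceMatrix(nE) * (nE / (nE - 1)),
      K = K, Gblocks = array(diag(3), dim = c(3, 3, 1)),
      method = "mne", alpha = 0.05, band = c(1, 45), samplingRate = 100,
      badChannels = character(0), electrodeLabels = paste0("e", seq_len(nE)),
      roiNames = character(0))
}

test_that("the buffer is a FIFO with strict length checks", {
  b <- streamBuffer(3, 5)
  for (i in 1:5) b <- pushSample(b, rep(i, 3))
  expect_true(bufferFull(b))
  w <- bufferWindow(b)
  expect_equal(w[1, ], 1:5)                 # oldest first
  b <- pushSample(b, rep(6, 3))
  expect_equal(bufferWindow(b)[1, ], 2:6)   # first sample evicted
  expect_error(pushSample(b, rep(1, 4)), "length")
  expect_error(streamBuffer(3, 3), "at least 4")
  expect_error(bufferWindow(streamBuffer(3, 5)), "not yet full")
})

test_that("per-buffer cleaning annihilates the artifact subspace and spares its complement", {
  set.seed(61)
  nE <- 8; nT <- 50
  WA <- matrix(rnorm(2 * nE), 2, nE)
  fl <- makeFilters(nE, WA = WA)
  cfg <- realtimeConfig(bufferMs = 500, samplingRate = 100, band = c(13, 30))
  # generic data: annihilation identity
  b <- streamBuffer(nE, nT)
  X <- matrix(rnorm(nE * nT), nE, nT)
  for (i in seq_len(nT)) b <- pushSample(b, X[, i])
  cleaned <- processBuffer(b, fl, cfg)
  des <- eegstream:::.bufferBandpass(cfg)
  W <- X
  if (des$demean) W <- W - rowMeans(W)
  if (nrow(des$sos)) W <- eegstream:::sosFiltfilt(des$sos, W)
  Xq <- fl@C %*% fl@R %*% W
  expect_lt(norm(fl@WA %*% cleaned, "F"), 1e-10 * norm(fl@WA %*% Xq, "F"))
  # data orthogonal to the artifact rows pass through unchanged
  P <- diag(nE) - t(WA) %*% solve(WA %*% t(WA)) %*% WA
  fl2 <- makeFilters(nE, WA = WA)
  fl2@R <- diag(nE); fl2@C <- diag(nE)      # isolate the regression step
  b2 <- streamBuffer(nE, nT)
  X2 <- P %*% matrix(rnorm(nE * nT), nE, nT)
  for (i in seq_len(nT)) b2 <- pushSample(b2, X2[, i])
  cfg2 <- realtimeConfig(bufferMs = 500, samplingRate = 100, band = c(13, 30))
  cleaned2 <- processBuffer(b2, fl2, cfg2)
  des2 <- eegstream:::.bufferBandpass(cfg2)
  W2 <- X2
  if (des2$demean) W2 <- W2 - rowMeans(W2)
  if (nrow(des2$sos)) W2 <- eegstream:::sosFiltfilt(des2$sos, W2)
  # filtering is channel-wise, so the window stays in the null space of WA
  expect_lt(max(abs(cleaned2 - W2)), 1e-6 * max(abs(W2)))
})

test_that("a buffer built from the calibration segment reproduces the static filter", {
  set.seed(62)
  nE <- 8; nT <- 60
  Xseg <- matrix(rnorm(nE * nT), nE, nT)
  ica <- fitICA(Xseg, seed = 1)
  flagged <- markArtifactICs(ica, 1:2)
  F0 <- artifactFilter(Xseg, flagged)          # static filter from this segment
  WA <- artifactUnmixing(flagged)
  fl <- makeFilters(nE, WA = WA)
  # adaptive filter rebuilt from the identical segment: same regression
  SA <- WA %*% Xseg
  Ftau <- diag(nE) - Xseg %*% t(SA) %*% solve(SA %*% t(SA)) %*% WA
  expect_lt(max(abs(Ftau %*% Xseg - F0 %*% Xseg)), 1e-8 * max(abs(Xseg)))
})

test_that("extractLatest returns the newest cleaned column and warm-up yields no output", {
  M <- matrix(1:12, 3, 4)
  expect_equal(extractLatest(M), c(10, 11, 12))
  nE <- 4
  fl <- makeFilters(nE)
  cfg <- realtimeConfig(bufferMs = 100, samplingRate = 100, band = c(13, 30))
  X <- matrix(rnorm(nE * 30), nE, 30)
  out <- runStream(X, fl, cfg)
  expect_equal(ncol(out$Y), 30 - cfg$nT + 1)   # exactly N - nT + 1 outputs
  expect_equal(out$timestamps[1], cfg$nT)
  expect_error(runStream(X[, 1:5], fl, cfg), "shorter")
})

test_that("localization is a plain linear map with shape checks", {
  K <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(localizeSample(rep(0, 4), K), rep(0, 6))
  y1 <- rnorm(4); y2 <- rnorm(4)
  expect_equal(localizeSample(y1 + y2, K),
               localizeSample(y1, K) + localizeSample(y2, K))
  expect_error(localizeSample(rnorm(5), K), "column")
})

test_that("replay yields every sample in order and reports truncation by byte offset", {
  set.seed(63)
  rec <- eegRecording(matrix(rnorm(3 * 100), 3, 100), c("a", "b", "c"), 100)
  tmp <- file.path(tempdir(), "replay.json")
  writeRecordingFixture(rec, tmp)
  it <- replayRecording(tmp)
  n <- 0
  while (!is.null(s <- it())) {
    n <- n + 1
    if (n == 1) expect_equal(s, rec@data[, 1], tolerance = 1e-6)
  }
  expect_equal(n, 100)
  # truncated payload: error names the byte offset
  bin <- paste0(tmp, ".bin")
  raw <- readBin(bin, "raw", n = file.info(bin)$size)
  writeBin(raw[1:(length(raw) - 10)], bin)
  expect_error(readRecordingFixture(tmp), "byte")
})

test_that("replayed streams are deterministic and R/C++ buffer paths agree", {
  set.seed(64)
  nE <- 6
  WA <- matrix(rnorm(2 * nE), 2, nE)
  fl <- makeFilters(nE, WA = WA, K = matrix(rnorm(6 * nE), 6, nE))
  cfg <- realtimeConfig(bufferMs = 200, samplingRate = 100, band = c(2, 40))
  X <- matrix(rnorm(nE * 200), nE, 200)
  out1 <- runStream(X, fl, cfg)
  out2 <- runStream(X, fl, cfg)
  expect_identical(out1$Y, out2$Y)
  expect_identical(out1$B, out2$B)
  # R-level processBuffer reproduces a C++ output column
  b <- streamBuffer(nE, cfg$nT)
  for (i in seq_len(cfg$nT)) b <- pushSample(b, X[, i])
  cleaned <- processBuffer(b, fl, cfg)
  expect_equal(extractLatest(cleaned), out1$Y[, 1], tolerance = 1e-10)
  expect_equal(localizeSample(extractLatest(cleaned), fl@K), out1$B[, 1],
               tolerance = 1e-10)
  # per-buffer annihilation holds across the whole replayed stream
  expect_lt(max(out1$annihilation), 1e-10)
})

test_that("stream outputs persist to a sink directory with a sidecar", {
  set.seed(65)
  nE <- 4
  fl <- makeFilters(nE)
  cfg <- realtimeConfig(bufferMs = 100, samplingRate = 100, band = c(13, 30))
  X <- matrix(rnorm(nE * 60), nE, 60)
  seen <- 0
  dir1 <- file.path(tempdir(), "streamout1")
  out <- runStream(X, fl, cfg, sink = function(Y, B, t) seen <<- seen + 1,
                   outDir = dir1)
  expect_equal(seen, ncol(out$Y))
  expect_true(file.exists(file.path(dir1, "sensor.bin")))
  side <- jsonlite::read_json(file.path(dir1, "stream.json"))
  expect_equal(side$n_out, ncol(out$Y))
  # a failing sink does not interrupt the stream
  expect_message(
    out2 <- runStream(X, fl, cfg, sink = function(Y, B, t) stop("boom")),
    "sink failed")
  expect_equal(ncol(out2$Y), ncol(out$Y))
})
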