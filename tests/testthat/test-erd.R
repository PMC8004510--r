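# ERD analytics: onset detection, epoching, band power, the relative
# power-change maps, and the reliability/residual-artifact metrics.

test_that("EMG onsets are found within 50 ms at the task cadence", {
  set.seed(71)
  fs <- 100
  n <- 120 * fs
  onsets <- as.integer(seq(6, 114, by = 12) * fs) + 1L     # 6 s move / 6 s rest
  gate <- rep(0, n)
  for (o in onsets) gate[o:(o + 6 * fs - 1)] <- 1
  emg <- rnorm(n) + 40 * gate * rnorm(n)
  det <- detectOnsets(emg, fs)
  expect_equal(length(det), length(onsets))
  expect_lt(max(abs(det - onsets)) / fs, 0.05)
  # flat EMG: nothing to find
  expect_warning(none <- detectOnsets(rep(2, n), fs), "no EMG")
  expect_length(none, 0)
  # two bursts closer than the refractory period collapse to one onset
  em2 <- 0.5 * rnorm(20 * fs)
  em2[(5 * fs):(5 * fs + 50)] <- em2[(5 * fs):(5 * fs + 50)] + 60
  em2[(6 * fs):(6 * fs + 50)] <- em2[(6 * fs):(6 * fs + 50)] + 60
  det2 <- detectOnsets(em2, fs, refractorySec = 3)
  expect_equal(length(det2), 1)
})

test_that("epoching drops out-of-bounds trials and errors on none usable", {
  fs <- 100
  x <- matrix(seq_len(30 * fs), 1)
  on <- as.integer(c(0.5, 5, 10, 29.5) * fs)
  expect_message(tr <- epochTrials(x, on, fs), "dropped")
  expect_equal(dim(tr@epochs)[3], 2)          # first and last dropped
  expect_equal(tr@onsets, on[2:3])
  expect_error(epochTrials(x, integer(0), fs), "no onsets")
  expect_error(suppressMessages(epochTrials(x, as.integer(0.1 * fs), fs)), "usable")
  # 12 in-bounds onsets give 12 epochs
  on12 <- as.integer(seq(2, 24, by = 2) * fs)
  expect_equal(dim(epochTrials(x, on12, fs)@epochs)[3], 12)
})

test_that("band power matches the analytic sinusoid value and scales quadratically", {
  fs <- 250
  t <- seq_len(20 * fs) / fs
  x <- sin(2 * pi * 20 * t)          # well inside the 5-45 Hz band
  core <- (2 * fs):(18 * fs)
  p1 <- bandPower(x, c(5, 45), fs)
  expect_equal(mean(p1[core]), 0.5, tolerance = 0.02)
  p2 <- bandPower(0.5 * x, c(5, 45), fs)
  expect_equal(mean(p2[core]) / mean(p1[core]), 0.25, tolerance = 0.005)
  pOut <- bandPower(sin(2 * pi * 70 * t), c(5, 45), fs)
  expect_lt(mean(pOut[core]) / mean(p1[core]), 0.01)
  expect_true(all(p1 >= 0))
  expect_error(bandPower(x, c(13, 200), fs), "Nyquist|band")
})

test_that("ERD hits its algebraic anchors and is scale invariant", {
  fs <- 100
  set.seed(72)
  # P == Pb -> 0%; P == 0 in the task window -> -100%
  n <- 5 * fs
  onset <- 2 * fs
  carrier <- sin(2 * pi * 20 * seq_len(n) / fs)
  const <- matrix(carrier, 1)
  gone <- matrix(carrier, 1)
  gone[1, (onset + 20):n] <- 0
  tr1 <- epochTrials(const, onset, fs, taskWindow = c(0.5, 2.5))
  tr2 <- epochTrials(gone, onset, fs, taskWindow = c(0.5, 2.5))
  e1 <- computeERD(tr1, c(13, 30))
  e2 <- computeERD(tr2, c(13, 30))
  expect_equal(e1@values, 0, tolerance = 0.5)
  expect_equal(e2@values, -100, tolerance = 0.5)
  # global rescaling leaves the ratio untouched to machine precision
  tr3 <- epochTrials(const * 37.5, onset, fs, taskWindow = c(0.5, 2.5))
  e3 <- computeERD(tr3, c(13, 30))
  expect_equal(e3@values, e1@values, tolerance = 1e-10)
  # bounded below by -100 for nonnegative power
  expect_gte(min(e2@values), -100 - 1e-9)
})

test_that("amplitude modulation depth 0.5 yields about -75% over 20 simulated trials", {
  set.seed(73)
  fs <- 100
  nTrials <- 20
  n <- nTrials * 12 * fs
  onsets <- as.integer((6 + 12 * (seq_len(nTrials) - 1)) * fs) + 1L
  env <- makeTaskModulation(n, fs, onsets, moveDur = 6, a = 0.5)
  carrier <- as.numeric(bandpassFilter(matrix(rnorm(n), 1), c(13, 30), fs = fs))
  x <- matrix(env * carrier, 1)
  tr <- epochTrials(x, onsets, fs)
  erd <- computeERD(tr, c(13, 30), smoothSec = 0)
  expect_lt(abs(erd@values - (-75)), 5)
})

test_that("zero baseline power is flagged undefined, not zeroed", {
  fs <- 100
  x <- matrix(0, 2, 6 * fs)
  x[1, ] <- sin(2 * pi * 20 * seq_len(6 * fs) / fs)
  tr <- epochTrials(x, 3 * fs, fs)
  erd <- computeERD(tr, c(13, 30))
  expect_true(erd@undefined[2])
  expect_true(is.na(erd@values[2]))
  expect_false(erd@undefined[1])
})

test_that("time-frequency profiles are baseline-zero and consistent with map mode", {
  set.seed(74)
  fs <- 100
  nTrials <- 8
  n <- nTrials * 12 * fs
  onsets <- as.integer((6 + 12 * (seq_len(nTrials) - 1)) * fs) + 1L
  env <- makeTaskModulation(n, fs, onsets, moveDur = 6, a = 0.4)
  x <- matrix(env * as.numeric(bandpassFilter(matrix(rnorm(n), 1), c(16, 24), fs = fs)) +
                0.1 * rnorm(n), 1)
  tr <- epochTrials(x, onsets, fs)
  tf <- erdTimeFrequency(tr, freqRange = c(10, 30), binHz = 4, roi = "m1")
  baseCols <- which(tr@times >= -1 & tr@times <= 0)
  expect_lt(max(abs(rowMeans(tf@values[, baseCols]))), 1e-9)
  # collapsing a TF row over the task window equals the map for that bin
  taskCols <- which(tr@times >= 0 & tr@times <= 2)
  f <- 3                                           # the 18-22 Hz bin
  bin <- c(tf@freqs[f] - 2, tf@freqs[f] + 2)
  mapERD <- computeERD(tr, bin)
  expect_equal(mean(tf@values[f, taskCols]), mapERD@values, tolerance = 1e-6)
})

test_that("spatial correlation matches its analytic attenuation under replicate noise", {
  set.seed(75)
  nV <- 400
  common <- rnorm(nV)
  snr <- 2                                   # amplitude SNR
  maps <- lapply(1:12, function(k) common * snr + rnorm(nV))
  got <- spatialCorrelation(maps)
  want <- snr^2 / (snr^2 + 1)
  # brute-force Monte-Carlo oracle for the same generative model
  mc <- replicate(60, {
    m1 <- common * snr + rnorm(nV); m2 <- common * snr + rnorm(nV)
    cor(m1, m2)
  })
  expect_lt(abs(got - want), 0.05)
  expect_lt(abs(got - mean(mc)), 0.05)
  expect_equal(spatialCorrelation(list(common, common)), 1.0)
  expect_equal(spatialCorrelation(list(common, -common)), -1.0)
  # constant map pairs are excluded with a message
  expect_message(r <- spatialCorrelation(list(common, rep(1, nV), common)),
                 "excluded")
  expect_equal(r, 1.0)
})

test_that("residual artifact correlations behave at the null and the identity", {
  set.seed(76)
  n <- 10000
  veog <- rnorm(n)
  src <- rbind(veog, rnorm(n))
  out <- residualArtifactCorrelation(src, rbind(veog), roiNames = c("same", "indep"))
  expect_equal(unname(out$correlations["same", 1]), 1.0, tolerance = 1e-12)
  expect_lt(unname(out$correlations["indep", 1]), 0.05)
  expect_equal(unname(out$maxPerROI["same"]), 1.0)
})
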