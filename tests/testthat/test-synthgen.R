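# Ground-truth simulator: trial structure, artifact generators,
# bad-channel injection and reproducibility.

test_that("an empty spec yields an all-zero recording with quiet auxiliaries", {
  lf <- smallLeadfield(16)
  spec <- simulationSpec(nTrials = 0L, duration = 5, blinkRate = 0, emgRate = 0,
                         noiseSD = 0, samplingRate = 100, seed = 1)
  sim <- simulateRecording(spec, lf)
  expect_equal(max(abs(eegData(sim$recording))), 0)
  expect_equal(ncol(sim$recording@data), 500)
})

test_that("a single dipolar source gives a rank-1 sensor covariance before noise", {
  lf <- smallLeadfield(16)
  src <- data.frame(voxel = offCenterVoxels(smallGrid())[3], ox = 0, oy = 1, oz = 0,
                    low = 13, high = 30, amplitude = 50, depth = 1, task = FALSE)
  spec <- simulationSpec(sources = src, nTrials = 0L, duration = 20,
                         blinkRate = 0, emgRate = 0, noiseSD = 0,
                         samplingRate = 100, seed = 2)
  sim <- simulateRecording(spec, lf)
  X <- eegData(sim$recording)
  ev <- svd(X)$d
  expect_gt(ev[1], 0)
  expect_lt(ev[2] / ev[1], 1e-10)
})

test_that("blink events are Poisson-consistent and written to the ground truth", {
  lf <- smallLeadfield(16)
  spec <- simulationSpec(nTrials = 0L, duration = 240, blinkRate = 10, emgRate = 0,
                         noiseSD = 0, samplingRate = 100, seed = 3)
  sim <- simulateRecording(spec, lf)
  nBlink <- length(sim$groundTruth@blinkTimes)
  # 10/min over 4 min: expect 40, allow +-4 sd of Poisson(40)
  expect_gt(nBlink, 40 - 4 * sqrt(40))
  expect_lt(nBlink, 40 + 4 * sqrt(40))
  # the vEOG auxiliary tracks the blink reference
  veog <- auxChannel(sim$recording, "veog")
  expect_gt(cor(veog, sim$groundTruth@blinkRef), 0.98)
})

test_that("task modulation envelopes encode the expected power drop", {
  env1 <- makeTaskModulation(1000, 100, onsets = 301, moveDur = 3, a = 1)
  expect_equal(env1, rep(1, 1000))
  env <- makeTaskModulation(1200, 100, onsets = 301, moveDur = 3, a = 0.5)
  expect_equal(env[450], 0.5)                 # mid-block
  expect_equal(env[100], 1)                   # rest before the block
  expect_equal(env[700], 1)                   # rest after the block
  expect_equal((mean(env[450:550]^2) - 1) * 100, -75, tolerance = 1)
  tiny <- makeTaskModulation(1200, 100, onsets = 301, moveDur = 3, a = 1e-6)
  expect_lt((mean(tiny[450:550]^2) - 1) * 100 + 100, 1e-3)   # ERD -> -100%
  expect_error(makeTaskModulation(1200, 100, onsets = c(301, 400), moveDur = 3, a = 0.5),
               "overlap")
})

test_that("bad-channel injection produces the advertised pathologies", {
  lf <- smallLeadfield(16)
  spec <- simulationSpec(sources = backgroundSources(lf, seed = 4), nTrials = 0L,
                         duration = 10, samplingRate = 1000, blinkRate = 0,
                         emgRate = 0, seed = 4)
  sim <- simulateRecording(spec, lf)
  set.seed(41)
  flat <- injectBadChannel(sim$recording, "E03", "flat")
  expect_equal(sd(flat@data[3, ]), 0)
  hf <- injectBadChannel(sim$recording, "E03", "hf-noise")
  hfBand <- bandpassFilter(eegData(hf), c(200, 250), fs = 1000)
  vars <- apply(hfBand, 1, var)
  others <- vars[-3]
  expect_gt(vars[3], mean(others) + 4 * sd(others))
  expect_error(injectBadChannel(sim$recording, "vEOG", "flat"), "auxiliary")
  # both injections recorded in ground truth when given in the spec
  spec2 <- simulationSpec(nTrials = 0L, duration = 2, samplingRate = 1000,
                          badChannels = data.frame(channel = c("E01", "E02"),
                                                   mode = c("flat", "hf-noise")),
                          seed = 5)
  sim2 <- simulateRecording(spec2, lf)
  expect_equal(nrow(sim2$groundTruth@badChannels), 2)
})

test_that("identical specs give bit-identical recordings", {
  lf <- smallLeadfield(16)
  spec <- simulationSpec(sources = backgroundSources(lf, seed = 6), nTrials = 2L,
                         samplingRate = 100, seed = 6)
  a <- simulateRecording(spec, lf)
  b <- simulateRecording(spec, lf)
  expect_identical(a$recording@data, b$recording@data)
  expect_identical(a$groundTruth@blinkTimes, b$groundTruth@blinkTimes)
  spec2 <- simulationSpec(sources = backgroundSources(lf, seed = 6), nTrials = 2L,
                          samplingRate = 100, seed = 7)
  c <- simulateRecording(spec2, lf)
  expect_false(identical(a$recording@data, c$recording@data))
})

test_that("the movement EMG auxiliary carries bursts aligned to true onsets", {
  lf <- smallLeadfield(16)
  spec <- simulationSpec(sources = backgroundSources(lf, seed = 8), nTrials = 5L,
                         samplingRate = 100, seed = 8)
  sim <- simulateRecording(spec, lf)
  det <- detectOnsets(auxChannel(sim$recording, "emgonset"), 100)
  expect_equal(length(det), 5)
  expect_lte(max(abs(det - sim$groundTruth@onsets)) / 100, 0.05)
})
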