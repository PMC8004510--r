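# Calibration orchestration and the spatial-filter archive.

calSim <- function(seed, blinkRate, duration = 40) {
  lf <- smallLeadfield()
  spec <- simulationSpec(sources = backgroundSources(lf, seed = seed),
                         nTrials = 0L, duration = duration, samplingRate = 100,
                         blinkRate = blinkRate, emgRate = 0, seed = seed)
  list(lf = lf, sim = simulateRecording(spec, lf))
}

test_that("artifact-free calibration leaves the attenuation filter near the identity", {
  s <- calSim(seed = 91, blinkRate = 0, duration = 120)
  res <- suppressMessages(suppressWarnings(
    runCalibration(s$sim$recording, s$lf, calibrationConfig(seed = 91))))
  # allow a small number of chance flags on a short record, but the
  # filter must stay close to the identity
  expect_lte(nrow(res$filters@WA), 3)
  nE <- length(res$filters@electrodeLabels)
  expect_lt(norm(res$filters@F0 - diag(nE), "F") / sqrt(nE), 0.35)
})

test_that("blink-contaminated calibration flags ICs and suppresses the blink topography", {
  s <- calSim(seed = 92, blinkRate = 15, duration = 60)
  res <- suppressMessages(suppressWarnings(
    runCalibration(s$sim$recording, s$lf, calibrationConfig(seed = 92))))
  fl <- res$filters
  expect_gte(nrow(fl@WA), 1)
  xq <- applySensorFilters(s$sim$recording, fl@C, fl@R)
  xqt <- bandpassFilter(xq, c(1, 45), auxPassthrough = TRUE)
  Xq <- eegData(xqt)
  blink <- s$sim$groundTruth@blinkRef
  before <- max(abs(cor(t(Xq), blink)))
  after <- max(abs(cor(t(fl@F0 %*% Xq), blink)))
  expect_gt(before, 0.4)
  expect_lt(after, 0.1)
  # annihilation identity on the calibration data
  expect_lt(norm(fl@WA %*% fl@F0 %*% Xq, "F"),
            1e-10 * norm(fl@WA %*% Xq, "F"))
})

test_that("calibration is deterministic: identical seeds give byte-identical archives", {
  s <- calSim(seed = 93, blinkRate = 10)
  cfg <- calibrationConfig(seed = 93)
  r1 <- suppressMessages(suppressWarnings(runCalibration(s$sim$recording, s$lf, cfg)))
  r2 <- suppressMessages(suppressWarnings(runCalibration(s$sim$recording, s$lf, cfg)))
  p1 <- file.path(tempdir(), "fl1.json")
  p2 <- file.path(tempdir(), "fl2.json")
  saveSpatialFilters(r1$filters, p1)
  saveSpatialFilters(r2$filters, p2)
  expect_identical(readBin(paste0(p1, ".bin"), "raw", file.info(paste0(p1, ".bin"))$size),
                   readBin(paste0(p2, ".bin"), "raw", file.info(paste0(p2, ".bin"))$size))
  # and the archive round-trips
  back <- loadSpatialFilters(p1)
  expect_identical(back@K, r1$filters@K)
  expect_identical(back@WA, r1$filters@WA)
  expect_equal(back@method, r1$filters@method)
})

test_that("ROI-configured calibration returns a downsampled localization filter", {
  s <- calSim(seed = 94, blinkRate = 5)
  grid <- s$lf@grid
  vs <- offCenterVoxels(grid)[c(2, 9)]
  rois <- data.frame(name = c("a", "b"),
                     x = grid@positions[vs, 1], y = grid@positions[vs, 2],
                     z = grid@positions[vs, 3], radius = 10)
  res <- suppressMessages(suppressWarnings(
    runCalibration(s$sim$recording, s$lf,
                   calibrationConfig(seed = 94, rois = rois))))
  expect_equal(nrow(res$filters@K), 6)
  expect_equal(res$filters@roiNames, c("a", "b"))
})

test_that("channel mismatch between recording and leadfield is rejected", {
  s <- calSim(seed = 95, blinkRate = 0, duration = 10)
  wrongLf <- smallLeadfield(16)
  expect_error(runCalibration(s$sim$recording, wrongLf, calibrationConfig()),
               "match")
})
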