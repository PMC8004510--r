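# Sensor-space algebra: average reference, adjacency, bad-channel
# repair, their application, and the band-pass.

test_that("reference matrix algebra is exact across montage sizes", {
  for (nE in c(2, 19, 32, 128)) {
    R <- referenceMatrix(nE)
    expect_lt(max(abs(R - t(R))), 1e-12)
    expect_lt(max(abs(R %*% R - R)), 1e-12)
    expect_lt(max(abs(R %*% rep(1, nE))), 1e-12)
    expect_equal(R[1, 1], (nE - 1) / nE)
    if (nE > 1) expect_equal(R[1, 2], -1 / nE)
  }
  expect_equal(referenceMatrix(2), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  expect_error(referenceMatrix(1), "at least 2")
})

test_that("adjacency uses the distance rule and zeroes bad channels", {
  fid <- rbind(nz = c(0, 50, 40), lpa = c(-50, 0, 40), rpa = c(50, 0, 40))
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(40, 0, 0), c(200, 0, 0))
  es <- electrodeSet(c("a", "b", "c", "d"), pos, fid)
  A <- buildAdjacency(es, threshold = 40)
  expect_equal(A["a", "b"], 1)     # 1 mm apart
  expect_equal(A["a", "c"], 1)     # exactly at threshold
  expect_equal(A["a", "d"], 0)     # far
  expect_true(all(diag(A) == 0))
  Ab <- buildAdjacency(es, bad = "b", threshold = 40)
  expect_true(all(Ab[, "b"] == 0))           # a bad channel never donates
  expect_true(all(Ab["a", "b"] == 0))        # good rows do not link to it
  expect_equal(Ab["b", "a"], 1)              # but it keeps its good neighbours
  # spread-out montage: no neighbours at all
  far <- electrodeSet(c("a", "b", "c"), rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0)), fid)
  expect_true(all(buildAdjacency(far, threshold = 40) == 0))
})

test_that("correction matrix follows the repair rule exactly", {
  fid <- rbind(nz = c(0, 50, 40), lpa = c(-50, 0, 40), rpa = c(50, 0, 40))
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5, 0), c(300, 0, 0))
  es <- electrodeSet(c("e1", "e2", "e3", "e4"), pos, fid)
  A <- buildAdjacency(es, bad = "e3", threshold = 40)
  C <- correctionMatrix(A, "e3")
  expect_equal(unname(C[3, ]), c(0.5, 0.5, 0, 0))     # mean of the two good neighbours
  good <- C[-3, ]
  expect_equal(unname(good), unname(diag(4)[-3, ]))   # identity elsewhere
  expect_equal(sum(C[3, ]), 1)
  # no bad channels: identity
  expect_equal(correctionMatrix(buildAdjacency(es, threshold = 40)), diag(4),
               ignore_attr = TRUE)
  # isolated bad channel is an error naming the channel
  Afar <- buildAdjacency(es, bad = "e4", threshold = 40)
  expect_error(correctionMatrix(Afar, "e4"), "e4")
})

test_that("sensor filters compose as C R X with auxiliary passthrough", {
  set.seed(5)
  X <- rbind(matrix(rnorm(4 * 100), 4, 100), aux = rnorm(100))
  rec <- eegRecording(X, c("e1", "e2", "e3", "e4", "vEOG"), 100,
                      auxMap = c(veog = 5L))
  R <- referenceMatrix(4)
  out <- applySensorFilters(rec, diag(4), R)
  expect_lt(max(abs(colMeans(eegData(out)))), 1e-12)         # zero-mean columns
  expect_identical(out@data[5, ], rec@data[5, ])             # aux untouched
  # identity filters: identity output
  out2 <- applySensorFilters(rec, diag(4), diag(4))
  expect_identical(out2@data, rec@data)
  # repaired channel equals the mean of its re-referenced neighbours
  fid <- rbind(nz = c(0, 50, 40), lpa = c(-50, 0, 40), rpa = c(50, 0, 40))
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5, 0), c(12, 5, 0))
  es <- electrodeSet(c("e1", "e2", "e3", "e4"), pos, fid)
  A <- buildAdjacency(es, bad = "e3", threshold = 15)
  C <- correctionMatrix(A, "e3")
  dimnames(C) <- NULL
  out3 <- applySensorFilters(rec, C, R)
  reref <- R %*% eegData(rec)
  neigh <- which(A[3, ] == 1)
  expect_equal(eegData(out3)[3, ], colMeans(reref[neigh, , drop = FALSE]))
  # mismatched dimensions are an error
  expect_error(applySensorFilters(rec, diag(3), referenceMatrix(3)), "dimensions")
})

test_that("band-pass preserves in-band tones and attenuates out-of-band ones", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  inband <- sin(2 * pi * 10 * t)
  outband <- sin(2 * pi * 80 * t)
  rec <- eegRecording(rbind(inband, outband, 0), c("in", "out", "zero"), fs)
  f <- bandpassFilter(rec, c(1, 50))
  # the 1 Hz high-pass settles over a few seconds; judge the interior
  core <- (3 * fs):(7 * fs)
  ampIn <- max(abs(f@data[1, core]))
  expect_gt(ampIn, 0.99)
  expect_lt(ampIn, 1.01)
  ampOut <- max(abs(f@data[2, core]))
  expect_lt(ampOut, 10^(-20 / 20))          # >= 20 dB down
  expect_equal(max(abs(f@data[3, ])), 0)    # zero in, zero out
  expect_equal(f@band, c(1, 50))
  expect_error(bandpassFilter(rec, c(10, 400)), "Nyquist|band")
})

test_that("a band reaching Nyquist degrades to a pure high-pass", {
  fs <- 100
  des <- eegstream:::designBandpass(c(1, 50), fs)
  expect_true(des$useHp)
  expect_false(des$useLp)
})
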