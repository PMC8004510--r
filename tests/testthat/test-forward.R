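# Forward model: co-registration, sphere fitting, source grid and the
# three-shell spherical leadfield.

test_that("co-registration recovers a known rigid transform and projects onto the scalp", {
  model <- smallModel()
  mont <- smallMontage()
  # identity case: already in model space, on the sphere
  same <- coregisterElectrodes(mont, model)
  expect_lt(max(abs(same@positions - mont@positions)), 1e-9)
  # rotate 90 degrees about z and translate; recover via fiducials
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(10, 0, 0)
  moved <- electrodeSet(mont@labels,
                        mont@positions %*% t(Rz) + matrix(shift, length(mont), 3, byrow = TRUE),
                        mont@fiducials %*% t(Rz) + matrix(shift, 3, 3, byrow = TRUE))
  back <- coregisterElectrodes(moved, model, modelFiducials = mont@fiducials)
  expect_lt(max(abs(back@positions - mont@positions)), 1e-9)
  # rigid transform preserves inter-electrode distances
  expect_lt(max(abs(dist(back@positions) - dist(moved@positions))), 1e-9)
  # radial projection: electrode at 1.1 r projected back along the ray
  inflated <- electrodeSet(mont@labels, mont@positions * 1.1, mont@fiducials)
  proj <- coregisterElectrodes(inflated, model, modelFiducials = mont@fiducials * 1)
  r <- sqrt(rowSums(proj@positions^2))
  expect_lt(max(abs(r - model@radii[3])), 1e-9)
  u1 <- proj@positions / r
  u2 <- mont@positions / sqrt(rowSums(mont@positions^2))
  expect_lt(max(abs(u1 - u2)), 1e-9)
})

test_that("fiducial validation rejects collinear landmarks", {
  fid <- rbind(nz = c(0, 1, 0), lpa = c(0, 2, 0), rpa = c(0, 3, 0))
  expect_error(electrodeSet("A", matrix(1, 1, 3), fid), "collinear")
})

test_that("sphere fitting recovers analytic and noisy spheres, rejects coplanar input", {
  set.seed(11)
  u <- matrix(rnorm(3 * 40), 40, 3)
  u <- u / sqrt(rowSums(u^2))
  fid <- rbind(nz = c(0, 95, 0), lpa = c(-95, 0, 0), rpa = c(95, 0, 0))
  es <- electrodeSet(paste0("E", 1:40), u * 95, fid)
  fit <- fitSphereToElectrodes(es)
  expect_lt(max(abs(fit@center)), 1e-6)
  expect_lt(abs(fit@radii[3] - 95), 1e-6)
  expect_equal(unname(fit@radii[2] / fit@radii[3]), 0.92, tolerance = 1e-12)
  # isotropic noise sigma = 1 mm, n = 128
  u2 <- matrix(rnorm(3 * 128), 128, 3)
  u2 <- u2 / sqrt(rowSums(u2^2))
  noisy <- electrodeSet(paste0("E", 1:128), u2 * 95 + matrix(rnorm(384), 128, 3), fid)
  fit2 <- fitSphereToElectrodes(noisy)
  expect_lt(abs(fit2@radii[3] - 95), 0.5)
  # coplanar points are degenerate
  flat <- electrodeSet(paste0("E", 1:4),
                       cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0), fid)
  expect_error(fitSphereToElectrodes(flat), "coplanar|degenerate")
})

test_that("source grid respects the mask, ordering and scaling law", {
  model <- smallModel()
  g <- buildSourceGrid(model, spacing = 6)
  expect_true(all(sqrt(rowSums(g@positions^2)) <= 0.95 * model@radii[1] + 1e-12))
  # x varies fastest in the stored order
  dx <- diff(g@positions[1:2, 1])
  expect_equal(dx, 6)
  expect_error(buildSourceGrid(model, spacing = 200), "empty")
  # halving the spacing multiplies the count by about 8
  n1 <- nrow(buildSourceGrid(model, spacing = 12)@positions)
  n2 <- nrow(buildSourceGrid(model, spacing = 6)@positions)
  expect_gt(n2 / n1, 6.5)
  expect_lt(n2 / n1, 9.5)
})

test_that("equal-conductivity leadfield matches the homogeneous-sphere closed form", {
  model <- sphericalHeadModel(conductivities = c(0.33, 0.33, 0.33))
  mont <- smallMontage()
  grid <- smallGrid()
  lf <- computeLeadfield(model, mont, grid, referenced = FALSE)
  off <- offCenterVoxels(grid)
  set.seed(42)
  for (k in 1:40) {
    v <- sample(off, 1)
    e <- sample(length(mont), 1)
    q <- rnorm(3)
    cols <- (3 * (v - 1) + 1):(3 * v)
    got <- sum(lf@gain[e, cols] * q)
    want <- homogeneousSpherePotential(model, grid@positions[v, ], q, mont@positions[e, ])
    expect_lt(abs(got - want) / max(abs(want), 1e-12), 1e-6)
  }
})

test_that("leadfield is linear, average-referenced and azimuthally symmetric", {
  lf <- smallLeadfield()
  grid <- smallGrid()
  # average reference: every column sums to zero over electrodes
  expect_lt(max(abs(colMeans(lf@gain))), 1e-12 * max(abs(lf@gain)))
  # linearity in the dipole moment
  v <- offCenterVoxels(grid)[5]
  cols <- (3 * (v - 1) + 1):(3 * v)
  q1 <- c(1, 2, -1); q2 <- c(0.5, -1, 3)
  lhs <- lf@gain[, cols] %*% (2 * q1 + 3 * q2)
  rhs <- 2 * lf@gain[, cols] %*% q1 + 3 * lf@gain[, cols] %*% q2
  expect_lt(max(abs(lhs - rhs)), 1e-12 * max(abs(lhs)))
  # a z-dipole on the z-axis: potential depends only on the polar angle
  model <- smallModel()
  ring <- t(vapply(seq(0, 2 * pi, length.out = 9)[-9], function(a)
    model@radii[3] * c(sin(0.7) * cos(a), sin(0.7) * sin(a), cos(0.7)), numeric(3)))
  fid <- rbind(nz = c(0, model@radii[3], 0), lpa = c(-model@radii[3], 0, 0),
               rpa = c(model@radii[3], 0, 0))
  es <- electrodeSet(paste0("R", 1:8), ring, fid)
  gz <- buildSourceGrid(model, spacing = 50)   # includes a near-axis voxel set
  lfr <- computeLeadfield(model, es, gz, referenced = FALSE)
  onAxis <- which(abs(gz@positions[, 1]) < 1e-9 & abs(gz@positions[, 2]) < 1e-9 &
                    gz@positions[, 3] > 1)
  skip_if(length(onAxis) == 0)
  vz <- onAxis[1]
  pot <- lfr@gain[, 3 * vz]            # unit dipole along z
  expect_lt(max(abs(pot - pot[1])), 1e-8 * max(abs(pot)))
})

test_that("series truncation is converged: doubling the order changes nothing material", {
  model <- smallModel()
  mont <- smallMontage(16)
  grid <- smallGrid()
  lf1 <- computeLeadfield(model, mont, grid, order = 150, maxOrder = 150)
  lf2 <- computeLeadfield(model, mont, grid, order = 300, maxOrder = 300)
  expect_lt(max(abs(lf1@gain - lf2@gain)) / max(abs(lf2@gain)), 1e-8)
})

test_that("dipoles outside the brain shell are rejected", {
  model <- smallModel()
  mont <- smallMontage(16)
  badGrid <- new("SourceGrid",
                 positions = matrix(c(0, 0, model@radii[1] + 5), 1, 3),
                 spacing = 10, maskRadius = 90, center = c(0, 0, 0))
  expect_error(computeLeadfield(model, mont, badGrid), "outside")
})

test_that("leadfield archive round-trips bit-exactly and validates compatibility", {
  lf <- smallLeadfield(16)
  tmp <- file.path(tempdir(), "lf.json")
  saveLeadfield(lf, tmp)
  lf2 <- loadLeadfield(tmp)
  expect_identical(lf2@gain, lf@gain)
  expect_identical(lf2@electrodes@labels, lf@electrodes@labels)
  expect_equal(lf2@grid@positions, lf@grid@positions)
  # mismatching electrode set is a compatibility error
  other <- smallMontage(32)
  expect_error(loadLeadfield(tmp, electrodes = other), "compatibility")
  # truncated binary payload is a compatibility error
  bin <- paste0(tmp, ".bin")
  full <- readBin(bin, "raw", n = file.info(bin)$size)
  writeBin(full[1:(length(full) - 24)], bin)   # drop one gain column worth
  expect_error(loadLeadfield(tmp), "compatibility")
})

test_that("an externally produced leadfield container is accepted", {
  # write the documented container layout by hand with a tiny gain
  mont <- smallMontage(16)
  grid <- smallGrid(25)
  nE <- 16L; nV <- nrow(grid@positions)
  gain <- matrix(seq_len(nE * 3 * nV) * 1e-3, nE, 3 * nV)
  gain <- gain - matrix(colMeans(gain), nE, 3 * nV, byrow = TRUE)
  tmp <- file.path(tempdir(), "ext_lf.json")
  hdr <- list(format = "eegstream-leadfield", version = 1L,
              n_electrodes = nE, n_voxels = nV,
              labels = mont@labels,
              electrode_positions = unname(mont@positions),
              fiducials = unname(mont@fiducials),
              grid_positions = unname(grid@positions),
              spacing = grid@spacing, mask_radius = grid@maskRadius,
              model = list(center = c(0, 0, 0), radii = c(81.8, 86.5, 94),
                           conductivities = c(0.33, 0.01, 0.43)),
              referenced = TRUE, binary = "ext_lf.json.bin",
              dtype = "float64", order = "column-major")
  jsonlite::write_json(hdr, tmp, digits = NA, auto_unbox = TRUE)
  con <- file(paste0(tmp, ".bin"), "wb")
  writeBin(as.numeric(gain), con, size = 8, endian = "little")
  close(con)
  lf <- loadLeadfield(tmp)
  expect_equal(lf@gain, gain)
  expect_s4_class(lf, "Leadfield")
})
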