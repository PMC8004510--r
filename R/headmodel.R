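# Forward model: volumetric source grid and the analytic three-shell
# spherical leadfield (Legendre series with per-harmonic transfer
# coefficients).

#' Build a regular volumetric source grid inside the brain shell
#'
#' Lattice points with the given spacing, centered on the model center,
#' kept when their distance from the center is at most `maskFraction`
#' times the brain radius. Ordering is deterministic: x varies fastest,
#' then y, then z.
#'
#' @param model a [SphericalHeadModel-class].
#' @param spacing lattice spacing in mm (default 6, matching a standard
#'   volumetric analysis grid).
#' @param maskFraction fraction of the brain radius used as the inclusion
#'   mask (default 0.95, keeping sources strictly inside the shell).
#' @return a [SourceGrid-class]
#' @export
buildSourceGrid <- function(model, spacing = 6, maskFraction = 0.95) {
  if (spacing <= 0) stop("spacing must be positive")
  rb <- model@radii[1]
  maskR <- maskFraction * rb
  if (spacing > maskR)
    stop("empty source grid: spacing exceeds the brain radius")
  m <- floor(maskR / spacing)
  ax <- spacing * seq(-m, m)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))  # x fastest
  keep <- sqrt(rowSums(g^2)) <= maskR
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) stop("empty source grid: spacing exceeds the brain diameter")
  g <- g + matrix(model@center, nrow(g), 3, byrow = TRUE)
  dimnames(g) <- NULL
  new("SourceGrid", positions = g, spacing = spacing, maskRadius = maskR,
      center = model@center)
}

# Per-harmonic scalp transfer coefficients t_n for the three-shell
# sphere, radii normalized to the scalp radius. Solved from the 5x5
# boundary-condition system per harmonic with row/column equilibration
# (r^(+-n) terms otherwise destroy conditioning at high order).
.shellResponse <- function(nmax, radiiNorm, cond) {
  r1 <- radiiNorm[1]; r2 <- radiiNorm[2]
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  t <- numeric(nmax)
  M <- matrix(0, 5, 5); rhs <- numeric(5)
  for (n in seq_len(nmax)) {
    M[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    rhs[1] <- -r1^(-(n + 1))
    M[2, ] <- c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
                s2 * (n + 1) * r1^(-(n + 2)), 0, 0)
    rhs[2] <- s1 * (n + 1) * r1^(-(n + 2))
    M[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    rhs[3] <- 0
    M[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-(n + 2)),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-(n + 2)))
    rhs[4] <- 0
    M[5, ] <- c(0, 0, 0, s3 * n, -s3 * (n + 1))
    rhs[5] <- 0
    cs <- c(r1^(-n), r2^(-n), r1^(n + 1), 1, r2^(n + 1))
    Ms <- sweep(M, 2, cs, `*`)
    rsc <- apply(abs(Ms), 1, max)
    y <- solve(Ms / rsc, rhs / rsc)
    x <- y * cs
    t[n] <- x[4] + x[5]
  }
  t
}

#' Compute the three-shell spherical leadfield
#'
#' Analytic Legendre-series solution of the quasi-static forward problem
#' for a current dipole inside three concentric conducting shells with an
#' insulating exterior. `gain[e, 3(v-1)+d]` is the scalp potential in
#' microvolt at electrode `e` for a unit dipole (1 nA m) at grid voxel `v`
#' oriented along axis `d`.
#'
#' The series is truncated adaptively: starting from `order` terms, the
#' truncation grows (up to `maxOrder`) until the worst-case remaining
#' tail, bounded geometrically at the most superficial source, is below
#' `tol` relative to the leading terms; a tail still above `tol` at
#' `maxOrder` is an error.
#'
#' @param model a [SphericalHeadModel-class].
#' @param electrodes co-registered [ElectrodeSet-class]; every position
#'   must lie on the scalp sphere.
#' @param grid a [SourceGrid-class] inside the brain shell.
#' @param order minimum number of series terms (default 60).
#' @param maxOrder hard cap on series terms (default 300).
#' @param tol relative truncation tolerance (default 1e-8).
#' @param referenced average-reference the columns (default `TRUE`,
#'   matching the downstream re-referenced pipeline).
#' @return a [Leadfield-class]
#' @export
computeLeadfield <- function(model, electrodes, grid, order = 60, maxOrder = 300,
                             tol = 1e-8, referenced = TRUE) {
  ctr <- model@center
  rs <- model@radii[3]
  E <- electrodes@positions - matrix(ctr, nrow(electrodes@positions), 3, byrow = TRUE)
  re <- sqrt(rowSums(E^2))
  if (any(abs(re - rs) > 1e-6))
    stop("electrodes must be co-registered onto the scalp sphere")
  V <- grid@positions - matrix(ctr, nrow(grid@positions), 3, byrow = TRUE)
  rv <- sqrt(rowSums(V^2))
  if (any(rv >= model@radii[1]))
    stop("source grid voxel outside the brain shell")
  nE <- nrow(E); nV <- nrow(V)
  # normalized geometry (scalp radius 1)
  Eh <- E / re                      # electrode unit vectors
  xs <- rv / rs                     # normalized source depths
  Vh <- V / ifelse(rv > 0, rv, 1)   # source unit vectors (center-safe)
  central <- rv < 1e-9 * rs
  radii <- model@radii / rs
  cond <- model@conductivities
  xmax <- max(xs[!central], 0)
  # choose truncation: tail of sum n t_n x^n bounded by C * N x^N/(1-x)
  N <- max(order, 10L)
  tailOK <- function(N) {
    if (xmax == 0) return(TRUE)
    # t_n is O(1); bound the tail of n x^(n-1) geometrically
    N * xmax^(N - 1) / (1 - xmax) < tol
  }
  while (!tailOK(N) && N < maxOrder) N <- min(maxOrder, ceiling(N * 1.5))
  if (!tailOK(N))
    stop(sprintf("leadfield series not converged at order %d (tail tol %.1g)", N, tol))
  tn <- .shellResponse(N, radii[1:2], cond)
  # cosine of angle between each electrode and each voxel: [nE x nV]
  CG <- Eh %*% t(Vh)
  # Legendre recurrences over the electrode x voxel table
  Pnm1 <- matrix(1, nE, nV); Pn <- CG
  Ppnm1 <- matrix(0, nE, nV); Ppn <- matrix(1, nE, nV)
  acc <- array(0, dim = c(nE, nV, 3))
  xpow <- matrix(1, nE, nV)  # x^(n-1), broadcast per column
  xsM <- matrix(xs, nE, nV, byrow = TRUE)
  for (n in seq_len(N)) {
    coefR <- tn[n] * n * xpow * Pn        # multiplies (q . r0hat)
    coefT <- tn[n] * xpow * Ppn           # multiplies q . (rhat - c r0hat)
    for (d in 1:3) {
      r0d <- matrix(Vh[, d], nE, nV, byrow = TRUE)
      red <- matrix(Eh[, d], nE, nV)
      acc[, , d] <- acc[, , d] + coefR * r0d + coefT * (red - CG * r0d)
    }
    Pnp1 <- ((2 * n + 1) * CG * Pn - n * Pnm1) / (n + 1)
    Ppnp1 <- Ppnm1 + (2 * n + 1) * Pn
    Pnm1 <- Pn; Pn <- Pnp1
    Ppnm1 <- Ppn; Ppn <- Ppnp1
    xpow <- xpow * xsM
  }
  # units: lengths mm, dipole 1 nA m, potential microvolt:
  # V = 1e3 / (4 pi sigma_brain r_scalp_mm^2) * series
  scale <- 1e3 / (4 * pi * cond[1] * rs^2)
  gain <- matrix(0, nE, 3 * nV)
  for (d in 1:3) gain[, seq(d, 3 * nV, by = 3)] <- scale * acc[, , d]
  if (any(central)) {
    # dipole at the exact center: radial/tangential split degenerates;
    # use the limit x -> 0 (only the n = 1 term survives): V = t_1 * q.rhat
    for (v in which(central)) {
      for (d in 1:3) gain[, 3 * (v - 1) + d] <- scale * tn[1] * Eh[, d]
    }
  }
  if (referenced) gain <- gain - matrix(colMeans(gain), nE, 3 * nV, byrow = TRUE)
  new("Leadfield", gain = gain, electrodes = electrodes, grid = grid,
      model = model, referenced = referenced)
}

#' Closed-form dipole potential in a homogeneous conducting sphere
#'
#' Independent closed-form solution (generating-function summation of the
#' Legendre series) for the surface potential of a current dipole inside
#' a single homogeneous sphere with insulating exterior. Used as the
#' equal-conductivity oracle for the three-shell series.
#'
#' @param model a [SphericalHeadModel-class]; only the scalp radius,
#'   center and brain conductivity are used.
#' @param dipolePos dipole position in mm (inside the sphere, off-center).
#' @param moment dipole moment vector in nA m.
#' @param electrodePos electrode position in mm (on the sphere surface).
#' @return potential in microvolt.
#' @export
homogeneousSpherePotential <- function(model, dipolePos, moment, electrodePos) {
  ctr <- model@center
  Rr <- model@radii[3]
  sig <- model@conductivities[1]
  p0 <- (dipolePos - ctr) / Rr
  pe <- (electrodePos - ctr)
  pe <- pe / vnorm(pe)
  b <- vnorm(p0)
  if (b < 1e-12) stop("dipole at the sphere center has no closed form here")
  r0h <- p0 / b
  cg <- sum(pe * r0h)
  x <- b
  g <- sqrt(1 - 2 * x * cg + x^2)
  S0 <- 2 * x * (cg - x) / g^3 + (1 / g - 1)
  S2 <- 2 * x / g^3 + x * (1 + 1 / g) / (1 - x * cg + g)
  qr0 <- sum(moment * r0h)
  qt <- sum(moment * (pe - cg * r0h))
  series <- (qr0 * S0 + qt * S2) / x
  1e3 * series / (4 * pi * sig * Rr^2)
}
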