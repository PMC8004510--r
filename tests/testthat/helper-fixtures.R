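# Shared fixtures, built in code. Geometry objects are cheap to build
# (fractions of a second) but reused across files via lazy caches.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

smallModel <- function() cached("model", sphericalHeadModel())

smallMontage <- function(n = 32) {
  cached(paste0("montage", n), fibonacciMontage(n, smallModel()))
}

smallGrid <- function(spacing = 25) {
  cached(paste0("grid", spacing), buildSourceGrid(smallModel(), spacing = spacing))
}

smallLeadfield <- function(n = 32, spacing = 25) {
  cached(paste0("lf", n, "_", spacing),
         computeLeadfield(smallModel(), smallMontage(n), smallGrid(spacing)))
}

# voxels safely away from the grid center (the closed-form oracle is
# undefined for a dipole exactly at the center)
offCenterVoxels <- function(grid) {
  which(sqrt(rowSums(grid@positions^2)) > 1)
}

# a tiny rest recording with background activity and artifacts
smallRestRecording <- function(seed = 1, duration = 30, lf = smallLeadfield()) {
  spec <- simulationSpec(sources = backgroundSources(lf, seed = seed),
                         nTrials = 0L, duration = duration,
                         samplingRate = 100, seed = seed)
  simulateRecording(spec, lf)
}
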