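# Ground-truth simulator: task-modulated band-limited dipolar sources
# mixed through the leadfield, ocular and muscle artifact generators
# with matching auxiliary reference channels, white sensor noise and
# bad-channel injections.

#' Quasi-uniform synthetic montage on the scalp sphere
#'
#' Golden-angle (Fibonacci) lattice over the upper portion of the scalp
#' sphere, emulating an EEG cap; fiducials are placed at the nasion
#' (+y), left (-x) and right (+x) preauricular points on the sphere.
#'
#' @param n number of electrodes (default 32).
#' @param model a [SphericalHeadModel-class] (default 94 mm scalp).
#' @param zMin lowest electrode height as a fraction of the scalp radius
#'   (default -0.35, roughly the cap edge).
#' @return a co-registered [ElectrodeSet-class] on the scalp sphere.
#' @export
fibonacciMontage <- function(n = 32, model = sphericalHeadModel(), zMin = -0.35) {
  rs <- model@radii[3]
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - zMin) * i / n          # from near the vertex down to zMin
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n) - 1)
  P <- cbind(rho * cos(th), rho * sin(th), z) * rs
  P <- P + matrix(model@center, n, 3, byrow = TRUE)
  fid <- rbind(nz = model@center + c(0, rs, 0),
               lpa = model@center + c(-rs, 0, 0),
               rpa = model@center + c(rs, 0, 0))
  electrodeSet(sprintf("E%02d", seq_len(n)), P, fid)
}

#' Build a simulation specification
#'
#' Defaults describe the validation study the package targets: a single
#' strong beta-band (13-30 Hz) source in left sensorimotor territory
#' whose amplitude is scaled by `depth` during 6 s movement blocks
#' alternating with 6 s rest (expected ERD `(depth^2 - 1) * 100`
#' percent), blink and muscle artifact generators, and white sensor
#' noise.
#'
#' @param sources data.frame (see [SimulationSpec-class]); `NULL` for a
#'   default single task-modulated beta source chosen by
#'   [defaultMotorSource()] once a leadfield is known.
#' @param moveDur,restDur task block durations in seconds (default 6/6).
#' @param nTrials number of move/rest cycles (0 = rest-only).
#' @param duration rest-only duration in seconds (default 240, a 4 min
#'   calibration).
#' @param blinkRate,blinkAmplitude blink events/minute (default 12) and
#'   peak sensor amplitude in microvolt (default 120).
#' @param emgRate,emgAmplitude muscle bursts/minute (default 8) and
#'   sensor amplitude in microvolt (default 25).
#' @param noiseSD white sensor noise SD in microvolt (default 2).
#' @param badChannels data.frame (`channel`, `mode`) or `NULL`.
#' @param samplingRate Hz (default 100, the realtime analysis rate).
#' @param seed RNG seed.
#' @return a [SimulationSpec-class]
#' @export
simulationSpec <- function(sources = NULL, moveDur = 6, restDur = 6, nTrials = 0L,
                           duration = 240, blinkRate = 12, blinkAmplitude = 120,
                           emgRate = 8, emgAmplitude = 25, noiseSD = 2,
                           badChannels = NULL, samplingRate = 100, seed = 1L) {
  if (is.null(sources))
    sources <- data.frame(voxel = integer(0), ox = numeric(0), oy = numeric(0),
                          oz = numeric(0), low = numeric(0), high = numeric(0),
                          amplitude = numeric(0), depth = numeric(0),
                          task = logical(0))
  if (is.null(badChannels))
    badChannels <- data.frame(channel = character(0), mode = character(0))
  new("SimulationSpec", sources = sources, moveDur = moveDur, restDur = restDur,
      nTrials = as.integer(nTrials), blinkRate = blinkRate,
      blinkAmplitude = blinkAmplitude, emgRate = emgRate,
      emgAmplitude = emgAmplitude, noiseSD = noiseSD,
      badChannels = badChannels, samplingRate = samplingRate,
      duration = duration, seed = as.integer(seed))
}

#' Default task-modulated beta source for a given leadfield
#'
#' Picks the grid voxel closest to a left-sensorimotor location (about
#' [-35, -20, 55] mm in the head frame) and returns a one-row source
#' table: beta carrier (13-30 Hz), modulation depth 0.5, tangential-ish
#' orientation.
#'
#' @param lf a [Leadfield-class].
#' @param depth modulation depth (default 0.5).
#' @param amplitude source strength in nA m (default 300, sized so the
#'   rhythm's reconstructed beta power dominates the background and
#'   sensor-noise baseline at its own voxel by more than an order of
#'   magnitude, i.e. a prominent sensorimotor rhythm).
#' @return a one-row data.frame suitable for [simulationSpec()].
#' @export
defaultMotorSource <- function(lf, depth = 0.5, amplitude = 300) {
  target <- lf@model@center + c(-35, -20, 55) *
    (lf@model@radii[1] / 94)           # scale to the model size
  d <- sqrt(colSums((t(lf@grid@positions) - target)^2))
  v <- which.min(d)
  data.frame(voxel = v, ox = 1, oy = 0, oz = 0, low = 13, high = 30,
             amplitude = amplitude, depth = depth, task = TRUE)
}

#' Distributed background brain activity for a simulation
#'
#' One broadband dipole per grid voxel with a reproducible random
#' orientation: the ongoing background activity against which ERD is
#' measured. Without it a simulated baseline consists of sensor noise
#' only, whose source-space projection is strongly depth-dependent and
#' unlike the physiological baseline ERD maps are normalized by.
#'
#' @param lf a [Leadfield-class].
#' @param amplitude per-dipole strength in nA m (default 10).
#' @param band carrier band in Hz (default broadband 1-45).
#' @param seed seed for the orientations (default 1).
#' @return data.frame of non-task sources for [simulationSpec()].
#' @export
backgroundSources <- function(lf, amplitude = 10, band = c(1, 45), seed = 1) {
  nV <- nrow(lf@grid@positions)
  U <- withSeed(seed, matrix(stats::rnorm(3 * nV), nV, 3))
  U <- U / sqrt(rowSums(U^2))
  data.frame(voxel = seq_len(nV), ox = U[, 1], oy = U[, 2], oz = U[, 3],
             low = band[1], high = band[2], amplitude = amplitude,
             depth = 1, task = FALSE)
}

#' Task-modulation amplitude envelope
#'
#' Piecewise envelope equal to 1 at rest and `a` during movement blocks,
#' with raised-cosine ramps; scaling a carrier by this envelope yields
#' an expected ERD of `(a^2 - 1) * 100` percent in the move window.
#'
#' @param n total samples.
#' @param fs sampling rate in Hz.
#' @param onsets movement block start samples.
#' @param moveDur block duration in seconds.
#' @param a modulation depth in (0, 1].
#' @param rampSec ramp duration (default 0.1 s; short enough that the
#'   ramps occupy a negligible share of a 2 s analysis window).
#' @return numeric envelope of length `n`.
#' @export
makeTaskModulation <- function(n, fs, onsets, moveDur, a, rampSec = 0.1) {
  if (a <= 0 || a > 1) stop("modulation depth must be in (0, 1]")
  if (length(onsets) > 1 && any(diff(sort(onsets)) < moveDur * fs))
    stop("movement windows overlap")
  env <- rep(1, n)
  nr <- max(1L, round(rampSec * fs))
  ramp <- (1 + cos(seq(0, pi, length.out = nr))) / 2   # 1 -> 0
  blockLen <- round(moveDur * fs)
  for (on in onsets) {
    lo <- max(1L, on); hi <- min(n, on + blockLen - 1L)
    if (lo > n) next
    env[lo:hi] <- a
    # ramps down into the block and back up at its end
    din <- lo:min(lo + nr - 1L, n)
    env[din] <- a + (1 - a) * ramp[seq_along(din)]
    dout <- hi:min(hi + nr - 1L, n)
    env[dout] <- a + (1 - a) * rev(ramp)[seq_along(dout)]
  }
  env
}

# biphasic blink template (raised-cosine up, inverted tail), unit peak
.blinkTemplate <- function(fs, durSec = 0.3) {
  n <- max(4L, round(durSec * fs))
  t <- seq(0, 1, length.out = n)
  w <- sin(pi * t)^2
  w * sin(2 * pi * t * 1.5) / max(abs(sin(pi * t)^2 * sin(2 * pi * t * 1.5)))
}

#' Simulate a recording with ground truth
#'
#' Generates `X = L J(t) + blink + muscle + noise` plus auxiliary
#' channels: `vEOG`/`hEOG` carry the blink generator's reference signal
#' (vertical dominant), `EMG1` the muscle-artifact reference, and
#' `EMGonset` bursts aligned to the true movement onsets (the channel a
#' movement-onset detector would use). All randomness is drawn from the
#' spec's seed, so identical specs give bit-identical recordings.
#'
#' Artifact construction: blinks are 300 ms biphasic pulses at Poisson
#' event times whose sensor topography is a stylized frontal gradient
#' (leadfield column of the most frontal-superior voxel, scaled, plus an
#' exponential fall-off from the nasion); muscle bursts are 20-50 Hz
#' filtered-noise bursts with topography concentrated on the lowest
#' (edge) electrodes, deliberately inside the analysis band so band-pass
#' filtering alone cannot remove them.
#'
#' @param spec a [SimulationSpec-class].
#' @param lf a [Leadfield-class] providing geometry and gain.
#' @return list with `recording` (an [EEGRecording-class]) and
#'   `groundTruth` (a [GroundTruth-class]).
#' @export
simulateRecording <- function(spec, lf) {
  fs <- spec@samplingRate
  nE <- nrow(lf@gain)
  nV <- nrow(lf@grid@positions)
  if (nrow(spec@sources) && max(spec@sources$voxel) > nV)
    stop("source voxel index outside the leadfield grid")
  cycle <- spec@moveDur + spec@restDur
  if (spec@nTrials > 0) {
    N <- as.integer(round(spec@nTrials * cycle * fs))
    onsets <- as.integer(round((spec@restDur + (seq_len(spec@nTrials) - 1) * cycle) * fs)) + 1L
  } else {
    N <- as.integer(round(spec@duration * fs))
    onsets <- integer(0)
  }
  withSeed(spec@seed, {
    X <- matrix(0, nE, N)
    nSrc <- nrow(spec@sources)
    srcSig <- matrix(0, max(nSrc, 1), N)
    envs <- matrix(1, max(nSrc, 1), N)
    if (nSrc) {
      for (s in seq_len(nSrc)) {
        row <- spec@sources[s, ]
        carrier <- bandpassFilter(matrix(stats::rnorm(N), 1), c(row$low, row$high), fs = fs)
        carrier <- carrier / stats::sd(carrier)
        env <- if (isTRUE(row$task) && length(onsets))
          makeTaskModulation(N, fs, onsets, spec@moveDur, row$depth) else rep(1, N)
        sig <- row$amplitude * env * as.numeric(carrier)
        srcSig[s, ] <- sig
        envs[s, ] <- env
        ori <- c(row$ox, row$oy, row$oz)
        ori <- ori / vnorm(ori)
        cols <- (3L * (row$voxel - 1L) + 1L):(3L * row$voxel)
        X <- X + (lf@gain[, cols] %*% ori) %*% matrix(sig, 1)
      }
    }
    # blink generator
    blinkRef <- numeric(N)
    blinkTimes <- integer(0)
    blinkTopo <- numeric(nE)
    if (spec@blinkRate > 0) {
      nBlink <- stats::rpois(1, spec@blinkRate * N / fs / 60)
      if (nBlink > 0) {
        blinkTimes <- sort(sample.int(max(N - round(0.4 * fs), 1), nBlink))
        tpl <- .blinkTemplate(fs)
        for (b in blinkTimes) {
          idx <- b:min(b + length(tpl) - 1L, N)
          blinkRef[idx] <- blinkRef[idx] + tpl[seq_along(idx)]
        }
      }
      # stylized frontal-superior topography
      frontVox <- which.max(lf@grid@positions[, 2] + 0.5 * lf@grid@positions[, 3])
      cols <- (3L * (frontVox - 1L) + 1L):(3L * frontVox)
      lcol <- lf@gain[, cols] %*% c(0, 0.3, 1)
      lcol <- lcol / max(abs(lcol))
      nzPos <- lf@electrodes@fiducials["nz", ]
      dFront <- sqrt(rowSums((lf@electrodes@positions -
                                matrix(nzPos, nE, 3, byrow = TRUE))^2))
      grad <- exp(-dFront / 60)
      blinkTopo <- as.numeric(0.5 * lcol + grad)
      blinkTopo <- blinkTopo / max(abs(blinkTopo)) * spec@blinkAmplitude
      X <- X + blinkTopo %*% matrix(blinkRef, 1)
    }
    # muscle (EMG-correlated broadband) generator
    emgRef <- numeric(N)
    emgTopo <- numeric(nE)
    if (spec@emgRate > 0) {
      nBurst <- stats::rpois(1, spec@emgRate * N / fs / 60)
      if (nBurst > 0) {
        burstStarts <- sort(sample.int(max(N - fs, 1), nBurst))
        raw <- numeric(N)
        for (b in burstStarts) {
          len <- round(stats::runif(1, 0.3, 0.8) * fs)
          idx <- b:min(b + len - 1L, N)
          w <- sin(pi * seq_along(idx) / length(idx))^2
          raw[idx] <- raw[idx] + w * stats::rnorm(length(idx))
        }
        hi <- min(50, 0.95 * fs / 2)
        emgRef <- as.numeric(bandpassFilter(matrix(raw, 1), c(20, hi), fs = fs))
        if (stats::sd(emgRef) > 0) emgRef <- emgRef / max(abs(emgRef))
      }
      z <- lf@electrodes@positions[, 3]
      emgTopo <- exp(-(z - min(z)) / 30)
      emgTopo <- emgTopo / max(emgTopo) * spec@emgAmplitude
      X <- X + emgTopo %*% matrix(emgRef, 1)
    }
    if (spec@noiseSD > 0) X <- X + matrix(stats::rnorm(nE * N, sd = spec@noiseSD), nE, N)
    # auxiliary channels: artifact references plus independent noise
    veog <- 400 * blinkRef + stats::rnorm(N, sd = 2)
    heog <- 80 * blinkRef + stats::rnorm(N, sd = 2)
    emg1 <- 60 * emgRef + stats::rnorm(N, sd = 1)
    emgOnset <- stats::rnorm(N, sd = 1)
    if (length(onsets)) {
      # EMG bursts switch on sharply at movement onset (real EMG onsets
      # are far steeper than the cortical amplitude ramps)
      gate <- makeTaskModulation(N, fs, onsets, spec@moveDur, a = 1e-3, rampSec = 0.02)
      burst <- (1 - gate) / (1 - 1e-3)     # ~1 inside move blocks, 0 at rest
      emgOnset <- emgOnset + 40 * burst * stats::rnorm(N)
    }
    labels <- c(lf@electrodes@labels, "vEOG", "hEOG", "EMG1", "EMGonset")
    data <- rbind(X, veog, heog, emg1, emgOnset)
    rec <- eegRecording(data, labels, fs,
                        auxMap = c(veog = nE + 1L, heog = nE + 2L,
                                   emg1 = nE + 3L, emgonset = nE + 4L))
    badTruth <- spec@badChannels
    for (i in seq_len(nrow(badTruth)))
      rec <- injectBadChannel(rec, badTruth$channel[i], badTruth$mode[i])
    gt <- new("GroundTruth", sourceSignals = srcSig[seq_len(max(nSrc, 1)), , drop = FALSE],
              envelopes = envs, onsets = onsets,
              blinkRef = blinkRef, emgRef = emgRef,
              blinkTopography = blinkTopo, emgTopography = emgTopo,
              blinkTimes = as.integer(blinkTimes), badChannels = badTruth)
    list(recording = rec, groundTruth = gt)
  })
}

#' Replace a channel with a pathological signal
#'
#' `"flat"` zeroes the channel (undefined correlation, the sentinel
#' case); `"hf-noise"` replaces it with strong 200-250 Hz noise (only
#' meaningful at sampling rates of at least 500 Hz), guaranteeing a
#' noise-variance outlier.
#'
#' @param rec an [EEGRecording-class].
#' @param channel EEG channel label or index.
#' @param mode `"flat"` or `"hf-noise"`.
#' @return the modified recording.
#' @export
injectBadChannel <- function(rec, channel, mode = c("flat", "hf-noise")) {
  mode <- match.arg(mode)
  idx <- if (is.character(channel)) match(channel, rec@labels) else as.integer(channel)
  if (is.na(idx)) stop("unknown channel: ", channel)
  if (idx %in% rec@auxMap) stop("cannot inject into an auxiliary channel")
  N <- ncol(rec@data)
  fs <- rec@samplingRate
  if (mode == "flat") {
    rec@data[idx, ] <- 0
  } else {
    amp <- 10 * max(stats::sd(rec@data[idx, ]), 1)
    noise <- stats::rnorm(N, sd = amp)
    if (fs >= 500) {
      hi <- min(250, 0.98 * fs / 2)
      noise <- as.numeric(bandpassFilter(matrix(noise, 1), c(200, hi), fs = fs))
    } else {
      warning("hf-noise injection below 500 Hz stays broadband (no 200-250 Hz band)")
    }
    rec@data[idx, ] <- noise + stats::rnorm(N, sd = 1)
  }
  rec
}
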