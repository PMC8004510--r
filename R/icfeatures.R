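# Automatic classification of artifactual independent components using
# three features: power correlation with auxiliary electrophysiology
# channels, goodness of a 1/f spectral fit, and kurtosis.

#' Classify artifactual independent components
#'
#' Three features per component: (1) the maximum absolute correlation
#' between the component's power (squared signal smoothed with a 1 s
#' moving average) and the identically processed auxiliary channels
#' (vEOG/hEOG/EMG); (2) the coefficient of determination of a linear fit
#' of log-power on log-frequency (a 1/f fit; Welch spectrum with 2 s
#' windows, 50% overlap) over the analysis band, counted only when the
#' fitted slope is negative; (3) the excess kurtosis of the component
#' time course. A component is artifactual when at least one feature
#' exceeds its threshold. Missing auxiliary channels disable feature 1
#' with a message; classification proceeds on the remaining features.
#'
#' @param ica an [ICADecomposition-class].
#' @param rec the calibration [EEGRecording-class] providing the
#'   auxiliary channels and sampling rate.
#' @param thresholds named numeric: `power` (default 0.3), `spectrum`
#'   (R^2, default 0.8), `kurtosis` (excess, default 10).
#' @param band frequency range (Hz) of the 1/f fit (default `c(1, 45)`
#'   clipped to Nyquist).
#' @return a data.frame with one row per component: the three features,
#'   per-feature exceedance flags and the overall `artifact` flag.
#' @export
classifyArtifactICs <- function(ica, rec,
                                thresholds = c(power = 0.3, spectrum = 0.8, kurtosis = 10),
                                band = c(1, 45)) {
  S <- ica@S
  nS <- nrow(S)
  fs <- rec@samplingRate
  smoothW <- round(fs)              # 1 s moving average
  powerCorr <- rep(NA_real_, nS)
  if (length(rec@auxMap)) {
    auxPow <- t(apply(rec@data[rec@auxMap, , drop = FALSE], 1,
                      function(a) movingAverage(a^2, smoothW)))
    for (i in seq_len(nS)) {
      p <- movingAverage(S[i, ]^2, smoothW)
      cc <- suppressWarnings(apply(auxPow, 1, stats::cor, y = p))
      powerCorr[i] <- max(abs(cc), na.rm = TRUE)
    }
  } else {
    message("no auxiliary channels: power-correlation feature unavailable")
  }
  hi <- min(band[2], 0.98 * fs / 2)
  spectrumR2 <- slope <- rep(NA_real_, nS)
  for (i in seq_len(nS)) {
    ps <- welchPSD(S[i, ], fs, windowSec = 2)
    sel <- ps$freq >= max(band[1], 1e-9) & ps$freq <= hi & ps$psd > 0
    if (sum(sel) >= 4) {
      fit <- stats::lm.fit(cbind(1, log(ps$freq[sel])), log(ps$psd[sel]))
      ssTot <- sum((log(ps$psd[sel]) - mean(log(ps$psd[sel])))^2)
      spectrumR2[i] <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 0
      slope[i] <- fit$coefficients[2]
    }
  }
  kurt <- apply(S, 1, e1071::kurtosis, type = 1)   # excess kurtosis
  overPower <- !is.na(powerCorr) & powerCorr > thresholds[["power"]]
  overSpectrum <- !is.na(spectrumR2) & spectrumR2 > thresholds[["spectrum"]] &
    !is.na(slope) & slope < 0
  overKurtosis <- is.finite(kurt) & kurt > thresholds[["kurtosis"]]
  data.frame(component = seq_len(nS),
             powerCorrelation = powerCorr,
             spectrumR2 = spectrumR2, spectrumSlope = slope,
             kurtosis = kurt,
             overPower = overPower, overSpectrum = overSpectrum,
             overKurtosis = overKurtosis,
             artifact = overPower | overSpectrum | overKurtosis)
}

#' Attach artifact flags to an ICA decomposition
#'
#' @param ica an [ICADecomposition-class].
#' @param features the table from [classifyArtifactICs()], or an integer
#'   vector of artifactual component indices.
#' @return the updated [ICADecomposition-class].
#' @export
markArtifactICs <- function(ica, features) {
  idx <- if (is.data.frame(features)) which(features$artifact) else as.integer(features)
  ica@artifactIndices <- idx
  validObject(ica)
  ica
}

#' Unmixing rows of the artifactual components
#'
#' @param ica an [ICADecomposition-class] with artifact flags set.
#' @return matrix `[n_A x n_E]` (zero rows when no component is flagged).
#' @export
artifactUnmixing <- function(ica) {
  ica@W[ica@artifactIndices, , drop = FALSE]
}
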