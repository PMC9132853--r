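#' Root-mean-square amplitude
#'
#' `sqrt(mean(x^2))` over the full analysis window.
#'
#' @param x numeric vector.
#' @return The RMS value.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty series")
  sqrt(mean(x^2))
}

#' Periodogram power spectral density
#'
#' Single-window periodogram of the zero-padded series (transient signals,
#' no segment averaging). The one-sided spectrum is normalised so that
#' `sum(power) * df` equals the time-domain power `mean(x^2)` of the
#' unpadded window (Parseval). Optionally the spectrum is divided by a
#' reference total power, the convention used when comparing spectra across
#' experiments.
#'
#' @param x numeric vector, sampled at `fs`.
#' @param fs sampling frequency, Hz (10 kHz for the virtual recordings).
#' @param pad zero-padding factor; the FFT length is the next power of two
#'   at least `pad * length(x)`.
#' @param ref_power optional reference total power to normalise by.
#' @return A data.frame with `freq` (Hz) and `power`.
#' @export
psd <- function(x, fs = 10000, pad = 4, ref_power = NULL) {
  n <- length(x)
  if (!n) stop("empty series")
  nfft <- 2^ceiling(log2(max(2, n * pad)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1)
  p <- Mod(X[half])^2 / (fs * n)
  scale <- rep(2, length(half))
  scale[1] <- 1
  if (nfft %% 2 == 0) scale[length(half)] <- 1
  p <- p * scale
  if (!is.null(ref_power)) p <- p / ref_power
  data.frame(freq = (half - 1) * fs / nfft, power = p)
}

#' Power-weighted mean frequency
#'
#' `sum(f * P) / sum(P)` of a power spectrum, the standard EMG mean
#' frequency (MNF).
#'
#' @param spectrum a data.frame as from [psd()].
#' @return Mean frequency in Hz (0 for an all-zero spectrum).
#' @export
mean_frequency <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (tot == 0) return(0)
  sum(spectrum$freq * spectrum$power) / tot
}

#' Coefficient of variation across channels
#'
#' `100 * sd / mean` with the population standard deviation, applied to
#' per-channel RMS values to quantify inter-channel variability (spatial
#' selectivity) of a sensor array.
#'
#' @param values numeric vector (e.g. per-channel RMS).
#' @return CoV in percent.
#' @export
cov_across_channels <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean of the channel values is zero")
  100 * sqrt(mean((values - m)^2)) / m
}

#' Distance from the null channel to the RMS maximum
#'
#' For magnetic components whose amplitude vanishes directly over the
#' source (fibre-aligned and surface-normal components), the distance
#' between the channel with minimal |RMS| and the channel with maximal RMS
#' along a profile is a resolution-limited proxy for the source depth.
#'
#' @param values per-channel RMS values along a line.
#' @param positions channel coordinates along the line, cm.
#' @return Distance in cm (resolved to the channel pitch).
#' @export
zero_to_max_distance <- function(values, positions) {
  stopifnot(length(values) == length(positions), length(values) > 1)
  abs(positions[which.max(values)] - positions[which.min(abs(values))])
}

#' Extract a channel recording from a run
#'
#' Returns the measurement vector time series `[phi, B_l, B_t, B_n]` of the
#' recorded channel nearest to `position` on the recording surface (the
#' muscle surface for an isolated muscle, the body surface otherwise).
#'
#' @param run an `mm_run` from [run_experiment()].
#' @param position `(x_l, x_t)` coordinates in cm.
#' @return A `channel_recording`: list with `position`, `time` (ms),
#'   `series` (matrix with columns `phi` (mV), `B_l`, `B_t`, `B_n` (pT);
#'   magnetic columns are `NA` for EMG-only channels) and `sampling_rate`
#'   (Hz).
#' @export
sample_channel <- function(run, position) {
  stopifnot(inherits(run, "mm_run"), length(position) >= 2)
  pos <- do.call(rbind, lapply(run$channels, `[[`, "position"))
  d2 <- (pos[, 1] - position[1])^2 + (pos[, 2] - position[2])^2
  if (min(d2) > (2 * run$config$spacing)^2)
    stop("no recorded channel near the requested position")
  run$channels[[which.min(d2)]]
}
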