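#' Per-epoch power spectrum (Welch, Hamming, 50% overlap)
#'
#' Computes a one-sided power spectrum from an epoch of samples by averaging
#' Hamming-windowed 1024-point FFT segments with 50% overlap, the convention
#' used by clinical EEG software. An epoch shorter than the FFT length is
#' analysed as a single zero-padded segment. The window is power-normalised so
#' that the summed spectrum approximates the mean square of the signal, and
#' the zero-frequency bin is removed.
#'
#' @param samples numeric vector of voltages (microvolts)
#' @param sampling_rate sampling frequency, Hz
#' @param nfft FFT segment length (default 1024)
#' @param epoch_start_time epoch start time carried through to the result
#' @return object of class `power_spectrum`: list with `frequencies` (Hz, zero
#'   bin absent), `power` (microvolt^2 per bin) and `epoch_start_time`
#' @export
power_spectrum <- function(samples, sampling_rate, nfft = 1024,
                           epoch_start_time = NA_real_) {
  if (length(samples) == 0L) stop("empty epoch")
  if (anyNA(samples) || any(!is.finite(samples))) stop("epoch contains NA/NaN samples")
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  n <- length(samples)
  seg_len <- min(n, nfft)
  w <- signal::hamming(seg_len)
  u <- sum(w^2)
  step <- floor(nfft / 2)
  if (n <= nfft) {
    starts <- 1L
  } else {
    starts <- seq(1L, n - nfft + 1L, by = step)
  }
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- samples[s:(s + seg_len - 1L)]
    y <- c(seg * w, numeric(nfft - seg_len))
    acc <- acc + Mod(stats::fft(y))^2
  }
  acc <- acc / length(starts)
  # one-sided, power-normalised: summed power ~ mean square of the signal
  half <- nfft / 2
  p <- acc[2:(half + 1)] / (nfft * u)
  p[1:(half - 1)] <- 2 * p[1:(half - 1)]   # double all interior bins, not Nyquist
  freqs <- (1:half) * sampling_rate / nfft
  structure(list(frequencies = freqs, power = p,
                 epoch_start_time = epoch_start_time),
            class = "power_spectrum")
}

#' Spectral features of one epoch
#'
#' Derives the detection variables from a power spectrum: total power Ptot
#' (sum over all retained bins, microvolt^2), median frequency F50 (smallest
#' grid frequency at which cumulative power reaches 50% of Ptot), spectral
#' edge F95 (95% analogue), and the fractional contribution of each EEG band.
#' Band fractions are normalised by the total in-band power (1 Hz to the Gamma
#' cap) so they sum to one; after 1-30 Hz filtering this denominator is
#' numerically indistinguishable from Ptot.
#'
#' An all-zero spectrum yields an undefined-feature marker (`defined = FALSE`,
#' `NA` features) rather than numbers.
#'
#' @param spectrum a [power_spectrum()]
#' @param band_edges band definition table, default [eeg_bands()] capped at
#'   the spectrum's maximum frequency
#' @return list of class `spectral_features` with `ptot`, `f50`, `f95`,
#'   `band_fraction` (named, Delta..Gamma), `epoch_start_time`, `defined`
#' @export
spectral_features <- function(spectrum, band_edges = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$frequencies
  p <- spectrum$power
  if (any(p < 0)) stop("negative power bin")
  if (is.null(band_edges)) band_edges <- eeg_bands(nyquist = max(f))
  ptot <- sum(p)
  out <- list(ptot = ptot, f50 = NA_real_, f95 = NA_real_,
              band_fraction = stats::setNames(rep(NA_real_, nrow(band_edges)),
                                              band_edges$band),
              epoch_start_time = spectrum$epoch_start_time,
              defined = FALSE)
  class(out) <- "spectral_features"
  if (ptot <= 0) return(out)
  cp <- cumsum(p)
  out$f50 <- f[which(cp >= 0.50 * ptot)[1]]
  out$f95 <- f[which(cp >= 0.95 * ptot)[1]]
  bp <- vapply(seq_len(nrow(band_edges)), function(i) {
    sum(p[f > band_edges$lower[i] & f <= band_edges$upper[i]])
  }, numeric(1))
  tot_in_band <- sum(bp)
  out$band_fraction <- stats::setNames(
    if (tot_in_band > 0) bp / tot_in_band else rep(NA_real_, length(bp)),
    band_edges$band)
  out$defined <- tot_in_band > 0
  out
}

#' Spectral feature series over all epochs
#'
#' Applies [power_spectrum()] and [spectral_features()] to every epoch of an
#' [epoch_split()] result, preserving order and phase tags. Epochs whose
#' features are undefined (zero power) are kept as flagged rows, never
#' dropped, so downstream run-length rules see them.
#'
#' @param epochs an `epoch_series`
#' @param nfft FFT segment length passed to [power_spectrum()]
#' @return a tibble with one row per epoch: `epoch_start_s`, `phase`,
#'   `ptot_uv2`, `f50_hz`, `f95_hz`, `delta_frac`, `theta_frac`, `alpha_frac`,
#'   `beta_frac`, `gamma_frac`, `defined`
#' @export
feature_series <- function(epochs, nfft = 1024) {
  stopifnot(inherits(epochs, "epoch_series"))
  n <- length(epochs$samples)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ft <- spectral_features(power_spectrum(epochs$samples[[i]],
                                           epochs$sampling_rate, nfft,
                                           epoch_start_time = epochs$start_s[i]))
    bf <- ft$band_fraction
    rows[[i]] <- tibble::tibble(
      epoch_start_s = epochs$start_s[i],
      phase = epochs$phase[i],
      ptot_uv2 = ft$ptot,
      f50_hz = ft$f50, f95_hz = ft$f95,
      delta_frac = bf[["Delta"]], theta_frac = bf[["Theta"]],
      alpha_frac = bf[["Alpha"]], beta_frac = bf[["Beta"]],
      gamma_frac = bf[["Gamma"]],
      defined = ft$defined)
  }
  dplyr::bind_rows(rows)
}

#' Export a spectral feature series as CSV
#'
#' @param series tibble from [feature_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_features <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
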