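# Independent oracles and small fixture builders shared across tests.

# Brute-force one-sided power spectrum of a single Hamming-windowed segment,
# computed from the DFT definition (explicit complex exponential sums), kept
# deliberately independent of the package's fft-based implementation.
brute_force_spectrum <- function(x, fs, nfft = 1024) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  y <- c(x * w, numeric(nfft - n))
  k <- 0:(nfft - 1)
  half <- nfft / 2
  p <- vapply(1:half, function(m) {
    Xm <- sum(y * exp(-2i * pi * m * k / nfft))
    Mod(Xm)^2
  }, numeric(1))
  p <- p / (nfft * sum(w^2))
  p[1:(half - 1)] <- 2 * p[1:(half - 1)]
  list(frequencies = (1:half) * fs / nfft, power = p)
}

# A power_spectrum object with given bin powers (for feature-rule fixtures).
make_spectrum <- function(frequencies, power, t = 0) {
  structure(list(frequencies = frequencies, power = power,
                 epoch_start_time = t),
            class = "power_spectrum")
}

# A feature tibble row set for detector tests: exposure epochs at 0..n-1 s
# with given per-epoch values, preceded by optional baseline epochs.
make_features <- function(f50, delta, ptot, phase = "exposure",
                          start = seq_along(f50) - 1, defined = TRUE) {
  tibble::tibble(
    epoch_start_s = start, phase = phase,
    ptot_uv2 = ptot, f50_hz = f50, f95_hz = f50 + 5,
    delta_frac = delta,
    theta_frac = pmax(0, (1 - delta) / 4), alpha_frac = pmax(0, (1 - delta) / 4),
    beta_frac = pmax(0, (1 - delta) / 2), gamma_frac = 0,
    defined = defined)
}

make_baseline <- function(median_f50 = 20, median_delta = 0.20, median_ptot = 200) {
  structure(list(median_ptot = median_ptot, median_f50 = median_f50,
                 median_delta_fraction = median_delta,
                 n_epochs_used = 10, n_epochs_excluded = 0),
            class = "baseline_summary")
}

# Short synthetic trace helper for IO/filter tests.
sine_trace <- function(freq, fs = 1000, baseline_s = 2, exposure_s = 4,
                       amplitude = 10) {
  t <- seq(-baseline_s, exposure_s - 1 / fs, by = 1 / fs)
  eeg_trace(amplitude * sin(2 * pi * freq * t), fs,
            baseline_window = c(-baseline_s, 0),
            exposure_window = c(0, exposure_s))
}
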