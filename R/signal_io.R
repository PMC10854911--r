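#' Single-channel EEG trace
#'
#' Container for a uniformly sampled single-channel EEG voltage series in
#' microvolts. Trace time is anchored so that t = 0 is the start of gas
#' exposure (lift-descent start); the conscious baseline occupies negative
#' time. The sample vector covers `[baseline_window[1], exposure_window[2])`
#' contiguously.
#'
#' @param samples numeric vector of voltages, microvolts
#' @param sampling_rate sampling frequency in Hz (> 0)
#' @param baseline_window length-2 numeric, `(start, end)` of the baseline in
#'   trace time (seconds); `end` must equal `exposure_window[1]`
#' @param exposure_window length-2 numeric, `(start, end)` of gas exposure
#' @param subject_id,treatment_label identifying labels
#' @return an object of class `eeg_trace`
#' @export
eeg_trace <- function(samples, sampling_rate,
                      baseline_window = c(-90, 0),
                      exposure_window = c(0, 240),
                      subject_id = "bird", treatment_label = "AIR") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector")
  if (anyNA(samples)) stop("samples contain NA/NaN")
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  baseline_window <- as.numeric(baseline_window)
  exposure_window <- as.numeric(exposure_window)
  if (length(baseline_window) != 2L || length(exposure_window) != 2L)
    stop("windows must be length-2 (start, end)")
  if (baseline_window[1] > baseline_window[2])
    stop("baseline window start must be <= end")
  if (exposure_window[1] >= exposure_window[2])
    stop("exposure window must have positive length")
  if (abs(baseline_window[2] - exposure_window[1]) > 1e-9)
    stop("baseline must end where exposure starts")
  dur <- exposure_window[2] - baseline_window[1]
  n_expect <- round(dur * sampling_rate)
  if (length(samples) != n_expect)
    stop(sprintf("expected %d samples for %.3f s at %g Hz, got %d",
                 n_expect, dur, sampling_rate, length(samples)))
  structure(list(
    samples = as.numeric(samples),
    sampling_rate = sampling_rate,
    baseline_window = baseline_window,
    exposure_window = exposure_window,
    subject_id = as.character(subject_id),
    treatment_label = as.character(treatment_label)
  ), class = "eeg_trace")
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf(
    "<eeg_trace> %s (%s): %.0f Hz, baseline [%g, %g) s, exposure [%g, %g) s\n",
    x$subject_id, x$treatment_label, x$sampling_rate,
    x$baseline_window[1], x$baseline_window[2],
    x$exposure_window[1], x$exposure_window[2]))
  invisible(x)
}

# trace time of the first sample
trace_t0 <- function(trace) trace$baseline_window[1]

#' Zero-phase band-pass filter
#'
#' Applies the squared magnitude response of an order-`order` Butterworth
#' band-pass (the transfer function a forward-backward pass realises) in the
#' frequency domain, so filtering is exactly zero-phase and introduces no group
#' delay that would bias detected onset times. The default 1-30 Hz passband
#' removes movement drift and mains/electromyographic interference while
#' keeping the Delta-Beta range the detection rules use.
#'
#' @param trace an [eeg_trace()]
#' @param low,high passband corner frequencies in Hz,
#'   `0 < low < high < sampling_rate / 2`
#' @param order Butterworth order per pass (default 4)
#' @return the filtered `eeg_trace`
#' @export
bandpass <- function(trace, low = 1, high = 30, order = 4) {
  stopifnot(inherits(trace, "eeg_trace"))
  fs <- trace$sampling_rate
  if (!is_scalar_number(low) || !is_scalar_number(high) ||
      low <= 0 || low >= high || high >= fs / 2)
    stop("need 0 < low < high < sampling_rate/2")
  trace$samples <- fft_bandpass(trace$samples, fs, low, high, order)
  trace
}

# Frequency-domain core of the zero-phase band-pass: multiplies the spectrum
# by the squared Butterworth magnitude (the response a forward-backward time
# domain pass realises), avoiding the numerical fragility of high-Q recursive
# filters at 1 Hz corners on 1 kHz data.
fft_bandpass <- function(x, fs, low, high, order = 4) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- abs(ifelse(k <= n / 2, k, k - n)) * fs / n
  h2 <- 1 / (1 + (f / high)^(2 * order))
  hp <- ifelse(f == 0, 0,
               1 / (1 + (low / pmax(f, .Machine$double.eps))^(2 * order)))
  Re(stats::fft(stats::fft(x) * h2 * hp, inverse = TRUE)) / n
}

#' Split a trace into fixed-length analysis epochs
#'
#' Cuts the baseline and exposure windows independently into contiguous,
#' non-overlapping epochs of `epoch_length` seconds (default 1 s). Trailing
#' samples that do not fill a whole epoch are discarded. Epoch start times are
#' relative to the start of their phase.
#'
#' @param trace an [eeg_trace()]
#' @param epoch_length epoch duration in seconds (> 0)
#' @return an object of class `epoch_series`: a list with `epoch_length`,
#'   `sampling_rate`, and parallel vectors/lists `phase`, `start_s`, `samples`
#' @export
epoch_split <- function(trace, epoch_length = 1) {
  stopifnot(inherits(trace, "eeg_trace"))
  if (!is_scalar_number(epoch_length) || epoch_length <= 0)
    stop("epoch_length must be positive")
  fs <- trace$sampling_rate
  spe <- round(epoch_length * fs)
  if (spe < 1) stop("epoch_length shorter than one sample")
  bl_len <- diff(trace$baseline_window)
  ex_len <- diff(trace$exposure_window)
  if (ex_len < epoch_length - 1e-9)
    stop("epoch_length longer than the exposure window")
  if (bl_len > 0 && bl_len < epoch_length - 1e-9)
    stop("epoch_length longer than the (non-empty) baseline window")

  cut_phase <- function(offset_samples, phase_len) {
    n_ep <- floor(phase_len / epoch_length + 1e-9)
    if (n_ep == 0) return(list(start = numeric(0), blocks = list()))
    starts <- (seq_len(n_ep) - 1) * epoch_length
    blocks <- lapply(seq_len(n_ep), function(i) {
      i0 <- offset_samples + (i - 1) * spe
      trace$samples[(i0 + 1):(i0 + spe)]
    })
    list(start = starts, blocks = blocks)
  }
  n_bl_samples <- round(bl_len * fs)
  bl <- cut_phase(0, bl_len)
  ex <- cut_phase(n_bl_samples, ex_len)
  structure(list(
    epoch_length = epoch_length,
    sampling_rate = fs,
    phase = c(rep("baseline", length(bl$start)), rep("exposure", length(ex$start))),
    start_s = c(bl$start, ex$start),
    samples = c(bl$blocks, ex$blocks)
  ), class = "epoch_series")
}

#' Write an EEG trace to disk
#'
#' Two on-disk representations are supported: a two-column delimited text file
#' (`time_s, uV`) with a commented metadata header, and a minimal single-signal
#' European Data Format (EDF) file (16-bit samples, 1 s data records, physical
#' unit microvolts). EDF requires whole-second windows. Window metadata is
#' carried in the EDF recording-identification field so that this package's
#' reader round-trips it.
#'
#' @param trace an [eeg_trace()]
#' @param path output file path
#' @param format `"csv"` or `"edf"`; default inferred from the file extension
#' @return `path`, invisibly
#' @export
write_signal <- function(trace, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(trace, "eeg_trace"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") write_signal_csv(trace, path) else write_signal_edf(trace, path)
  invisible(path)
}

#' Read an EEG trace from disk
#'
#' Counterpart of [write_signal()]. Samples are rescaled to microvolts when the
#' file declares millivolts or volts. Files missing the sampling rate or the
#' physical unit are rejected; CSV time stamps are checked for uniform
#' sampling.
#'
#' @param path input file path
#' @param format `"csv"` or `"edf"`; default inferred from the extension
#' @param baseline_window,exposure_window optional window overrides (seconds in
#'   trace time); needed for files written by other software that cannot carry
#'   window metadata
#' @return an [eeg_trace()]
#' @export
read_signal <- function(path, format = c("auto", "csv", "edf"),
                        baseline_window = NULL, exposure_window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  tr <- if (format == "csv") read_signal_csv(path) else read_signal_edf(path)
  if (!is.null(baseline_window) || !is.null(exposure_window)) {
    tr <- eeg_trace(tr$samples, tr$sampling_rate,
                    baseline_window %||% tr$baseline_window,
                    exposure_window %||% tr$exposure_window,
                    tr$subject_id, tr$treatment_label)
  }
  tr
}

unit_to_uv <- function(unit) {
  switch(tolower(trimws(unit)),
         "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
         stop("unsupported physical unit: ", unit))
}

write_signal_csv <- function(trace, path) {
  fs <- trace$sampling_rate
  t <- trace_t0(trace) + (seq_along(trace$samples) - 1) / fs
  hdr <- c(
    "# stunEEG trace v1",
    sprintf("# sampling_rate_hz: %.10g", fs),
    sprintf("# baseline_window_s: %.10g %.10g",
            trace$baseline_window[1], trace$baseline_window[2]),
    sprintf("# exposure_window_s: %.10g %.10g",
            trace$exposure_window[1], trace$exposure_window[2]),
    sprintf("# subject_id: %s", trace$subject_id),
    sprintf("# treatment_label: %s", trace$treatment_label),
    "# unit: uV",
    "time_s,uV")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.6f,%.6f", t, trace$samples), con)
}

read_signal_csv <- function(path) {
  lines <- readLines(path, n = 200L)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  fs <- get("sampling_rate_hz")
  unit <- get("unit")
  if (is.null(fs)) stop("CSV trace is missing '# sampling_rate_hz:' metadata")
  if (is.null(unit)) stop("CSV trace is missing '# unit:' metadata")
  fs <- as.numeric(fs)
  dat <- utils::read.csv(path, comment.char = "#", header = TRUE)
  if (!all(c("time_s") %in% names(dat)) || ncol(dat) < 2)
    stop("CSV trace must have columns time_s and a voltage column")
  if (nrow(dat) < 2) stop("CSV trace truncated: fewer than 2 samples")
  dt <- diff(dat$time_s)
  if (max(abs(dt - 1 / fs)) > 0.01 / fs)
    stop("non-uniform sampling in CSV trace")
  bw <- get("baseline_window_s")
  ew <- get("exposure_window_s")
  t0 <- dat$time_s[1]
  n <- nrow(dat)
  if (is.null(bw) || is.null(ew)) {
    bw <- c(t0, t0)
    ew <- c(t0, t0 + n / fs)
  } else {
    bw <- as.numeric(strsplit(bw, "\\s+")[[1]])
    ew <- as.numeric(strsplit(ew, "\\s+")[[1]])
  }
  eeg_trace(dat[[2]] * unit_to_uv(unit), fs, bw, ew,
            get("subject_id") %||% "bird", get("treatment_label") %||% "AIR")
}

# ---- minimal single-signal EDF ---------------------------------------------
# EDF: 256-byte fixed header + 256-byte signal header, then 1 s data records of
# little-endian int16. Physical scaling is linear between the declared
# physical and digital extrema. No R package for EDF is used; the subset
# written here (one signal, integer-second records) is all the pipeline needs.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)  # left-justified, space padded
}

write_signal_edf <- function(trace, path) {
  fs <- trace$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  n <- length(trace$samples)
  nrec <- n / fs
  if (abs(nrec - round(nrec)) > 1e-9)
    stop("EDF writer requires a whole number of 1 s records; use format = 'csv'")
  nrec <- round(nrec)
  amax <- max(abs(trace$samples), 1e-6)
  pmax <- signif(amax * 1.0001, 6)
  pmin <- -pmax
  dmax <- 32767; dmin <- -32768
  scale <- (pmax - pmin) / (dmax - dmin)
  dig <- as.integer(round((trace$samples - pmin) / scale) + dmin)
  dig <- as.integer(pmin(pmax(dig, dmin), dmax))

  rec_id <- sprintf("BASELINE_S=%g EXPOSURE_S=%g TREAT=%s",
                    diff(trace$baseline_window), diff(trace$exposure_window),
                    trace$treatment_label)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)                      # version
  put(trace$subject_id, 80)        # patient identification
  put(rec_id, 80)                  # recording identification
  put("01.01.26", 8); put("00.00.00", 8)
  put("512", 8)                    # header bytes
  put("", 44)                      # reserved
  put(as.character(nrec), 8)
  put("1", 8)                      # record duration, s
  put("1", 4)                      # number of signals
  put("EEG", 16)                   # label
  put("subdermal needle", 80)      # transducer
  put("uV", 8)
  put(format(pmin, scientific = FALSE), 8)
  put(format(pmax, scientific = FALSE), 8)
  put(as.character(dmin), 8)
  put(as.character(dmax), 8)
  put("HP:0.1Hz LP:100Hz", 80)
  put(as.character(as.integer(fs)), 8)
  put("", 32)
  writeBin(dig, con, size = 2L, endian = "little")
}

read_signal_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 512) stop("EDF file truncated: header incomplete")
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  get(8)                       # version
  subject <- get(80)
  rec_id <- get(80)
  get(8); get(8)
  hdr_bytes <- as.numeric(get(8))
  get(44)
  nrec <- as.numeric(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.numeric(get(4))
  if (is.na(ns) || ns != 1) stop("only single-signal EDF files are supported")
  if (is.na(nrec) || is.na(rec_dur)) stop("EDF header missing record structure")
  get(16); get(80)
  unit <- get(8)
  if (!nzchar(unit)) stop("EDF file does not declare a physical unit")
  pmin <- as.numeric(get(8)); pmax <- as.numeric(get(8))
  dmin <- as.numeric(get(8)); dmax <- as.numeric(get(8))
  get(80)
  spr <- as.numeric(get(8))
  get(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("EDF signal header incomplete")
  fs <- spr / rec_dur
  n <- nrec * spr
  if (sz < hdr_bytes + 2 * n) stop("EDF file truncated: fewer samples than declared")
  dig <- readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
  if (length(dig) != n) stop("EDF file truncated while reading samples")
  phys <- pmin + (dig - dmin) * (pmax - pmin) / (dmax - dmin)
  phys <- phys * unit_to_uv(unit)

  bl <- sub(".*BASELINE_S=([0-9.eE+-]+).*", "\\1", rec_id)
  ex <- sub(".*EXPOSURE_S=([0-9.eE+-]+).*", "\\1", rec_id)
  treat <- if (grepl("TREAT=", rec_id)) sub(".*TREAT=(\\S+).*", "\\1", rec_id) else "AIR"
  total <- n / fs
  if (grepl("BASELINE_S=", rec_id) && grepl("EXPOSURE_S=", rec_id)) {
    bl <- as.numeric(bl); ex <- as.numeric(ex)
    bw <- c(-bl, 0); ew <- c(0, ex)
  } else {
    bw <- c(0, 0); ew <- c(0, total)
  }
  eeg_trace(phys, fs, bw, ew, subject, treat)
}
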