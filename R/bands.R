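#' EEG frequency band definitions
#'
#' The canonical avian-EEG band edges used throughout the package: Delta
#' (1-4 Hz; the sub-1 Hz remainder is removed by the 1-30 Hz band-pass and the
#' dropped zero-frequency bin), Theta (4-8 Hz), Alpha (8-13 Hz), Beta
#' (13-32 Hz) and Gamma (32-200 Hz, capped at Nyquist). A band covers
#' frequencies `f` with `lower < f <= upper`.
#'
#' @param nyquist optional Nyquist frequency (Hz); when supplied the Gamma
#'   upper edge is capped at `min(200, nyquist)`.
#' @return a data.frame with columns `band`, `lower`, `upper`
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function(nyquist = NULL) {
  b <- data.frame(
    band  = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    lower = c(1, 4, 8, 13, 32),
    upper = c(4, 8, 13, 32, 200),
    stringsAsFactors = FALSE
  )
  if (!is.null(nyquist)) b$upper[b$band == "Gamma"] <- min(200, nyquist)
  b
}

#' Gas-stunning treatment labels
#'
#' Two-phase CO2 (40C90C: <40% CO2 for 2 min then >90% CO2 for 2 min),
#' 40% CO2 / 60% N2 (40C60N), 20% CO2 / 80% N2 (20C80N), and an atmospheric-air
#' control (AIR).
#'
#' @return character vector of treatment labels
#' @export
treatment_labels <- function() c("40C90C", "40C60N", "20C80N", "AIR")
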