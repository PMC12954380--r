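#' Processing configuration for spectro-titration analysis
#'
#' Bundles the physical constants, spectral windows and electrode offset used
#' throughout the titration pipeline. Defaults correspond to a one-electron
#' titration followed in the 465--485 nm band, baseline-corrected against the
#' featureless 650--700 nm region, at 293 K, measured against an Ag/AgCl
#' reference electrode sitting +280 mV above the standard hydrogen electrode
#' (SHE) at 100 mM KCl.
#'
#' @param baseline_window numeric length-2, nm. Wavelength window (inclusive)
#'   whose mean absorbance is subtracted from each spectrum.
#' @param analysis_band numeric length-2, nm. Window (inclusive) over which
#'   absorbance is averaged to follow the redox transition.
#' @param faraday Faraday constant, J mol^-1 V^-1.
#' @param gas_constant ideal gas constant, J mol^-1 K^-1.
#' @param temperature absolute temperature, K.
#' @param electrons_z number of electrons in the transition (>= 1).
#' @param reference_offset reference-electrode offset vs SHE, mV. Added to
#'   applied potentials by [to_she()].
#'
#' @return An object of class `processing_config` (a named list).
#' @examples
#' cfg <- processing_config()
#' cfg$analysis_band
#' @export
processing_config <- function(baseline_window = c(650, 700),
                              analysis_band = c(465, 485),
                              faraday = 96485.34,
                              gas_constant = 8.3145,
                              temperature = 293,
                              electrons_z = 1L,
                              reference_offset = 280) {
  stopifnot(length(baseline_window) == 2L, length(analysis_band) == 2L)
  if (baseline_window[1] >= baseline_window[2])
    stop("baseline_window must satisfy lower < upper")
  if (analysis_band[1] >= analysis_band[2])
    stop("analysis_band must satisfy lower < upper")
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (electrons_z < 1) stop("electrons_z must be >= 1")
  structure(list(
    baseline_window = as.numeric(baseline_window),
    analysis_band = as.numeric(analysis_band),
    faraday = faraday,
    gas_constant = gas_constant,
    temperature = temperature,
    electrons_z = as.integer(electrons_z),
    reference_offset = reference_offset
  ), class = "processing_config")
}

#' @export
print.processing_config <- function(x, ...) {
  cat("Titration processing configuration\n")
  cat(sprintf("  baseline window : %g-%g nm\n",
              x$baseline_window[1], x$baseline_window[2]))
  cat(sprintf("  analysis band   : %g-%g nm\n",
              x$analysis_band[1], x$analysis_band[2]))
  cat(sprintf("  T = %g K, z = %d, F = %g J mol^-1 V^-1, R = %g J mol^-1 K^-1\n",
              x$temperature, x$electrons_z, x$faraday, x$gas_constant))
  cat(sprintf("  reference offset: %+g mV vs SHE\n", x$reference_offset))
  invisible(x)
}

# Thermal voltage RT/(zF) in mV; the natural width scale of the transition.
thermal_mV <- function(config) {
  1000 * config$gas_constant * config$temperature /
    (config$electrons_z * config$faraday)
}

#' Convert an applied potential to the SHE scale
#'
#' Potentials are set by the potentiostat relative to the reference electrode
#' (here Ag/AgCl ink at 100 mM KCl); reporting is on the standard hydrogen
#' electrode (SHE) scale, obtained by adding the reference offset.
#'
#' @param applied_potential numeric, mV vs the reference electrode.
#' @param config a [processing_config()].
#' @return numeric, mV vs SHE.
#' @examples
#' to_she(0)    # +280
#' to_she(55)   # +335
#' @export
to_she <- function(applied_potential, config = processing_config()) {
  applied_potential + config$reference_offset
}
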