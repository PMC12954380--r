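#' Gaussian-band component spectra for a two-state chromophore
#'
#' Builds reduced- and oxidized-state absorbance spectra as sums of Gaussian
#' bands on a common wavelength grid, as a stand-in for the UV/Vis spectra of
#' a redox protein. The defaults caricature a high-potential iron-sulfur
#' protein: oxidation raises absorbance broadly across 320--380 nm and
#' 420--580 nm, so the 465--485 nm analysis band carries signal, while the
#' 650--700 nm baseline window stays flat.
#'
#' @param reduced_peaks,oxidized_peaks data.frames with columns `center`
#'   (nm), `width` (Gaussian sigma, nm, > 0), `height` (AU), one row per
#'   band. Empty data.frames give flat spectra.
#' @param wavelengths wavelength grid, nm (default 250--800 nm in 0.5 nm
#'   steps).
#' @param flat_offset constant absorbance added to both states, AU.
#' @param config a [processing_config()]; the grid must cover its baseline
#'   window and analysis band.
#' @return object of class `component_spectra`: list with `wavelengths`,
#'   `reduced`, `oxidized`.
#' @examples
#' cs <- make_component_spectra()
#' range(cs$oxidized - cs$reduced)
#' @export
make_component_spectra <- function(
    reduced_peaks = data.frame(center = c(280, 330, 460),
                               width = c(12, 30, 45),
                               height = c(0.60, 0.08, 0.04)),
    oxidized_peaks = data.frame(center = c(280, 340, 475, 560),
                                width = c(12, 28, 45, 30),
                                height = c(0.60, 0.22, 0.16, 0.06)),
    wavelengths = seq(250, 800, by = 0.5),
    flat_offset = 0.02,
    config = processing_config()) {
  check_peaks <- function(p) {
    if (nrow(p) > 0 && any(p$width <= 0)) stop("peak widths must be > 0")
  }
  check_peaks(reduced_peaks); check_peaks(oxidized_peaks)
  covers <- function(win)
    min(wavelengths) <= win[1] && max(wavelengths) >= win[2]
  if (!covers(config$analysis_band) || !covers(config$baseline_window))
    stop("wavelength grid must cover both the analysis band and the baseline window")
  sum_bands <- function(p) {
    s <- rep(flat_offset, length(wavelengths))
    for (i in seq_len(nrow(p)))
      s <- s + p$height[i] * exp(-0.5 * ((wavelengths - p$center[i]) / p$width[i])^2)
    s
  }
  out <- structure(list(wavelengths = wavelengths,
                        reduced = sum_bands(reduced_peaks),
                        oxidized = sum_bands(oxidized_peaks)),
                   class = "component_spectra")
  b <- config$analysis_band
  in_band <- wavelengths >= b[1] & wavelengths <= b[2]
  if (!any((out$oxidized - out$reduced)[in_band] > 0))
    stop("oxidized spectrum must exceed reduced somewhere inside the analysis band")
  out
}

# mean oxidized-minus-reduced contrast over the analysis band; sets the
# scale of "percent noise" in simulations
band_contrast <- function(components, config = processing_config()) {
  b <- config$analysis_band
  sel <- components$wavelengths >= b[1] & components$wavelengths <= b[2]
  mean(components$oxidized[sel] - components$reduced[sel])
}

#' Ground truth for a simulated titration experiment
#'
#' @param Em_true true midpoint potential, mV vs SHE.
#' @param noise_sd per-point Gaussian noise SD in AU; `NULL` (default)
#'   resolves at simulation time to 2% of the component spectra's mean
#'   analysis-band contrast.
#' @param drift_total total fractional path-length loss across the run
#'   (0.05 = the last spectrum is measured at 95% of the initial path).
#' @param ladder applied-potential schedule, mV vs SHE, in acquisition
#'   order. The default spans -50 to +550 mV in 20 mV steps with the first
#'   potential repeated at the end, anchoring the drift correction. Distinct
#'   ladder steps must lie within 20--50 mV.
#' @param replicates number of replicate runs.
#' @param seed integer seed.
#' @return object of class `titration_truth`.
#' @export
titration_truth <- function(Em_true, noise_sd = NULL, drift_total = 0.05,
                            ladder = c(seq(-50, 550, by = 20), -50),
                            replicates = 3L, seed = 1L) {
  steps <- diff(sort(unique(ladder)))
  if (any(steps < 20 - 1e-9) || any(steps > 50 + 1e-9))
    stop("ladder steps must lie within 20-50 mV")
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(Em_true = Em_true, noise_sd = noise_sd,
                 drift_total = drift_total, ladder = as.numeric(ladder),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "titration_truth")
}

#' Simulate a spectro-titration experiment
#'
#' Emulates a thin-layer spectroelectrochemical run: at every ladder
#' potential the chromophore equilibrates to its Nernstian oxidized fraction
#' ([oxidized_fraction()]); the measured spectrum is the corresponding
#' mixture of the component spectra, scaled by a linearly shrinking path
#' factor `1 - drift_total * i/(N-1)` across acquisition order, with i.i.d.
#' Gaussian noise on every wavelength sample. Each replicate gets its own
#' noise stream (derived deterministically from `truth$seed`).
#'
#' Applied potentials are written vs the reference electrode (ladder minus
#' `config$reference_offset`) so that a round trip through
#' [read_titration()] and [to_she()] reproduces the SHE-scale ladder.
#'
#' @param truth a [titration_truth()].
#' @param components a [make_component_spectra()].
#' @param config a [processing_config()].
#' @param dir optional output directory; when given, one CSV per replicate
#'   (`replicate_<r>.csv`, titration dialect) plus `truth.json` are written.
#' @return list with `series` (list of [titration_series()], one per
#'   replicate), `truth`, and `files` (paths, when `dir` was given).
#' @export
simulate_titration <- function(truth, components = make_component_spectra(),
                               config = processing_config(), dir = NULL) {
  stopifnot(inherits(truth, "titration_truth"),
            inherits(components, "component_spectra"))
  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0.02 * band_contrast(components, config)
  ladder <- truth$ladder
  N <- length(ladder)
  wl <- components$wavelengths
  f_ox <- oxidized_fraction(ladder, truth$Em_true, config)
  path <- 1 - truth$drift_total * (seq_len(N) - 1) / (N - 1)
  clean <- (outer(components$reduced, 1 - f_ox) +
              outer(components$oxidized, f_ox)) *
    rep(path, each = length(wl))

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }

  series <- vector("list", truth$replicates)
  for (r in seq_len(truth$replicates)) {
    set.seed(truth$seed + r - 1L)
    A <- clean + stats::rnorm(length(clean), 0, noise_sd)
    df <- data.frame(
      acquisition_index = rep(seq_len(N) - 1L, each = length(wl)),
      applied_potential_mV = rep(ladder - config$reference_offset,
                                 each = length(wl)),
      wavelength_nm = rep(wl, N),
      absorbance = as.numeric(A))
    series[[r]] <- titration_series(
      df, reference_offset = config$reference_offset,
      metadata = list(replicate = r, Em_true = truth$Em_true))
  }

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(truth$replicates)
    for (r in seq_len(truth$replicates)) {
      files[r] <- file.path(dir, sprintf("replicate_%d.csv", r))
      write_titration(series[[r]], files[r])
    }
    tr <- truth
    tr$noise_sd <- noise_sd
    jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, "truth.json"))
  }
  list(series = series, truth = truth, files = files)
}
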