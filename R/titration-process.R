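#' Baseline-correct every spectrum of a titration series
#'
#' Subtracts, from each spectrum, its mean absorbance over the baseline
#' window (default 650--700 nm, a region without cofactor features), so that
#' the window mean of every corrected spectrum is exactly zero. The
#' correction is a per-spectrum constant: any wavelength-independent offset
#' (cell positioning, lamp drift between spectra) is absorbed here, which is
#' why adding a constant to the raw data cannot move the fitted midpoint.
#'
#' @param series a [titration_series()].
#' @param config a [processing_config()].
#' @return the corrected `titration_series`. Idempotent.
#' @export
baseline_correct <- function(series, config = processing_config()) {
  stopifnot(inherits(series, "titration_series"))
  df <- series$spectra
  w <- config$baseline_window
  in_win <- df$wavelength_nm >= w[1] & df$wavelength_nm <= w[2]
  cnt <- tapply(in_win, df$acquisition_index, sum)
  if (any(cnt < 2))
    stop(sprintf(
      "baseline window %g-%g nm contains < 2 samples for acquisition_index %s",
      w[1], w[2], names(cnt)[which(cnt < 2)[1]]))
  base <- tapply(ifelse(in_win, df$absorbance, NA_real_),
                 df$acquisition_index, mean, na.rm = TRUE)
  df$absorbance <- df$absorbance -
    as.numeric(base[as.character(df$acquisition_index)])
  series$spectra <- df
  series
}

#' Average the analysis band of each spectrum
#'
#' Reduces each spectrum to the arithmetic mean of its absorbances inside the
#' analysis band (default 465--485 nm, the region of maximal redox-linked
#' change for the proteins this pipeline was built around). Band membership
#' is tested inclusively on the recorded wavelength grid; no interpolation.
#'
#' @param series a [titration_series()].
#' @param config a [processing_config()].
#' @return a `titration_trace`: data.frame with columns `acquisition_index`,
#'   `applied_potential_mV`, `value`, one row per spectrum in acquisition
#'   order.
#' @export
band_average <- function(series, config = processing_config()) {
  stopifnot(inherits(series, "titration_series"))
  df <- series$spectra
  b <- config$analysis_band
  in_band <- df$wavelength_nm >= b[1] & df$wavelength_nm <= b[2]
  cnt <- tapply(in_band, df$acquisition_index, sum)
  if (any(cnt < 1))
    stop(sprintf("analysis band %g-%g nm is empty for acquisition_index %s",
                 b[1], b[2], names(cnt)[which(cnt < 1)[1]]))
  val <- tapply(ifelse(in_band, df$absorbance, NA_real_),
                df$acquisition_index, mean, na.rm = TRUE)
  idx <- as.integer(names(val))
  ord <- order(idx)
  pot <- df$applied_potential_mV[match(idx, df$acquisition_index)]
  structure(data.frame(acquisition_index = idx[ord],
                       applied_potential_mV = pot[ord],
                       value = as.numeric(val)[ord]),
            class = c("titration_trace", "data.frame"))
}

#' Correct linear path-length drift in a band trace
#'
#' In a thin-layer cell the optical path length can shrink slowly during the
#' experiment (capillary forces in the sealing film, evaporation). When the
#' first and the last spectrum of the run were taken at the same potential,
#' the signal difference between them measures the accumulated drift; a ramp
#' linear in acquisition index, anchored at those two spectra, is subtracted
#' so that they become equal and every other point is shifted proportionally
#' to its index.
#'
#' @param trace a trace from [band_average()].
#' @param repeated_potential the potential (mV, same scale as the trace)
#'   poised at both the start and the end of the run.
#' @param tol numeric tolerance for matching `repeated_potential`.
#' @return the corrected trace.
#' @export
drift_correct <- function(trace, repeated_potential, tol = 1e-6) {
  hits <- which(abs(trace$applied_potential_mV - repeated_potential) <= tol)
  if (length(hits) == 0L)
    stop(sprintf(
      "potential %g mV not present in trace; skip drift correction", repeated_potential))
  if (length(hits) < 2L)
    stop(sprintf(
      "potential %g mV occurs only once; need a first/last pair - skip drift correction",
      repeated_potential))
  i_first <- trace$acquisition_index[hits[1]]
  i_last <- trace$acquisition_index[hits[length(hits)]]
  d <- trace$value[hits[length(hits)]] - trace$value[hits[1]]
  trace$value <- trace$value -
    d * (trace$acquisition_index - i_first) / (i_last - i_first)
  trace
}

# potential occurring more than once with the widest acquisition-index
# spread; NULL when no potential repeats
find_repeated_potential <- function(trace, tol = 1e-6) {
  pots <- trace$applied_potential_mV
  idx <- trace$acquisition_index
  cand <- unique(pots)
  best <- NULL
  best_span <- 0
  for (p in cand) {
    at <- idx[abs(pots - p) <= tol]
    if (length(at) >= 2L && diff(range(at)) > best_span) {
      best <- p
      best_span <- diff(range(at))
    }
  }
  best
}

#' Min-max normalize a band trace
#'
#' Rescales the trace affinely onto \[0, 1\], so the most-reduced spectrum
#' (the smallest band absorbance for a band that grows on oxidation) defines
#' the zero of `Y = A - A_red`. The midpoint potential is invariant under any
#' affine rescaling of the response, so this choice standardizes amplitudes
#' across replicates without touching the headline result.
#'
#' @param trace a trace from [band_average()] (optionally drift-corrected).
#' @return the normalized trace.
#' @export
normalize_trace <- function(trace) {
  rng <- range(trace$value)
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1) * 8 ||
      diff(rng) == 0)
    stop("trace is constant: no redox transition present to normalize")
  trace$value <- (trace$value - rng[1]) / diff(rng)
  trace
}

#' Reduce a titration series to a normalized potential trace
#'
#' Full preprocessing chain: [baseline_correct()], [band_average()],
#' optional [drift_correct()], [normalize_trace()], and conversion of the
#' applied potentials to the SHE scale via [to_she()].
#'
#' @param series a [titration_series()].
#' @param config a [processing_config()]; its `reference_offset` is
#'   overridden by the series' own offset when present.
#' @param repeat_potential potential (mV vs reference electrode) repeated at
#'   the start and end of the run, used to anchor the drift correction.
#'   `"auto"` (default) picks the repeating potential with the widest
#'   acquisition span and silently skips correction when none repeats;
#'   `NULL` disables drift correction.
#' @return a normalized `titration_trace` with `applied_potential_mV`
#'   expressed vs SHE.
#' @export
process_titration <- function(series, config = processing_config(),
                              repeat_potential = "auto") {
  offset <- series$reference_offset
  if (is.null(offset)) offset <- config$reference_offset
  trace <- band_average(baseline_correct(series, config), config)
  if (identical(repeat_potential, "auto"))
    repeat_potential <- find_repeated_potential(trace)
  if (!is.null(repeat_potential))
    trace <- drift_correct(trace, repeat_potential)
  trace <- normalize_trace(trace)
  trace$applied_potential_mV <- trace$applied_potential_mV + offset
  trace
}

#' Fit the midpoint potential of a titration series
#'
#' One-call analysis of a single series: preprocessing via
#' [process_titration()] followed by [fit_nernst()]. With
#' `branch = "separate"` the oxidizing (potential increasing) and reducing
#' (potential decreasing) sweeps are fitted independently and the difference
#' of their midpoints is reported as hysteresis; the default fits all points
#' jointly, which is appropriate when a single equilibrium midpoint is
#' sought.
#'
#' @inheritParams process_titration
#' @param branch `"joint"` (default) or `"separate"`.
#' @return For `"joint"`, a list with `fit` (a `nernst_fit`) and `trace`.
#'   For `"separate"`, additionally `fit_oxidizing`, `fit_reducing` and
#'   `hysteresis_mV` (oxidizing minus reducing midpoint).
#' @export
fit_titration <- function(series, config = processing_config(),
                          repeat_potential = "auto",
                          branch = c("joint", "separate")) {
  branch <- match.arg(branch)
  trace <- process_titration(series, config, repeat_potential)
  E <- trace$applied_potential_mV
  if (branch == "joint")
    return(list(fit = fit_nernst(E, trace$value, config), trace = trace,
                branch = branch))
  dE <- diff(E)
  up <- c(TRUE, dE >= 0)    # point belongs to the rising sweep
  down <- c(dE <= 0, TRUE)
  if (sum(up) < 4L || sum(down) < 4L)
    stop("separate-branch fitting needs >= 4 points in each sweep direction")
  f_up <- fit_nernst(E[up], trace$value[up], config)
  f_dn <- fit_nernst(E[down], trace$value[down], config)
  list(fit = fit_nernst(E, trace$value, config),
       fit_oxidizing = f_up, fit_reducing = f_dn,
       hysteresis_mV = f_up$Em - f_dn$Em,
       trace = trace, branch = branch)
}

#' Analyze replicate titrations with bootstrap uncertainty
#'
#' Processes each replicate series independently to a normalized trace,
#' aggregates per-acquisition means and standard deviations across
#' replicates, fits the Nernstian model to the means, and estimates the
#' midpoint uncertainty by parametric bootstrap ([bootstrap_em_sd()]) using
#' the per-point SDs.
#'
#' @param series_list list of [titration_series()], one per replicate,
#'   sharing the same acquisition schedule.
#' @inheritParams process_titration
#' @param n_replicates,sd_scale,seed passed to [bootstrap_em_sd()].
#' @return list with `fit` (`nernst_fit` on the per-point means),
#'   `bootstrap` (`bootstrap_estimate`), and `summary` (data.frame of
#'   potentials vs SHE, means and SDs).
#' @export
fit_titration_replicates <- function(series_list,
                                     config = processing_config(),
                                     repeat_potential = "auto",
                                     n_replicates = 1000L, sd_scale = 3,
                                     seed = 1L) {
  stopifnot(length(series_list) >= 2L)
  traces <- lapply(series_list, process_titration, config = config,
                   repeat_potential = repeat_potential)
  n_acq <- vapply(traces, nrow, integer(1))
  if (length(unique(n_acq)) != 1L)
    stop("replicates differ in number of acquisitions")
  E <- traces[[1]]$applied_potential_mV
  for (t in traces[-1])
    if (max(abs(t$applied_potential_mV - E)) > 1e-6)
      stop("replicates differ in their potential schedule")
  vals <- vapply(traces, `[[`, numeric(n_acq[1]), "value")
  means <- rowMeans(vals)
  sds <- apply(vals, 1, stats::sd)
  fit <- fit_nernst(E, means, config)
  boot <- bootstrap_em_sd(E, means, sds, config,
                          n_replicates = n_replicates,
                          sd_scale = sd_scale, seed = seed)
  list(fit = fit, bootstrap = boot,
       summary = data.frame(potential_mV_SHE = E, mean = means, sd = sds))
}

#' Write a midpoint-potential report as JSON
#'
#' @param result a result from [fit_titration_replicates()] or
#'   [fit_titration()].
#' @param file output path.
#' @param protein_label label stored in the report.
#' @return `file`, invisibly.
#' @export
write_em_report <- function(result, file, protein_label = "") {
  fit <- result$fit
  rep <- list(
    protein_label = protein_label,
    Em_mV_SHE = fit$Em,
    Em_sd_mV = if (!is.null(result$bootstrap)) result$bootstrap$Em_sd else NA,
    a = fit$amplitude_a,
    c = fit$offset_c,
    n_points = fit$n_points,
    branch_mode = if (!is.null(result$branch)) result$branch else "joint",
    seed = if (!is.null(result$bootstrap)) result$bootstrap$seed else NA
  )
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' Plot a titration trace with its Nernstian fit
#'
#' @param trace a `titration_trace` with potentials vs SHE.
#' @param fit optional `nernst_fit` to overlay.
#' @param config a [processing_config()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_titration_fit <- function(trace, fit = NULL,
                               config = processing_config(), ...) {
  graphics::plot(trace$applied_potential_mV, trace$value,
                 xlab = "E (mV vs SHE)",
                 ylab = "normalized band absorbance", ...)
  if (!is.null(fit)) {
    Egrid <- seq(min(trace$applied_potential_mV),
                 max(trace$applied_potential_mV), length.out = 300)
    graphics::lines(Egrid, nernst_response(Egrid, fit$Em, fit$amplitude_a,
                                           fit$offset_c, config), col = 2)
    graphics::abline(v = fit$Em, lty = 3, col = 2)
  }
  invisible(NULL)
}
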