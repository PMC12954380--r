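#' Single-transition Nernstian response
#'
#' Absorbance change of a one-site redox titration followed at a fixed
#' wavelength band, relative to the fully reduced reference spectrum:
#' \deqn{Y = A - A_{red} = \frac{a}{e^{zF(E - E_m)/RT} + 1} + c}
#' where `E` is the poised potential, `Em` the midpoint potential, `a` the
#' amplitude of the transition and `c` an offset. The amplitude may take
#' either sign: a band that gains absorbance on oxidation has `a < 0` in this
#' parameterization (the fraction-reduced term decays with `E`).
#'
#' @param E potential(s), mV vs SHE.
#' @param Em midpoint potential, mV vs SHE.
#' @param a transition amplitude (either sign).
#' @param c offset.
#' @param config a [processing_config()] supplying z, F, R, T.
#' @return numeric vector of responses, same length as `E`.
#' @examples
#' cfg <- processing_config()
#' nernst_response(303, Em = 303, a = 1, c = 0, cfg)  # a/2 at E = Em
#' @seealso [fit_nernst()], [oxidized_fraction()]
#' @export
nernst_response <- function(E, Em, a, c, config = processing_config()) {
  a / (exp((E - Em) / thermal_mV(config)) + 1) + c
}

#' Equilibrium oxidized fraction at a poised potential
#'
#' One-electron (or z-electron) Nernstian equilibrium:
#' `f_ox = 1 / (1 + exp(-zF(E - Em)/RT))`. Complements the reduced fraction
#' exactly (`f_ox + f_red = 1`).
#'
#' @inheritParams nernst_response
#' @return fraction(s) in \[0, 1\].
#' @examples
#' oxidized_fraction(303, 303)               # 0.5
#' oxidized_fraction(303 + 55.5, 303)        # ~0.90 (ln 9 spacing at 293 K)
#' @export
oxidized_fraction <- function(E, Em, config = processing_config()) {
  1 / (1 + exp(-(E - Em) / thermal_mV(config)))
}

# Profiled residual sum of squares of the Nernstian model.
#
# For each candidate Em the model is linear in (a, c); the optimal pair is
# obtained in closed form from the normal equations, giving RSS as a smooth
# 1-D function of Em. Vectorized over `Em`.
profile_rss <- function(Em, E, y, config) {
  w <- thermal_mV(config)
  n <- length(y)
  G <- 1 / (exp(outer(E, Em, "-") / w) + 1)   # n x m basis matrix
  Sg  <- colSums(G)
  Sgg <- colSums(G * G)
  Sgy <- colSums(G * y)
  Sy  <- sum(y)
  Syy <- sum(y * y)
  den <- n * Sgg - Sg^2
  a <- ifelse(den > .Machine$double.eps * n * pmax(Sgg, 1),
              (n * Sgy - Sg * Sy) / den, 0)
  cc <- (Sy - a * Sg) / n
  rss <- Syy + a^2 * Sgg + n * cc^2 - 2 * a * Sgy - 2 * cc * Sy +
    2 * a * cc * Sg
  list(rss = pmax(rss, 0), a = a, c = cc)
}

#' Fit a single-transition Nernstian function to a titration trace
#'
#' Least-squares fit of [nernst_response()] to normalized band absorbances
#' versus potential. The number of electrons `z` is held fixed at
#' `config$electrons_z`; amplitude `a`, midpoint `Em` and offset `c` are free,
#' and `a` is deliberately unconstrained in sign so one functional form covers
#' bands that gain or lose absorbance on oxidation.
#'
#' The optimizer profiles out the linear parameters: for fixed `Em` the
#' conditionally optimal `(a, c)` have a closed form, reducing the problem to
#' a 1-D minimization over `Em` which is solved by a coarse grid scan followed
#' by golden-section refinement. This has no starting-value sensitivity, which
#' matters when the fitter is called thousands of times inside the parametric
#' bootstrap.
#'
#' @param potentials_SHE potentials, mV vs SHE.
#' @param values normalized band absorbances (same length).
#' @param config a [processing_config()].
#' @param Em_range optional length-2 search interval for `Em` (mV vs SHE);
#'   defaults to the sampled potential range widened by 200 mV on both sides.
#' @param grid_step coarse-scan step in mV before refinement.
#' @return An object of class `nernst_fit`: list with elements `Em`,
#'   `amplitude_a`, `offset_c`, `residual_sum_squares`, `n_points`, and
#'   `extrapolated` (TRUE when the fitted `Em` falls outside the sampled
#'   potential range, flagging an unreliable determination).
#' @examples
#' cfg <- processing_config()
#' E <- seq(-50, 550, 20)
#' y <- nernst_response(E, Em = 303, a = -1, c = 1, cfg)
#' fit_nernst(E, y, cfg)
#' @export
fit_nernst <- function(potentials_SHE, values, config = processing_config(),
                       Em_range = NULL, grid_step = 2) {
  E <- as.numeric(potentials_SHE)
  y <- as.numeric(values)
  if (length(E) != length(y))
    stop("potentials and values must have the same length")
  if (length(E) < 4L)
    stop("at least 4 points are required to fit a Nernstian transition")
  if (!all(is.finite(E)) || !all(is.finite(y)))
    stop("potentials and values must be finite")
  span <- diff(range(E))
  if (span <= 2 * thermal_mV(config))
    stop("potential span must exceed 2*RT/zF to constrain the transition")
  if (is.null(Em_range)) Em_range <- range(E) + c(-200, 200)

  grid <- seq(Em_range[1], Em_range[2], by = grid_step)
  prof <- profile_rss(grid, E, y, config)
  i0 <- which.min(prof$rss)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(function(m) profile_rss(m, E, y, config)$rss,
                         interval = c(lo, hi), tol = 1e-7)
  Em <- opt$minimum
  fin <- profile_rss(Em, E, y, config)
  structure(list(
    Em = Em,
    amplitude_a = fin$a,
    offset_c = fin$c,
    residual_sum_squares = fin$rss,
    n_points = length(y),
    extrapolated = Em < min(E) || Em > max(E)
  ), class = "nernst_fit")
}

#' @export
print.nernst_fit <- function(x, ...) {
  cat("Single-transition Nernstian fit\n")
  cat(sprintf("  Em = %.1f mV vs SHE%s\n", x$Em,
              if (x$extrapolated) "  [outside sampled range!]" else ""))
  cat(sprintf("  a = %.4g, c = %.4g, RSS = %.3g on %d points\n",
              x$amplitude_a, x$offset_c, x$residual_sum_squares, x$n_points))
  invisible(x)
}

#' Parametric-bootstrap uncertainty of a fitted midpoint potential
#'
#' Generates `n_replicates` synthetic datasets from the experimentally
#' determined per-point means, adding Gaussian noise with standard deviation
#' `sd_scale * sds` at each point, refits the Nernstian model to every
#' replicate, and reports the standard deviation of the resulting midpoint
#' distribution as the uncertainty estimate. Inflating the per-point SDs
#' (default factor 3) makes the estimate deliberately conservative.
#'
#' Replicates whose refit fails are dropped and counted; more than 10%
#' failures aborts with an error rather than reporting a biased spread.
#'
#' @param potentials potentials, mV vs SHE.
#' @param means per-potential mean normalized absorbances.
#' @param sds per-potential standard deviations (>= 0, same length).
#' @param config a [processing_config()].
#' @param n_replicates number of bootstrap datasets (default 1000).
#' @param sd_scale factor applied to `sds` before drawing noise (default 3).
#' @param seed integer seed; the call is reproducible and restores the
#'   caller's RNG state on exit.
#' @return An object of class `bootstrap_estimate`: list with `Em_mean`,
#'   `Em_sd`, `n_replicates`, `n_failed`, `sd_scale`, `seed`.
#' @examples
#' cfg <- processing_config()
#' E <- seq(-50, 550, 20)
#' y <- nernst_response(E, 303, -1, 1, cfg)
#' bootstrap_em_sd(E, y, rep(0.01, length(E)), cfg,
#'                 n_replicates = 50, seed = 1)
#' @export
bootstrap_em_sd <- function(potentials, means, sds,
                            config = processing_config(),
                            n_replicates = 1000L, sd_scale = 3,
                            seed = 1L) {
  if (length(potentials) != length(means) || length(means) != length(sds))
    stop("potentials, means and sds must have the same length")
  if (any(sds < 0)) stop("sds must be non-negative")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  # anchor the fit on the central estimate; bootstrap refits search a window
  # around it, wide enough for any plausible replicate-to-replicate excursion
  base <- fit_nernst(potentials, means, config)
  win <- base$Em + c(-1, 1) * max(150, 6 * thermal_mV(config))
  noise_sd <- sd_scale * sds
  n <- length(means)

  ems <- numeric(n_replicates)
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    y <- means + stats::rnorm(n, 0, noise_sd)
    fit <- tryCatch(fit_nernst(potentials, y, config, Em_range = win),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      ems[r] <- NA_real_
    } else {
      ems[r] <- fit$Em
    }
  }
  if (failed > 0.1 * n_replicates)
    stop(sprintf("bootstrap aborted: %d of %d replicate fits failed (> 10%%)",
                 failed, n_replicates))
  ems <- ems[!is.na(ems)]
  structure(list(
    Em_mean = mean(ems),
    Em_sd = stats::sd(ems),
    n_replicates = as.integer(n_replicates),
    n_failed = failed,
    sd_scale = sd_scale,
    seed = as.integer(seed)
  ), class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf(
    "Parametric bootstrap: Em = %.1f +/- %.1f mV (%d replicates, %d failed, sd x%g, seed %d)\n",
    x$Em_mean, x$Em_sd, x$n_replicates, x$n_failed, x$sd_scale, x$seed))
  invisible(x)
}
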