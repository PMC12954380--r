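# spectra on a grid covering both the baseline window and the analysis band
make_series <- function(pots, absorb_fun, wl = seq(400, 700, by = 5),
                        offset = 280) {
  df <- do.call(rbind, lapply(seq_along(pots), function(i) {
    data.frame(acquisition_index = i - 1L,
               applied_potential_mV = pots[i],
               wavelength_nm = wl,
               absorbance = absorb_fun(wl, i))
  }))
  titration_series(df, reference_offset = offset)
}

test_that("titration CSV round-trips and counts generator output", {
  s <- make_series(c(0, 50, 100), function(wl, i) 0.1 * i + wl / 1e4)
  f <- tempfile(fileext = ".csv")
  write_titration(s, f)
  r <- read_titration(f)
  expect_s3_class(r, "titration_series")
  expect_identical(sort(unique(r$spectra$acquisition_index)), 0:2)
  expect_equal(r$reference_offset, 280)
  expect_equal(r$spectra$absorbance, s$spectra$absorbance, tolerance = 1e-9)

  # triplicate synthetic output: replicates x ladder-length records in all
  truth <- titration_truth(300, noise_sd = 0, drift_total = 0, seed = 1)
  sim <- simulate_titration(truth, dir = tempfile("simdir"))
  n_per <- length(truth$ladder)
  counts <- vapply(sim$series, function(s)
    length(unique(s$spectra$acquisition_index)), integer(1))
  expect_identical(counts, rep(n_per, 3L))
  reread <- read_titration(sim$files[1])
  expect_identical(length(unique(reread$spectra$acquisition_index)), n_per)
})

test_that("malformed titration input is rejected with a pointed error", {
  s <- make_series(c(0, 50, 100), function(wl, i) 0.1 * i)
  # duplicated acquisition index (same index, two potentials)
  bad <- s$spectra
  bad$acquisition_index[bad$acquisition_index == 2L] <- 1L
  expect_error(titration_series(bad), "duplicated index|more than one")
  # non-monotone wavelengths
  bad2 <- s$spectra
  bad2$wavelength_nm[2:3] <- bad2$wavelength_nm[3:2]
  expect_error(titration_series(bad2), "strictly increasing")
  # ragged CSV row
  f <- tempfile(fileext = ".csv")
  write_titration(s, f)
  lines <- readLines(f)
  lines[5] <- sub(",[^,]*$", "", lines[5])
  writeLines(lines, f)
  expect_error(read_titration(f), "ragged row")
})

test_that("baseline correction zeroes the 650-700 nm window and is idempotent", {
  cfg <- processing_config()
  const <- make_series(c(0, 100), function(wl, i) rep(0.30, length(wl)))
  out <- baseline_correct(const, cfg)
  expect_equal(out$spectra$absorbance, rep(0, nrow(out$spectra)))

  step <- make_series(c(0, 100), function(wl, i)
    ifelse(wl < 650, 0.2, 0.4))
  out2 <- baseline_correct(step, cfg)
  expect_equal(unique(out2$spectra$absorbance[out2$spectra$wavelength_nm < 650]),
               -0.2)
  expect_equal(unique(out2$spectra$absorbance[out2$spectra$wavelength_nm >= 650]),
               0)
  expect_equal(baseline_correct(out2, cfg)$spectra$absorbance,
               out2$spectra$absorbance)

  # window mean is zero for arbitrary spectra
  arb <- make_series(c(0, 100), function(wl, i) sin(wl / 30) + 0.2 * i)
  corr <- baseline_correct(arb, cfg)$spectra
  w <- corr$wavelength_nm >= 650 & corr$wavelength_nm <= 700
  for (ix in unique(corr$acquisition_index))
    expect_equal(mean(corr$absorbance[w & corr$acquisition_index == ix]), 0,
                 tolerance = 1e-12)

  # no samples in window -> error
  narrow <- make_series(c(0, 100), function(wl, i) wl / 1000,
                        wl = seq(400, 600, 5))
  expect_error(baseline_correct(narrow, cfg), "baseline window")
})

test_that("band averaging is the arithmetic mean over 465-485 nm", {
  cfg <- processing_config()
  s <- make_series(0, function(wl, i)
    ifelse(wl == 465, 0.1, ifelse(wl == 475, 0.2, ifelse(wl == 485, 0.3, 9))),
    wl = c(400, 465, 475, 485, 650, 675, 700))
  expect_equal(band_average(s, cfg)$value, 0.2)

  one <- make_series(0, function(wl, i) wl / 1000,
                     wl = c(400, 470, 650, 675, 700))
  expect_equal(band_average(one, cfg)$value, 0.470)

  # independent re-summation on a synthetic oxidized-component spectrum
  cs <- make_component_spectra()
  s2 <- titration_series(data.frame(acquisition_index = 0L,
                                    applied_potential_mV = 0,
                                    wavelength_nm = cs$wavelengths,
                                    absorbance = cs$oxidized))
  sel <- cs$wavelengths >= 465 & cs$wavelengths <= 485
  expect_equal(band_average(s2, cfg)$value,
               sum(cs$oxidized[sel]) / sum(sel), tolerance = 1e-12)

  no_band <- make_series(0, function(wl, i) wl, wl = seq(600, 700, 5))
  expect_error(band_average(no_band, cfg), "empty")
})

test_that("drift correction removes a constructed index-linear ramp exactly", {
  base_trace <- structure(
    data.frame(acquisition_index = 0:10,
               applied_potential_mV = c(-50, seq(0, 400, 50), -50),
               value = c(0.1, seq(0.2, 0.9, length.out = 9), 0.1)),
    class = c("titration_trace", "data.frame"))

  # zero first/last difference: unchanged
  expect_equal(drift_correct(base_trace, -50)$value, base_trace$value)

  # additive ramp d*i/(N-1): inverted to machine precision
  d <- 0.07
  ramped <- base_trace
  ramped$value <- ramped$value + d * ramped$acquisition_index / 10
  fixed <- drift_correct(ramped, -50)
  expect_equal(fixed$value, base_trace$value, tolerance = 1e-12)
  rel_err <- max(abs(fixed$value - base_trace$value)) / d
  expect_lt(rel_err, 1e-9)

  # postcondition: the first/last repeats agree after correction
  noisy <- ramped
  noisy$value <- noisy$value + sin(seq_len(11)) * 0.01
  out <- drift_correct(noisy, -50)
  expect_equal(out$value[1], out$value[11], tolerance = 1e-12)

  expect_error(drift_correct(base_trace, 999), "skip drift correction")
  expect_error(drift_correct(base_trace, 200), "skip drift correction")
})

test_that("trace normalization is min-max onto [0,1] and order-preserving", {
  tr <- structure(data.frame(acquisition_index = 0:2,
                             applied_potential_mV = c(0, 50, 100),
                             value = c(2, 3, 4)),
                  class = c("titration_trace", "data.frame"))
  expect_equal(normalize_trace(tr)$value, c(0, 0.5, 1))
  expect_equal(normalize_trace(normalize_trace(tr))$value, c(0, 0.5, 1))

  sig <- tr
  sig$value <- c(0.05, 0.4, 0.92)
  expect_identical(order(normalize_trace(sig)$value), order(sig$value))

  flat <- tr
  flat$value <- rep(1, 3)
  expect_error(normalize_trace(flat), "constant")
})

test_that("potentials convert to the SHE scale by the +280 mV offset", {
  cfg <- processing_config()
  expect_equal(to_she(0, cfg), 280)
  expect_equal(to_she(-280, cfg), 0)
  expect_equal(to_she(55, cfg), 335)
})

test_that("the Nernstian response has the correct midpoint, limits and ln 9 spacing", {
  cfg <- processing_config()
  expect_equal(nernst_response(303, 303, a = 0.8, c = 0.1, cfg),
               0.8 / 2 + 0.1)
  expect_equal(nernst_response(303 + 1e5, 303, 1, 0, cfg), 0, tolerance = 1e-12)
  expect_equal(nernst_response(303 - 1e5, 303, 1, 0, cfg), 1, tolerance = 1e-12)

  # RT/F computed independently here; E - Em = RT ln(9)/F gives Y = 0.100
  w_mV <- 8.3145 * 293 / 96485.34 * 1000
  expect_equal(nernst_response(303 + w_mV * log(9), 303, 1, 0, cfg), 0.100,
               tolerance = 1e-3)
  expect_equal(oxidized_fraction(303 + w_mV * log(9), 303, cfg), 0.900,
               tolerance = 1e-3)
  expect_equal(oxidized_fraction(120, 303, cfg) +
                 1 / (1 + exp((120 - 303) / w_mV)), 1, tolerance = 1e-12)
})

test_that("fit_nernst recovers noiseless midpoints and matches the grid oracle", {
  cfg <- processing_config()
  E <- seq(-50, 550, 20)
  for (em in c(303, 335)) {
    y <- nernst_response(E, em, a = -1, c = 1, cfg)
    fit <- fit_nernst(E, y, cfg)
    expect_equal(fit$Em, em, tolerance = 0.1)
    expect_false(fit$extrapolated)
    expect_lt(abs(fit$Em - oracle_grid_em(E, y, cfg)), 1)
  }
  # translation equivariance
  y <- nernst_response(E, 303, -1, 1, cfg)
  expect_equal(fit_nernst(E + 10, y, cfg)$Em - fit_nernst(E, y, cfg)$Em,
               10, tolerance = 1e-6)
  # oracle agreement holds on noisy data too
  set.seed(42)
  yn <- y + rnorm(length(E), 0, 0.03)
  expect_lt(abs(fit_nernst(E, yn, cfg)$Em - oracle_grid_em(E, yn, cfg)), 1)
  # guard rails
  expect_error(fit_nernst(E[1:3], y[1:3], cfg), "at least 4")
  expect_error(fit_nernst(c(0, 10, 20, 30), c(1, 2, 3, 4), cfg), "span")
})

test_that("fit_nernst agrees with an independent Levenberg-Marquardt fit", {
  cfg <- processing_config()
  E <- seq(-50, 550, 20)
  set.seed(7)
  y <- nernst_response(E, 280, -0.9, 0.95, cfg) + rnorm(length(E), 0, 0.02)
  mine <- fit_nernst(E, y, cfg)
  w <- 1000 * cfg$gas_constant * cfg$temperature / (cfg$electrons_z * cfg$faraday)
  lm_fit <- minpack.lm::nlsLM(
    y ~ a / (exp((E - Em) / w) + 1) + c,
    start = list(a = -1, Em = 250, c = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(mine$Em, coef(lm_fit)[["Em"]], tolerance = 0.05)
  expect_equal(mine$amplitude_a, coef(lm_fit)[["a"]], tolerance = 1e-3)
})

test_that("the fitted transition spans 2 ln(9) RT/F between 10% and 90%", {
  cfg <- processing_config()
  E <- seq(-50, 550, 20)
  fit <- fit_nernst(E, nernst_response(E, 240, -1, 1, cfg), cfg)
  g_of <- function(E) (nernst_response(E, fit$Em, fit$amplitude_a,
                                       fit$offset_c, cfg) - fit$offset_c) /
    fit$amplitude_a
  e10 <- uniroot(function(E) g_of(E) - 0.1, c(-500, 1000), tol = 1e-10)$root
  e90 <- uniroot(function(E) g_of(E) - 0.9, c(-500, 1000), tol = 1e-10)$root
  span_closed_form <- 2 * log(9) * 8.3145 * 293 / 96485.34 * 1000
  expect_equal(abs(e10 - e90), span_closed_form, tolerance = 1)
})

test_that("a wavelength-independent offset on raw spectra leaves Em unchanged", {
  cfg <- processing_config()
  truth <- titration_truth(317, noise_sd = 0, drift_total = 0.05, seed = 3)
  sim <- simulate_titration(truth)
  s <- sim$series[[1]]
  em1 <- fit_titration(s, cfg)$fit$Em
  shifted <- s
  shifted$spectra$absorbance <- shifted$spectra$absorbance + 0.37
  em2 <- fit_titration(shifted, cfg)$fit$Em
  # identical up to float cancellation in the baseline subtraction
  expect_equal(em1, em2, tolerance = 1e-5)
})

test_that("bootstrap Em uncertainty is deterministic, zero-noise-degenerate and scale-monotone", {
  cfg <- processing_config()
  E <- seq(-50, 550, 20)
  means <- nernst_response(E, 303, -1, 1, cfg)
  sds <- rep(0.02, length(E))

  b0 <- bootstrap_em_sd(E, means, rep(0, length(E)), cfg,
                        n_replicates = 20, seed = 1)
  expect_equal(b0$Em_sd, 0, tolerance = 1e-9)

  b1 <- bootstrap_em_sd(E, means, sds, cfg, n_replicates = 200, seed = 5)
  b1b <- bootstrap_em_sd(E, means, sds, cfg, n_replicates = 200, seed = 5)
  expect_identical(b1$Em_sd, b1b$Em_sd)

  b3 <- bootstrap_em_sd(E, means, sds, cfg, n_replicates = 200, seed = 5,
                        sd_scale = 3)
  b1s <- bootstrap_em_sd(E, means, sds, cfg, n_replicates = 200, seed = 5,
                         sd_scale = 1)
  expect_gt(b3$Em_sd, b1s$Em_sd)
  expect_gt(b3$Em_sd, 0)

  # RNG state of the caller is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(bootstrap_em_sd(E, means, sds, cfg,
                                           n_replicates = 10, seed = 9))
  expect_identical(rnorm(1), before)
  expect_error(bootstrap_em_sd(E, means, sds[-1], cfg), "same length")
  expect_error(bootstrap_em_sd(E, means, -sds, cfg), "non-negative")
})

test_that("separate-branch fitting reports hysteresis on an up-down ladder", {
  cfg <- processing_config()
  up <- seq(-50, 550, 25)
  ladder <- c(up, rev(up)[-1])
  truth <- titration_truth(300, noise_sd = 0, drift_total = 0,
                           ladder = ladder, replicates = 1, seed = 2)
  sim <- simulate_titration(truth)
  res <- fit_titration(sim$series[[1]], cfg, repeat_potential = NULL,
                       branch = "separate")
  expect_equal(res$fit_oxidizing$Em, 300, tolerance = 0.5)
  expect_equal(res$fit_reducing$Em, 300, tolerance = 0.5)
  expect_equal(res$hysteresis_mV, 0, tolerance = 1)
})
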