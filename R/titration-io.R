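#' Construct a titration series
#'
#' A titration series holds the ordered UV/Vis spectra of one OTTLE
#' (optically transparent thin-layer electrode) experiment: one spectrum per
#' poised potential, in acquisition order. Spectra are stored in long format.
#'
#' @param spectra data.frame with columns `acquisition_index` (integer >= 0,
#'   unique and contiguous from 0 per spectrum), `applied_potential_mV`
#'   (constant within a spectrum, vs the reference electrode),
#'   `wavelength_nm` (strictly increasing within a spectrum), `absorbance`.
#' @param reference_offset reference-electrode offset vs SHE, mV.
#' @param metadata optional named list of free-form labels.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(spectra, reference_offset = 280,
                             metadata = list()) {
  need <- c("acquisition_index", "applied_potential_mV",
            "wavelength_nm", "absorbance")
  if (!all(need %in% names(spectra)))
    stop("spectra must have columns: ", paste(need, collapse = ", "))
  spectra <- spectra[order(spectra$acquisition_index), , drop = FALSE]
  validate_series_spectra(spectra)
  structure(list(spectra = spectra,
                 reference_offset = reference_offset,
                 metadata = metadata),
            class = "titration_series")
}

validate_series_spectra <- function(df) {
  if (nrow(df) == 0L) stop("titration series contains no spectra")
  if (!all(is.finite(df$absorbance))) stop("absorbances must be finite")
  idx <- sort(unique(df$acquisition_index))
  if (!identical(as.integer(idx), seq_along(idx) - 1L))
    stop("acquisition_index values must be unique and contiguous from 0")
  for (i in idx) {
    sub <- df[df$acquisition_index == i, , drop = FALSE]
    if (length(unique(sub$applied_potential_mV)) != 1L)
      stop(sprintf(
        "acquisition_index %d maps to more than one applied potential (duplicated index?)", i))
    dw <- diff(sub$wavelength_nm)
    if (any(dw <= 0))
      stop(sprintf(
        "wavelengths not strictly increasing within acquisition_index %d (duplicated index or shuffled rows?)", i))
  }
  invisible(df)
}

#' @export
print.titration_series <- function(x, ...) {
  pots <- potentials_of(x)
  cat(sprintf("Titration series: %d spectra, %d distinct potentials\n",
              length(pots), length(unique(pots))))
  cat(sprintf("  applied potentials %g..%g mV (reference offset %+g mV vs SHE)\n",
              min(pots), max(pots), x$reference_offset))
  rng <- range(x$spectra$wavelength_nm)
  cat(sprintf("  wavelengths %g..%g nm\n", rng[1], rng[2]))
  invisible(x)
}

# applied potential of each spectrum, in acquisition order
potentials_of <- function(series) {
  df <- series$spectra
  idx <- sort(unique(df$acquisition_index))
  vapply(idx, function(i)
    df$applied_potential_mV[match(i, df$acquisition_index)], numeric(1))
}

#' Read a titration series from CSV
#'
#' Long-format dialect: optional leading comment line
#' `# reference_offset_mV=<float>`, then columns `acquisition_index,
#' applied_potential_mV, wavelength_nm, absorbance` (one row per spectrum and
#' wavelength). Malformed input (ragged rows, non-monotone wavelengths,
#' duplicated acquisition indices) raises an error naming the offence.
#'
#' @param source path to a CSV file in the titration dialect.
#' @param reference_offset fallback offset (mV vs SHE) used when the file
#'   carries no `reference_offset_mV` header.
#' @return a [titration_series()].
#' @seealso [write_titration()], [simulate_titration()]
#' @export
read_titration <- function(source, reference_offset = 280) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0L) stop("empty titration file: ", source)
  hdr <- grep("^#", lines, value = TRUE)
  off <- reference_offset
  m <- regmatches(hdr, regexec("reference_offset_mV\\s*=\\s*([-0-9.eE+]+)", hdr))
  m <- Filter(function(x) length(x) == 2L, m)
  if (length(m) > 0L) off <- as.numeric(m[[1]][2])

  body <- lines[!grepl("^#", lines)]
  nfield <- lengths(strsplit(body, ",", fixed = TRUE))
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0L)
    stop(sprintf("ragged row %d in %s: expected %d fields, found %d",
                 bad[1], source, nfield[1], nfield[bad[1]]))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("acquisition_index", "applied_potential_mV",
            "wavelength_nm", "absorbance")
  if (!all(need %in% names(df)))
    stop("missing columns in ", source, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s', data row %d of %s",
                   cn, which(is.na(v))[1], source))
    df[[cn]] <- v
  }
  df$acquisition_index <- as.integer(df$acquisition_index)
  titration_series(df, reference_offset = off,
                   metadata = list(source = source))
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration()]; emits the reference offset as a
#' `# reference_offset_mV=` header followed by the long-format table.
#' Output is deterministic (fixed number formatting), so identical series
#' produce byte-identical files.
#'
#' @param series a [titration_series()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_titration <- function(series, file) {
  stopifnot(inherits(series, "titration_series"))
  df <- series$spectra
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# reference_offset_mV=%g", series$reference_offset), con)
  writeLines("acquisition_index,applied_potential_mV,wavelength_nm,absorbance",
             con)
  writeLines(sprintf("%d,%g,%g,%.10g",
                     df$acquisition_index, df$applied_potential_mV,
                     df$wavelength_nm, df$absorbance), con)
  invisible(file)
}
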