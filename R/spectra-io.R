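## Containers and delimited-text I/O for spectra and titration tables.
##
## CSV dialect: comma-separated, '.' decimal, UTF-8; optional metadata header
## of '#'-prefixed "key: value" lines. Recognized metadata keys: compound,
## temperature_K, protein_conc_M, marker, pathlength_cm, n_residues.

#' Construct a spectrum
#'
#' A `spectrum` holds one measured spectrum on a strictly increasing axis:
#' fluorescence emission (a.u. vs nm), circular dichroism (millidegrees vs
#' nm) or infrared absorbance (vs cm\eqn{^{-1}}). Input points may arrive in
#' any order; they are sorted by axis value on construction.
#'
#' @param x Numeric axis values (nm or cm\eqn{^{-1}}), finite and positive.
#' @param y Numeric intensities, finite, same length as `x`.
#' @param axis_kind `"wavelength_nm"` or `"wavenumber_cm-1"`.
#' @param meta Named list of free-form labels (compound id, temperature,
#'   molar ratio, site marker, ...).
#' @return An object of class `spectrum` with fields `x`, `y`, `axis_kind`,
#'   `meta`.
#' @examples
#' sp <- spectrum(205:250, rnorm(46), "wavelength_nm")
#' length(sp$x)
#' @export
spectrum <- function(x, y, axis_kind = c("wavelength_nm", "wavenumber_cm-1"),
                     meta = list()) {
  axis_kind <- match.arg(axis_kind)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    abort_validation("'x' and 'y' must have the same length")
  if (length(x) < 8L)
    abort_validation(sprintf("a spectrum needs at least 8 points (got %d)", length(x)))
  if (!all(is.finite(x)) || any(x <= 0))
    abort_validation("axis values must all be finite and positive")
  if (!all(is.finite(y)))
    abort_validation("intensities must all be finite")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (anyDuplicated(x))
    abort_validation("axis values must be distinct")
  structure(list(axis_kind = axis_kind, x = x, y = y, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %s in [%g, %g]\n",
              length(x$x), x$axis_kind, min(x$x), max(x$x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a fluorescence titration series
#'
#' One temperature/site-marker condition of a quenching titration of serum
#' albumin: total added ligand (quencher) concentrations and fluorescence
#' intensities at the analysis wavelength, with optional absorbances at the
#' excitation and emission wavelengths for inner-filter correction. The first
#' point must be the zero-quencher reference supplying \eqn{F_0}.
#'
#' @param quencher_conc Total added ligand concentration, mol dm\eqn{^{-3}},
#'   strictly increasing, first value 0.
#' @param F Fluorescence intensities (a.u.), all positive.
#' @param A_ex,A_em Optional absorbances at excitation/emission wavelengths
#'   (default 0).
#' @param temperature Temperature in K.
#' @param protein_conc Protein concentration, mol dm\eqn{^{-3}}.
#' @param marker Site marker present: `"none"`, `"PHB"` (phenylbutazone) or
#'   `"IBP"` (ibuprofen).
#' @param meta Named list of extra labels.
#' @return An object of class `titration_series` with a `points` data frame
#'   (`quencher_conc`, `F`, `A_ex`, `A_em`) and condition fields.
#' @examples
#' ts <- titration_series(c(0, 2e-7, 4e-7, 6e-7), c(1000, 980, 961, 943))
#' ts$points$F[1]  # F0
#' @export
titration_series <- function(quencher_conc, F, A_ex = 0, A_em = 0,
                             temperature = 297, protein_conc = 1e-6,
                             marker = c("none", "PHB", "IBP"), meta = list()) {
  marker <- match.arg(marker)
  quencher_conc <- as.numeric(quencher_conc)
  F <- as.numeric(F)
  n <- length(quencher_conc)
  if (length(F) != n)
    abort_validation("'quencher_conc' and 'F' must have the same length")
  if (n < 4L)
    abort_validation(sprintf("a titration needs at least 4 points (got %d)", n))
  A_ex <- rep_len(as.numeric(A_ex), n)
  A_em <- rep_len(as.numeric(A_em), n)
  ord <- order(quencher_conc)
  quencher_conc <- quencher_conc[ord]
  F <- F[ord]; A_ex <- A_ex[ord]; A_em <- A_em[ord]
  if (any(!is.finite(quencher_conc)) || any(quencher_conc < 0))
    abort_validation("quencher concentrations must be finite and >= 0")
  if (any(diff(quencher_conc) <= 0))
    abort_validation("quencher concentrations must be strictly increasing (no duplicates)")
  if (quencher_conc[1] != 0)
    abort_validation("the first titration point must have quencher_conc == 0 (the F0 reference)")
  if (any(!is.finite(F)) || any(F <= 0))
    abort_validation("fluorescence intensities must be finite and > 0")
  if (any(A_ex < 0) || any(A_em < 0))
    abort_validation("absorbances must be >= 0")
  stopifnot_number(temperature, "temperature", positive = TRUE)
  stopifnot_number(protein_conc, "protein_conc", positive = TRUE)
  structure(list(temperature = temperature, protein_conc = protein_conc,
                 marker = marker,
                 points = data.frame(quencher_conc = quencher_conc, F = F,
                                     A_ex = A_ex, A_em = A_em),
                 meta = meta),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, %g K, marker=%s, F0=%g\n",
              nrow(x$points), x$temperature, x$marker, x$points$F[1]))
  invisible(x)
}

## metadata header -----------------------------------------------------------

read_meta_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    if (!grepl(":", h, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", h))
    val <- trimws(sub("^[^:]*:", "", h))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

read_csv_body <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L)
    abort_format(sprintf("'%s': no data rows found", path))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(df = df, meta = read_meta_header(lines))
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_format(sprintf("'%s': missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
  for (cc in cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort_format(sprintf("'%s': non-numeric value in column '%s' (data line %d)",
                           path, cc, if (is.na(bad)) 1L else bad))
    }
  }
  invisible(df)
}

## readers -------------------------------------------------------------------

#' Read a fluorescence titration from CSV
#'
#' Two dialects are supported. `"summary"` files carry one row per addition
#' with columns `quencher_conc_M`, `F` and optional `A_ex`, `A_em`.
#' `"spectra"` files carry full emission spectra with columns
#' `wavelength_nm`, `intensity`, `quencher_conc_M`; the analysis intensity
#' for every concentration is read at the emission-maximum wavelength of the
#' zero-quencher spectrum, held fixed across the titration (using each
#' spectrum's own maximum would fold peak red-shifts into the quenching
#' signal). Metadata header lines (`# key: value`) populate the condition
#' fields (`temperature_K`, `protein_conc_M`, `marker`).
#'
#' @param path Path to a CSV file.
#' @param dialect `"summary"` or `"spectra"`.
#' @return A [titration_series()].
#' @export
read_titration <- function(path, dialect = c("summary", "spectra")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort_io(sprintf("file not found: '%s'", path))
  parsed <- read_csv_body(path)
  df <- parsed$df
  meta <- parsed$meta
  temperature <- if (!is.null(meta$temperature_K)) meta$temperature_K else 297
  protein_conc <- if (!is.null(meta$protein_conc_M)) meta$protein_conc_M else 1e-6
  marker <- if (!is.null(meta$marker)) meta$marker else "none"
  if (!marker %in% .MARKERS)
    abort_format(sprintf("unknown marker '%s' (expected one of %s)",
                         marker, paste(.MARKERS, collapse = ", ")))

  if (dialect == "summary") {
    require_columns(df, c("quencher_conc_M", "F"), path)
    A_ex <- if ("A_ex" %in% names(df)) df$A_ex else 0
    A_em <- if ("A_em" %in% names(df)) df$A_em else 0
    if (!any(df$quencher_conc_M == 0))
      abort_validation(sprintf("'%s': no zero-concentration (F0) row", path))
    return(titration_series(df$quencher_conc_M, df$F, A_ex, A_em,
                            temperature = temperature,
                            protein_conc = protein_conc,
                            marker = marker, meta = meta))
  }

  ## spectra dialect
  require_columns(df, c("wavelength_nm", "intensity", "quencher_conc_M"), path)
  concs <- sort(unique(df$quencher_conc_M))
  if (!any(concs == 0))
    abort_validation(sprintf("'%s': no zero-concentration (F0) spectrum", path))
  ref <- df[df$quencher_conc_M == 0, ]
  lambda_max <- ref$wavelength_nm[which.max(ref$intensity)]
  F <- vapply(concs, function(cc) {
    sub <- df[df$quencher_conc_M == cc, ]
    i <- which(sub$wavelength_nm == lambda_max)
    if (length(i) != 1L)
      stats::approx(sub$wavelength_nm, sub$intensity, xout = lambda_max)$y
    else sub$intensity[i]
  }, numeric(1))
  meta$analysis_wavelength_nm <- lambda_max
  titration_series(concs, F, temperature = temperature,
                   protein_conc = protein_conc, marker = marker, meta = meta)
}

#' Read a two-column spectrum from CSV
#'
#' Expects two numeric columns (axis then intensity, any column names) and an
#' optional `#`-prefixed metadata header. Rows may be in any order; the
#' returned spectrum is sorted ascending by axis value.
#'
#' @inheritParams spectrum
#' @param path Path to a CSV file.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, axis_kind = c("wavelength_nm", "wavenumber_cm-1")) {
  axis_kind <- match.arg(axis_kind)
  if (!file.exists(path))
    abort_io(sprintf("file not found: '%s'", path))
  parsed <- read_csv_body(path)
  df <- parsed$df
  if (ncol(df) < 2L)
    abort_format(sprintf("'%s': expected two numeric columns, found %d", path, ncol(df)))
  require_columns(df, names(df)[1:2], path)
  if (nrow(df) < 8L)
    abort_validation(sprintf("'%s': a spectrum needs at least 8 rows (got %d)", path, nrow(df)))
  spectrum(df[[1]], df[[2]], axis_kind = axis_kind, meta = parsed$meta)
}

## writers -------------------------------------------------------------------

format_meta_header <- function(meta) {
  keep <- vapply(meta, function(v) is.character(v) || is.numeric(v), logical(1))
  meta <- meta[keep]
  if (!length(meta)) return(character())
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k, if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
}

#' Write a titration series to summary-dialect CSV
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  meta <- series$meta
  meta$temperature_K <- series$temperature
  meta$protein_conc_M <- series$protein_conc
  meta$marker <- series$marker
  df <- data.frame(quencher_conc_M = series$points$quencher_conc,
                   F = series$points$F,
                   A_ex = series$points$A_ex,
                   A_em = series$points$A_em)
  lines <- c(format_meta_header(meta),
             paste(names(df), collapse = ","),
             apply(df, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = NA),
                                            collapse = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a spectrum to two-column CSV
#'
#' @param sp A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  axis_col <- if (sp$axis_kind == "wavelength_nm") "wavelength_nm" else "wavenumber_cm1"
  lines <- c(format_meta_header(sp$meta),
             paste(axis_col, "intensity", sep = ","),
             paste(format(sp$x, digits = 17, trim = TRUE),
                   format(sp$y, digits = 17, trim = TRUE), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## report tables -------------------------------------------------------------

.REPORT_STAGES <- c("stern_volmer", "binding", "thermodynamics", "site_markers",
                    "cd_helix", "ftir_structure", "druglikeness")

#' Write per-stage report tables
#'
#' Writes one CSV per analysis stage into `out_dir`. Stage names are drawn
#' from a fixed vocabulary so downstream consumers can rely on file names;
#' files are written (and paths returned) in that fixed order regardless of
#' the order of `results`.
#'
#' @param results Named list of data frames; names must be among
#'   `stern_volmer`, `binding`, `thermodynamics`, `site_markers`, `cd_helix`,
#'   `ftir_structure`, `druglikeness`.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written file paths.
#' @export
write_report_tables <- function(results, out_dir) {
  if (!length(results)) return(character())
  if (is.null(names(results)) || any(!nzchar(names(results))))
    abort_validation("'results' must be a named list of data frames")
  unknown <- setdiff(names(results), .REPORT_STAGES)
  if (length(unknown))
    abort_validation(sprintf("unknown report stage(s): %s",
                             paste(unknown, collapse = ", ")))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(sprintf("cannot create output directory '%s'", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0)
    abort_io(sprintf("output directory '%s' is not writable", out_dir))
  stages <- intersect(.REPORT_STAGES, names(results))
  paths <- character(0)
  for (st in stages) {
    p <- file.path(out_dir, paste0(st, ".csv"))
    utils::write.csv(results[[st]], p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  paths
}
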