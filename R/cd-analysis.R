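## Circular dichroism: mean residue ellipticity and alpha-helix content at
## 208 nm, and the per-ratio helix-loss table.

#' Mean residue ellipticity
#'
#' Normalizes an observed CD signal (millidegrees) to a per-residue molar
#' scale:
#' \deqn{MRE = \frac{CD_{obs}\ (mdeg)}{10 \cdot C \cdot n \cdot l}}
#' where \eqn{C} is the protein molar concentration (mol dm\eqn{^{-3}}),
#' \eqn{n} the number of amino-acid residues (583 for BSA) and \eqn{l} the
#' cuvette path length in cm. Linear in the observed signal, inverse-linear
#' in each normalizer.
#'
#' @param observed_cd Observed ellipticity in millidegrees (any sign).
#'   Vectorized.
#' @param C Protein concentration, mol dm\eqn{^{-3}}, > 0.
#' @param n_residues Residue count, >= 1 (default 583, BSA).
#' @param l Path length in cm, > 0.
#' @return MRE in deg cm\eqn{^2} dmol\eqn{^{-1}}.
#' @examples
#' mean_residue_ellipticity(-60, C = 1e-6)  # about -10292
#' @export
mean_residue_ellipticity <- function(observed_cd, C, n_residues = .BSA_N_RESIDUES,
                                     l = 1) {
  if (any(!is.finite(observed_cd)))
    abort_validation("'observed_cd' must be finite")
  stopifnot_number(C, "C", positive = TRUE)
  stopifnot_number(n_residues, "n_residues", positive = TRUE)
  if (n_residues < 1) abort_validation("'n_residues' must be >= 1")
  stopifnot_number(l, "l", positive = TRUE)
  observed_cd / (10 * C * n_residues * l)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' \deqn{\alpha\text{-helix}(\%) = \frac{-MRE_{208} - 4000}{33000 - 4000} \times 100}
#' The anchors are the standard 208 nm calibration: 33,000 is the MRE
#' magnitude of a pure alpha helix and 4000 the magnitude where the beta-form
#' and random-coil contributions cross, so \eqn{MRE_{208} = -33000} maps to
#' 100\% helix and \eqn{MRE_{208} = -4000} to 0\%. The value is returned
#' unclamped together with an `in_range` flag: out-of-range percentages
#' usually indicate wrong concentration or path-length metadata and clamping
#' would hide that.
#'
#' @param MRE208 Mean residue ellipticity at 208 nm, deg cm\eqn{^2}
#'   dmol\eqn{^{-1}}. Vectorized.
#' @return A data frame with columns `helix_percent` and `in_range`
#'   (`helix_percent` within \[0, 100\]).
#' @examples
#' alpha_helix_percent(-18850)  # about 51.2%
#' @export
alpha_helix_percent <- function(MRE208) {
  if (any(!is.finite(MRE208)))
    abort_validation("'MRE208' must be finite")
  pct <- (-MRE208 - 4000) / (33000 - 4000) * 100
  data.frame(helix_percent = pct, in_range = pct >= 0 & pct <= 100)
}

## CD signal at exactly 208 nm, linearly interpolated on the wavelength grid
cd_at_208 <- function(sp) {
  if (min(sp$x) > 208 || max(sp$x) < 208)
    abort_validation(sprintf("spectrum range [%g, %g] nm does not cover 208 nm",
                             min(sp$x), max(sp$x)))
  stats::approx(sp$x, sp$y, xout = 208)$y
}

#' Per-ratio helix content and helix loss from a CD titration
#'
#' For each CD spectrum (one per ligand:protein molar ratio, ratio 0 being
#' the free protein) the ellipticity at 208 nm is read by linear
#' interpolation, converted to mean residue ellipticity and then to
#' alpha-helix percentage. The loss is the drop in helix percentage from the
#' free protein to the highest ratio, in percentage points.
#'
#' @param spectra List of [spectrum()] objects, each with a numeric `ratio`
#'   entry in its `meta` (ligand:protein molar ratio); must include ratio 0
#'   and each must cover 208 nm.
#' @param C Protein concentration, mol dm\eqn{^{-3}}.
#' @param n_residues Residue count (default 583).
#' @param l Path length, cm.
#' @return A list of class `helix_loss` with `table` (data frame: `ratio`,
#'   `MRE208`, `helix_percent`, `in_range`, ascending in ratio) and
#'   `loss_points` (helix\% at ratio 0 minus helix\% at the highest ratio).
#' @export
helix_loss_table <- function(spectra, C = 1e-6, n_residues = .BSA_N_RESIDUES,
                             l = 1) {
  if (!is.list(spectra) || !length(spectra) ||
      !all(vapply(spectra, inherits, logical(1), "spectrum")))
    abort_validation("'spectra' must be a non-empty list of spectrum objects")
  ratios <- vapply(spectra, function(s) {
    r <- s$meta$ratio
    if (is.null(r) || !is_number(r))
      abort_validation("every CD spectrum needs a numeric 'ratio' metadata entry")
    r
  }, numeric(1))
  if (!any(ratios == 0))
    abort_validation("CD series must include the ratio-0 (free protein) spectrum")
  if (anyDuplicated(ratios))
    abort_validation("duplicate ligand:protein ratios in CD series")
  ord <- order(ratios)
  ratios <- ratios[ord]
  spectra <- spectra[ord]
  mre <- vapply(spectra, function(s) mean_residue_ellipticity(cd_at_208(s), C, n_residues, l),
                numeric(1))
  helix <- alpha_helix_percent(mre)
  tab <- data.frame(ratio = ratios, MRE208 = mre,
                    helix_percent = helix$helix_percent, in_range = helix$in_range)
  loss <- tab$helix_percent[1] - tab$helix_percent[nrow(tab)]
  structure(list(table = tab, loss_points = loss), class = "helix_loss")
}

#' @export
print.helix_loss <- function(x, ...) {
  cat("<helix_loss>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  loss (ratio 0 -> %g): %.2f percentage points\n",
              x$table$ratio[nrow(x$table)], x$loss_points))
  invisible(x)
}
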