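## Fluorescence-quenching analysis: inner-filter correction, Stern-Volmer
## regression with quenching-mechanism classification, double-logarithm
## binding regression, and site-marker competition.

#' Inner-filter correction of observed fluorescence
#'
#' Re-absorption of excitation and emission light by the added ligand
#' attenuates the measured signal; the corrected intensity is
#' \deqn{F_{corr} = F_{obs} \cdot 10^{(A_{ex}+A_{em})/2}}
#' where \eqn{A_{ex}} and \eqn{A_{em}} are the solution absorbances at the
#' excitation and emission wavelengths. The correction is the identity at
#' zero absorbance and strictly increasing in \eqn{A_{ex}+A_{em}}.
#'
#' @param F_obs Observed fluorescence intensity (a.u.), > 0. Vectorized.
#' @param A_ex,A_em Absorbances at excitation/emission wavelengths, >= 0.
#' @return Corrected intensity, same length as `F_obs`; always >= `F_obs`.
#' @examples
#' correct_inner_filter(100, 0.2, 0.1)  # 100 * 10^0.15
#' @export
correct_inner_filter <- function(F_obs, A_ex = 0, A_em = 0) {
  if (any(!is.finite(F_obs)) || any(F_obs <= 0))
    abort_validation("'F_obs' must be finite and > 0")
  if (any(!is.finite(A_ex)) || any(A_ex < 0) || any(!is.finite(A_em)) || any(A_em < 0))
    abort_validation("absorbances must be finite and >= 0")
  F_obs * 10^((A_ex + A_em) / 2)
}

## apply the correction across a series when absorbances are present
corrected_intensities <- function(series) {
  p <- series$points
  correct_inner_filter(p$F, p$A_ex, p$A_em)
}

## ordinary least squares, returned with diagnostics; kept as a plain
## closed-form call site so tests can compare against the normal equations
ols_line <- function(x, y) {
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ## noiseless synthetic inputs are a designed use; silence the
  ## "essentially perfect fit" note summary.lm emits for them
  s <- suppressWarnings(summary(fit))
  r2 <- if (all(y == y[1])) 1 else s$r.squared  # flat response: perfect fit
  list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
       stderr_slope = unname(s$coefficients[2, 2]))
}

#' Stern-Volmer regression of a quenching titration
#'
#' Fits \eqn{F_0/F = 1 + K_{SV}[Q]} by ordinary least squares over the
#' nonzero-quencher points with a free intercept. The quenching rate constant
#' is \eqn{k_q = K_{SV}/\tau_0} with \eqn{\tau_0} the unquenched fluorophore
#' lifetime. Inner-filter correction is applied first whenever the series
#' carries absorbances. A fitted intercept farther than 0.05 from 1 raises a
#' warning (the model forces 1 at \eqn{[Q]=0}; large deviation signals
#' curvature or a bad reference).
#'
#' @param series A [titration_series()].
#' @param tau0 Unquenched fluorophore lifetime in seconds (default
#'   `1e-8` s, the conventional biopolymer value).
#' @return An object of class `stern_volmer_fit`: `K_SV` (dm3 mol-1),
#'   `intercept`, `k_q` (dm3 mol-1 s-1), `tau0`, `r2`, `stderr_KSV`,
#'   `temperature`, `intercept_warning`.
#' @export
fit_stern_volmer <- function(series, tau0 = .TAU0_DEFAULT) {
  stopifnot(inherits(series, "titration_series"))
  stopifnot_number(tau0, "tau0", positive = TRUE)
  Fc <- corrected_intensities(series)
  q <- series$points$quencher_conc
  F0 <- Fc[1]
  keep <- q > 0
  if (sum(keep) < 3L)
    abort_fit(sprintf("Stern-Volmer fit needs >= 3 nonzero-quencher points (got %d)",
                      sum(keep)))
  ratio <- F0 / Fc[keep]
  fit <- ols_line(q[keep], ratio)
  intercept_warning <- abs(fit$intercept - 1) > 0.05
  if (intercept_warning)
    warn_albuminbind(sprintf(
      "Stern-Volmer intercept %.4f deviates from 1 by more than 0.05", fit$intercept))
  structure(list(K_SV = fit$slope, intercept = fit$intercept,
                 k_q = fit$slope / tau0, tau0 = tau0,
                 r2 = fit$r2, stderr_KSV = fit$stderr_slope,
                 temperature = series$temperature,
                 intercept_warning = intercept_warning),
            class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf("<stern_volmer_fit> %g K: K_SV = %.4g dm3/mol, k_q = %.4g dm3/mol/s, r2 = %.4f\n",
              x$temperature, x$K_SV, x$k_q, x$r2))
  invisible(x)
}

#' Classify the quenching mechanism from the temperature trend
#'
#' Static quenching (ground-state complex) is called when the Stern-Volmer
#' constant decreases with temperature and every quenching rate constant
#' exceeds the maximum scatter-collision limit of
#' \eqn{2 \times 10^{10}} dm\eqn{^3} mol\eqn{^{-1}} s\eqn{^{-1}}; dynamic
#' (collisional) quenching is called for the complementary pattern
#' (increasing \eqn{K_{SV}}, all \eqn{k_q} below the limit). Any other
#' combination of evidence is reported as ambiguous. Trends are strict
#' monotonicity over the supplied temperatures; with only a few temperatures
#' no significance testing is attempted.
#'
#' @param fits List of `stern_volmer_fit` objects ordered by strictly
#'   increasing temperature (>= 2 temperatures).
#' @return An object of class `mechanism_call`: `verdict` (`"static"`,
#'   `"dynamic"` or `"ambiguous"`), `ksv_trend`, `kq_exceeds_threshold`
#'   (logical per temperature), `threshold`.
#' @export
classify_mechanism <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, inherits, logical(1), "stern_volmer_fit")))
    abort_validation("'fits' must be a list of >= 2 stern_volmer_fit objects")
  temps <- vapply(fits, `[[`, numeric(1), "temperature")
  if (anyDuplicated(temps))
    abort_validation("duplicate temperatures in Stern-Volmer fits")
  if (any(diff(temps) <= 0))
    abort_validation("fits must be ordered by strictly increasing temperature")
  ksv <- vapply(fits, `[[`, numeric(1), "K_SV")
  kq <- vapply(fits, `[[`, numeric(1), "k_q")
  d <- diff(ksv)
  ksv_trend <- if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing" else "non-monotone"
  exceeds <- kq > .KQ_COLLISION_LIMIT
  verdict <- if (ksv_trend == "decreasing" && all(exceeds)) "static"
    else if (ksv_trend == "increasing" && all(!exceeds)) "dynamic"
    else "ambiguous"
  structure(list(verdict = verdict, ksv_trend = ksv_trend,
                 kq_exceeds_threshold = stats::setNames(exceeds, temps),
                 threshold = .KQ_COLLISION_LIMIT),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (K_SV %s with T; k_q > 2e10 at %d/%d temperatures)\n",
              x$verdict, x$ksv_trend, sum(x$kq_exceeds_threshold),
              length(x$kq_exceeds_threshold)))
  invisible(x)
}

#' Double-logarithm binding regression
#'
#' For static quenching by a 1:1 (or n:1) ground-state complex,
#' \deqn{\log_{10}\frac{F_0-F}{F} = \log_{10} K_b + n \log_{10} [Q]}
#' so an ordinary least-squares line of \eqn{\log_{10}((F_0-F)/F)} on
#' \eqn{\log_{10}[Q]} yields the binding constant \eqn{K_b}
#' (\eqn{10^{intercept}}) and the number of binding sites \eqn{n} (slope).
#' Points with \eqn{F \ge F_0} carry no quenching signal; they are excluded
#' and counted in a warning.
#'
#' @param series A [titration_series()].
#' @return An object of class `binding_fit`: `log10_Kb`, `Kb` (dm3 mol-1),
#'   `n_sites`, `r2`, `n_points_used`, `n_points_excluded`, `temperature`,
#'   `marker`.
#' @export
fit_double_log <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  Fc <- corrected_intensities(series)
  q <- series$points$quencher_conc
  F0 <- Fc[1]
  nz <- q > 0
  usable <- nz & (F0 - Fc > 0)
  excluded <- sum(nz) - sum(usable)
  if (sum(usable) < 3L)
    abort_fit(sprintf("double-log fit needs >= 3 points with F0 - F > 0 (got %d)",
                      sum(usable)))
  if (excluded > 0)
    warn_albuminbind(sprintf("%d point(s) with F >= F0 excluded from double-log fit",
                             excluded))
  x <- log10(q[usable])
  y <- log10((F0 - Fc[usable]) / Fc[usable])
  fit <- ols_line(x, y)
  structure(list(log10_Kb = fit$intercept, Kb = 10^fit$intercept,
                 n_sites = fit$slope, r2 = fit$r2,
                 n_points_used = sum(usable), n_points_excluded = excluded,
                 temperature = series$temperature, marker = series$marker),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %g K (%s): Kb = %.4g dm3/mol, n = %.3f, r2 = %.4f (%d pts)\n",
              x$temperature, x$marker, x$Kb, x$n_sites, x$r2, x$n_points_used))
  invisible(x)
}

#' Site-marker competition assessment
#'
#' Serum albumin carries two principal drug pockets: Sudlow site I
#' (subdomain IIA, probed by phenylbutazone) and site II (subdomain IIIA,
#' probed by ibuprofen). If a marker occupies the ligand's pocket, the
#' apparent binding constant measured in its presence drops. The pocket is
#' assigned to whichever marker depresses \eqn{K_b} more, provided both
#' ratios are below 1; any other pattern is indeterminate.
#'
#' @param fit_alone,fit_PHB,fit_IBP `binding_fit` objects at the same
#'   temperature: marker-free, with phenylbutazone, with ibuprofen.
#' @return An object of class `site_assignment`: `ratio_PHB`, `ratio_IBP`
#'   (marker/alone \eqn{K_b} ratios) and `site` (`"site_I_IIA"`,
#'   `"site_II_IIIA"` or `"indeterminate"`).
#' @export
assess_site_competition <- function(fit_alone, fit_PHB, fit_IBP) {
  fits <- list(fit_alone, fit_PHB, fit_IBP)
  if (!all(vapply(fits, inherits, logical(1), "binding_fit")))
    abort_validation("all three arguments must be binding_fit objects")
  temps <- vapply(fits, `[[`, numeric(1), "temperature")
  if (max(temps) - min(temps) > 1e-9)
    abort_validation(sprintf("site-marker fits must share one temperature (got %s K)",
                             paste(unique(temps), collapse = ", ")))
  ratio_PHB <- fit_PHB$Kb / fit_alone$Kb
  ratio_IBP <- fit_IBP$Kb / fit_alone$Kb
  site <- if (ratio_IBP < ratio_PHB && ratio_PHB < 1 && ratio_IBP < 1) "site_II_IIIA"
    else if (ratio_PHB < ratio_IBP && ratio_PHB < 1 && ratio_IBP < 1) "site_I_IIA"
    else "indeterminate"
  structure(list(ratio_PHB = ratio_PHB, ratio_IBP = ratio_IBP, site = site),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("<site_assignment> %s (Kb ratios: PHB %.3f, IBP %.3f)\n",
              x$site, x$ratio_PHB, x$ratio_IBP))
  invisible(x)
}
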