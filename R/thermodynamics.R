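## van't Hoff analysis of the temperature dependence of the binding constant,
## Gibbs energy, and interaction-type classification.

#' van't Hoff regression of binding constants over temperature
#'
#' Fits \eqn{\ln K_b = -\Delta H^\circ/(RT) + \Delta S^\circ/R} by ordinary
#' least squares of \eqn{\ln K_b} on \eqn{1/T}, so
#' \eqn{\Delta H^\circ = -R \cdot slope} and
#' \eqn{\Delta S^\circ = R \cdot intercept}. The Gibbs energy at each fitted
#' temperature is \eqn{\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ}.
#' Natural logarithms are used throughout so that the regression is
#' algebraically consistent with \eqn{\Delta G^\circ = -RT\ln K_b} without
#' base-conversion factors.
#'
#' @param kb_by_temperature Named numeric vector: names are temperatures in
#'   K, values are binding constants in dm\eqn{^3} mol\eqn{^{-1}} (> 0).
#'   At least 2 distinct temperatures.
#' @return An object of class `vant_hoff_fit`: `dH` (J mol-1), `dS`
#'   (J mol-1 K-1), `r2`, `gas_constant`, `dG_by_T` (named numeric, J mol-1).
#' @examples
#' kb <- c(`297` = 1.1e5, `303` = 0.8e5, `308` = 0.6e5)
#' fit_vant_hoff(kb)
#' @export
fit_vant_hoff <- function(kb_by_temperature) {
  kb <- as.numeric(kb_by_temperature)
  temps <- suppressWarnings(as.numeric(names(kb_by_temperature)))
  if (any(is.na(temps)))
    abort_validation("'kb_by_temperature' must have numeric temperature names (K)")
  if (any(!is.finite(kb)) || any(kb <= 0))
    abort_validation("all binding constants must be finite and > 0")
  if (any(temps <= 0))
    abort_validation("temperatures must be > 0 K")
  if (length(unique(temps)) < 2L)
    abort_fit("van't Hoff fit needs >= 2 distinct temperatures")
  fit <- ols_line(1 / temps, log(kb))
  dH <- -fit$slope * .R_GAS
  dS <- fit$intercept * .R_GAS
  dG <- dH - temps * dS
  structure(list(dH = dH, dS = dS, r2 = fit$r2, gas_constant = .R_GAS,
                 dG_by_T = stats::setNames(dG, temps),
                 temperatures = temps),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> dH = %.2f kJ/mol, dS = %.2f J/mol/K, r2 = %.4f\n",
              x$dH / 1000, x$dS, x$r2))
  for (i in seq_along(x$dG_by_T))
    cat(sprintf("  dG(%s K) = %.2f kJ/mol\n", names(x$dG_by_T)[i], x$dG_by_T[i] / 1000))
  invisible(x)
}

#' Gibbs free energy of binding
#'
#' \eqn{\Delta G^\circ = -RT \ln K_b} with \eqn{R = 8.314}
#' J mol\eqn{^{-1}} K\eqn{^{-1}}; negative whenever \eqn{K_b > 1}
#' (spontaneous association).
#'
#' @param Kb Binding constant, dm\eqn{^3} mol\eqn{^{-1}}, > 0. Vectorized.
#' @param T Temperature in K, > 0.
#' @return \eqn{\Delta G^\circ} in J mol\eqn{^{-1}}.
#' @examples
#' gibbs_free_energy(1e5, 297)  # about -28.4 kJ/mol
#' @export
gibbs_free_energy <- function(Kb, T) {
  if (any(!is.finite(Kb)) || any(Kb <= 0))
    abort_validation("'Kb' must be finite and > 0")
  if (any(!is.finite(T)) || any(T <= 0))
    abort_validation("'T' must be finite and > 0")
  -.R_GAS * T * log(Kb)
}

#' Classify the dominant intermolecular forces from van't Hoff signs
#'
#' The joint signs of \eqn{\Delta H^\circ} and \eqn{\Delta S^\circ}
#' discriminate the principal binding forces (Ross-Subramanian rules):
#' both negative indicates van der Waals forces and/or hydrogen bonding,
#' both positive hydrophobic interactions, and
#' \eqn{\Delta H^\circ < 0, \Delta S^\circ > 0} electrostatic interactions.
#' Values within 1e-9 of zero are treated as zero and yield an
#' indeterminate call. Binding is flagged spontaneous when every fitted
#' \eqn{\Delta G^\circ} is negative.
#'
#' @param fit A `vant_hoff_fit`.
#' @return An object of class `interaction_call`: `forces` (one of
#'   `"vdW_or_H_bond"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"indeterminate"`) and `spontaneous` (logical).
#' @export
classify_interaction <- function(fit) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  eps <- 1e-9
  sgn <- function(v) if (v > eps) 1L else if (v < -eps) -1L else 0L
  sH <- sgn(fit$dH); sS <- sgn(fit$dS)
  forces <- if (sH < 0 && sS < 0) "vdW_or_H_bond"
    else if (sH > 0 && sS > 0) "hydrophobic"
    else if (sH < 0 && sS > 0) "electrostatic"
    else "indeterminate"
  structure(list(forces = forces, spontaneous = all(fit$dG_by_T < 0)),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s, %sspontaneous\n",
              x$forces, if (x$spontaneous) "" else "not "))
  invisible(x)
}
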