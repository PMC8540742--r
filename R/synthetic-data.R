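## Synthetic-spectra generators with known ground truth. Each generator
## samples exactly the model its analysis stage assumes, so in the noiseless
## limit the analysis is the generator's inverse and parameter recovery is a
## strict correctness check.

#' Default ligand-binding scenario
#'
#' Constructs a `binding_scenario` describing a fluorescence quenching
#' titration of BSA (1e-6 mol dm\eqn{^{-3}}) by a ligand forming a 1:1
#' ground-state complex, with van't Hoff temperature dependence
#' \eqn{K_b(T) = \exp(-\Delta H^\circ/(RT) + \Delta S^\circ/R)}. The default
#' enthalpy/entropy pair (\eqn{\Delta H^\circ = -40} kJ mol\eqn{^{-1}},
#' \eqn{\Delta S^\circ = -39} J mol\eqn{^{-1}} K\eqn{^{-1}}) puts
#' \eqn{K_b(297\,K) \approx 9.95\times 10^4} dm\eqn{^3} mol\eqn{^{-1}} and
#' makes both signs negative (van der Waals / hydrogen-bond regime), the
#' magnitudes typical of drug-like ligands on albumin. Titration design:
#' ligand:protein molar ratios 0.1--2.0 in 0.2 steps at 297, 303 and 308 K.
#'
#' @param dH,dS Binding enthalpy (J mol\eqn{^{-1}}) and entropy
#'   (J mol\eqn{^{-1}} K\eqn{^{-1}}).
#' @param n_sites Number of binding sites (Hill-type exponent on `[Q]`).
#' @param tau0 Unquenched fluorophore lifetime, s.
#' @param F0 Reference fluorescence intensity, a.u.
#' @param emission_peak,emission_fwhm Emission band position/width, nm
#'   (used when full spectra are requested).
#' @param protein_conc Protein concentration, mol dm\eqn{^{-3}}.
#' @param ratios Ligand:protein molar ratios of the additions (nonzero,
#'   increasing).
#' @param temperatures Temperatures, K, increasing.
#' @param marker_factors Named multiplicative attenuations of the apparent
#'   `Kb` in the presence of each site marker, in (0, 1].
#' @param epsilon_ex,epsilon_em Ligand molar absorptivities at the
#'   excitation/emission wavelengths, dm\eqn{^3} mol\eqn{^{-1}}
#'   cm\eqn{^{-1}} (0 disables the inner-filter effect).
#' @param noise_sigma Gaussian noise s.d. as a fraction of `F0`.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `binding_scenario`.
#' @examples
#' sc <- default_scenario()
#' kb_at_temperature(sc, 297)  # about 9.95e4
#' @export
default_scenario <- function(dH = -40000, dS = -39, n_sites = 1,
                             tau0 = .TAU0_DEFAULT, F0 = 1000,
                             emission_peak = 348, emission_fwhm = 50,
                             protein_conc = 1e-6,
                             ratios = seq(0.1, 1.9, by = 0.2),
                             temperatures = c(297, 303, 308),
                             marker_factors = c(PHB = 0.9, IBP = 0.5),
                             epsilon_ex = 0, epsilon_em = 0,
                             noise_sigma = 0, seed = 42L) {
  stopifnot_number(dH, "dH"); stopifnot_number(dS, "dS")
  stopifnot_number(n_sites, "n_sites", positive = TRUE)
  stopifnot_number(tau0, "tau0", positive = TRUE)
  stopifnot_number(F0, "F0", positive = TRUE)
  stopifnot_number(protein_conc, "protein_conc", positive = TRUE)
  if (any(ratios <= 0) || any(diff(ratios) <= 0))
    abort_validation("'ratios' must be positive and strictly increasing")
  if (any(diff(temperatures) <= 0) || any(temperatures <= 0))
    abort_validation("'temperatures' must be positive and strictly increasing")
  if (any(marker_factors <= 0) || any(marker_factors > 1))
    abort_validation("'marker_factors' must lie in (0, 1]")
  stopifnot_number(noise_sigma, "noise_sigma", nonnegative = TRUE)
  structure(list(dH = dH, dS = dS, n_sites = n_sites, tau0 = tau0, F0 = F0,
                 emission_peak = emission_peak, emission_fwhm = emission_fwhm,
                 protein_conc = protein_conc, ratios = ratios,
                 temperatures = temperatures, marker_factors = marker_factors,
                 epsilon_ex = epsilon_ex, epsilon_em = epsilon_em,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "binding_scenario")
}

#' Binding constant implied by a scenario at a temperature
#'
#' \eqn{K_b(T) = \exp(-\Delta H^\circ/(RT) + \Delta S^\circ/R)}.
#'
#' @param scenario A `binding_scenario`.
#' @param temperature Temperature, K. Vectorized.
#' @return `Kb` in dm\eqn{^3} mol\eqn{^{-1}}.
#' @export
kb_at_temperature <- function(scenario, temperature) {
  stopifnot(inherits(scenario, "binding_scenario"))
  exp(-scenario$dH / (.R_GAS * temperature) + scenario$dS / .R_GAS)
}

#' Simulate one fluorescence quenching titration
#'
#' Generates a [titration_series()] under the static-quenching 1:1-complex
#' model the double-log regression assumes:
#' \eqn{F = F_0 / (1 + K_b [Q]^n)} with
#' \eqn{[Q]_i = ratio_i \times} protein concentration and, in the presence
#' of a site marker, \eqn{K_b} attenuated by the scenario's marker factor.
#' When the scenario's molar absorptivities are nonzero, the emitted
#' intensities are attenuated by \eqn{10^{-(A_{ex}+A_{em})/2}} with
#' \eqn{A = \epsilon [Q] l} (l = 1 cm), so [correct_inner_filter()] is the
#' exact inverse. Gaussian noise of s.d. `noise_sigma * F0` is added to the
#' quenched points under a seed derived deterministically from the scenario
#' seed, the temperature and the marker; the zero-quencher reference is
#' exactly `F0`.
#'
#' @param scenario A [default_scenario()]-style `binding_scenario`.
#' @param temperature One of `scenario$temperatures`.
#' @param marker `"none"`, `"PHB"` or `"IBP"`.
#' @return A [titration_series()] whose `meta` records the ground truth
#'   (`Kb_true`, `n_true`, `seed_used`).
#' @export
simulate_titration <- function(scenario, temperature,
                               marker = c("none", "PHB", "IBP")) {
  stopifnot(inherits(scenario, "binding_scenario"))
  marker <- match.arg(marker)
  if (!temperature %in% scenario$temperatures)
    abort_validation(sprintf("temperature %g K is not in the scenario design (%s)",
                             temperature,
                             paste(scenario$temperatures, collapse = ", ")))
  factor <- 1
  if (marker != "none") {
    if (!marker %in% names(scenario$marker_factors))
      abort_config(sprintf("no marker factor configured for '%s'", marker))
    factor <- scenario$marker_factors[[marker]]
  }
  kb_eff <- kb_at_temperature(scenario, temperature) * factor
  q <- scenario$ratios * scenario$protein_conc
  F_true <- scenario$F0 / (1 + kb_eff * q^scenario$n_sites)
  A_ex <- scenario$epsilon_ex * q  # l = 1 cm
  A_em <- scenario$epsilon_em * q
  F_obs <- F_true / 10^((A_ex + A_em) / 2)
  sub_seed <- (scenario$seed + 1009L * match(marker, .MARKERS) +
                 as.integer(round(temperature))) %% .Machine$integer.max
  if (scenario$noise_sigma > 0) {
    F_obs <- withr::with_seed(sub_seed, {
      F_obs + stats::rnorm(length(F_obs), sd = scenario$noise_sigma * scenario$F0)
    })
    F_obs <- pmax(F_obs, 1e-6 * scenario$F0)
  }
  titration_series(c(0, q), c(scenario$F0, F_obs),
                   A_ex = c(0, A_ex), A_em = c(0, A_em),
                   temperature = temperature,
                   protein_conc = scenario$protein_conc,
                   marker = marker,
                   meta = list(Kb_true = kb_eff, n_true = scenario$n_sites,
                               seed_used = sub_seed))
}

#' Default secondary-structure scenario
#'
#' Constructs a `structure_scenario` used by the CD and FT-IR generators.
#' The default amide-I composition is the free-BSA benchmark (alpha-helix
#' 53.8\%, beta-sheet 29.2\%, beta-turn 17.0\%) with band centers at 1658,
#' 1632 and 1685 cm\eqn{^{-1}}; the default CD series starts at 60\% helix
#' for the free protein and falls to 55.7\% at ligand:protein ratio 10
#' (a 4.3-percentage-point loss, in the middle of the few-point losses
#' typical for drug-like ligands on albumin).
#'
#' @param class_fractions Named fractions per structure class, summing to 1.
#' @param band_centers,band_fwhms Named numeric vectors (cm\eqn{^{-1}});
#'   each center must lie inside its class's assignment range.
#' @param helix_by_ratio Named numeric vector mapping ligand:protein molar
#'   ratio to CD helix fraction in \[0, 1\].
#' @param noise_sigma Gaussian noise s.d. as a fraction of the peak signal.
#' @param seed Integer seed.
#' @return An object of class `structure_scenario`.
#' @export
structure_scenario <- function(class_fractions = c(alpha_helix = 0.538,
                                                   beta_sheet = 0.292,
                                                   beta_turn = 0.170),
                               band_centers = c(alpha_helix = 1658,
                                                beta_sheet = 1632,
                                                beta_turn = 1685,
                                                beta_antiparallel = 1695,
                                                random_coil = 1645),
                               band_fwhms = c(alpha_helix = 14,
                                              beta_sheet = 16,
                                              beta_turn = 10,
                                              beta_antiparallel = 8,
                                              random_coil = 12),
                               helix_by_ratio = c(`0` = 0.600, `0.5` = 0.592,
                                                  `1` = 0.585, `5` = 0.568,
                                                  `10` = 0.557),
                               noise_sigma = 0, seed = 42L) {
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% .STRUCTURE_CLASSES))
    abort_validation(sprintf("class_fractions names must be among: %s",
                             paste(.STRUCTURE_CLASSES, collapse = ", ")))
  if (abs(sum(class_fractions) - 1) > 1e-9)
    abort_validation("class_fractions must sum to 1")
  if (any(class_fractions < 0))
    abort_validation("class_fractions must be >= 0")
  for (cls in names(class_fractions)) {
    if (is.na(band_centers[cls]) || is.na(band_fwhms[cls]))
      abort_config(sprintf("no band center/fwhm configured for class '%s'", cls))
    if (assign_band_class(band_centers[[cls]]) != cls)
      abort_config(sprintf("band center %g cm-1 is outside the '%s' assignment range",
                           band_centers[[cls]], cls))
  }
  ratios <- suppressWarnings(as.numeric(names(helix_by_ratio)))
  if (any(is.na(ratios)))
    abort_validation("'helix_by_ratio' must have numeric ratio names")
  if (any(helix_by_ratio < 0 | helix_by_ratio > 1))
    abort_validation("helix fractions must lie in [0, 1]")
  stopifnot_number(noise_sigma, "noise_sigma", nonnegative = TRUE)
  structure(list(class_fractions = class_fractions,
                 band_centers = band_centers, band_fwhms = band_fwhms,
                 helix_by_ratio = helix_by_ratio,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "structure_scenario")
}

#' Simulate a CD titration series
#'
#' For each ligand:protein ratio in the scenario, builds a smooth two-lobe
#' negative band over 205--250 nm (lobes near 208 and 222 nm, the classic
#' alpha-helical CD signature) scaled so that the ellipticity at exactly
#' 208 nm equals \eqn{-(4000 + 29000 h) \cdot 10 C n l} millidegrees for
#' helix fraction \eqn{h} -- i.e. the exact inverse of the
#' [mean_residue_ellipticity()] / [alpha_helix_percent()] chain. Seeded
#' Gaussian noise (s.d. `noise_sigma` of the 208 nm magnitude) is added per
#' spectrum.
#'
#' @param scenario A [structure_scenario()].
#' @param C Protein concentration, mol dm\eqn{^{-3}}.
#' @param n_residues Residue count (default 583).
#' @param l Path length, cm.
#' @return List of [spectrum()] objects with `ratio` metadata, ascending in
#'   ratio.
#' @export
simulate_cd_series <- function(scenario, C = 1e-6, n_residues = .BSA_N_RESIDUES,
                               l = 1) {
  stopifnot(inherits(scenario, "structure_scenario"))
  if (!length(scenario$helix_by_ratio))
    abort_validation("'helix_by_ratio' is empty")
  ratios <- as.numeric(names(scenario$helix_by_ratio))
  ord <- order(ratios)
  wl <- seq(205, 250, by = 0.5)
  ## fixed two-lobe shape, value 1 at 208 nm
  shape <- function(lambda)
    exp(-(lambda - 208)^2 / (2 * 6^2)) + 0.9 * exp(-(lambda - 222)^2 / (2 * 8^2))
  shp <- shape(wl) / shape(208)
  out <- vector("list", length(ratios))
  for (i in seq_along(ord)) {
    j <- ord[i]
    h <- scenario$helix_by_ratio[[j]]
    cd208 <- -(4000 + 29000 * h) * (10 * C * n_residues * l)
    y <- cd208 * shp
    if (scenario$noise_sigma > 0) {
      sub_seed <- (scenario$seed + 7919L * i) %% .Machine$integer.max
      y <- withr::with_seed(sub_seed,
        y + stats::rnorm(length(y), sd = scenario$noise_sigma * abs(cd208)))
    }
    out[[i]] <- spectrum(wl, y, axis_kind = "wavelength_nm",
                         meta = list(ratio = ratios[j], helix_true = h,
                                     seed_used = scenario$seed))
  }
  out
}

#' Simulate an FT-IR amide-I spectrum
#'
#' Builds an absorbance spectrum on a 0.5 cm\eqn{^{-1}} grid over
#' 1580--1720 cm\eqn{^{-1}} as a sum of Gaussian bands, one per structure
#' class with nonzero fraction, with band areas proportional to
#' `class_fractions` at the scenario's centers and widths -- exactly the
#' model [fit_band_components()] fits -- plus a mild linear baseline and
#' seeded Gaussian noise (s.d. `noise_sigma` of the peak height).
#'
#' @param scenario A [structure_scenario()].
#' @param baseline Length-2 numeric `c(intercept, slope)` of the additive
#'   baseline (absorbance units; default a small positive tilt).
#' @return A [spectrum()] with `axis_kind = "wavenumber_cm-1"`; its `meta`
#'   records the true class fractions.
#' @export
simulate_ftir_spectrum <- function(scenario, baseline = c(0.02, 5e-5)) {
  stopifnot(inherits(scenario, "structure_scenario"))
  fr <- scenario$class_fractions
  fr <- fr[fr > 0]
  if (abs(sum(scenario$class_fractions) - 1) > 1e-9)
    abort_validation("class_fractions must sum to 1")
  x <- seq(1580, 1720, by = 0.5)
  y <- baseline[1] + baseline[2] * (x - 1580)
  for (cls in names(fr)) {
    ctr <- scenario$band_centers[[cls]]
    w <- scenario$band_fwhms[[cls]]
    amp <- fr[[cls]] / (w * .GAUSS_AREA_FACTOR)  # unit total band area
    y <- y + gaussian_band(x, ctr, w, amp)
  }
  if (scenario$noise_sigma > 0) {
    peak <- max(y - (baseline[1] + baseline[2] * (x - 1580)))
    sub_seed <- (scenario$seed + 104729L) %% .Machine$integer.max
    y <- withr::with_seed(sub_seed,
      y + stats::rnorm(length(y), sd = scenario$noise_sigma * peak))
  }
  spectrum(x, y, axis_kind = "wavenumber_cm-1",
           meta = c(list(seed_used = scenario$seed), as.list(fr)))
}
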