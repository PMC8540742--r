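## End-to-end orchestration: compose the analysis stages over whole
## experiments, write the per-stage report tables and a machine-readable
## parameter summary. Errors are re-raised with the failing stage's name;
## tables already written by earlier stages are left in place.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage '%s': %s", stage, conditionMessage(e)),
                        class = unique(c("albuminbind_stage_error", class(e)))))
  })
}

#' Run the full fluorescence-quenching workflow
#'
#' Executes, in order: inner-filter correction (implicit in the fits),
#' Stern-Volmer regression per temperature, quenching-mechanism
#' classification, double-logarithm binding regression per condition,
#' van't Hoff thermodynamics with interaction-type classification, and --
#' when marker series are supplied -- site-marker competition. Each stage's
#' table is written to `out_dir` (if given) as soon as it is available, so a
#' failure in a later stage leaves earlier outputs intact.
#'
#' @param series List of [titration_series()]: at least 2 marker-free
#'   temperatures; series with `marker = "PHB"` / `"IBP"` are optional and
#'   feed the site-competition stage.
#' @param tau0 Unquenched fluorophore lifetime, s.
#' @param out_dir Optional output directory for the report tables.
#' @param compound Compound label used in the report tables.
#' @return An object of class `fluorescence_workflow`: `stern_volmer`
#'   (list of fits), `mechanism`, `binding` (list of fits), `vant_hoff`,
#'   `interaction`, `site` (or `NULL`), `tables` (the report data frames).
#' @export
run_fluorescence_workflow <- function(series, tau0 = .TAU0_DEFAULT,
                                      out_dir = NULL, compound = "compound") {
  if (!is.list(series) || !all(vapply(series, inherits, logical(1), "titration_series")))
    abort_validation("'series' must be a list of titration_series objects")
  markers <- vapply(series, `[[`, character(1), "marker")
  plain <- series[markers == "none"]
  if (length(plain) < 2L)
    abort_validation("need >= 2 marker-free temperature series for the workflow")
  plain <- plain[order(vapply(plain, `[[`, numeric(1), "temperature"))]
  tables <- list()
  emit <- function() if (!is.null(out_dir)) write_report_tables(tables, out_dir)

  sv <- run_stage("stern_volmer",
                  lapply(plain, fit_stern_volmer, tau0 = tau0))
  tables$stern_volmer <- data.frame(
    compound = compound,
    temperature_K = vapply(sv, `[[`, numeric(1), "temperature"),
    K_SV = vapply(sv, `[[`, numeric(1), "K_SV"),
    intercept = vapply(sv, `[[`, numeric(1), "intercept"),
    k_q = vapply(sv, `[[`, numeric(1), "k_q"),
    r2 = vapply(sv, `[[`, numeric(1), "r2"))
  emit()

  mech <- run_stage("mechanism", classify_mechanism(sv))

  binding <- run_stage("binding", lapply(series, fit_double_log))
  tables$binding <- data.frame(
    compound = compound,
    temperature_K = vapply(binding, `[[`, numeric(1), "temperature"),
    marker = vapply(binding, `[[`, character(1), "marker"),
    Kb = vapply(binding, `[[`, numeric(1), "Kb"),
    n = vapply(binding, `[[`, numeric(1), "n_sites"),
    r2 = vapply(binding, `[[`, numeric(1), "r2"))
  emit()

  plain_fit <- binding[markers == "none"]
  kb <- stats::setNames(vapply(plain_fit, `[[`, numeric(1), "Kb"),
                        vapply(plain_fit, `[[`, numeric(1), "temperature"))
  if (length(kb) == 2L)
    warn_albuminbind("van't Hoff fit from only 2 temperatures: low confidence")
  vh <- run_stage("vant_hoff", fit_vant_hoff(kb))
  inter <- run_stage("interaction", classify_interaction(vh))
  thermo <- data.frame(compound = compound,
                       dH_kJ_mol = vh$dH / 1000, dS_J_mol_K = vh$dS, r2 = vh$r2,
                       forces = inter$forces, spontaneous = inter$spontaneous)
  for (i in seq_along(vh$dG_by_T))
    thermo[[sprintf("dG_kJ_mol_%sK", names(vh$dG_by_T)[i])]] <- vh$dG_by_T[[i]] / 1000
  tables$thermodynamics <- thermo
  emit()

  site <- NULL
  if (any(markers == "PHB") && any(markers == "IBP")) {
    site <- run_stage("site_competition", {
      fit_phb <- binding[markers == "PHB"][[1]]
      fit_ibp <- binding[markers == "IBP"][[1]]
      i_alone <- which(markers == "none" &
                         vapply(binding, `[[`, numeric(1), "temperature") ==
                           fit_phb$temperature)
      if (!length(i_alone))
        abort_validation(sprintf("no marker-free series at the marker temperature %g K",
                                 fit_phb$temperature))
      assess_site_competition(binding[[i_alone[1]]], fit_phb, fit_ibp)
    })
    tables$site_markers <- data.frame(compound = compound,
                                      ratio_PHB = site$ratio_PHB,
                                      ratio_IBP = site$ratio_IBP,
                                      site = site$site)
    emit()
  }

  structure(list(stern_volmer = sv, mechanism = mech, binding = binding,
                 vant_hoff = vh, interaction = inter, site = site,
                 tables = tables),
            class = "fluorescence_workflow")
}

#' @export
print.fluorescence_workflow <- function(x, ...) {
  cat("<fluorescence_workflow>\n")
  print(x$mechanism)
  print(x$vant_hoff)
  print(x$interaction)
  if (!is.null(x$site)) print(x$site)
  invisible(x)
}

#' Run a full multi-modality report
#'
#' Executes whichever analysis stages have inputs in `config` --
#' fluorescence titrations, CD spectra, FT-IR spectra, descriptor table --
#' writes one CSV per stage plus a `parameters.json` with every fitted
#' parameter, and a `manifest.json` recording the seed and stages run.
#' Outputs contain no timestamps, so a rerun with the same inputs and seed
#' is byte-identical.
#'
#' @param config Named list. Recognized entries: `fluorescence` (list of
#'   [titration_series()]), `cd` (list with `spectra` plus optional `C`,
#'   `n_residues`, `l`), `ftir` (list of IR [spectrum()] objects),
#'   `descriptors` (data frame for [screen_table()]), `tau0`, `seed`,
#'   `compound`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-stage results and `paths` of all
#'   files written.
#' @export
run_full_report <- function(config, out_dir) {
  if (!is.list(config) ||
      !any(c("fluorescence", "cd", "ftir", "descriptors") %in% names(config)))
    abort_config("config must supply at least one of: fluorescence, cd, ftir, descriptors")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  compound <- if (!is.null(config$compound)) config$compound else "compound"
  tau0 <- if (!is.null(config$tau0)) config$tau0 else .TAU0_DEFAULT
  results <- list()
  params <- list()
  tables <- list()

  if (!is.null(config$fluorescence)) {
    wf <- run_stage("fluorescence",
                    run_fluorescence_workflow(config$fluorescence, tau0 = tau0,
                                              compound = compound))
    results$fluorescence <- wf
    tables <- c(tables, wf$tables)
    params$fluorescence <- list(
      K_SV = stats::setNames(vapply(wf$stern_volmer, `[[`, numeric(1), "K_SV"),
                             vapply(wf$stern_volmer, `[[`, numeric(1), "temperature")),
      mechanism = wf$mechanism$verdict,
      Kb = stats::setNames(vapply(wf$binding, `[[`, numeric(1), "Kb"),
                           paste0(vapply(wf$binding, `[[`, numeric(1), "temperature"),
                                  "K_", vapply(wf$binding, `[[`, character(1), "marker"))),
      n_sites = vapply(wf$binding, `[[`, numeric(1), "n_sites"),
      dH_J_mol = wf$vant_hoff$dH, dS_J_mol_K = wf$vant_hoff$dS,
      dG_J_mol = wf$vant_hoff$dG_by_T,
      forces = wf$interaction$forces, spontaneous = wf$interaction$spontaneous,
      site = if (!is.null(wf$site)) wf$site$site else NULL)
  }

  if (!is.null(config$cd)) {
    cdcfg <- config$cd
    hl <- run_stage("cd", helix_loss_table(
      cdcfg$spectra,
      C = if (!is.null(cdcfg$C)) cdcfg$C else 1e-6,
      n_residues = if (!is.null(cdcfg$n_residues)) cdcfg$n_residues else .BSA_N_RESIDUES,
      l = if (!is.null(cdcfg$l)) cdcfg$l else 1))
    results$cd <- hl
    tab <- hl$table
    tab <- cbind(compound = compound, tab)
    tab$loss_points <- c(rep(NA, nrow(tab) - 1), hl$loss_points)
    tables$cd_helix <- tab
    params$cd <- list(helix_percent = stats::setNames(hl$table$helix_percent,
                                                      hl$table$ratio),
                      loss_points = hl$loss_points)
  }

  if (!is.null(config$ftir)) {
    sp_list <- config$ftir
    if (inherits(sp_list, "spectrum")) sp_list <- list(sp_list)
    fits <- run_stage("ftir", lapply(sp_list, analyze_ftir))
    results$ftir <- fits
    rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
      comp <- fits[[i]]$components
      ratio <- sp_list[[i]]$meta$ratio
      data.frame(compound = compound,
                 ratio = if (is.null(ratio)) NA_real_ else ratio,
                 component_center_cm1 = comp$center, fwhm_cm1 = comp$fwhm,
                 area_pct = 100 * comp$area / sum(comp$area),
                 assignment = comp$assignment)
    }))
    tables$ftir_structure <- rows
    params$ftir <- lapply(fits, function(f) as.list(f$structure$percent_by_class))
  }

  if (!is.null(config$descriptors)) {
    screened <- run_stage("druglikeness", screen_table(config$descriptors))
    results$druglikeness <- screened
    tables$druglikeness <- screened
    params$druglikeness <- list(
      n_compounds = nrow(screened),
      n_ro5_pass = sum(screened$ro5_pass),
      n_veber_pass = sum(screened$veber_pass))
  }

  paths <- write_report_tables(tables, out_dir)
  json_path <- file.path(out_dir, "parameters.json")
  jsonlite::write_json(params, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(stages = names(results),
                   seed = if (!is.null(config$seed)) config$seed else NA,
                   compound = compound)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(paths = c(paths, json_path, manifest_path))))
}
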