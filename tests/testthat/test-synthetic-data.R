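test_that("default scenario reproduces its closed-form binding constants", {
  sc <- default_scenario()
  expect_equal(kb_at_temperature(sc, 297), 99540.0598291, tolerance = 1e-9)
  expect_lt(kb_at_temperature(sc, 303), kb_at_temperature(sc, 297))
  expect_equal(sc$dH - 297 * sc$dS, -28417)  # dG(297) < 0
  # titration intensity at molar ratio 1.0
  ts <- simulate_titration(sc, 297)
  q6 <- ts$points$quencher_conc[7]          # sixth addition, molar ratio 1.1
  expect_equal(ts$points$F[7], 1000 / (1 + 99540.0598291 * q6), tolerance = 1e-9)
})

test_that("identical scenario and seed give bit-identical outputs", {
  sc <- default_scenario(noise_sigma = 0.01)
  a <- simulate_titration(sc, 303)
  b <- simulate_titration(sc, 303)
  expect_identical(a$points, b$points)
  c <- simulate_titration(default_scenario(noise_sigma = 0.01, seed = 43L), 303)
  expect_false(identical(a$points$F, c$points$F))

  st <- structure_scenario(noise_sigma = 0.01)
  expect_identical(simulate_ftir_spectrum(st)$y, simulate_ftir_spectrum(st)$y)
  expect_identical(simulate_cd_series(st)[[2]]$y, simulate_cd_series(st)[[2]]$y)
})

test_that("generators are right inverses of their analysis stages", {
  sc <- default_scenario()
  for (T in sc$temperatures) {
    fit <- fit_double_log(simulate_titration(sc, T))
    expect_equal(fit$Kb, kb_at_temperature(sc, T), tolerance = 1e-3)
    expect_equal(fit$n_sites, 1, tolerance = 1e-3)
  }
  # marker attenuation propagates through to the site call
  alone <- fit_double_log(simulate_titration(sc, 297, "none"))
  phb <- fit_double_log(simulate_titration(sc, 297, "PHB"))
  ibp <- fit_double_log(simulate_titration(sc, 297, "IBP"))
  expect_equal(phb$Kb / alone$Kb, 0.9, tolerance = 1e-3)
  expect_equal(ibp$Kb / alone$Kb, 0.5, tolerance = 1e-3)
  expect_equal(assess_site_competition(alone, phb, ibp)$site, "site_II_IIIA")
})

test_that("simulated inner-filter attenuation is exactly undone by Eq.-1 correction", {
  sc <- default_scenario(epsilon_ex = 5e4, epsilon_em = 2e4)
  ts <- simulate_titration(sc, 297)
  expect_true(any(ts$points$A_ex > 0))
  fit <- fit_double_log(ts)       # applies the correction internally
  expect_equal(fit$Kb, kb_at_temperature(sc, 297), tolerance = 1e-3)
  # without correction the recovered constant is biased
  stripped <- titration_series(ts$points$quencher_conc, ts$points$F,
                               temperature = 297)
  expect_gt(abs(fit_double_log(stripped)$Kb - kb_at_temperature(sc, 297)) /
              kb_at_temperature(sc, 297), 0.01)
})

test_that("estimator spread grows with the programmed noise level", {
  kb_sd <- function(noise) {
    kbs <- vapply(1:60, function(s) {
      sc <- default_scenario(noise_sigma = noise, seed = 1000L + s)
      # at the highest noise level some low-[Q] points show no net quenching
      # and are excluded with a warning; that is expected here
      suppressWarnings(fit_double_log(simulate_titration(sc, 297))$Kb)
    }, numeric(1))
    stats::sd(kbs)
  }
  spreads <- c(kb_sd(0.001), kb_sd(0.005), kb_sd(0.02))
  expect_true(all(diff(spreads) > 0))
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(default_scenario(ratios = c(0.5, 0.3)),
               class = "albuminbind_validation_error")
  expect_error(default_scenario(marker_factors = c(PHB = 1.2, IBP = 0.5)),
               class = "albuminbind_validation_error")
  sc <- default_scenario(marker_factors = c(PHB = 0.9))
  expect_error(simulate_titration(sc, 297, "IBP"),
               class = "albuminbind_config_error")
  expect_error(simulate_titration(default_scenario(), 300),
               class = "albuminbind_validation_error")
  expect_error(structure_scenario(class_fractions = c(alpha_helix = 0.6,
                                                      beta_sheet = 0.6)),
               class = "albuminbind_validation_error")
  expect_error(structure_scenario(helix_by_ratio = c(`0` = 1.2)),
               class = "albuminbind_validation_error")
  expect_error(structure_scenario(band_centers = c(alpha_helix = 1700,
                                                   beta_sheet = 1632,
                                                   beta_turn = 1685),
                                  class_fractions = c(alpha_helix = 1)),
               class = "albuminbind_config_error")
})

test_that("simulated CD hits the programmed 208 nm ellipticity", {
  sc <- structure_scenario(helix_by_ratio = c(`0` = 0.60))
  sp <- simulate_cd_series(sc)[[1]]
  expect_equal(sp$y[sp$x == 208], -124.762, tolerance = 1e-9)
})

test_that("FT-IR generator scale and composition behave as configured", {
  one <- structure_scenario(class_fractions = c(beta_sheet = 1))
  res <- analyze_ftir(simulate_ftir_spectrum(one))
  expect_equal(unname(res$structure$percent_by_class["beta_sheet"]), 100,
               tolerance = 1e-6)

  # doubling all amplitudes leaves percentages unchanged
  sc <- structure_scenario()
  sp <- simulate_ftir_spectrum(sc)
  doubled <- spectrum(sp$x, 2 * sp$y, "wavenumber_cm-1")
  p1 <- analyze_ftir(sp)$structure$percent_by_class
  p2 <- analyze_ftir(doubled)$structure$percent_by_class
  expect_equal(p1, p2, tolerance = 1e-9)
})
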