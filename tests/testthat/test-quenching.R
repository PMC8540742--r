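test_that("inner-filter correction matches closed-form values and is invertible", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.2, 0.1), 141.253754462, tolerance = 1e-9)
  expect_equal(correct_inner_filter(50, 0.4, 0.4), 125.594321575, tolerance = 1e-9)
  expect_error(correct_inner_filter(100, -0.1, 0), class = "albuminbind_validation_error")

  # invertibility and monotonicity over random inputs
  set.seed(11)
  for (i in 1:50) {
    F_obs <- runif(1, 1, 1e4)
    A <- runif(2, 0, 1.5)
    Fc <- correct_inner_filter(F_obs, A[1], A[2])
    expect_gte(Fc, F_obs)
    expect_equal(Fc * 10^(-(A[1] + A[2]) / 2), F_obs, tolerance = 1e-12)
  }
  A_sum <- seq(0, 2, by = 0.1)
  expect_true(all(diff(correct_inner_filter(100, A_sum, 0)) > 0))
})

test_that("Stern-Volmer fit recovers an exact line and flat data", {
  q <- seq(2e-7, 2e-6, by = 2e-7)
  F0 <- 1000
  ts <- titration_series(c(0, q), c(F0, F0 / (1 + 1e5 * q)))
  fit <- fit_stern_volmer(ts)
  expect_equal(fit$K_SV, 1e5, tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$k_q, fit$K_SV / fit$tau0)

  flat <- titration_series(c(0, q), rep(F0, 11))
  expect_equal(fit_stern_volmer(flat)$K_SV, 0, tolerance = 1e-9)
})

test_that("OLS slope and intercept equal the normal-equation solution", {
  set.seed(7)
  for (i in 1:20) {
    q <- seq(2e-7, 2e-6, by = 2e-7)
    F0 <- 1000
    F <- F0 / (1 + 1e5 * q) + rnorm(length(q), sd = 0.005 * F0)
    ts <- titration_series(c(0, q), c(F0, F))
    fit <- fit_stern_volmer(ts)
    oracle <- ols_normal_equations(q, F0 / F)
    expect_equal(fit$K_SV, oracle$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
  }
})

test_that("Stern-Volmer preconditions and diagnostics fire", {
  short <- titration_series(c(0, 1e-7, 2e-7, 3e-7), c(1000, 990, 980, 970))
  short$points <- short$points[1:3, ]
  expect_error(fit_stern_volmer(short), class = "albuminbind_fit_error")

  # strong upward curvature leaves a fitted intercept well below 1
  q <- seq(2e-7, 2e-6, by = 2e-7)
  curved <- titration_series(c(0, q), c(1000, 1000 / (1 + 4e11 * q^2)))
  expect_warning(fit_stern_volmer(curved), class = "albuminbind_warning")
})

test_that("mechanism classification follows the trend x threshold rule table", {
  mk <- function(ksv, temps, tau0 = 1e-8) {
    lapply(seq_along(ksv), function(i)
      structure(list(K_SV = ksv[i], intercept = 1, k_q = ksv[i] / tau0,
                     tau0 = tau0, r2 = 1, stderr_KSV = 0,
                     temperature = temps[i], intercept_warning = FALSE),
                class = "stern_volmer_fit"))
  }
  temps <- c(297, 303, 308)
  static <- classify_mechanism(mk(c(1.2e5, 1.0e5, 0.8e5), temps))
  expect_equal(static$verdict, "static")
  expect_equal(static$ksv_trend, "decreasing")
  expect_true(all(static$kq_exceeds_threshold))

  dynamic <- classify_mechanism(mk(c(8, 10, 12), temps, tau0 = 1e-8))  # k_q ~ 1e9
  expect_equal(dynamic$verdict, "dynamic")

  expect_equal(classify_mechanism(mk(c(1e5, 1.2e5, 0.9e5), temps))$verdict,
               "ambiguous")
  # decreasing K_SV but sub-threshold k_q: evidence conflicts -> ambiguous
  expect_equal(classify_mechanism(mk(c(12, 10, 8), temps))$verdict, "ambiguous")
  expect_error(classify_mechanism(mk(c(1e5, 9e4), c(297, 297))),
               class = "albuminbind_validation_error")
})

test_that("double-log regression recovers the generating (Kb, n)", {
  ts1 <- make_static_series(Kb = 1e5, n = 1)
  fit1 <- fit_double_log(ts1)
  expect_equal(fit1$Kb, 1e5, tolerance = 1e-3)
  expect_equal(fit1$n_sites, 1, tolerance = 1e-3)
  expect_equal(fit1$Kb, 10^fit1$log10_Kb)
  expect_equal(fit1$r2, 1, tolerance = 1e-9)

  ts2 <- make_static_series(Kb = 5e4, n = 1.2)
  fit2 <- fit_double_log(ts2)
  expect_equal(fit2$Kb, 5e4, tolerance = 5e-3)
  expect_equal(fit2$n_sites, 1.2, tolerance = 5e-3)

  # with n = 1 the Stern-Volmer slope equals Kb
  expect_equal(fit_stern_volmer(ts1)$K_SV, fit1$Kb, tolerance = 1e-3)
})

test_that("unquenched or non-quenching points are excluded or fatal", {
  q <- seq(2e-7, 2e-6, by = 2e-7)
  flat <- titration_series(c(0, q), rep(1000, 11))
  expect_error(fit_double_log(flat), class = "albuminbind_fit_error")

  F <- 1000 / (1 + 1e5 * q)
  F[1] <- 1000  # first addition shows no quenching
  noisy <- titration_series(c(0, q), c(1000, F))
  expect_warning(fit <- fit_double_log(noisy), class = "albuminbind_warning")
  expect_equal(fit$n_points_used, 9)
  expect_equal(fit$n_points_excluded, 1)
})

test_that("site-marker competition applies the Sudlow-site rule", {
  mkfit <- function(Kb, marker = "none", temperature = 297) {
    structure(list(log10_Kb = log10(Kb), Kb = Kb, n_sites = 1, r2 = 1,
                   n_points_used = 10, n_points_excluded = 0,
                   temperature = temperature, marker = marker),
              class = "binding_fit")
  }
  s1 <- assess_site_competition(mkfit(1.0e5), mkfit(0.9e5, "PHB"), mkfit(0.5e5, "IBP"))
  expect_equal(s1$site, "site_II_IIIA")
  expect_equal(s1$ratio_IBP, 0.5)
  s2 <- assess_site_competition(mkfit(1.0e5), mkfit(0.4e5, "PHB"), mkfit(0.9e5, "IBP"))
  expect_equal(s2$site, "site_I_IIA")
  s3 <- assess_site_competition(mkfit(1.0e5), mkfit(1.1e5, "PHB"), mkfit(0.9e5, "IBP"))
  expect_equal(s3$site, "indeterminate")
  expect_error(assess_site_competition(mkfit(1e5), mkfit(9e4, "PHB", 303),
                                       mkfit(5e4, "IBP")),
               class = "albuminbind_validation_error")
})

test_that("k_q scales inversely with tau0", {
  ts <- make_static_series(Kb = 1e5)
  f1 <- fit_stern_volmer(ts, tau0 = 1e-8)
  f2 <- fit_stern_volmer(ts, tau0 = 5e-9)
  expect_equal(f2$k_q, 2 * f1$k_q, tolerance = 1e-12)
})
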