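test_that("summary-dialect titration files parse with metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# temperature_K: 303",
               "# protein_conc_M: 1e-6",
               "# marker: PHB",
               "quencher_conc_M,F",
               "0,1000", "2e-7,980", "4e-7,961", "6e-7,942"), path)
  ts <- read_titration(path, "summary")
  expect_s3_class(ts, "titration_series")
  expect_equal(ts$points$F[1], 1000)
  expect_equal(nrow(ts$points), 4)
  expect_equal(ts$temperature, 303)
  expect_equal(ts$marker, "PHB")
})

test_that("spectra-dialect intensities are read at the reference emission maximum", {
  wl <- seq(300, 400, by = 1)
  peak0 <- 348
  rows <- do.call(rbind, lapply(c(0, 2e-7, 4e-7, 6e-7), function(q) {
    # quenched spectra red-shift by 4 nm: analysis wavelength must stay at the
    # zero-quencher peak, not follow the shifted maxima
    peak <- if (q == 0) peak0 else peak0 + 4
    f <- 1000 / (1 + 1e5 * q)
    data.frame(wavelength_nm = wl, intensity = f * exp(-(wl - peak)^2 / 400),
               quencher_conc_M = q)
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  ts <- read_titration(path, "spectra")
  expect_equal(ts$meta$analysis_wavelength_nm, peak0)
  f_at_ref <- function(q) 1000 / (1 + 1e5 * q) * exp(-(peak0 - (peak0 + 4))^2 / 400)
  expect_equal(ts$points$F[2], f_at_ref(2e-7), tolerance = 1e-9)
})

test_that("titration files without a zero-concentration reference are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("quencher_conc_M,F", "2e-7,980", "4e-7,961", "6e-7,942", "8e-7,925"),
             path)
  expect_error(read_titration(path, "summary"),
               class = "albuminbind_validation_error")
})

test_that("missing columns are reported by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conc,F", "0,1000", "2e-7,980", "4e-7,961", "6e-7,942"), path)
  expect_error(read_titration(path, "summary"), "quencher_conc_M",
               class = "albuminbind_format_error")
})

test_that("duplicate concentrations are rejected", {
  expect_error(titration_series(c(0, 2e-7, 2e-7, 4e-7), c(1000, 980, 979, 961)),
               class = "albuminbind_validation_error")
})

test_that("spectra load sorted regardless of file row order", {
  x <- seq(1700, 1600, by = -5)            # stored descending
  y <- exp(-(x - 1650)^2 / 500)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm1,intensity", paste(x, y, sep = ",")), path)
  sp <- read_spectrum(path, "wavenumber_cm-1")
  expect_true(all(diff(sp$x) > 0))
  expect_equal(sp$y, rev(y))

  shuffled <- sample(seq_along(x))
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm1,intensity",
               paste(x[shuffled], y[shuffled], sep = ",")), path2)
  sp2 <- read_spectrum(path2, "wavenumber_cm-1")
  expect_equal(sp2$x, sp$x)
  expect_equal(sp2$y, sp$y)
})

test_that("malformed spectrum files fail with format or validation errors", {
  one_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm", as.character(205:250)), one_col)
  expect_error(read_spectrum(one_col), class = "albuminbind_format_error")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,intensity", paste(205:210, 1:6, sep = ",")), short)
  expect_error(read_spectrum(short), class = "albuminbind_validation_error")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,intensity",
               paste(205:211, c(1:3, "oops", 5:7), sep = ",")), bad)
  expect_error(read_spectrum(bad), class = "albuminbind_format_error")
})

test_that("write/read round trips preserve values to 1e-9 relative", {
  sc <- default_scenario(noise_sigma = 0.002, epsilon_ex = 100, epsilon_em = 50)
  ts <- simulate_titration(sc, 297)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration(ts, path)
  back <- read_titration(path, "summary")
  expect_equal(back$points$quencher_conc, ts$points$quencher_conc, tolerance = 1e-9)
  expect_equal(back$points$F, ts$points$F, tolerance = 1e-9)
  expect_equal(back$points$A_ex, ts$points$A_ex, tolerance = 1e-9)
  expect_equal(back$temperature, ts$temperature)
  expect_equal(back$marker, ts$marker)

  sp <- simulate_ftir_spectrum(structure_scenario(noise_sigma = 0.001))
  spath <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, spath)
  back_sp <- read_spectrum(spath, "wavenumber_cm-1")
  expect_equal(back_sp$x, sp$x, tolerance = 1e-9)
  expect_equal(back_sp$y, sp$y, tolerance = 1e-9)
})

test_that("report tables are written per stage in deterministic order", {
  out <- withr::local_tempdir()
  res <- list(binding = data.frame(temperature_K = c(297, 303, 308),
                                   Kb = c(1e5, 8e4, 6e4)),
              stern_volmer = data.frame(temperature_K = 297, K_SV = 1e5))
  paths <- write_report_tables(res, out)
  expect_equal(basename(paths), c("stern_volmer.csv", "binding.csv"))
  expect_equal(nrow(utils::read.csv(paths[2])), 3)

  expect_identical(write_report_tables(list(), out), character())
  expect_error(write_report_tables(list(bogus = data.frame(a = 1)), out),
               class = "albuminbind_validation_error")
})
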