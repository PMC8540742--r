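# Independent oracles used across test files.

# Brute-force ordinary least squares via the normal equations, independent of
# the lm() route used inside the package.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Exact static-quenching titration: F = F0 / (1 + Kb * q^n)
make_static_series <- function(Kb, n = 1, F0 = 1000, q = seq(2e-7, 2e-6, by = 2e-7),
                               temperature = 297, marker = "none") {
  F <- F0 / (1 + Kb * q^n)
  titration_series(c(0, q), c(F0, F), temperature = temperature, marker = marker)
}

# Analytic sum-of-Gaussians amide-I profile (FWHM parameterization)
gauss_sum <- function(x, centers, fwhms, amplitudes) {
  y <- numeric(length(x))
  for (j in seq_along(centers))
    y <- y + amplitudes[j] * exp(-4 * log(2) * (x - centers[j])^2 / fwhms[j]^2)
  y
}
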