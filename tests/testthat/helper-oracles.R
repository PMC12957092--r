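# Independent oracles used across the suite.

# brute-force least squares through the normal equations (no lm)
normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# complementary error function via the normal CDF
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

# wide noiseless Gaussian band on a fine wavelength grid
unit_gaussian_band <- function(center, sigma = 30, step = 1) {
  gen_band_spectrum(center, sigma, 1,
                    generator_spec(1, "none",
                                   grid_start = center - 6 * sigma,
                                   grid_stop = center + 6 * sigma,
                                   grid_step = step))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
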