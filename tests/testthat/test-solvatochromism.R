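test_that("orientation polarizability matches published solvent values", {
  expect_lt(abs(orientation_polarizability(46.68, 1.479) - 0.263), 5e-4)
  expect_lt(abs(orientation_polarizability(7.58, 1.4072) - 0.210), 5e-4)
  # terms cancel when eps = n^2
  expect_equal(orientation_polarizability(1.4235^2, 1.4235), 0)
  expect_error(orientation_polarizability(0.5, 1.4), ">= 1")
})

test_that("Stokes shifts match published wavenumber differences", {
  expect_equal(stokes_shift(346, 465.5), 7419.5, tolerance = 0.05)
  expect_equal(stokes_shift(354, 496), 8087.3, tolerance = 0.05)
  expect_equal(stokes_shift(450, 450), 0)
  expect_error(stokes_shift(-1, 450), "positive")
})

test_that("bundled solvent table reproduces its printed derived columns", {
  tab <- triazine_solvent_table()
  expect_equal(nrow(tab), 9)

  dnu <- stokes_shift(tab$lambda_abs_nm, tab$lambda_em_nm)
  expect_equal(dnu, tab$stokes_shift_printed_cm1, tolerance = 0.05 / 7000)

  # delta f reproduces to one unit in the third decimal, except the two
  # rows whose printed values are inconsistent with eps and n (cyclohexane,
  # where the formula gives a slightly negative value, and methanol)
  df <- orientation_polarizability(tab$eps, tab$n)
  keep <- !tab$solvent %in% c("cyclohexane", "methanol")
  expect_true(all(abs(df[keep] - tab$delta_f_printed[keep]) <= 1e-3))
  # and the two exceptions are genuinely off by more than that
  expect_true(all(abs(df[!keep] - tab$delta_f_printed[!keep]) > 5e-4))
})

test_that("solvatochromic series validates its inputs", {
  expect_error(solvatochromic_series("a", 2, 1.4, 0.1, 350, 450), "3 solvents")
  expect_error(
    solvatochromic_series(c("a", "b", "c"), c(2, 3, 4), c(1.4, 1.4, 1.4),
                          c(0.1, 0.2, 0.3), c(350, 350, 350), c(450, 450, 340)),
    "red of"
  )
})

test_that("Lippert fit recovers the generating dipole change", {
  ser <- gen_solvatochromic_series(4.28, 4.1, intercept_cm1 = 5000)
  fit <- lippert_fit(ser, 4.1)
  expect_lt(abs(fit$slope - 2676), 1)
  expect_lt(abs(unname(fit$derived_quantity) - 4.28), 0.001)
  expect_gt(fit$r_squared, 1 - 1e-9)

  # zero dipole change -> flat line -> zero estimate (up to fp noise in
  # the flat-line slope)
  ser0 <- gen_solvatochromic_series(0, 4.1)
  expect_lt(abs(unname(lippert_fit(ser0, 4.1)$derived_quantity)), 1e-4)

  # doubling the cavity radius at fixed slope scales delta mu by 2^(3/2)
  f1 <- lippert_fit(ser, 4.1)
  f2 <- lippert_fit(ser, 8.2)
  expect_equal(unname(f2$derived_quantity) / unname(f1$derived_quantity),
               2^1.5, tolerance = 1e-9)

  # intercept absorption: shifting all Stokes shifts leaves delta mu alone
  ser_b <- gen_solvatochromic_series(4.28, 4.1, intercept_cm1 = 6500)
  expect_equal(unname(lippert_fit(ser_b, 4.1)$derived_quantity),
               unname(fit$derived_quantity), tolerance = 1e-6)
})

test_that("Reichardt fit recovers the generating dipole change", {
  ser <- gen_reichardt_series(1.86, 4.1)
  fit <- reichardt_fit(ser, 4.1)
  expect_lt(abs(unname(fit$derived_quantity) - 1.86), 0.001)

  # reference-betaine identity: a = 6.2 Angstrom and slope 11307.6 -> 9 D
  ser_b <- gen_reichardt_series(9, 6.2, intercept_cm1 = 4000)
  fit_b <- reichardt_fit(ser_b, 6.2)
  expect_lt(abs(fit_b$slope - 11307.6), 0.5)
  expect_lt(abs(unname(fit_b$derived_quantity) - 9), 0.001)

  ser0 <- gen_reichardt_series(0, 4.1)
  expect_lt(abs(unname(reichardt_fit(ser0, 4.1)$derived_quantity)), 1e-4)
})

test_that("negative solvatochromic slopes yield zero dipole change with a flag", {
  tab <- triazine_solvent_table()
  # reversed trend: Stokes shift decreasing in delta f
  ser <- solvatochromic_series(tab$solvent, tab$eps, tab$n, tab$etn,
                               rep(360, 9),
                               1 / (1 / 360 - (8000 - 3000 * orientation_polarizability(tab$eps, tab$n)) / 1e7))
  fit <- lippert_fit(ser, 4.1)
  expect_lt(fit$slope, 0)
  expect_equal(unname(fit$derived_quantity), 0)
  expect_match(fit$flag, "negative slope")
})

test_that("both fitters agree with the normal-equations oracle", {
  tab <- triazine_solvent_table()
  set.seed(42)
  for (i in 1:10) {
    ser <- gen_solvatochromic_series(runif(1, 1, 6), 4.1,
                                     intercept_cm1 = runif(1, 4000, 6000),
                                     spec = generator_spec(i, "additive_gaussian",
                                                           sigma = 150))
    f <- lippert_fit(ser, 4.1)
    o <- normal_equations(ser$delta_f, ser$stokes_cm1)
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
    fr <- reichardt_fit(ser, 4.1)
    or <- normal_equations(ser$etn, ser$stokes_cm1)
    expect_equal(fr$slope, or$slope, tolerance = 1e-9)
  }
})

test_that("solvent include/exclude subsets the fit", {
  ser <- gen_solvatochromic_series(4.28, 4.1)
  fit <- lippert_fit(ser, 4.1, exclude = c("cyclohexane", "dioxane"))
  expect_equal(fit$n_points, 7)
  expect_lt(abs(unname(fit$derived_quantity) - 4.28), 0.001)
})

test_that("Reichardt polarity conversions use the bundled scale", {
  expect_equal(et_normalized_from_et30(55.4), 0.762, tolerance = 5e-4)
  expect_equal(et_normalized_from_et30(30.7), 0)
  expect_equal(et_normalized_from_et30(63.1), 1.0, tolerance = 1e-9)
  expect_equal(et30_from_lambda(28591), 1.0)
  expect_equal(et30_from_lambda(453.2), 63.09, tolerance = 0.005)
  # monotone decreasing in wavelength
  expect_true(all(diff(et30_from_lambda(seq(400, 700, 50))) < 0))
  expect_error(et30_from_lambda(0), "positive")
})

test_that("oscillator strength integrates the extinction spectrum", {
  # constant extinction 1e4 across exactly 5000 cm^-1: f = 4.32e-10 * 5e7
  nu <- seq(22000, 27000, 100)
  rect <- spectrum(nu, rep(1e4, length(nu)), "wavenumber_cm1")
  f <- oscillator_strength(rect)
  expect_equal(f, 0.0216, tolerance = 1e-9)

  zero <- spectrum(nu, rep(0, length(nu)), "wavenumber_cm1")
  expect_equal(oscillator_strength(zero), 0)

  rect2 <- rect
  rect2$signal <- rect2$signal * 3
  expect_equal(oscillator_strength(rect2), 3 * f)

  wrong <- spectrum(nu, rep(1, length(nu)), "wavelength_nm")
  expect_error(oscillator_strength(wrong), "wavenumber")
})

test_that("transition dipole follows the oscillator-strength relation", {
  expect_equal(transition_dipole(0.23, nm_to_wavenumber(358.5)), 4.18,
               tolerance = 0.005)
  expect_equal(transition_dipole(0, 25000), 0)
  expect_equal(transition_dipole(0.4, 25000) / transition_dipole(0.1, 25000),
               2, tolerance = 1e-12)
  expect_error(transition_dipole(0.2, -5), "positive")
})

test_that("relative quantum yield multiplies its correction factors", {
  expect_equal(quantum_yield_relative(1, 1, 0.05, 0.05, 1.33, 1.33), 0.54)
  expect_equal(quantum_yield_relative(2, 1, 0.05, 0.05, 1.33, 1.33), 1.08)
  expect_equal(quantum_yield_relative(0.05, 1, 0.05, 0.05, 1.33, 1.33), 0.027)
  expect_warning(quantum_yield_relative(1, 1, 0.2, 0.05, 1.33, 1.33),
                 "reabsorption|0.1")
  expect_error(quantum_yield_relative(0, 1, 0.05, 0.05, 1.33, 1.33), "positive")
})
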