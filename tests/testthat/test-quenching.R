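test_that("quenching series validates its invariants", {
  expect_error(quenching_series(c(1e-10, 2e-10, 3e-10), c(1, 1, 1)), "first")
  expect_error(quenching_series(c(0, 2e-10, 1e-10), c(1, 1, 1)), "increasing")
  expect_error(quenching_series(c(0, 1e-10, 2e-10), c(1, -1, 1)), "positive")
  s <- quenching_series(c(0, 1e-10, 2e-10, 3e-10), c(100, 60, 40, 30),
                        lifetime_ns = rep(2.1, 4))
  expect_equal(attr(s, "tau0_ns"), 2.1)
})

test_that("Stern-Volmer fit recovers the slope exactly on clean data", {
  q <- c(0, 1e-10, 2e-10, 3e-10)
  i0 <- 500
  s <- quenching_series(q, i0 / (1 + 6.7e9 * q))
  fit <- stern_volmer_fit(s)
  expect_equal(unname(fit$derived_quantity), 6.7e9, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)

  # constant intensities: zero quenching constant
  flat <- quenching_series(q, rep(123, 4))
  expect_equal(unname(stern_volmer_fit(flat)$derived_quantity), 0)

  # intensity scale invariance
  s2 <- quenching_series(q, 7.7 * i0 / (1 + 6.7e9 * q))
  expect_equal(unname(stern_volmer_fit(s2)$derived_quantity), 6.7e9,
               tolerance = 1e-9)

  expect_error(stern_volmer_fit(quenching_series(c(0, 1e-10, 2e-10), c(3, 2, 1))),
               "3 nonzero")

  # distorted I0 flags the intercept
  bad <- quenching_series(q, c(2 * i0, i0 / (1 + 6.7e9 * q[-1])))
  expect_warning(stern_volmer_fit(bad), "intercept")
})

test_that("bimolecular rate reproduces the published quenching constants", {
  expect_equal(bimolecular_rate(6.7e9, 2.1), 3.19e18, tolerance = 5e-3)
  expect_equal(bimolecular_rate(12.6e9, 2.1), 6e18, tolerance = 1e-9)
  expect_equal(bimolecular_rate(5e3, 1e9), 5e3)  # 1 s lifetime
  expect_error(bimolecular_rate(1e9, 0), "positive")
})

test_that("quenching classification separates the textbook regimes", {
  q <- seq(0, 3e-10, length.out = 5)
  # superquenching with flat lifetimes: static mechanism
  s <- quenching_series(q, 100 / (1 + 6.7e9 * q), lifetime_ns = rep(2.1, 5))
  cls <- classify_quenching(6.7e9, bimolecular_rate(6.7e9, 2.1), 9.2e10, s)
  expect_equal(cls$classification, "superquenching")
  expect_equal(cls$mechanism, "static")
  expect_true(cls$lifetime_invariant)
  expect_gt(cls$kq_kd_ratio, 10)

  # diffusion-limited collisional quenching: tau tracks intensity
  q2 <- seq(0, 0.02, length.out = 5)
  clean <- 100 / (1 + 50 * q2)
  d <- quenching_series(q2, clean, lifetime_ns = 2.1 * clean / 100)
  cls2 <- classify_quenching(50, series = d)
  expect_equal(cls2$classification, "dynamic")
  expect_false(cls2$lifetime_invariant)

  # negative fitted slope: enhancement
  cls3 <- classify_quenching(-2e3)
  expect_equal(cls3$classification, "enhancement")

  # no lifetimes: diagnostic unknown, classification from K_SV alone
  s_no <- quenching_series(q, 100 / (1 + 6.7e9 * q))
  cls4 <- classify_quenching(6.7e9, 3.19e18, 9.2e10, s_no)
  expect_true(is.na(cls4$lifetime_invariant))
  expect_equal(cls4$classification, "superquenching")
  expect_equal(cls4$mechanism, "static")  # from kq/kd >> 10
})

test_that("Perrin fit recovers volume and radius from clean data", {
  n0 <- photophysical_constants()$n0_per_cm3_m
  q <- seq(0, 3e-7, length.out = 6)
  v_true <- 8.52e-15
  s <- quenching_series(q, 1000 * exp(-v_true * n0 * q))
  fit <- perrin_fit(s)
  expect_equal(unname(fit$derived_quantity), v_true, tolerance = 1e-9)
  expect_equal(fit$perrin_r_nm, 126.70, tolerance = 1e-3)

  # linearity of the fitted volume in the generating slope
  s2 <- quenching_series(q, 1000 * exp(-2 * v_true * n0 * q))
  expect_equal(unname(perrin_fit(s2)$derived_quantity), 2 * v_true,
               tolerance = 1e-9)

  flat <- quenching_series(q, rep(10, 6))
  expect_equal(unname(perrin_fit(flat)$derived_quantity), 0)
})

test_that("sphere radius-volume conversion matches the published table", {
  expect_equal(radius_from_volume(8.52e-15), 126, tolerance = 1 / 126)
  expect_equal(radius_from_volume(1.39e-14), 149, tolerance = 1 / 149)
  expect_equal(radius_from_volume(4 / 3 * pi), 1e7)  # r = 1 cm
  expect_equal(radius_from_volume(0), 0)
  expect_error(radius_from_volume(-1), ">= 0")
})

test_that("contact radius sums and flags the active-sphere comparison", {
  cr <- contact_radius(0.41, 25)
  expect_equal(cr$contact_r_nm, 25.41)
  expect_equal(contact_radius(0, 7)$contact_r_nm, 7)
  cr2 <- contact_radius(0.41, 25, perrin_r_nm = 126)
  expect_true(cr2$exceeds_contact)
  expect_match(cr2$flag, "exceeds contact")
  expect_false(contact_radius(0.41, 25, perrin_r_nm = 10)$exceeds_contact)
})

test_that("quenching report satisfies its internal identities exactly", {
  q <- seq(0, 1.8e-9, length.out = 8)
  s <- gen_quenching_series("stern_volmer", 6.7e9, q,
                            spec = generator_spec(7, "multiplicative_gaussian",
                                                  sigma = 0.05))
  rep <- quenching_report(s, tau0_ns = 2.1, kd_m1s1 = 9.2e10,
                          r_fluorophore_nm = 0.41, r_quencher_nm = 25)
  expect_equal(rep$kq_m1s1 * 2.1e-9, rep$ksv_m1, tolerance = 1e-12)
  expect_equal(4 / 3 * pi * (rep$perrin_r_nm * 1e-7)^3, rep$perrin_v_cm3,
               tolerance = 1e-9)
  expect_equal(rep$contact_r_nm, 25.41)
})

test_that("enhancement curve reports factors, monotonicity and red-shift", {
  q <- c(0, 1e-10, 2e-10, 3e-10)
  s <- quenching_series(q, c(100, 130, 170, 200))
  e <- enhancement_curve(s)
  expect_equal(e$max_factor, 2.0)
  expect_equal(e$monotone, "increasing")

  flat <- quenching_series(q, rep(100, 4))
  expect_true(all(enhancement_curve(flat)$factors == 1))

  sp0 <- unit_gaussian_band(480)
  sp1 <- unit_gaussian_band(492)
  e2 <- enhancement_curve(s, spectra = list(sp0, sp1))
  expect_equal(e2$peak_shift_nm, 12, tolerance = 0.1)
})

test_that("overlap integral matches the equal-Gaussian closed form", {
  g1 <- unit_gaussian_band(500, sigma = 30)
  expect_equal(overlap_integral(g1, g1), 1.0, tolerance = 1e-6)

  g2 <- unit_gaussian_band(560, sigma = 30)
  ov <- overlap_integral(g1, g2)
  expect_equal(ov, erfc(60 / (2 * sqrt(2) * 30)), tolerance = 0.01)

  # symmetry and intensity-scale invariance
  expect_equal(overlap_integral(g2, g1), ov, tolerance = 1e-12)
  g2s <- g2
  g2s$signal <- g2s$signal * 40
  expect_equal(overlap_integral(g1, g2s), ov, tolerance = 1e-12)

  far <- unit_gaussian_band(1200, sigma = 10)
  expect_warning(ov0 <- overlap_integral(g1, far), "disjoint")
  expect_equal(ov0, 0)
})

test_that("monoexponential decay fit recovers the lifetime", {
  d <- gen_decay_trace(2.1)
  expect_equal(unname(fit_monoexponential_decay(d)$derived_quantity), 2.1,
               tolerance = 1e-9)
  d1 <- gen_decay_trace(1)
  expect_equal(unname(fit_monoexponential_decay(d1)$derived_quantity), 1,
               tolerance = 1e-9)

  # count-scale invariance
  d2 <- d
  d2$signal <- d2$signal * 17
  expect_equal(unname(fit_monoexponential_decay(d2)$derived_quantity), 2.1,
               tolerance = 1e-9)

  rising <- spectrum(seq(0, 10, length.out = 20),
                     exp(seq(0, 10, length.out = 20) / 3), "time_ns")
  expect_error(fit_monoexponential_decay(rising), "non-decaying")
})
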