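test_that("tensionless critical diameter matches 2*sqrt(2k/|W|)", {
  # bare gold: 20 kT membrane, |W| = 42 mN/m -> ~4 nm
  expect_equal(
    critical_diameter_tensionless(membrane_spec(8.4e-20), adhesion_spec(0.042)),
    4, tolerance = 1e-12)
  # hand arithmetic: 2*sqrt(2e-19 / 2e-3) = 2*sqrt(1e-16) = 20 nm
  expect_equal(
    critical_diameter_tensionless(membrane_spec(1e-19), adhesion_spec(0.002)),
    20, tolerance = 1e-12)
  # k -> 0 limit
  expect_equal(
    critical_diameter_tensionless(membrane_spec(1e-30), adhesion_spec(0.042)),
    0, tolerance = 1e-3)
  expect_error(
    critical_diameter_tensionless(membrane_spec(), adhesion_spec(0)),
    "no adhesion")
})

test_that("tension raises the full-wrapping critical diameter", {
  a <- adhesion_spec(0.002)
  # sigma = 0 recovers the tensionless value
  expect_identical(
    critical_diameter_with_tension(membrane_spec(1e-19, tension = 0), a),
    critical_diameter_tensionless(membrane_spec(1e-19), a))
  # 2*sqrt(2e-19 / 1e-3) = 28.284 nm
  expect_equal(
    critical_diameter_with_tension(membrane_spec(1e-19, tension = 1e-3), a),
    2 * sqrt(2 * 1e-19 / 1e-3) * 1e9, tolerance = 1e-12)
  expect_equal(
    critical_diameter_with_tension(membrane_spec(1e-19, tension = 1e-3), a),
    28.2842712, tolerance = 1e-7)
  # sigma >= |W|: full wrapping unreachable
  expect_identical(
    critical_diameter_with_tension(membrane_spec(1e-19, tension = 0.002), a),
    Inf)
  expect_identical(
    critical_diameter_with_tension(membrane_spec(1e-19, tension = 0.01), a),
    Inf)
})

test_that("dc decreases in |W|, increases in k, and dc_sigma >= dc", {
  W_grid <- c(0.001, 0.002, 0.005, 0.01, 0.042, 0.1)
  dc_W <- vapply(W_grid, function(W)
    critical_diameter_tensionless(membrane_spec(), adhesion_spec(W)),
    numeric(1))
  expect_true(all(diff(dc_W) < 0))

  k_grid <- c(1e-20, 4e-20, 8.4e-20, 2e-19, 1e-18)
  dc_k <- vapply(k_grid, function(k)
    critical_diameter_tensionless(membrane_spec(k), adhesion_spec(0.01)),
    numeric(1))
  expect_true(all(diff(dc_k) > 0))

  for (sigma in c(0, 1e-4, 5e-3, 9e-3)) {
    m <- membrane_spec(tension = sigma)
    a <- adhesion_spec(0.01)
    dc <- critical_diameter_tensionless(m, a)
    dcs <- critical_diameter_with_tension(m, a)
    if (sigma == 0) expect_identical(dcs, dc) else expect_gt(dcs, dc)
  }
})

test_that("contact energy follows -kw + m/a - 2*kappa/a^2", {
  # flat-surface limit: no curvature terms
  flat <- adhesion_spec(0.042, flat_strength_kw = 0.042,
                        linear_coeff_m = 0, slb_modulus = 0)
  expect_equal(contact_energy(c(1, 10, 1000), flat), rep(-0.042, 3))
  # a = 10 nm: -0.01 + 5e-11/1e-8 - 2e-19/1e-16 = -0.007 N/m
  au <- adhesion_spec(0.042, flat_strength_kw = 0.01,
                      linear_coeff_m = 5e-11, slb_modulus = 1e-19)
  expect_equal(contact_energy(10, au), -0.007, tolerance = 1e-12)
  # asymptote to -kw
  expect_equal(contact_energy(1e9, au), -0.01, tolerance = 1e-6)
  expect_error(contact_energy(-1, au), "positive")
  expect_error(contact_energy(10, adhesion_spec(0.042)), "constants")
})

test_that("adhesion critical diameter solves the contact-energy quadratic", {
  # gold: negative discriminant -> adhesive at all sizes
  expect_identical(
    adhesion_critical_diameter(adhesion_spec(0.042, 0.042, 0, 0)), 0)
  expect_identical(
    adhesion_critical_diameter(adhesion_spec(0.042, 0.01, 5e-11, 1e-19)), 0)
  # larger root: (1e-10 + sqrt(1e-20 - 8e-21)) / 0.02 = 7.236e-9 m
  dc <- adhesion_critical_diameter(adhesion_spec(0.042, 0.01, 1e-10, 1e-19))
  expect_equal(dc, 2 * (1e-10 + sqrt(2e-21)) / 0.02 * 1e9, tolerance = 1e-12)
  expect_equal(dc, 14.47, tolerance = 1e-3)
  expect_error(adhesion_critical_diameter(adhesion_spec(0.042, 0, 0, 0)),
               "non-adhesive")
})

test_that("adhesion critical diameter agrees with a brute-force sign scan", {
  set.seed(42)
  for (i in 1:15) {
    kw <- runif(1, 0.005, 0.05)
    m <- runif(1, 0, 2e-10)
    ks <- runif(1, 0, 2e-19)
    adh <- adhesion_spec(0.042, kw, m, ks)
    got <- adhesion_critical_diameter(adh)
    want <- oracle_adhesion_dc(kw, m, ks)
    expect_equal(got, want, tolerance = 0.03,
                 info = sprintf("kw=%g m=%g ks=%g", kw, m, ks))
  }
})

test_that("wrapping classification partitions diameters into three regimes", {
  m <- membrane_spec(1e-19, tension = 1e-3)
  a <- adhesion_spec(0.002)           # dc = 20, dc_sigma = 28.28
  expect_identical(classify_wrapping(25, m, a)$label, "PARTIALLY_WRAPPED")
  expect_identical(classify_wrapping(10, m, a)$label, "ADHERED_UNWRAPPED")
  expect_identical(classify_wrapping(30, m, a)$label, "FULLY_WRAPPED")

  # zero tension: the partial regime is empty
  m0 <- membrane_spec(1e-19)
  expect_identical(classify_wrapping(25, m0, a)$label, "FULLY_WRAPPED")
  # sigma >= |W|: never fully wrapped
  mInf <- membrane_spec(1e-19, tension = 0.002)
  expect_identical(classify_wrapping(1000, mInf, a)$label,
                   "PARTIALLY_WRAPPED")

  # partition: contiguous, exhaustive, ordered over a fine diameter sweep
  labels <- vapply(seq(1, 60, by = 0.25), function(d)
    classify_wrapping(d, m, a)$label, character(1))
  runs <- rle(labels)$values
  expect_identical(runs, c("ADHERED_UNWRAPPED", "PARTIALLY_WRAPPED",
                           "FULLY_WRAPPED"))
})
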