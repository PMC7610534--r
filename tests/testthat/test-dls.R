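setup_dls <- optical_setup()

test_that("scattering vector and Stokes-Einstein follow the standard optics", {
  expect_equal(scattering_vector(setup_dls),
               4 * pi * 1.33 * sin(173 / 2 * pi / 180) / 630e-9,
               tolerance = 1e-12)
  expect_equal(scattering_vector(setup_dls), 2.648e7, tolerance = 1e-3)
  # halving the wavelength doubles q
  expect_equal(scattering_vector(optical_setup(wavelength = 315)),
               2 * scattering_vector(setup_dls), tolerance = 1e-12)
  expect_error(optical_setup(angle = 0), "angle")

  su <- optical_setup(viscosity = 8.872e-4)
  expect_equal(stokes_einstein_diffusivity(100, su), 4.92e-12,
               tolerance = 1e-3)
  expect_equal(stokes_einstein_diffusivity(200, su),
               stokes_einstein_diffusivity(100, su) / 2, tolerance = 1e-12)
  expect_equal(
    stokes_einstein_diffusivity(100, optical_setup(temperature = 1e-6)), 0,
    tolerance = 1e-15)
})

test_that("simulated correlograms are Siegert-consistent mixtures", {
  # single population: ln(g2 - 1) linear in tau with slope -2 D q^2
  cg <- simulate_correlogram(population(100, 1e12), setup_dls,
                             delays = seq(1, 500, by = 1), beta = 0.8)
  lf <- lm(log(g2 - 1) ~ I(delay_us * 1e-6), data = cg)
  rate <- stokes_einstein_diffusivity(100, setup_dls) *
    scattering_vector(setup_dls)^2
  expect_equal(-coef(lf)[[2]] / 2, rate, tolerance = 1e-6)
  expect_equal(exp(coef(lf)[[1]]), 0.8, tolerance = 1e-6)
  # intercept g2(0) = 1 + beta
  cg0 <- simulate_correlogram(population(50, 1e10), setup_dls,
                              delays = 1e-6, beta = 0.8)
  expect_equal(cg0$g2, 1.8, tolerance = 1e-6)
  # noiseless g2 is non-increasing
  cg2 <- simulate_correlogram(list(population(10, 1e12),
                                   population(179, 1e9)), setup_dls)
  expect_true(all(diff(cg2$g2) <= 1e-15))
  expect_error(simulate_correlogram(list()), "empty")
})

test_that("Rayleigh d^6 weights explain vesicle-mode dominance", {
  cg <- simulate_correlogram(list(population(10, 1e10),
                                  population(179, 1e10)), setup_dls)
  w <- attr(cg, "weights")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[2], 179^6 / (10^6 + 179^6), tolerance = 1e-12)
  expect_gt(w[2], 0.9999999)
  # weights always normalised
  cg3 <- simulate_correlogram(list(population(5, 3e13), population(25, 4e11),
                                   population(60, 2e10)), setup_dls)
  expect_equal(sum(attr(cg3, "weights")), 1, tolerance = 1e-12)
})

test_that("cumulant analysis inverts the forward model", {
  # noiseless monoexponential
  cg <- simulate_correlogram(population(100, 1e12), setup_dls)
  cf <- cumulant_fit(cg, setup_dls)
  expect_equal(cf$diameter, 100, tolerance = 1e-3)
  expect_lt(abs(cf$pdi), 0.02)
  # seeded noisy vesicle correlogram
  cg179 <- gen_correlogram(population(179, 1e9), setup_dls,
                           noise_sd = 1e-3, seed = 2)
  expect_equal(cumulant_fit(cg179, setup_dls)$diameter, 179,
               tolerance = 0.02)
  # two-population mixture collapses onto the vesicle mode
  mix <- simulate_correlogram(list(population(10, 1e10),
                                   population(179, 1e10)), setup_dls)
  expect_equal(cumulant_fit(mix, setup_dls)$diameter, 179, tolerance = 0.01)
  # flat (fully decayed) input is rejected
  dead <- data.frame(delay_us = 1:100, g2 = rep(1 - 1e-6, 100))
  expect_error(cumulant_fit(dead, setup_dls), "non-positive")
})

test_that("diameter recovery holds across the study's sizes and seeds", {
  for (d in c(5, 10, 25, 35, 50, 60, 179)) {
    for (s in 1:3) {
      cg <- gen_correlogram(population(d, 1e11), setup_dls,
                            noise_sd = 1e-3, seed = s)
      expect_lt(abs(cumulant_fit(cg, setup_dls)$diameter - d) / d, 0.02,
                label = sprintf("d=%g seed=%d rel err", d, s))
    }
  }
})

test_that("population shift metric tracks intensity moving to the slow mode", {
  # comparable mode intensities: 60 nm particles vs 179 nm vesicles
  n_np <- 1e12
  n_ves <- n_np / (179^6 / 60^6)     # equal-intensity modes
  before <- gen_correlogram(list(population(60, n_np),
                                 population(179, n_ves)),
                            setup_dls, noise_sd = 1e-4, seed = 20)
  expect_lt(abs(population_shift_metric(before, before, setup_dls)$metric),
            0.01)
  # extremes: all particle intensity moves to the vesicle mode
  pure_np <- gen_correlogram(population(60, n_np), setup_dls,
                             noise_sd = 1e-4, seed = 21)
  pure_ves <- gen_correlogram(population(179, n_ves), setup_dls,
                              noise_sd = 1e-4, seed = 22)
  ext <- population_shift_metric(pure_np, pure_ves, setup_dls)
  expect_true(ext$converged)
  expect_gt(ext$metric, 0.95)
  # monotone in the bound fraction over a seeded sweep
  fracs <- c(0.2, 0.4, 0.6, 0.8)
  metrics <- vapply(seq_along(fracs), function(i) {
    f <- fracs[i]
    after <- gen_correlogram(list(population(60, (1 - f) * n_np),
                                  population(179, (1 + f) * n_ves)),
                             setup_dls, noise_sd = 1e-4, seed = 30 + i)
    population_shift_metric(before, after, setup_dls)$metric
  }, numeric(1))
  expect_true(all(metrics > 0 & metrics < 1))
  expect_true(all(diff(metrics) > 0))
  expect_error(population_shift_metric(before, pure_np[-1, ], setup_dls),
               "match")
})
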