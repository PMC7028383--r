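test_that("signal scaling obeys the exact n-photon power laws", {
  # cubic law at n = 3, quadratic at n = 2, inverse tau^(n-1)
  expect_equal(signal_per_pulse(2e-9, 60e-15, 1e20, 3) /
                 signal_per_pulse(1e-9, 60e-15, 1e20, 3), 8)
  expect_equal(signal_per_pulse(1e-9, 30e-15, 1e10, 2) /
                 signal_per_pulse(1e-9, 60e-15, 1e10, 2), 2)
  expect_error(signal_per_pulse(1e-9, 60e-15, 1, 4), "order")
  # log-log slope equals the order
  e <- 10^seq(-10, -8, by = 0.25)
  for (n in 2:3) {
    s <- signal_per_pulse(e, 60e-15, 1e15, n)
    expect_equal(unname(coef(lm(log10(s) ~ log10(e)))[2]), n, tolerance = 1e-10)
  }
})

test_that("Cn calibration recovers ground truth and round-trips", {
  # single synthetic point: exact solve
  c3_true <- 2.5e22
  m1 <- data.frame(pulse_energy_j = 1.5e-9, pulse_duration_s = 60e-15,
                   signal_photons_per_pulse =
                     signal_per_pulse(1.5e-9, 60e-15, c3_true, 3))
  expect_equal(calibrate_cn(m1, 3)$cn, c3_true, tolerance = 1e-12)
  # noisy points: truth inside the fit's 95% CI, prediction within 10%
  set.seed(5)
  e <- runif(10, 0.5e-9, 3e-9)
  m <- data.frame(pulse_energy_j = e, pulse_duration_s = 60e-15,
                  signal_photons_per_pulse =
                    signal_per_pulse(e, 60e-15, c3_true, 3) *
                      exp(rnorm(10, 0, 0.05)))
  cal <- calibrate_cn(m, 3)
  expect_gt(c3_true, cal$ci95[1])
  expect_lt(c3_true, cal$ci95[2])
  pred <- signal_per_pulse(2e-9, 60e-15, cal$cn, 3)
  expect_equal(pred, signal_per_pulse(2e-9, 60e-15, c3_true, 3),
               tolerance = 0.1)
  expect_error(calibrate_cn(transform(m1, signal_photons_per_pulse = 0), 3),
               "zero")
})

test_that("surface pulse energy scales exponentially and composes in depth", {
  expect_equal(surface_pulse_energy(1.86, 0, 293), 1.86)
  # two attenuation lengths: 1.86 exp(2) ~ 14 nJ
  expect_equal(surface_pulse_energy(1.86, 2 * 293, 293), 1.86 * exp(2))
  expect_equal(surface_pulse_energy(1.86, 2 * 293, 293), 14, tolerance = 0.02)
  # four attenuation lengths: ~100 nJ
  expect_equal(surface_pulse_energy(1.86, 4 * 293, 293), 100, tolerance = 0.02)
  # semigroup property in depth
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0, 800); b <- runif(1, 0, 800); eal <- runif(1, 100, 400)
    expect_equal(surface_pulse_energy(1.5, a + b, eal),
                 surface_pulse_energy(surface_pulse_energy(1.5, a, eal), b, eal),
                 tolerance = 1e-12)
  }
  expect_error(surface_pulse_energy(1, 100, -5), "positive")
})

test_that("EAL fitting recovers exponential decays and power fractions", {
  # noiseless: exact recovery
  tab <- gen_depth_signal_table(300, 3, depths_um = seq(0, 600, 20))
  fit <- fit_eal(tab, 3)
  expect_equal(fit$eal_um, 300, tolerance = 1e-9)
  expect_equal(fit$surface_signal, 0.1, tolerance = 1e-9)
  # 5% multiplicative noise, 50 depths: within 5%
  tabn <- gen_depth_signal_table(300, 3, depths_um = seq(0, 735, 15),
                                 noise_frac = 0.05, seed = 21)
  expect_equal(fit_eal(tabn, 3)$eal_um, 300, tolerance = 0.05)
  # focus-power fraction drops one decade per EAL*ln(10)
  tab10 <- gen_depth_signal_table(200, 2,
                                  depths_um = c(0, 100, 200 * log(10)))
  f <- fit_eal(tab10, 2)$power_fraction
  expect_equal(f$power_fraction[3], 0.1, tolerance = 1e-9)
  expect_error(fit_eal(tab[c(1, 3, 2), ], 3), "monotone")
})

test_that("cross-over depth matches the closed form on printed inputs", {
  # GCaMP6s surface pulse energies and measured EALs
  expect_equal(crossover_depth(0.24, 1.86, 153, 297),
               log(1.86 / 0.24) / (1 / 153 - 1 / 297), tolerance = 1e-12)
  expect_equal(crossover_depth(0.24, 1.86, 153, 297), 646, tolerance = 0.01)
  expect_equal(crossover_depth(1, 1, 150, 300), 0)
  # invariant under common rescaling of the energy unit
  expect_equal(crossover_depth(0.24e3, 1.86e3, 153, 297),
               crossover_depth(0.24, 1.86, 153, 297))
  expect_warning(zx <- crossover_depth(2, 1, 153, 297), "no crossover")
  expect_true(is.na(zx))
})

test_that("three-photon saturation reproduces the GCaMP6s pulse energies", {
  p <- saturation_params()
  expect_equal(saturation_probability(4.3, p), 0.63, tolerance = 0.05)
  expect_equal(saturation_probability(2.0, p), 0.10, tolerance = 0.05)
  expect_equal(saturation_probability(0, p), 0)
  # strictly increasing in pulse energy
  pr <- saturation_probability(seq(0.5, 8, by = 0.5), p)
  expect_true(all(diff(pr) > 0))
  # cube-law consistency of the inverse: E(1-1/e)/E(0.105) = (1/0.105)^(1/3)
  # on the exponent scale
  r <- saturation_energy(1 - exp(-1), p) / saturation_energy(0.105, p)
  expect_equal(r, (1 / log(1 / (1 - 0.105)))^(1 / 3), tolerance = 1e-10)
  # inverse round trip
  for (target in c(0.05, 0.3, 0.63, 0.95))
    expect_equal(saturation_probability(saturation_energy(target, p), p),
                 target, tolerance = 1e-10)
  expect_error(saturation_energy(1.2, p), "strictly")
})
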