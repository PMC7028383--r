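test_that("launch draws follow the Gaussian back-aperture fill", {
  beam <- beam_geometry(z_focus_um = 1000)
  # 70% fill of an NA 1.05 objective gives effective NA ~0.75
  expect_equal(beam$na_eff, 0.735, tolerance = 1e-12)
  expect_equal(beam$na_eff, 0.75, tolerance = 0.03)
  # u = 1 launches an on-axis ray through the focus
  on_axis <- launch_photon(beam, 1)
  expect_equal(on_axis$w_mm, 0)
  expect_equal(on_axis$r_mm, 0)
  # polar angle at the 1/e^2 radius equals the effective NA
  at_w0 <- launch_photon(beam, exp(-2))
  expect_equal(beam$n0 * sin(at_w0$theta_rad), beam$na_eff, tolerance = 1e-12)
  # distributional oracle: w^2 is exponential with rate 2/w0^2
  set.seed(19)
  u <- runif(1e5)
  d <- launch_photon(beam, u)
  ks <- suppressWarnings(ks.test(d$w_mm^2, "pexp", rate = 2 / beam$w0_mm^2))
  expect_gt(ks$p.value, 0.01)
  # geometry: every ray converges on the focal point
  expect_equal(d$r_mm, tan(d$theta_rad) * 1.0, tolerance = 1e-12)
  expect_error(launch_photon(beam, 0), "in \\(0, 1\\]")
})

test_that("transport reduces to Beer-Lambert in a purely absorbing medium", {
  ag <- slab_transport(1e5, mua = 0.5, mus = 0, g = 0, thickness_mm = 6,
                       seed = 101)
  prof <- colSums(ag$values)            # proportional to absorbed per z-bin
  z_edges <- c(0, ag$z_mm + ag$dz_mm / 2)
  expected <- exp(-0.5 * z_edges[-length(z_edges)]) - exp(-0.5 * z_edges[-1])
  # compare normalised depth profiles
  expect_equal(prof / sum(prof), expected / sum(expected), tolerance = 0.02)
  # total absorbed matches the analytic slab absorption
  expect_equal(ag$heating_fraction, 1 - exp(-0.5 * 6), tolerance = 0.01)
})

test_that("photon weight is conserved exactly", {
  b <- beam_geometry(z_focus_um = 500)
  tis <- tissue_optics(1320)
  ag <- simulate_transport(b, tis, n_photons = 2e4, seed = 1)
  expect_lt(abs(ag$conservation), 1e-9)
  # without roulette the residual bucket is only the hard floor
  ag2 <- simulate_transport(b, tis, n_photons = 5e3, seed = 2,
                            roulette = FALSE)
  expect_lt(abs(ag2$conservation), 1e-9)
  expect_lt(abs(ag2$roulette_net), 1e-6)
  # fate fractions sum to one up to the roulette noise
  expect_equal(sum(ag$fate_summary), 1, tolerance = 1e-2)
  # volume integral of Sh equals the heating fraction (per watt in)
  vol <- pi * outer((ag$r_mm + ag$dr_mm / 2)^2 - (ag$r_mm - ag$dr_mm / 2)^2,
                    rep(ag$dz_mm, length(ag$z_mm)))
  expect_equal(sum(ag$values * vol) / 1000, ag$heating_fraction,
               tolerance = 1e-6)
})

test_that("runs are seed-reproducible and statistically consistent", {
  b <- beam_geometry(z_focus_um = 1000)
  tis <- tissue_optics(1320)
  a1 <- simulate_transport(b, tis, n_photons = 1e4, seed = 33)
  a2 <- simulate_transport(b, tis, n_photons = 1e4, seed = 33)
  expect_identical(a1$values, a2$values)
  expect_identical(a1$fate_summary, a2$fate_summary)
  a3 <- simulate_transport(b, tis, n_photons = 1e4, seed = 34)
  se <- sqrt(attr(a1$fate_summary, "se")^2 + attr(a3$fate_summary, "se")^2)
  expect_true(all(abs(a1$fate_summary - a3$fate_summary) < 3.5 * se + 1e-9))
})

test_that("slab fates agree with an unweighted analog Monte Carlo oracle", {
  mua <- 0.3; mus <- 2; g <- 0.5; L <- 0.8
  set.seed(55)
  oracle <- analog_slab_mc(2e4, mua, mus, g, L)
  ag <- slab_transport(4e4, mua, mus, g, L, seed = 56)
  got <- c(absorbed = unname(ag$fate_summary["heating"]),
           reflected = unname(ag$fate_summary["window"]),
           transmitted = unname(ag$fate_summary["escaped"]))
  se <- sqrt(oracle * (1 - oracle) / 2e4 + got * (1 - got) / 4e4)
  expect_true(all(abs(got - oracle[names(got)]) < 3 * se[names(got)]))
})

test_that("heating increases with absorption at fixed scattering", {
  b <- beam_geometry(z_focus_um = 1000)
  heat <- vapply(c(0.05, 0.12, 0.3), function(mua) {
    tis <- tissue_optics(1320, mua_per_mm = mua, mus_per_mm = 3.2)
    simulate_transport(b, tis, n_photons = 8e3, seed = 77)$heating_fraction
  }, numeric(1))
  expect_true(all(diff(heat) > 0))
})

test_that("near-transparent tissue lets all photons escape", {
  b <- beam_geometry(z_focus_um = 1000)
  tis <- tissue_optics(1320, mua_per_mm = 1e-6, mus_per_mm = 1e-6)
  ag <- simulate_transport(b, tis, n_photons = 2e3, seed = 9)
  expect_gt(ag$fate_summary["escaped"], 0.999)
  expect_lt(ag$heating_fraction, 1e-3)
})

test_that("integrated absorption is stable under voxel refinement", {
  b <- beam_geometry(z_focus_um = 1000)
  tis <- tissue_optics(1320)
  coarse <- simulate_transport(b, tis,
                               simulation_geometry(voxel_um = 40),
                               n_photons = 2e4, seed = 12)
  fine <- simulate_transport(b, tis,
                             simulation_geometry(voxel_um = 20),
                             n_photons = 2e4, seed = 12)
  expect_identical(coarse$heating_fraction, fine$heating_fraction)
  vol <- function(a) pi * outer((a$r_mm + a$dr_mm / 2)^2 -
                                  (a$r_mm - a$dr_mm / 2)^2,
                                rep(a$dz_mm, length(a$z_mm)))
  expect_equal(sum(coarse$values * vol(coarse)),
               sum(fine$values * vol(fine)), tolerance = 0.02)
})
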