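test_that("insulated zero-source field settles at the perfusion balance", {
  th <- thermal_params()
  f <- solve_bioheat(heat_grid(20, 20, 100), 0, th,
                     bioheat_bc(insulated = TRUE))
  t_expected <- th$t_a + th$q_m / th$perfusion_mw_mm3_c   # ~36.99 C
  expect_equal(max(abs(f$values - t_expected)), 0, tolerance = 1e-8)
  expect_equal(max_temperature(f, radius_um = 300, height_um = 500),
               t_expected, tolerance = 1e-8)
  expect_equal(t_expected, 37.0, tolerance = 0.01)
})

test_that("point source in a perfused medium matches the Green's function", {
  th <- thermal_params(q_m = 1e-9)       # suppress metabolic background
  L <- th$perfusion_length_mm
  k <- th$k
  q_mw <- 5
  nr <- 80; nz <- 160; dv <- 0.05
  zsrc <- nz / 2 * dv - dv / 2
  green <- function(d) q_mw * exp(-d / L) / (4 * pi * k * pmax(d, 1e-6))
  bc <- bioheat_bc(dirichlet_fn = function(r, z) {
    th$t_a + green(sqrt(r^2 + (z - zsrc)^2))
  })
  grid <- heat_grid(nr, nz, dv * 1000)
  src <- matrix(0, nr, nz)
  src[1, nz / 2] <- q_mw / (2 * pi * grid$r_mm[1] * dv * dv)  # mW/mm^3
  f <- solve_bioheat(grid, thermal = th, bc = bc, source_mw_mm3 = src)
  # compare along the axis and diagonally, away from the source cell and rim
  for (off_mm in c(0.3, 0.6, 1.2)) {
    iz <- nz / 2 + round(off_mm / dv)
    got <- f$values[1, iz] - th$t_a
    want <- green(abs(grid$z_mm[iz] - zsrc))
    expect_equal(got, want, tolerance = 0.03)
    ir <- round(off_mm / dv)
    got_r <- f$values[ir, nz / 2] - th$t_a
    want_r <- green(sqrt(grid$r_mm[ir]^2))
    expect_equal(got_r, want_r, tolerance = 0.03)
  }
})

test_that("steady state conserves power: source = perfusion sink + boundary", {
  grid <- heat_grid(60, 60, 100)
  src <- matrix(0, 60, 60)
  src[1:4, 8:12] <- 5
  f <- solve_bioheat(grid, thermal = thermal_params(), bc = bioheat_bc(),
                     source_mw_mm3 = src)
  b <- f$balance
  input <- b["optical_mw"] + b["metabolic_mw"]
  output <- b["perfusion_sink_mw"] + b["boundary_loss_mw"]
  expect_equal(unname(input), unname(output), tolerance = 0.01)
})

test_that("temperature field is linear in the optical source", {
  grid <- heat_grid(50, 50, 100)
  src <- matrix(0, 50, 50)
  src[1:5, 5:15] <- 2
  f0 <- solve_bioheat(grid, source_mw_mm3 = src * 0)
  f1 <- solve_bioheat(grid, source_mw_mm3 = src)
  f2 <- solve_bioheat(grid, source_mw_mm3 = 2 * src)
  expect_equal(f2$values - f0$values, 2 * (f1$values - f0$values),
               tolerance = 1e-8)
})

test_that("transient solution relaxes to the steady state", {
  grid <- heat_grid(40, 40, 150)
  src <- matrix(0, 40, 40)
  src[1:4, 4:10] <- 3
  fs <- solve_bioheat(grid, source_mw_mm3 = src, mode = "steady")
  ft <- solve_bioheat(grid, source_mw_mm3 = src, mode = "transient",
                      t_s = 600, dt_s = 2)
  expect_lt(max(abs(fs$values - ft$values)), 0.05)
  # convergence towards the steady state is monotone in time
  f60 <- solve_bioheat(grid, source_mw_mm3 = src, mode = "transient",
                       t_s = 60, dt_s = 1)
  expect_gt(max(abs(f60$values - fs$values)),
            max(abs(ft$values - fs$values)))
})

test_that("hottest-volume metric averages below the pointwise maximum", {
  grid <- heat_grid(60, 60, 100)
  src <- matrix(0, 60, 60)
  src[1:3, 18:24] <- 10
  f <- solve_bioheat(grid, source_mw_mm3 = src)
  m <- max_temperature(f)
  expect_lte(m, max(f$values))
  expect_gt(m, mean(f$values))
  # uniform field returns that value
  fu <- f; fu$values[] <- 38.2
  expect_equal(max_temperature(fu), 38.2)
  # metric stable under 2x grid refinement of the same physical source
  grid2 <- heat_grid(120, 120, 50)
  src2 <- matrix(0, 120, 120)
  src2[1:6, 35:48] <- 10
  f2 <- solve_bioheat(grid2, source_mw_mm3 = src2)
  expect_equal(max_temperature(f2), m, tolerance = 0.004)  # within 0.1 C
})

test_that("zero power with a cooled window keeps the brain below 37 C", {
  grid <- heat_grid(100, 100, 60)
  f <- solve_bioheat(grid, 0)
  expect_lt(max(f$values), 37)
  # window cooling pulls the surface under the window towards the window
  expect_lt(f$values[1, 1], 33)
})

test_that("scan-induced fluctuation follows the half-period cooling rule", {
  expect_equal(scan_fluctuation(0.1, 2), 0.05)
  expect_equal(scan_fluctuation(0.1, 1), 0.1)
  expect_equal(scan_fluctuation(0.1, 1e9), 0, tolerance = 1e-9)
  expect_error(scan_fluctuation(-0.1, 2), "positive")
})

test_that("immersion-water correction matches the printed transmissions", {
  # 80 mW after the objective arrives as ~68 mW at the surface at 1320 nm
  expect_equal(water_absorption_correction(80, 1.0, 1320), 68, tolerance = 0.01)
  expect_equal(water_absorption_correction(80, 0, 1320), 80)
  # at 920 nm the correction is below 2% over 2 mm
  expect_gt(water_absorption_correction(100, 2, 920), 98)
  expect_error(water_absorption_correction(80, -1), ">= 0")
})
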