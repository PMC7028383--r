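test_that("staining model ties inhomogeneity to labelled fraction", {
  st <- staining_model(chi = 50)
  expect_equal(st$volume_fraction, 0.02)
  expect_equal(staining_model(volume_fraction = 0.02)$chi, 50)
  expect_equal(st$chi * st$volume_fraction, 1)
  expect_error(staining_model(chi = 0.5), ">= 1")
  expect_error(staining_model(), "give")
})

test_that("two-photon SBR reaches unity near 4.7 attenuation lengths", {
  st <- staining_model(chi = 50)
  z1 <- sbr_unity_depth(2, st)
  expect_gt(z1, 4.0)
  expect_lt(z1, 5.4)
  # shallow imaging: SBR of order 10^2
  expect_gt(sbr_vs_depth(2, st, 0.5)$sbr, 20)
  expect_lt(sbr_vs_depth(2, st, 0.5)$sbr, 500)
})

test_that("SBR is monotone in depth, staining inhomogeneity and order", {
  st <- staining_model(chi = 50)
  prof <- sbr_vs_depth(2, st, seq(0.5, 6, by = 0.5))
  expect_true(all(diff(prof$sbr) < 0))
  # higher inhomogeneity gives higher SBR at fixed depth
  s_chi <- vapply(c(10, 50, 200, 1000),
                  function(ch) sbr_vs_depth(2, staining_model(chi = ch), 4)$sbr,
                  numeric(1))
  expect_true(all(diff(s_chi) > 0))
  # three-photon SBR beats two-photon at every depth for equal EAL/staining
  for (z in c(1, 2, 4, 4.7, 6)) {
    expect_gte(sbr_vs_depth(3, st, z, wavelength_nm = 920, eal_um = 154)$sbr,
               sbr_vs_depth(2, st, z, wavelength_nm = 920, eal_um = 154)$sbr)
  }
})

test_that("brute-force voxel integration confirms higher-order suppression", {
  # independent oracle: discretise the focused double cone on a (rho, zeta)
  # grid and integrate I^n directly, with ballistic attenuation of the power
  eal <- 154; zr <- 0.69; w0 <- 0.39; zf <- 3 * eal
  zeta <- seq(-zf + 1, 4 * eal, by = 1)           # um steps along the axis
  w <- w0 * sqrt(1 + (zeta / zr)^2)
  ratio_in_out <- function(n) {
    # per-plane integral of I^n for a Gaussian profile: P^n / (w^2)^(n-1),
    # evaluated by explicit radial quadrature rather than the closed form
    per_plane <- vapply(seq_along(zeta), function(i) {
      rho <- seq(0, 6 * w[i], length.out = 200)
      I <- exp(-(zf + zeta[i]) / eal) * 2 / (pi * w[i]^2) *
        exp(-2 * rho^2 / w[i]^2)
      sum((I^n) * 2 * pi * rho) * (rho[2] - rho[1])
    }, numeric(1))
    infocus <- abs(zeta) <= zr
    sum(per_plane[infocus]) / sum(per_plane[!infocus])
  }
  expect_gt(ratio_in_out(3), ratio_in_out(2))
})

test_that("apparent amplitude follows the background dilution law", {
  expect_equal(apparent_dff(0.3, 1), 0.15)
  expect_equal(apparent_dff(0.3, Inf), 0.3)
  expect_equal(apparent_dff(0.42, 3), 0.42 / (1 + 1 / 3))
  # composition with the discriminability correction reproduces the
  # background-corrected d' exactly: d'(F0', dff') with F0' = F0 (1 + 1/SBR)
  ind <- gcamp6s()
  for (s in c(0.5, 1, 4, 50)) {
    ind_app <- indicator_params(apparent_dff(ind$dff_single_ap, s),
                                ind$tau_decay_s)
    expect_equal(dprime(ind_app, 100 * (1 + 1 / s)),
                 dprime(ind, 100, sbr = s), tolerance = 1e-12)
  }
})

test_that("SBR measurement recovers generator ground truth", {
  gs <- gen_stack(stack_spec(sbr = 5, depths_um = seq(0, 100, 20), seed = 42))
  ms <- measure_sbr(gs$stack, background_mask = !gs$mask[, , 1])
  expect_equal(mean(ms$sbr), 5, tolerance = 0.1)
  expect_false(attr(ms, "infinite_background"))
  # background-free stack flags infinite SBR
  gs0 <- gen_stack(stack_spec(sbr = Inf, depths_um = c(0, 10), seed = 7))
  ms0 <- measure_sbr(gs0$stack,
                     background_mask = !apply(gs0$mask, 1:2, any))
  expect_true(attr(ms0, "infinite_background"))
  expect_true(all(!is.finite(ms0$sbr)))
  # theory-driven background makes measured SBR decrease with depth
  gsd <- gen_stack(stack_spec(depths_um = seq(200, 700, 100),
                              signal_peak_counts = 3000, seed = 12))
  msd <- measure_sbr(gsd$stack,
                     background_mask = !apply(gsd$mask, 1:2, any))
  expect_true(all(diff(msd$sbr) < 0))
  expect_error(measure_sbr(gs$stack, background_mask = gs$mask[, , 1] & FALSE),
               "empty")
})

test_that("staining estimation recovers the 2% labelled fraction", {
  gs <- gen_stack(stack_spec(sbr = 20, depths_um = seq(0, 100, 10), seed = 3))
  est <- estimate_staining(gs$stack)
  expect_equal(est$volume_fraction, 0.02, tolerance = 0.25)
  expect_lt(abs(est$volume_fraction - 0.02), 0.005)
  expect_equal(est$chi, 50, tolerance = 0.3)
  expect_equal(est$chi * est$volume_fraction, 1)
  # all-background frame is flagged
  flat <- array(0, c(32, 32, 1))
  expect_error(estimate_staining(flat), "no labelled")
})
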