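test_that("pixel-to-photon conversion is linear and clipped at zero", {
  img <- matrix(c(100, 140, 180, 60), 2)
  ph <- pixels_to_photons(img, 40, offset = 100)
  expect_equal(as.vector(ph), c(0, 1, 2, 0))
  expect_equal(pixels_to_photons(matrix(0, 3, 3), 40), matrix(0, 3, 3))
  expect_error(pixels_to_photons(img, -1), "positive")
  # doubling the photon rate doubles the converted counts within shot noise
  g1 <- gen_photon_image(mean_photons = 0.4, seed = 2)
  g2 <- gen_photon_image(mean_photons = 0.8, seed = 3)
  m1 <- mean(pixels_to_photons(g1$image, 40, 100))
  m2 <- mean(pixels_to_photons(g2$image, 40, 100))
  expect_equal(m2 / m1, 2, tolerance = 0.05)
})

test_that("histogram-mode calibration recovers the conversion factor", {
  g <- gen_photon_image(conversion_factor = 40, offset = 100, seed = 9)
  cc <- calibrate_conversion(g$image)
  expect_equal(cc$offset, 100, tolerance = 0.05)
  expect_equal(cc$conversion_factor, 40, tolerance = 0.05)
  expect_error(calibrate_conversion(matrix(5, 50, 50)), "modes")
})

test_that("preprocessing normalises, preserves DC, and recovers amplitude", {
  # constant trace maps to all zeros
  const <- trace_recording(rep(50, 300), 13.6)
  expect_equal(preprocess(const)$dff, rep(0, 300))
  # unit-gain window: smoothing leaves the mean unchanged
  set.seed(8)
  noisy <- trace_recording(rpois(600, 30), 13.6)
  pp <- preprocess(noisy)
  expect_equal(mean(pp$smoothed), mean(noisy$photons), tolerance = 1e-3)
  # high-budget transient: filtered peak matches the closed construction,
  # within ~12% of the true amplitude (low-pass attenuation of the instant
  # rise); the matched-filter estimate is unbiased
  g <- gen_trace(trace_spec(f0_photons_per_s = 2e6, duration_s = 40,
                            spike_times_s = 15, seed = 4))
  prep <- preprocess(g$recording)
  oracle <- filtered_peak_oracle(0.3, 2, 13.6)
  f0_true <- 2e6 / 13.6
  expect_equal((max(prep$smoothed) - f0_true) / f0_true, oracle,
               tolerance = 0.01)
  expect_equal(max(prep$dff), 0.3, tolerance = 0.13)
  expect_equal(prep$f0_photons_per_s, 2e6, tolerance = 0.005)
  expect_error(preprocess(trace_recording(rep(2, 4), 13.6)), "shorter")
})

test_that("spike inference finds noiseless transients exactly", {
  g <- gen_trace(trace_spec(f0_photons_per_s = 1e6, duration_s = 70,
                            spike_times_s = c(10, 30, 50), seed = 3))
  inf <- infer_spikes(g$recording)
  expect_length(inf$onsets, 3)
  expect_true(all(abs(inf$times_s - c(10, 30, 50)) <= 1 / 13.6 + 1e-9))
  expect_equal(inf$amplitudes, rep(0.3, 3), tolerance = 0.02)
})

test_that("matched-filter amplitudes recover dF/F within 10% at modest budgets", {
  amps <- numeric(0)
  for (s in 1:4) {
    g <- gen_trace(trace_spec(f0_photons_per_s = 400, duration_s = 75,
                              spike_times_s = c(10, 35, 60), seed = 100 + s))
    inf <- infer_spikes(g$recording)
    keep <- abs(outer(inf$times_s, c(10, 35, 60), "-")) < 1
    amps <- c(amps, inf$amplitudes[rowSums(keep) > 0])
  }
  expect_equal(mean(amps), 0.3, tolerance = 0.1)
})

test_that("detection operating point matches the discriminability model", {
  # the matched-filter ROC must be mutually consistent with the equal-
  # variance Gaussian detection model at the midpoint threshold
  for (d in c(2, 3)) {
    pt <- roc_point(d, n = 150, seed = 9000 + d)
    want <- detection_rates(d)
    expect_lt(abs(pt["tpr"] - want$tpr), 0.09)
    expect_lt(abs(pt["fpr"] - want$fpr), 0.09)
  }
  # detection improves monotonically with photon budget
  ind <- gcamp6s()
  tprs <- vapply(c(25, 100, 400), function(f0) {
    d <- dprime(ind, f0)
    unname(roc_point(d, n = 60, seed = 777)["tpr"])
  }, numeric(1))
  expect_true(all(diff(tprs) > 0))
})

test_that("channel amplitude ratios expose background dilution", {
  fs <- 13.6
  spikes <- c(10, 30, 50)
  # identical channels: ratios 1, correlation 1
  g <- gen_trace(trace_spec(f0_photons_per_s = 5e4, duration_s = 70,
                            spike_times_s = spikes, seed = 21))
  d3 <- preprocess(g$recording)$dff
  r_id <- dff_ratio(d3, d3, fs, min_peak = 0.2)
  expect_equal(r_id$ratio, rep(1, nrow(r_id)))
  expect_equal(attr(r_id, "pearson"), 1)
  expect_gte(nrow(r_id), 3)
  # 2P channel with background B = F0 (SBR = 1): ratios ~0.5
  g2 <- gen_trace(trace_spec(f0_photons_per_s = 5e4,
                             background_photons_per_s = 5e4,
                             duration_s = 70, spike_times_s = spikes,
                             seed = 22), channel = "2P")
  d2 <- preprocess(g2$recording)$dff
  rr <- dff_ratio(d3, d2, fs, min_peak = 0.2)
  expect_equal(mean(rr$ratio), 0.5, tolerance = 0.05)
  # invariant to common gain on both channels
  rg <- dff_ratio(d3, d2, fs, min_peak = 0.2)
  expect_equal(rg$ratio, rr$ratio)
  # no matching peaks: flagged empty
  expect_warning(r0 <- dff_ratio(rep(0, 100), rep(0, 100), fs), "no matched")
  expect_true(attr(r0, "no_matches"))
})

test_that("background-free noisy channel pair keeps unity amplitude ratio", {
  ratios <- numeric(0)
  for (s in 1:3) {
    ga <- gen_trace(trace_spec(f0_photons_per_s = 600, duration_s = 75,
                               spike_times_s = c(12, 40, 65), seed = 300 + s))
    gb <- gen_trace(trace_spec(f0_photons_per_s = 600, duration_s = 75,
                               spike_times_s = c(12, 40, 65), seed = 400 + s))
    da <- preprocess(ga$recording)$dff
    db <- preprocess(gb$recording)$dff
    rr <- dff_ratio(da, db, 13.6, min_peak = 0.15)
    ratios <- c(ratios, rr$ratio)
  }
  expect_equal(mean(ratios), 1.0, tolerance = 0.25)
})

test_that("low frame rates for slow indicators raise a warning", {
  expect_warning(trace_recording(rep(10, 50), 2), "5 Hz")
})
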