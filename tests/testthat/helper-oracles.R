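# Independent oracles used across the suite. These deliberately re-derive
# quantities with brute force or closed forms, not through the package's own
# computational paths.

# Unweighted (analog) Monte Carlo for a pencil beam normally incident on a
# homogeneous slab: every photon is followed until it is absorbed (discrete
# event with probability mua/mut per interaction), leaves through the top
# (reflected) or leaves through the bottom (transmitted).
analog_slab_mc <- function(n, mua, mus, g, thickness_mm) {
  mut <- mua + mus
  counts <- c(absorbed = 0, reflected = 0, transmitted = 0)
  for (i in seq_len(n)) {
    z <- 0; uz <- 1; ux <- 0; uy <- 0
    repeat {
      s <- -log(runif(1)) / mut
      z <- z + s * uz
      if (z < 0) { counts["reflected"] <- counts["reflected"] + 1; break }
      if (z > thickness_mm) {
        counts["transmitted"] <- counts["transmitted"] + 1; break
      }
      if (runif(1) < mua / mut) {
        counts["absorbed"] <- counts["absorbed"] + 1; break
      }
      # Henyey-Greenstein deflection
      u <- runif(1)
      ct <- if (g == 0) 2 * u - 1 else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * u)
        (1 + g^2 - tmp^2) / (2 * g)
      }
      st <- sqrt(1 - ct^2)
      psi <- runif(1, 0, 2 * pi)
      if (abs(uz) > 0.99999) {
        ux <- st * cos(psi); uy <- st * sin(psi); uz <- ct * sign(uz)
      } else {
        den <- sqrt(1 - uz^2)
        nux <- st * (ux * uz * cos(psi) - uy * sin(psi)) / den + ux * ct
        nuy <- st * (uy * uz * cos(psi) + ux * sin(psi)) / den + uy * ct
        nuz <- -st * cos(psi) * den + uz * ct
        ux <- nux; uy <- nuy; uz <- nuz
      }
    }
  }
  counts / n
}

# Configure the transport engine as a plain slab: parked pencil beam (tiny
# fill, focus at the surface), slab thickness as the escape depth, huge
# window so every top exit counts as "window" (= reflectance).
slab_transport <- function(n, mua, mus, g, thickness_mm, seed) {
  b <- beam_geometry(z_focus_um = 0, fov_diameter_um = 0,
                     fill_fraction = 1e-4)
  tis <- tissue_optics(1320, mua_per_mm = mua, mus_per_mm = mus, g = g)
  geo <- simulation_geometry(escape_radius_mm = 500,
                             escape_depth_mm = thickness_mm,
                             window_radius_mm = 500, voxel_um = 100)
  simulate_transport(b, tis, geo, n_photons = n, seed = seed)
}

# Noiseless expected peak of the preprocessed (frame-integrated, Hamming-
# filtered) trace for an instant-rise exponential transient: direct
# construction, filtered with an explicitly built window.
filtered_peak_oracle <- function(a, tau_s, fs, filter_s = 0.37) {
  tt <- (seq_len(400) - 0.5) / fs
  t0 <- 100 / fs       # onset on a frame boundary, as in the generator tests
  x <- 1 + a * exp(-(tt - t0) / tau_s) * (tt >= t0)
  n_w <- max(3L, round(filter_s * fs)); if (n_w %% 2 == 0) n_w <- n_w + 1L
  m <- (n_w - 1) / 2
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_w - 1)) / (n_w - 1))
  w <- w / sum(w)
  sm <- vapply((m + 1):(length(x) - m),
               function(i) sum(w * x[(i - m):(i + m)]), numeric(1))
  max(sm) - 1
}

# Monte Carlo operating point of the matched-filter statistic at a given
# discriminability: `n` transient-present and `n` transient-absent windows,
# decided at threshold 0, using gen_trace as the generative model and
# transient_llr as the statistic.
roc_point <- function(d_target, n, seed, fs = 13.6, ind = gcamp6s()) {
  f0 <- min_baseline_rate(ind, d_target)
  onset_s <- 2
  onset_frame <- round(onset_s * fs) + 1L
  hits <- falses <- logical(n)
  for (i in seq_len(n)) {
    g1 <- gen_trace(trace_spec(ind, f0_photons_per_s = f0, frame_rate_hz = fs,
                               duration_s = 14, spike_times_s = onset_s,
                               seed = seed + 2 * i))
    g0 <- gen_trace(trace_spec(ind, f0_photons_per_s = f0, frame_rate_hz = fs,
                               duration_s = 14, spike_times_s = numeric(0),
                               seed = seed + 2 * i + 1))
    l1 <- transient_llr(g1$recording, ind, f0_counts_per_frame = f0 / fs)
    l0 <- transient_llr(g0$recording, ind, f0_counts_per_frame = f0 / fs)
    hits[i] <- l1[onset_frame] > 0
    falses[i] <- l0[onset_frame] > 0
  }
  c(tpr = mean(hits), fpr = mean(falses))
}
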