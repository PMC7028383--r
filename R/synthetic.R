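# Synthetic-data generators emulating the study's raw data: shot-noise-
# limited calcium traces, vessel image stacks with depth-dependent signal
# and background, depth-signal decay tables, and photon-calibration images.
# All generators are seeded and bit-reproducible; each returns its ground
# truth so the measurement modules can be round-trip tested against it.

#' Specification of a synthetic calcium trace
#'
#' Defaults describe the recordings the trace pipeline targets: GCaMP6s
#' kinetics, a baseline of 100 detected photons/s (the d' = 3 budget),
#' 13.6 Hz frame rate, 75 s duration, and sparse spontaneous firing at
#' 0.1 Hz.
#'
#' @param indicator An [indicator_params].
#' @param f0_photons_per_s Baseline signal photon rate, photons/s.
#' @param background_photons_per_s Time-invariant background rate,
#'   photons/s (0 for background-free 3P-like recordings; equal to
#'   `f0_photons_per_s` emulates SBR = 1).
#' @param frame_rate_hz Frame rate, Hz.
#' @param duration_s Trace duration, s.
#' @param spike_times_s Transient onset times; `NULL` to draw a Poisson
#'   train at `poisson_rate_hz`.
#' @param poisson_rate_hz Spontaneous event rate when `spike_times_s` is
#'   `NULL`.
#' @param seed Integer seed.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(indicator = gcamp6s(), f0_photons_per_s = 100,
                       background_photons_per_s = 0, frame_rate_hz = 13.6,
                       duration_s = 75, spike_times_s = NULL,
                       poisson_rate_hz = 0.1, seed = 1L) {
  stopifnot(inherits(indicator, "indicator_params"))
  if (f0_photons_per_s < 0 || background_photons_per_s < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (duration_s <= 0 || frame_rate_hz <= 0)
    stop("duration and frame rate must be positive", call. = FALSE)
  structure(list(indicator = indicator, f0_photons_per_s = f0_photons_per_s,
                 background_photons_per_s = background_photons_per_s,
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 spike_times_s = spike_times_s,
                 poisson_rate_hz = poisson_rate_hz, seed = seed),
            class = "trace_spec")
}

#' Generate a shot-noise-limited calcium trace
#'
#' Frame counts are Poisson draws of the integrated rate
#' \deqn{F_0 (1 + \sum_k (\Delta F/F) e^{-(t - t_k)/\tau}) + B}
#' per frame: exponential-decay transients on a constant baseline plus a
#' time-invariant background, the generative model underlying the
#' discriminability index.
#'
#' @param spec A [trace_spec].
#' @param channel Channel label for the returned recording.
#' @return List with `recording` (a [trace_recording]) and `events`
#'   (data frame of ground-truth onset times and amplitudes).
#' @export
gen_trace <- function(spec, channel = "3P") {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  fs <- spec$frame_rate_hz
  n <- floor(spec$duration_s * fs)
  tt <- (seq_len(n) - 0.5) / fs
  spikes <- spec$spike_times_s
  if (is.null(spikes)) {
    nsp <- stats::rpois(1, spec$poisson_rate_hz * spec$duration_s)
    spikes <- sort(stats::runif(nsp, 0, spec$duration_s))
  }
  ind <- spec$indicator
  rate <- rep(spec$f0_photons_per_s, n)
  for (tk in spikes) {
    on <- tt >= tk
    rate[on] <- rate[on] +
      spec$f0_photons_per_s * ind$dff_single_ap * exp(-(tt[on] - tk) / ind$tau_decay_s)
  }
  rate <- rate + spec$background_photons_per_s
  counts <- stats::rpois(n, rate / fs)
  rec <- trace_recording(counts, fs, channel = channel)
  list(recording = rec,
       events = data.frame(time_s = spikes,
                           amplitude_dff = rep(ind$dff_single_ap,
                                               length(spikes))))
}

#' Specification of a synthetic vasculature image stack
#'
#' Defaults emulate fluorescein-labelled cortical vasculature: ~2%
#' labelled volume (staining inhomogeneity ~50), vessel radius 4 um
#' (diameters below 20 um), an exponentially attenuating n-photon signal
#' with depth, and a background level following the theoretical SBR.
#'
#' @param nx,ny Lateral frame size in pixels.
#' @param depths_um Imaging depth of each frame, um.
#' @param voxel_um Lateral pixel size, um.
#' @param vessel_volume_fraction Target labelled area fraction per frame.
#' @param vessel_radius_um Vessel radius, um.
#' @param eal_um Effective attenuation length of the excitation, um.
#' @param order Excitation order n (2 or 3).
#' @param sbr Per-frame signal-to-background ratio: `NULL` to use the
#'   [sbr_vs_depth()] theory at chi = 1/volume-fraction, a scalar for a
#'   constant SBR, a vector for explicit per-frame values, or `Inf` for
#'   background-free frames.
#' @param signal_peak_counts Mean counts of an in-focus vessel pixel in
#'   the shallowest frame.
#' @param seed Integer seed.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(nx = 128, ny = 128, depths_um = seq(0, 300, by = 10),
                       voxel_um = 2, vessel_volume_fraction = 0.02,
                       vessel_radius_um = 3, eal_um = 154, order = 2,
                       sbr = NULL, signal_peak_counts = 500, seed = 1L) {
  if (vessel_volume_fraction <= 0 || vessel_volume_fraction >= 1)
    stop("`vessel_volume_fraction` must be in (0, 1)", call. = FALSE)
  if (vessel_radius_um <= 0 || vessel_radius_um * 2 >= 20.001)
    stop("vessel diameter must be positive and below 20 um", call. = FALSE)
  if (vessel_radius_um < voxel_um)
    stop("vessel radius below one pixel is not resolvable", call. = FALSE)
  structure(list(nx = nx, ny = ny, depths_um = depths_um, voxel_um = voxel_um,
                 vessel_volume_fraction = vessel_volume_fraction,
                 vessel_radius_um = vessel_radius_um, eal_um = eal_um,
                 order = order, sbr = sbr,
                 signal_peak_counts = signal_peak_counts, seed = seed),
            class = "stack_spec")
}

# rasterize one random straight tube segment into a frame; `h_cap` bounds the
# segment half-length so the target area fraction is approached from below
.add_tube <- function(mask, xg, yg, radius, h_cap = Inf) {
  nx <- nrow(mask); ny <- ncol(mask)
  span <- max(xg) - min(xg)
  x0 <- stats::runif(1, min(xg), max(xg))
  y0 <- stats::runif(1, min(yg), max(yg))
  ang <- stats::runif(1, 0, pi)
  h <- stats::runif(1, 0.15, 0.5) * span          # segment half-length
  h <- min(h, max(h_cap, 3 * radius))
  dx <- cos(ang); dy <- sin(ang)
  px <- outer(xg - x0, rep(1, ny))
  py <- outer(rep(1, nx), yg - y0)
  t <- pmin(pmax(px * dx + py * dy, -h), h)
  d2 <- (px - t * dx)^2 + (py - t * dy)^2
  mask | (d2 <= radius^2)
}

#' Generate a vasculature image stack with ground truth
#'
#' Each frame contains straight random tubes ("vessels") at the target
#' area fraction. The in-focus vessel signal decays with depth as
#' exp(-n z / EAL) (constant surface power), the uniform background level
#' is set from the requested or theoretical SBR at each depth, and pixel
#' values are Poisson draws of the resulting means.
#'
#' @param spec A [stack_spec].
#' @return List with `stack` (nx x ny x nframes array of counts), `mask`
#'   (logical ground-truth vessel mask), `depths_um`, and `truth` (list
#'   with the generating fraction, EAL, per-frame signal and background
#'   means and SBR).
#' @export
gen_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  set.seed(spec$seed)
  nf <- length(spec$depths_um)
  xg <- (seq_len(spec$nx) - 0.5) * spec$voxel_um
  yg <- (seq_len(spec$ny) - 0.5) * spec$voxel_um
  tube_frac <- 2 * spec$vessel_radius_um / (max(xg) - min(xg))  # rough/area
  if (spec$vessel_volume_fraction > 0.5)
    stop("infeasible vessel fraction for this geometry", call. = FALSE)

  sig <- spec$signal_peak_counts *
    exp(-spec$order * (spec$depths_um - spec$depths_um[1]) / spec$eal_um)
  sbr <- spec$sbr
  if (is.null(sbr)) {
    st <- staining_model(volume_fraction = spec$vessel_volume_fraction)
    prof <- sbr_vs_depth(spec$order, st,
                         pmax(spec$depths_um, 1) / spec$eal_um,
                         eal_um = spec$eal_um)
    sbr <- prof$sbr
  }
  sbr <- rep_len(sbr, nf)

  stack <- array(0, c(spec$nx, spec$ny, nf))
  mask <- array(FALSE, c(spec$nx, spec$ny, nf))
  bg_mean <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- matrix(FALSE, spec$nx, spec$ny)
    span <- max(xg) - min(xg)
    guard <- 0
    while (mean(m) < spec$vessel_volume_fraction && guard < 200) {
      remaining <- spec$vessel_volume_fraction - mean(m)
      h_cap <- remaining * span^2 / (4 * spec$vessel_radius_um)
      m <- .add_tube(m, xg, yg, spec$vessel_radius_um, h_cap)
      guard <- guard + 1
    }
    bg_mean[f] <- if (is.finite(sbr[f])) sig[f] / sbr[f] else 0
    mu <- matrix(bg_mean[f], spec$nx, spec$ny)
    mu[m] <- mu[m] + sig[f]
    stack[, , f] <- stats::rpois(length(mu), mu)
    mask[, , f] <- m
  }
  list(stack = stack, mask = mask, depths_um = spec$depths_um,
       truth = list(volume_fraction = spec$vessel_volume_fraction,
                    eal_um = spec$eal_um, order = spec$order,
                    signal_mean = sig, background_mean = bg_mean, sbr = sbr))
}

#' Generate a depth-signal decay table
#'
#' Evaluates the n-photon signal yield at constant surface pulse energy,
#' S(z) = S(0) exp(-n z / EAL), with optional multiplicative log-normal
#' noise — the fixture consumed by [fit_eal()].
#'
#' @param eal_um Ground-truth effective attenuation length, um.
#' @param order Excitation order n.
#' @param depths_um Depth grid, um.
#' @param s0_photons_per_pulse Surface signal yield (default 0.1
#'   photons/pulse, the standard normalisation).
#' @param noise_frac Multiplicative noise fraction (log-normal sigma).
#' @param seed Integer seed.
#' @return Data frame with columns `depth_um`, `signal_photons_per_pulse`.
#' @export
gen_depth_signal_table <- function(eal_um, order, depths_um = seq(0, 600, 12.5),
                                   s0_photons_per_pulse = 0.1,
                                   noise_frac = 0, seed = 1L) {
  if (eal_um <= 0 || s0_photons_per_pulse <= 0)
    stop("EAL and surface signal must be positive", call. = FALSE)
  set.seed(seed)
  s <- s0_photons_per_pulse * exp(-order * depths_um / eal_um)
  if (noise_frac > 0)
    s <- s * exp(stats::rnorm(length(s), 0, noise_frac))
  data.frame(depth_um = depths_um, signal_photons_per_pulse = s)
}

#' Generate a pixel-value image with a known photon conversion factor
#'
#' Pixels are `offset + factor * Poisson(mean_photons)` plus Gaussian read
#' noise, the model behind histogram-mode conversion-factor calibration.
#'
#' @param nx,ny Image size.
#' @param mean_photons Mean photons per pixel (small, so the zero- and
#'   one-photon histogram modes are populated).
#' @param conversion_factor Pixel increment per photon.
#' @param offset Detector offset.
#' @param read_noise_sd Gaussian read noise, pixel units.
#' @param seed Integer seed.
#' @return List with `image`, `photons` (ground-truth counts), and the
#'   generating parameters.
#' @export
gen_photon_image <- function(nx = 256, ny = 256, mean_photons = 0.5,
                             conversion_factor = 40, offset = 100,
                             read_noise_sd = 3, seed = 1L) {
  set.seed(seed)
  k <- stats::rpois(nx * ny, mean_photons)
  img <- matrix(offset + conversion_factor * k +
                  stats::rnorm(nx * ny, 0, read_noise_sd), nx, ny)
  list(image = img, photons = matrix(k, nx, ny),
       conversion_factor = conversion_factor, offset = offset)
}
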