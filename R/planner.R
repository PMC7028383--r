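#' Constraints for imaging-parameter planning
#'
#' @param focus_pulse_energy_nj_range Allowed pulse-energy range at the
#'   focus, nJ; 1-2 nJ balances signal against fluorophore saturation and
#'   nonlinear damage.
#' @param ablation_bound_nj Pulse energy at the focus that ablates tissue
#'   (~10 nJ); plans must stay strictly below it.
#' @param peak_temp_limit_c Peak-temperature safety bound, C (default 41).
#' @param thermal_power_limit_mw Either a single safe average power (mW,
#'   after the objective) or a `function(depth_um, fov_um)` returning one;
#'   the default interpolates the safe powers established for this
#'   geometry at 600 um (100 mW) and 1 mm (120 mW) depth and should be
#'   replaced by [power_sweep()] results for other configurations.
#' @param laser_max_rep_rate_hz Hardware cap on the repetition rate.
#' @param duty_cycle Fraction of pulses actually delivered (adaptive
#'   excitation of ROIs only reduces the time-averaged repetition rate by
#'   this factor).
#' @return An object of class `planner_constraints`.
#' @export
planner_constraints <- function(focus_pulse_energy_nj_range = c(1, 2),
                                ablation_bound_nj = 10,
                                peak_temp_limit_c = 41,
                                thermal_power_limit_mw = NULL,
                                laser_max_rep_rate_hz = 16e6,
                                duty_cycle = 1) {
  r <- focus_pulse_energy_nj_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1] || r[2] >= ablation_bound_nj)
    stop("focus energy range must lie within (0, ablation bound)", call. = FALSE)
  if (peak_temp_limit_c <= 37)
    stop("`peak_temp_limit_c` must exceed body temperature", call. = FALSE)
  if (is.null(thermal_power_limit_mw))
    thermal_power_limit_mw <- function(depth_um, fov_um)
      stats::approx(c(600, 1000), c(100, 120), xout = depth_um, rule = 2)$y
  structure(list(focus_pulse_energy_nj_range = r,
                 ablation_bound_nj = ablation_bound_nj,
                 peak_temp_limit_c = peak_temp_limit_c,
                 thermal_power_limit_mw = thermal_power_limit_mw,
                 laser_max_rep_rate_hz = laser_max_rep_rate_hz,
                 duty_cycle = duty_cycle),
            class = "planner_constraints")
}

#' Maximum repetition rate under a thermal power budget
#'
#' The thermally safe average power divided by the pulse energy at the
#' sample surface: 100 mW at 14 nJ/pulse allows 7 MHz; 120 mW at
#' 100 nJ/pulse only 1.2 MHz.
#'
#' @param p_thermal_mw Maximum safe average power, mW.
#' @param e_surface_nj Pulse energy at the brain surface, nJ.
#' @param divider_base_hz When given, the result is floored to
#'   `divider_base_hz / m` for integer m (pulse-picked lasers).
#' @return Repetition rate, Hz.
#' @export
max_rep_rate <- function(p_thermal_mw, e_surface_nj, divider_base_hz = NULL) {
  if (any(p_thermal_mw <= 0) || any(e_surface_nj <= 0))
    stop("inputs must be positive", call. = FALSE)
  rate <- p_thermal_mw * 1e-3 / (e_surface_nj * 1e-9)
  if (!is.null(divider_base_hz))
    rate <- divider_base_hz / ceiling(divider_base_hz / rate)
  rate
}

# lateral focal-spot FWHM, um (Gaussian focus approximation)
.spot_fwhm_um <- function(wavelength_nm, na_eff) {
  0.51 * (wavelength_nm / 1000) / na_eff
}

#' Plan imaging parameters for a target depth
#'
#' Step-by-step optimisation: fix the pulse energy at the focus at the top
#' of the allowed range (or the value required for the target signal
#' yield), scale it to the surface through the EAL, divide the thermally
#' safe average power by the surface pulse energy to get the repetition
#' rate, then choose the sampling grid — two pixels per focal spot and the
#' largest frame rate >= `min_frame_rate_hz` such that the repetition
#' rate is an integer multiple of (pixels per frame) x (frame rate).
#' The achievable neuron budget is reported against the baseline photon
#' rate required for the target discriminability.
#'
#' @param depth_um Imaging depth, um.
#' @param eal_um Effective attenuation length at the excitation
#'   wavelength, um.
#' @param constraints A [planner_constraints].
#' @param indicator An [indicator_params].
#' @param target_dprime Target discriminability for a single transient.
#' @param e_focus_req_nj Pulse energy at the focus required for the
#'   reference signal yield of 0.1 detected photons/pulse (1.86 nJ for
#'   GCaMP6s at 1320 nm, 60 fs).
#' @param fov_um Scanned field of view, um.
#' @param wavelength_nm Excitation wavelength, nm.
#' @param na_eff Effective numerical aperture.
#' @param min_frame_rate_hz Minimum acceptable frame rate (5 Hz for
#'   GCaMP6s dynamics).
#' @param signal_yield_per_pulse Detected photons/pulse at the focus for
#'   `e_focus_req_nj` (0.1 by construction).
#' @param neuron_diameter_um Nominal neuron diameter for the photon-budget
#'   accounting.
#' @return An object of class `imaging_plan` (a list; see fields), or an
#'   error naming the binding constraint when no feasible plan exists.
#' @export
make_plan <- function(depth_um, eal_um, constraints = planner_constraints(),
                      indicator = gcamp6s(), target_dprime = 3,
                      e_focus_req_nj = 1.86, fov_um = 230,
                      wavelength_nm = 1320, na_eff = 0.75,
                      min_frame_rate_hz = 5, signal_yield_per_pulse = 0.1,
                      neuron_diameter_um = 10) {
  stopifnot(inherits(constraints, "planner_constraints"),
            inherits(indicator, "indicator_params"))
  rng <- constraints$focus_pulse_energy_nj_range
  e_focus <- min(max(e_focus_req_nj, rng[1]), rng[2])
  if (e_focus >= constraints$ablation_bound_nj)
    stop("infeasible: focus pulse energy at the ablation bound", call. = FALSE)

  e_surface <- surface_pulse_energy(e_focus, depth_um, eal_um)
  p_lim <- constraints$thermal_power_limit_mw
  p_mw <- if (is.function(p_lim)) p_lim(depth_um, fov_um) else p_lim
  rate_thermal <- max_rep_rate(p_mw, e_surface) / constraints$duty_cycle
  rep_rate <- min(rate_thermal, constraints$laser_max_rep_rate_hz)
  binding <- if (rate_thermal < constraints$laser_max_rep_rate_hz)
    "thermal power limit" else "laser repetition rate"

  pixel_um <- .spot_fwhm_um(wavelength_nm, na_eff) / 2   # two px per spot
  npix_req <- max(2L, ceiling(fov_um / pixel_um))
  # largest square grid compatible with >=1 pulse/pixel at the minimum
  # frame rate; the requested FOV is shrunk when the rate cannot fill it
  npix_max <- floor(sqrt(rep_rate / min_frame_rate_hz))
  npix_line <- min(npix_req, npix_max)
  if (npix_line < 2)
    stop("infeasible: repetition rate too low for ", min_frame_rate_hz,
         " Hz at any usable FOV (binding constraint: ", binding, ")",
         call. = FALSE)
  pixels_per_frame <- as.double(npix_line)^2
  ppp <- floor(rep_rate / (pixels_per_frame * min_frame_rate_hz))
  frame_rate <- rep_rate / (ppp * pixels_per_frame)
  fov_um <- npix_line * pixel_um

  f0_req <- min_baseline_rate(indicator, target_dprime)
  px_per_neuron <- pi * (neuron_diameter_um / 2 / pixel_um)^2
  f0_per_neuron <- signal_yield_per_pulse * (e_focus / e_focus_req_nj)^3 *
    ppp * px_per_neuron * frame_rate
  structure(list(
    wavelength_nm = wavelength_nm,
    depth_um = depth_um, eal_um = eal_um, depth_eals = depth_um / eal_um,
    e_focus_nj = e_focus, e_surface_nj = e_surface,
    rep_rate_hz = rep_rate * constraints$duty_cycle,
    avg_power_mw = rep_rate * constraints$duty_cycle * e_surface * 1e-6,
    thermal_power_limit_mw = p_mw,
    fov_um = fov_um, pixel_um = pixel_um, pixels_per_frame = pixels_per_frame,
    frame_rate_hz = frame_rate, pulses_per_pixel = ppp,
    binding_constraint = binding,
    f0_per_neuron_photons_s = f0_per_neuron,
    f0_required_photons_s = f0_req,
    dprime_achievable = dprime(indicator, f0_per_neuron)
  ), class = "imaging_plan")
}

#' @export
print.imaging_plan <- function(x, ...) {
  cat(sprintf(paste0(
    "<imaging_plan> %g nm, depth %g um (%.1f EALs)\n",
    "  pulse energy: %.3g nJ focus -> %.3g nJ surface\n",
    "  repetition rate %.3g MHz (%s), avg power %.3g mW\n",
    "  FOV %g um, %g px/frame, %g pulses/px, frame rate %.2f Hz\n",
    "  photons per neuron %.3g /s (needs %.3g /s), d' %.2f\n"),
    x$wavelength_nm, x$depth_um, x$depth_eals, x$e_focus_nj, x$e_surface_nj,
    x$rep_rate_hz / 1e6, x$binding_constraint, x$avg_power_mw, x$fov_um,
    x$pixels_per_frame, x$pulses_per_pixel, x$frame_rate_hz,
    x$f0_per_neuron_photons_s, x$f0_required_photons_s, x$dprime_achievable))
  invisible(x)
}

#' Compare candidate three-photon excitation wavelengths
#'
#' At a fixed peak-intensity (pulse-energy) limit the signal scales
#' linearly with the allowed average power, so a wavelength with more
#' thermal headroom gains signal linearly — but a lower indicator
#' sensitivity enters d' linearly while the photon-rate gain enters only
#' as a square root. With ~50% more allowed power but half the dF/F,
#' 1280 nm scores d' lower than 1320 nm for calcium imaging.
#'
#' @param power_headroom Relative allowed average power per candidate
#'   (named vector; default 1320 nm = 1, 1280 nm = 1.5).
#' @param dff_factor Relative indicator dF/F per candidate (default
#'   1280 nm half of 1320 nm).
#' @return Data frame with one row per wavelength: relative signal,
#'   relative d', and the preferred candidate flagged.
#' @export
wavelength_tradeoff <- function(power_headroom = c(`1320` = 1, `1280` = 1.5),
                                dff_factor = c(`1320` = 1, `1280` = 0.5)) {
  wl <- names(power_headroom)
  stopifnot(setequal(wl, names(dff_factor)))
  rel_d <- sqrt(power_headroom) * dff_factor[wl]
  out <- data.frame(wavelength_nm = as.numeric(wl),
                    rel_power = unname(power_headroom),
                    rel_signal = unname(power_headroom),
                    rel_dff = unname(dff_factor[wl]),
                    rel_dprime = unname(rel_d),
                    preferred = seq_along(wl) == which.max(rel_d))
  out[order(-out$rel_dprime), ]
}
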