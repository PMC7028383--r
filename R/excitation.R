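# Physical constants (SI)
.hc_Jm <- 6.62607015e-34 * 2.99792458e8  # Planck constant times c, J m

#' Pulse train description
#'
#' @param rep_rate_hz Laser repetition rate f in Hz.
#' @param pulse_duration_s Pulse duration (FWHM, sech^2 profile assumed) in
#'   seconds.
#' @param pulse_energy_j Pulse energy P/f in joules at `reference_plane`.
#' @param reference_plane Where the pulse energy is referenced:
#'   `"surface"` (brain surface), `"focus"`, or `"after_objective"`.
#' @return An object of class `pulse_train` with derived `avg_power_w`.
#' @export
pulse_train <- function(rep_rate_hz, pulse_duration_s, pulse_energy_j,
                        reference_plane = c("surface", "focus", "after_objective")) {
  reference_plane <- match.arg(reference_plane)
  vals <- c(rep_rate_hz, pulse_duration_s, pulse_energy_j)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all pulse-train parameters must be positive and finite", call. = FALSE)
  structure(
    list(rep_rate_hz = rep_rate_hz, pulse_duration_s = pulse_duration_s,
         pulse_energy_j = pulse_energy_j,
         avg_power_w = rep_rate_hz * pulse_energy_j,
         reference_plane = reference_plane),
    class = "pulse_train"
  )
}

#' n-photon signal per pulse
#'
#' Detected n-photon-excited signal yield per laser pulse,
#' \deqn{S_{nP}/f = C_n (P/f)^n / \tau^{n-1},}
#' exactly quadratic (n = 2) or cubic (n = 3) in the pulse energy and
#' inversely proportional to the (n-1)th power of the pulse duration.
#'
#' @param pulse_energy_j Pulse energy P/f in joules (at the brain surface,
#'   matching the calibration of `cn`). Vectorised.
#' @param pulse_duration_s Pulse duration in seconds.
#' @param cn Calibration coefficient C_n, from [calibrate_cn()].
#' @param order Excitation order n, 2 or 3.
#' @return Detected photons per pulse.
#' @export
signal_per_pulse <- function(pulse_energy_j, pulse_duration_s, cn, order) {
  if (!order %in% c(2, 3)) stop("`order` must be 2 or 3", call. = FALSE)
  if (any(cn < 0)) stop("`cn` must be non-negative", call. = FALSE)
  cn * pulse_energy_j^order / pulse_duration_s^(order - 1)
}

#' Calibrate the n-photon excitation coefficient
#'
#' Solves for C_n in the n-photon scaling law from one or more measurements
#' of (pulse energy, pulse duration, detected photons/pulse). The fit is a
#' least-squares estimate of log C_n with the power-law exponents held at
#' their theoretical values; a single measurement gives the exact solve.
#'
#' @param measurements A data frame with columns `pulse_energy_j`,
#'   `pulse_duration_s`, `signal_photons_per_pulse`; all entries positive.
#' @param order Excitation order n, 2 or 3.
#' @return A list of class `calibration_constants` with elements `cn`,
#'   `order`, `log_cn_se` (NA for a single point), and `ci95` (95%
#'   confidence interval for `cn`, NA for fewer than 3 points).
#' @export
calibrate_cn <- function(measurements, order) {
  if (!order %in% c(2, 3)) stop("`order` must be 2 or 3", call. = FALSE)
  m <- as.data.frame(measurements)
  need <- c("pulse_energy_j", "pulse_duration_s", "signal_photons_per_pulse")
  if (!all(need %in% names(m)))
    stop("`measurements` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(m) < 1) stop("need at least one measurement", call. = FALSE)
  if (any(m$signal_photons_per_pulse <= 0))
    stop("zero or negative signal cannot calibrate C_n", call. = FALSE)
  if (any(m$pulse_energy_j <= 0) || any(m$pulse_duration_s <= 0))
    stop("pulse energies and durations must be positive", call. = FALSE)
  lg <- log(m$signal_photons_per_pulse) - order * log(m$pulse_energy_j) +
    (order - 1) * log(m$pulse_duration_s)
  se <- if (nrow(m) > 1) stats::sd(lg) / sqrt(nrow(m)) else NA_real_
  ci <- if (nrow(m) >= 3) {
    exp(mean(lg) + stats::qt(c(0.025, 0.975), df = nrow(m) - 1) * se)
  } else c(NA_real_, NA_real_)
  structure(list(cn = exp(mean(lg)), order = order, log_cn_se = se, ci95 = ci),
            class = "calibration_constants")
}

#' Surface pulse energy required for a given focus pulse energy
#'
#' Scales a required pulse energy at the focus back to the brain surface
#' under exponential attenuation with the effective attenuation length:
#' E_surface = E_focus * exp(depth / EAL).
#'
#' @param e_focus_req_nj Required pulse energy at the focus, nJ (vectorised).
#' @param depth_um Imaging depth in micrometres, >= 0 (vectorised).
#' @param eal_um Effective attenuation length in micrometres, > 0.
#' @return Pulse energy at the brain surface in nJ.
#' @examples
#' surface_pulse_energy(1.86, 2 * 293, 293) # ~ 14 nJ
#' @export
surface_pulse_energy <- function(e_focus_req_nj, depth_um, eal_um) {
  if (any(eal_um <= 0)) stop("`eal_um` must be positive", call. = FALSE)
  if (any(depth_um < 0)) stop("`depth_um` must be >= 0", call. = FALSE)
  e_focus_req_nj * exp(depth_um / eal_um)
}

#' Fit the effective attenuation length from a depth-signal table
#'
#' Fits the exponential decay of n-photon signal with depth (constant
#' surface pulse energy) and returns the effective attenuation length. The
#' fit is linear in the natural logarithm of the signal, whose slope is
#' -n/EAL for n-photon excitation; on a log10 axis the same slope reads
#' ln(10)/EAL per decade of signal drop for the focus-power fraction. The
#' focus/surface power fraction is the n-th root of the signal ratio to the
#' surface value.
#'
#' @param depth_signal_table Data frame with columns `depth_um` (strictly
#'   monotone) and `signal_photons_per_pulse` (positive); at least 3 rows.
#' @param order Excitation order n, 2 or 3.
#' @return A list with `eal_um`, `surface_signal` (fitted signal at depth
#'   0), `fit` (the `lm` object), and `power_fraction` — a data frame of
#'   `depth_um` and the measured focus/surface power fraction.
#' @export
fit_eal <- function(depth_signal_table, order) {
  if (!order %in% c(2, 3)) stop("`order` must be 2 or 3", call. = FALSE)
  d <- as.data.frame(depth_signal_table)
  if (!all(c("depth_um", "signal_photons_per_pulse") %in% names(d)))
    stop("need columns depth_um and signal_photons_per_pulse", call. = FALSE)
  if (nrow(d) < 3) stop("need at least 3 depths", call. = FALSE)
  dz <- diff(d$depth_um)
  if (!(all(dz > 0) || all(dz < 0)))
    stop("depth column must be strictly monotone", call. = FALSE)
  if (any(d$signal_photons_per_pulse <= 0))
    stop("signals must be positive", call. = FALSE)
  fit <- stats::lm(log(signal_photons_per_pulse) ~ depth_um, data = d)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("signal does not decay with depth; cannot estimate an EAL", call. = FALSE)
  s0 <- exp(unname(stats::coef(fit)[1]))
  frac <- (d$signal_photons_per_pulse /
             d$signal_photons_per_pulse[which.min(d$depth_um)])^(1 / order)
  list(
    eal_um = -order / slope,
    surface_signal = s0,
    fit = fit,
    power_fraction = data.frame(depth_um = d$depth_um, power_fraction = frac)
  )
}

#' Cross-over depth between two excitation modalities
#'
#' Depth at which the surface pulse energies required for equal signal by
#' the two modalities coincide, under pure exponential attenuation:
#' \deqn{z_x = \ln(E_3/E_2) / (1/EAL_2 - 1/EAL_3).}
#' Below `z_x` the lower-order (shorter-wavelength) modality needs less
#' surface pulse energy; beyond it the higher-order one does.
#'
#' @param e2_surface_nj Surface pulse energy of the lower-order modality at
#'   depth 0, nJ.
#' @param e3_surface_nj Surface pulse energy of the higher-order modality at
#'   depth 0, nJ; must be >= `e2_surface_nj` for a crossover to exist.
#' @param eal2_um,eal3_um Effective attenuation lengths (um); `eal3_um` >
#'   `eal2_um`.
#' @return Cross-over depth in micrometres (0 when the energies are equal).
#'   Returns `NA` with a warning when `e3 < e2` (no crossover).
#' @examples
#' crossover_depth(0.24, 1.86, 153, 297) # ~ 646 um (GCaMP6s surface energies)
#' @export
crossover_depth <- function(e2_surface_nj, e3_surface_nj, eal2_um, eal3_um) {
  if (e2_surface_nj <= 0 || e3_surface_nj <= 0)
    stop("surface energies must be positive", call. = FALSE)
  if (!(eal3_um > eal2_um && eal2_um > 0))
    stop("need eal3_um > eal2_um > 0", call. = FALSE)
  if (e3_surface_nj < e2_surface_nj) {
    warning("e3 < e2 at the surface: no crossover (higher order is always cheaper)")
    return(NA_real_)
  }
  log(e3_surface_nj / e2_surface_nj) / (1 / eal2_um - 1 / eal3_um)
}

#' Three-photon saturation parameters
#'
#' Parameters of the focal three-photon excitation-probability model. The
#' defaults reproduce the GCaMP6s saturation pulse energies (2 nJ for 10%,
#' ~4.3 nJ for 63% excitation probability per pulse) for a 1320-nm, 60-fs
#' sech^2 pulse focused at effective NA 0.75.
#'
#' @param sigma3_cm6s2 Three-photon excitation cross section, cm^6 s^2.
#' @param na_eff Effective numerical aperture, <= 1.05.
#' @param gp3 Third-order temporal coherence factor g_p(3) of the pulse
#'   shape (0.51 for sech^2 relative to a flat-top of the same FWHM).
#' @param wavelength_nm Excitation wavelength, nm.
#' @param pulse_duration_s Pulse duration (FWHM), s.
#' @return An object of class `saturation_params`.
#' @export
saturation_params <- function(sigma3_cm6s2 = 3e-82, na_eff = 0.75, gp3 = 0.51,
                              wavelength_nm = 1320, pulse_duration_s = 60e-15) {
  vals <- c(sigma3_cm6s2, na_eff, gp3, wavelength_nm, pulse_duration_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all saturation parameters must be positive", call. = FALSE)
  if (na_eff > 1.05) stop("`na_eff` must be <= 1.05", call. = FALSE)
  structure(list(sigma3_cm6s2 = sigma3_cm6s2, na_eff = na_eff, gp3 = gp3,
                 wavelength_nm = wavelength_nm,
                 pulse_duration_s = pulse_duration_s),
            class = "saturation_params")
}

# Per-pulse photon fluence at the focus centre, photons/cm^2 per nJ-scale
# energy argument (E in joules): Phi = E * pi * NA^2 / (h c lambda).
.focal_fluence_cm2 <- function(e_j, p) {
  lambda_cm <- p$wavelength_nm * 1e-7
  hc_Jcm <- .hc_Jm * 100
  e_j * pi * p$na_eff^2 / (hc_Jcm * lambda_cm)
}

#' Three-photon excitation probability per pulse
#'
#' Probability that a fluorophore at the centre of the focus is excited by
#' one pulse,
#' \deqn{P_r = 1 - \exp(-g_p^{(3)} \sigma_3 \Phi^3 / \tau^2),}
#' where \eqn{\Phi = E \pi NA^2/(h c \lambda)} is the per-pulse photon
#' fluence at the focus centre. Saturation (ground-state depletion) sets in
#' as \eqn{P_r} approaches 1.
#'
#' @param e_focus_nj Pulse energy at the focus, nJ (vectorised).
#' @param p A [saturation_params] object.
#' @return Excitation probability per pulse in (0, 1).
#' @examples
#' p <- saturation_params()
#' saturation_probability(4.3, p) # ~ 0.63
#' saturation_probability(2.0, p) # ~ 0.10
#' @export
saturation_probability <- function(e_focus_nj, p = saturation_params()) {
  stopifnot(inherits(p, "saturation_params"))
  if (any(e_focus_nj < 0)) stop("`e_focus_nj` must be >= 0", call. = FALSE)
  phi <- .focal_fluence_cm2(e_focus_nj * 1e-9, p)
  -expm1(-p$gp3 * p$sigma3_cm6s2 * phi^3 / p$pulse_duration_s^2)
}

#' @rdname saturation_probability
#' @param pr Target excitation probability per pulse, in (0, 1).
#' @details `saturation_energy()` inverts the model, returning the focus
#'   pulse energy (nJ) that yields excitation probability `pr`.
#' @export
saturation_energy <- function(pr, p = saturation_params()) {
  stopifnot(inherits(p, "saturation_params"))
  if (any(pr <= 0) || any(pr >= 1))
    stop("`pr` must lie strictly in (0, 1)", call. = FALSE)
  phi_req <- (-log1p(-pr) * p$pulse_duration_s^2 /
                (p$gp3 * p$sigma3_cm6s2))^(1 / 3)
  lambda_cm <- p$wavelength_nm * 1e-7
  hc_Jcm <- .hc_Jm * 100
  phi_req * hc_Jcm * lambda_cm / (pi * p$na_eff^2) * 1e9
}
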