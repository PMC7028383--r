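#' Calcium indicator parameters
#'
#' Bundles the two indicator properties that set the shot-noise-limited
#' discriminability of a single calcium transient: the peak fractional
#' fluorescence change of a single-action-potential transient and its 1/e
#' exponential decay time.
#'
#' @param dff_single_ap Peak fractional fluorescence change (ΔF/F),
#'   dimensionless, > 0.
#' @param tau_decay_s 1/e decay time of the transient in seconds, > 0.
#' @param name Label for the indicator.
#' @return An object of class `indicator_params`.
#' @examples
#' gcamp6s()
#' indicator_params(0.23, 0.7, "jGCaMP7f-like")
#' @export
indicator_params <- function(dff_single_ap, tau_decay_s, name = "custom") {
  stopifnot(is.numeric(dff_single_ap), is.numeric(tau_decay_s))
  if (!is.finite(dff_single_ap) || dff_single_ap <= 0)
    stop("`dff_single_ap` must be a positive finite number", call. = FALSE)
  if (!is.finite(tau_decay_s) || tau_decay_s <= 0)
    stop("`tau_decay_s` must be a positive finite number", call. = FALSE)
  structure(
    list(dff_single_ap = dff_single_ap, tau_decay_s = tau_decay_s, name = name),
    class = "indicator_params"
  )
}

#' @rdname indicator_params
#' @details `gcamp6s()` returns the GCaMP6s defaults used throughout:
#'   ΔF/F = 0.30 per action potential and τ1/e = 2 s.
#' @export
gcamp6s <- function() indicator_params(0.30, 2, "GCaMP6s")

#' @export
print.indicator_params <- function(x, ...) {
  cat(sprintf("<indicator_params> %s: dF/F = %.3g, tau_1/e = %.3g s\n",
              x$name, x$dff_single_ap, x$tau_decay_s))
  invisible(x)
}

#' Discriminability index of a single calcium transient
#'
#' Shot-noise-limited discriminability d' of one exponential-decay calcium
#' transient recorded at baseline photon rate `f0`, optionally degraded by a
#' time-invariant fluorescence background at signal-to-background ratio
#' `sbr`:
#' \deqn{d' = \frac{\Delta F/F \sqrt{F_0 \tau_{1/e}/2}}{\sqrt{1 + 1/SBR}}}
#' With `sbr = Inf` this is the background-free limit.
#'
#' @param ind An [indicator_params] object.
#' @param f0 Baseline detected photon rate of the neuron, photons/s, >= 0.
#' @param sbr Signal-to-background ratio, > 0; may be `Inf`.
#' @return Dimensionless d' (vectorised over `f0` and `sbr`).
#' @examples
#' dprime(gcamp6s(), 100)          # = 3
#' dprime(gcamp6s(), 100, sbr = 1) # = 3 / sqrt(2)
#' @export
dprime <- function(ind, f0, sbr = Inf) {
  stopifnot(inherits(ind, "indicator_params"))
  if (any(f0 < 0)) stop("`f0` must be >= 0", call. = FALSE)
  if (any(sbr <= 0)) stop("`sbr` must be > 0", call. = FALSE)
  ind$dff_single_ap * sqrt(f0 * ind$tau_decay_s / 2) / sqrt(1 + 1 / sbr)
}

#' Minimum baseline photon rate for a target discriminability
#'
#' Inverts [dprime()]: the baseline rate F0 at which a single transient of
#' the given indicator reaches discriminability `d_target`. A finite
#' background multiplies the background-free requirement by (1 + 1/SBR).
#'
#' @inheritParams dprime
#' @param d_target Target d', > 0 (0 is allowed and returns 0).
#' @return Required baseline rate in photons/s.
#' @examples
#' min_baseline_rate(gcamp6s(), 3) # = 100 photons/s
#' @export
min_baseline_rate <- function(ind, d_target, sbr = Inf) {
  stopifnot(inherits(ind, "indicator_params"))
  if (any(d_target < 0)) stop("`d_target` must be >= 0", call. = FALSE)
  if (any(sbr <= 0)) stop("`sbr` must be > 0", call. = FALSE)
  (d_target / ind$dff_single_ap)^2 * (2 / ind$tau_decay_s) * (1 + 1 / sbr)
}

#' True- and false-positive rates at a given discriminability
#'
#' Equal-variance Gaussian two-class detection model with the decision
#' threshold midway between the class means (the minimum-error rule for
#' equal priors): TPR = Phi(d'/2), FPR = 1 - Phi(d'/2). At d' = 3 this
#' gives the 93% / 7% operating point.
#'
#' @param d_prime Discriminability index, >= 0 (vectorised).
#' @return A data frame with columns `d_prime`, `tpr`, `fpr`.
#' @examples
#' detection_rates(3)
#' @export
detection_rates <- function(d_prime) {
  if (any(d_prime < 0)) stop("`d_prime` must be >= 0", call. = FALSE)
  tpr <- stats::pnorm(d_prime / 2)
  data.frame(d_prime = d_prime, tpr = tpr, fpr = 1 - tpr)
}

#' Photon-counting stacking (pile-up) error
#'
#' When photons are counted one-per-laser-pulse, two or more photons
#' arriving within the same pulse period register as one. For Poisson
#' arrivals with mean `count_ratio` photons per pulse (detected count rate
#' divided by the repetition rate) the fractional undercount is
#' \deqn{1 - (1 - e^{-\lambda})/\lambda,} which tends to \eqn{\lambda/2}
#' as \eqn{\lambda \to 0}.
#'
#' @param count_ratio Mean detected photons per laser pulse, >= 0
#'   (vectorised).
#' @return Fractional undercount in `[0, 1)`.
#' @examples
#' stacking_error(0.05) # about 0.0246, i.e. within 2.5%
#' @export
stacking_error <- function(count_ratio) {
  if (any(count_ratio < 0)) stop("`count_ratio` must be >= 0", call. = FALSE)
  out <- 1 + expm1(-count_ratio) / count_ratio
  out[count_ratio == 0] <- 0
  out
}
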