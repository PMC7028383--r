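#' Staining inhomogeneity model
#'
#' Binary staining description of a labelled sample: a fraction
#' `volume_fraction` of the tissue carries fluorophore at the peak
#' concentration and the rest none, so the inhomogeneity
#' chi = (peak concentration) / (mean concentration) equals
#' 1 / volume_fraction. For cortical vasculature labelled with dextran
#' dye the labelled fraction is ~2%, i.e. chi ~ 50.
#'
#' @param chi Staining inhomogeneity, >= 1. Exactly one of `chi` and
#'   `volume_fraction` may be given.
#' @param volume_fraction Labelled volume fraction in (0, 1].
#' @return An object of class `staining_model`.
#' @export
staining_model <- function(chi = NULL, volume_fraction = NULL) {
  if (is.null(chi) && is.null(volume_fraction))
    stop("give `chi` or `volume_fraction`", call. = FALSE)
  if (is.null(chi)) chi <- 1 / volume_fraction
  if (is.null(volume_fraction)) volume_fraction <- 1 / chi
  if (chi < 1) stop("`chi` must be >= 1", call. = FALSE)
  if (volume_fraction <= 0 || volume_fraction > 1)
    stop("`volume_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(chi = chi, volume_fraction = volume_fraction),
            class = "staining_model")
}

# Per-plane n-photon generation terms for a beam focused at depth zf (um).
# zeta is the axial offset from the focus (negative towards the surface);
# everything is normalised to the surface power and the focal beam area.
#
# Ballistic: Gaussian beam, area growing as 1 + (zeta/zR)^2, ballistic power
# attenuated as exp(-depth/EAL).
# Scattered halo: the power removed from the ballistic beam survives (tissue
# absorption is small over a few EALs) and illuminates an annular halo whose
# RMS half-angle is the single-scatter value sqrt(2(1-g)); its n-photon
# generation uses the same P^n / area^(n-1) law with the halo area.
.sbr_integrands <- function(order, eal_um, w0_um, zr_um, theta_s) {
  list(
    ballistic = function(zeta, zf) {
      exp(-order * (zf + zeta) / eal_um) / (1 + (zeta / zr_um)^2)^(order - 1)
    },
    halo = function(depth) {
      (-expm1(-depth / eal_um))^order *
        (w0_um^2 / (w0_um^2 + (theta_s * depth)^2))^(order - 1)
    }
  )
}

#' Theoretical signal-to-background ratio versus depth
#'
#' Models the SBR of n-photon imaging of a binarily stained sample as a
#' function of normalised depth. The in-focus signal is the n-photon
#' excitation within one Rayleigh range of the focus, generated by
#' ballistically attenuated light in a structure at peak concentration.
#' The background has two parts, both at mean concentration: (i) the
#' out-of-focus double cone of the focused Gaussian beam, and (ii) a
#' scattered-light halo carrying the power scattered out of the ballistic
#' beam, spread over the single-scatter RMS half-angle sqrt(2(1-g)).
#' For two-photon imaging at chi = 50 the model reaches SBR = 1 at ~4.5
#' normalised depths, matching the ~4.7 EAL depth limit of the underlying
#' theory; for three-photon imaging the higher-order suppression keeps the
#' SBR orders of magnitude higher at the same depth.
#'
#' @param order Excitation order n, 2 or 3.
#' @param staining A [staining_model].
#' @param depth_eals Depths in units of the EAL (vectorised).
#' @param wavelength_nm Excitation wavelength (sets the focal geometry).
#' @param eal_um Effective attenuation length, um.
#' @param na_eff Effective numerical aperture.
#' @param n_medium Refractive index of the medium.
#' @param g Scattering anisotropy (sets the halo spread).
#' @return An object of class `sbr_profile`: data frame with columns
#'   `depth_eals`, `depth_um`, `sbr`.
#' @export
sbr_vs_depth <- function(order, staining, depth_eals,
                         wavelength_nm = if (order == 2) 920 else 1320,
                         eal_um = if (order == 2) 154 else 293,
                         na_eff = 0.75, n_medium = 1.33, g = 0.9) {
  if (!order %in% c(2, 3)) stop("`order` must be 2 or 3", call. = FALSE)
  stopifnot(inherits(staining, "staining_model"))
  if (any(depth_eals < 0)) stop("depths must be >= 0", call. = FALSE)
  lam_um <- wavelength_nm / 1000
  w0_um <- lam_um / (pi * na_eff)
  zr_um <- pi * w0_um^2 * n_medium / lam_um
  theta_s <- sqrt(2 * (1 - g))
  fns <- .sbr_integrands(order, eal_um, w0_um, zr_um, theta_s)
  zmax_beyond <- 6 * eal_um                       # integration cut below focus

  # the cone integrand spans many decades (power-law near the focus, tiny
  # exponential tail near the surface): integrate piecewise on a geometric
  # partition so the adaptive quadrature converges at every depth
  int_piecewise <- function(f, lo, hi, ...) {
    brk <- unique(c(lo, sign(lo) * zr_um * 10^(0:8), hi))
    brk <- sort(brk[brk >= min(lo, hi) & brk <= max(lo, hi)])
    if (length(brk) < 2) brk <- c(lo, hi)
    sum(vapply(seq_len(length(brk) - 1), function(i) {
      stats::integrate(f, brk[i], brk[i + 1], ..., rel.tol = 1e-7,
                       stop.on.error = FALSE)$value
    }, numeric(1)))
  }

  one <- function(zf_um) {
    if (zf_um <= zr_um) return(Inf)               # focus at the surface
    sig <- stats::integrate(fns$ballistic, -zr_um, zr_um, zf = zf_um,
                            rel.tol = 1e-8)$value
    bg <- int_piecewise(fns$ballistic, -zf_um, -zr_um, zf = zf_um) +
      int_piecewise(fns$ballistic, zr_um, zmax_beyond, zf = zf_um) +
      stats::integrate(fns$halo, 0, zf_um + zmax_beyond,
                       rel.tol = 1e-7)$value
    if (!is.finite(bg) || bg < 0)
      stop("background integral did not converge", call. = FALSE)
    staining$chi * sig / bg
  }
  sbr <- vapply(depth_eals * eal_um, one, numeric(1))
  structure(data.frame(depth_eals = depth_eals,
                       depth_um = depth_eals * eal_um, sbr = sbr),
            class = c("sbr_profile", "data.frame"))
}

#' Depth at which the theoretical SBR reaches a given level
#'
#' @inheritParams sbr_vs_depth
#' @param level SBR level to solve for (default 1, the practical depth
#'   limit).
#' @param interval Search interval in EAL units.
#' @param ... Passed on to [sbr_vs_depth()].
#' @return Depth in EAL units where the modelled SBR crosses `level`.
#' @export
sbr_unity_depth <- function(order, staining, level = 1,
                            interval = c(0.5, 12), ...) {
  f <- function(z) log(sbr_vs_depth(order, staining, z, ...)$sbr / level)
  stats::uniroot(f, interval, tol = 1e-4)$root
}

#' Apparent transient amplitude under background contamination
#'
#' A time-invariant background at signal-to-background ratio SBR raises
#' the apparent baseline to F0 (1 + 1/SBR) and reduces the apparent
#' fractional change to dff_true / (1 + 1/SBR). At SBR = 1 the apparent
#' amplitude is half the true one.
#'
#' @param dff_true True fractional fluorescence change (vectorised).
#' @param sbr Signal-to-background ratio, > 0; may be `Inf`.
#' @return Apparent fractional change.
#' @export
apparent_dff <- function(dff_true, sbr) {
  if (any(sbr <= 0)) stop("`sbr` must be > 0", call. = FALSE)
  dff_true / (1 + 1 / sbr)
}

#' Measure the signal-to-background ratio of an image stack
#'
#' Per frame, the signal is the mean of the brightest `top_frac` pixels
#' minus the background, and the background is the mean pixel value inside
#' `background_mask` (unlabelled regions). A zero background yields an
#' infinite SBR, flagged in the result.
#'
#' @param stack A 3-d array (x, y, frame) or a matrix for a single frame.
#' @param background_mask Logical mask of unlabelled pixels, same x-y shape
#'   as the stack.
#' @param top_frac Brightest-pixel fraction used as the signal (0.001 for
#'   SBR, 0.005 for signal-decay/EAL curves).
#' @return Data frame with columns `frame`, `signal`, `background`, `sbr`;
#'   attribute `"infinite_background"` is TRUE when any frame had zero
#'   background.
#' @export
measure_sbr <- function(stack, background_mask, top_frac = 0.001) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  if (!any(background_mask)) stop("`background_mask` is empty", call. = FALSE)
  nf <- dim(stack)[3]
  out <- data.frame(frame = seq_len(nf), signal = NA_real_,
                    background = NA_real_, sbr = NA_real_)
  for (f in seq_len(nf)) {
    fr <- stack[, , f]
    bg <- mean(fr[background_mask])
    k <- max(1L, round(top_frac * length(fr)))
    sig <- mean(sort(as.vector(fr), decreasing = TRUE)[seq_len(k)]) - bg
    out$signal[f] <- sig
    out$background[f] <- bg
    out$sbr[f] <- if (bg > 0) sig / bg else Inf
  }
  attr(out, "infinite_background") <- any(!is.finite(out$sbr))
  out
}

#' Read or write an image stack as multi-page TIFF
#'
#' Thin wrappers around the `tiff` package for exchanging stacks with
#' acquisition software. Pixel counts are scaled by `scale` into the
#' 16-bit-style [0, 1] range TIFF stores.
#'
#' @param path File path.
#' @param stack 3-d array (x, y, frame) of counts.
#' @param scale Counts corresponding to full scale (default 2^16 - 1).
#' @return `read_stack_tiff()` returns the counts array;
#'   `write_stack_tiff()` returns `path` invisibly.
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (i in seq_along(pages)) out[, , i] <- pages[[i]] * scale
  out
}

#' @rdname read_stack_tiff
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) pmin(stack[, , f] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Estimate staining statistics from an image stack
#'
#' Segments the labelled structures in each frame with a global Otsu
#' threshold (the standard gray-threshold segmentation), takes the labelled
#' pixel fraction per frame, and converts the mean fraction to a staining
#' inhomogeneity under the binary-staining assumption chi = 1/fraction.
#'
#' @param stack A 3-d array (x, y, frame) or a single-frame matrix.
#' @return A [staining_model] with attributes `"fractions"` (per frame) and
#'   `"flagged_empty"` (frames where segmentation found nothing).
#' @export
estimate_staining <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  nf <- dim(stack)[3]
  fractions <- rep(NA_real_, nf)
  empty <- logical(nf)
  for (f in seq_len(nf)) {
    fr <- stack[, , f]
    mx <- max(fr)
    if (mx <= 0) { empty[f] <- TRUE; next }
    thr <- EBImage::otsu(fr / mx, range = c(0, 1)) * mx
    fractions[f] <- mean(fr > thr)
    if (fractions[f] == 0) empty[f] <- TRUE
  }
  if (all(empty)) stop("segmentation found no labelled pixels in any frame",
                       call. = FALSE)
  frac <- mean(fractions[!empty])
  out <- staining_model(volume_fraction = frac)
  attr(out, "fractions") <- fractions
  attr(out, "flagged_empty") <- empty
  out
}
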