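#' Tissue optical parameters
#'
#' Gray-matter optical parameters per excitation wavelength. Defaults for
#' 920, 1280 and 1320 nm: absorption 0.039 / 0.078 / 0.12 per mm,
#' scattering 6.7 / 3.2 / 3.2 per mm, anisotropy 0.9 and refractive index
#' 1.36 at all three wavelengths. The implied effective attenuation lengths
#' 1/(mu_a + mu_s) are ~148 um at 920 nm and ~300 um at 1280/1320 nm.
#'
#' @param wavelength_nm One of 920, 1280, 1320 for the built-in table, or
#'   any value when all coefficients are supplied explicitly.
#' @param mua_per_mm,mus_per_mm Absorption / scattering coefficients, 1/mm.
#' @param g Scattering anisotropy, in `[0, 1)`.
#' @param n_refr Tissue refractive index.
#' @return An object of class `tissue_optics`.
#' @export
tissue_optics <- function(wavelength_nm, mua_per_mm = NULL, mus_per_mm = NULL,
                          g = 0.9, n_refr = 1.36) {
  tab <- list(`920` = c(0.039, 6.7), `1280` = c(0.078, 3.2),
              `1320` = c(0.12, 3.2))
  if (is.null(mua_per_mm) || is.null(mus_per_mm)) {
    key <- as.character(wavelength_nm)
    if (!key %in% names(tab))
      stop("no built-in optical parameters for ", wavelength_nm,
           " nm; supply mua_per_mm and mus_per_mm", call. = FALSE)
    mua_per_mm <- tab[[key]][1]
    mus_per_mm <- tab[[key]][2]
  }
  if (mua_per_mm < 0 || mus_per_mm < 0) stop("coefficients must be >= 0", call. = FALSE)
  if (g < 0 || g >= 1) stop("`g` must be in [0, 1)", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, mua_per_mm = mua_per_mm,
                 mus_per_mm = mus_per_mm, g = g, n_refr = n_refr),
            class = "tissue_optics")
}

#' Beam and objective geometry
#'
#' Geometry of the focused excitation beam: an objective of the given NA
#' and focal length, underfilled so that the 1/e^2 Gaussian beam diameter
#' matches `fill_fraction` of the back aperture. The defaults (NA 1.05,
#' f = 7.2 mm, 70% fill) give an effective NA of ~0.75.
#'
#' @param z_focus_um Imaging (focal) depth below the tissue surface, um.
#' @param fov_diameter_um Diameter of the scanned field of view, um (0 for
#'   a parked beam).
#' @param objective_na Full objective numerical aperture.
#' @param focal_length_mm Objective focal length, mm.
#' @param fill_fraction 1/e^2 beam diameter over back-aperture diameter,
#'   in (0, 1].
#' @param n0 Immersion refractive index (water).
#' @return An object of class `beam_geometry`; element `na_eff` holds the
#'   effective NA implied by the fill.
#' @export
beam_geometry <- function(z_focus_um, fov_diameter_um = 230,
                          objective_na = 1.05, focal_length_mm = 7.2,
                          fill_fraction = 0.70, n0 = 1.33) {
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop("`fill_fraction` must be in (0, 1]", call. = FALSE)
  if (z_focus_um < 0) stop("`z_focus_um` must be >= 0", call. = FALSE)
  w0_mm <- fill_fraction * objective_na * focal_length_mm
  structure(list(z_focus_um = z_focus_um, fov_diameter_um = fov_diameter_um,
                 objective_na = objective_na, focal_length_mm = focal_length_mm,
                 fill_fraction = fill_fraction, n0 = n0, w0_mm = w0_mm,
                 na_eff = w0_mm / focal_length_mm),
            class = "beam_geometry")
}

#' Simulation volume geometry
#'
#' @param escape_radius_mm Lateral escape bound from the window centre, mm.
#' @param escape_depth_mm Axial escape bound, mm.
#' @param window_radius_mm Cranial window radius: photons back-scattered
#'   out of the surface within this radius are classified as exiting
#'   through the window, outside it as hitting the skull.
#' @param voxel_um Pitch of the cylindrical (r, z) absorption grid, um.
#' @param layers Optional list of `tissue_optics` layers, each with an
#'   added element `zmax_mm` (layer lower boundary); default is a single
#'   homogeneous layer of the tissue passed to [simulate_transport()].
#' @return An object of class `simulation_geometry`.
#' @export
simulation_geometry <- function(escape_radius_mm = 6, escape_depth_mm = 6,
                                window_radius_mm = 2.5, voxel_um = 20,
                                layers = NULL) {
  if (escape_radius_mm <= 0 || escape_depth_mm <= 0 || voxel_um <= 0)
    stop("bounds and voxel pitch must be positive", call. = FALSE)
  structure(list(escape_radius_mm = escape_radius_mm,
                 escape_depth_mm = escape_depth_mm,
                 window_radius_mm = window_radius_mm,
                 voxel_um = voxel_um, layers = layers),
            class = "simulation_geometry")
}

#' Sample photon launch coordinates for an underfilled objective
#'
#' Converts uniform draws into launch coordinates of the focused Gaussian
#' beam: back-aperture radius `w = w0 sqrt(-ln(u)/2)`, polar angle
#' `theta = asin(w / (n0 f))`, and surface entry radius `r = tan(theta) z`
#' so that every ray converges on the focal point at depth `z`. Draws that
#' fall outside the physical aperture (`w > n0 f`) are rejected upstream;
#' here they return `NA` and callers resample.
#'
#' @param beam A [beam_geometry] object.
#' @param u Uniform(0, 1] draws (vectorised).
#' @return Data frame with columns `w_mm`, `theta_rad`, `r_mm` (entry
#'   radius at the surface for the beam's focal depth).
#' @export
launch_photon <- function(beam, u) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (any(u <= 0) || any(u > 1)) stop("`u` must be in (0, 1]", call. = FALSE)
  w <- beam$w0_mm * sqrt(-log(u) / 2)
  s <- w / (beam$n0 * beam$focal_length_mm)
  theta <- asin(pmin(s, 1))
  theta[s > 1] <- NA_real_
  data.frame(w_mm = w, theta_rad = theta,
             r_mm = tan(theta) * beam$z_focus_um / 1000)
}

#' Monte Carlo photon transport through scanned focused illumination
#'
#' Launches `n_photons` weighted photons from the tissue surface (Gaussian
#' back-aperture fill, focal positions scanned uniformly over the FOV disk)
#' and propagates them with exponential free paths, Henyey-Greenstein
#' scattering, implicit-capture absorption and Russian roulette. Photon
#' weight is classified into four terminal fates: absorbed in the tissue
#' (contributing to heating), back-scattered out through the cranial
#' window, back-scattered to the skull, or escaped beyond the 6-mm bounds.
#'
#' @param beam A [beam_geometry] object.
#' @param tissue A [tissue_optics] object (used as a single homogeneous
#'   layer unless `geom$layers` is set).
#' @param geom A [simulation_geometry] object.
#' @param n_photons Number of photon packets (>= 1e5 recommended for fate
#'   fractions to the percent level).
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @param roulette Use Russian roulette termination (default TRUE; FALSE
#'   propagates to a hard weight floor, slower but useful for conservation
#'   checks).
#' @return An object of class `absorption_grid`: a list with
#'   \describe{
#'     \item{values}{matrix (r x z) of absorbed power density Sh, mW/mm^3
#'       per watt entering the tissue surface;}
#'     \item{r_mm, z_mm}{voxel-centre coordinates;}
#'     \item{fate_summary}{named fractions (heating, window, skull,
#'       escaped) with attribute `"se"` giving binomial standard errors;}
#'     \item{heating_fraction}{fraction of launched weight absorbed;}
#'     \item{conservation}{deposited + exited + roulette residual minus
#'       launched weight, per unit launched (machine-precision zero).}
#'   }
#' @export
simulate_transport <- function(beam, tissue, geom = simulation_geometry(),
                               n_photons = 1e5, seed = NULL, roulette = TRUE) {
  stopifnot(inherits(beam, "beam_geometry"), inherits(tissue, "tissue_optics"),
            inherits(geom, "simulation_geometry"))
  if (n_photons < 1) stop("`n_photons` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(geom$layers)) {
    mua <- tissue$mua_per_mm; mus <- tissue$mus_per_mm; g <- tissue$g
    zmax <- geom$escape_depth_mm
  } else {
    mua <- vapply(geom$layers, `[[`, numeric(1), "mua_per_mm")
    mus <- vapply(geom$layers, `[[`, numeric(1), "mus_per_mm")
    g <- vapply(geom$layers, `[[`, numeric(1), "g")
    zmax <- vapply(geom$layers, `[[`, numeric(1), "zmax_mm")
  }

  dv <- geom$voxel_um / 1000
  nr <- ceiling(geom$escape_radius_mm / dv)
  nz <- ceiling(geom$escape_depth_mm / dv)
  if (dv > 2 * beam$z_focus_um / 1000 + dv * 1e-9 && beam$z_focus_um > 0)
    warning("voxel pitch is coarse relative to the focal depth")

  res <- .mc_transport_cpp(as.integer(n_photons),
                           beam$z_focus_um / 1000,
                           beam$fov_diameter_um / 2000,
                           beam$w0_mm, beam$focal_length_mm, beam$n0,
                           mua, mus, g, zmax,
                           geom$escape_radius_mm, geom$escape_depth_mm,
                           geom$window_radius_mm,
                           nr, nz, dv, dv, roulette)

  launched <- res$launched
  fates <- c(heating = res$heating, window = res$window,
             skull = res$skull, escaped = res$escaped) / launched
  se <- sqrt(pmax(fates * (1 - fates), 0) / n_photons)
  attr(fates, "se") <- se

  r_edges <- dv * (0:nr)
  vol <- pi * (r_edges[-1]^2 - r_edges[-(nr + 1)]^2) * dv   # mm^3 shell volumes
  sh <- sweep(res$grid / launched, 1, vol, "/") * 1000      # mW/mm^3 per W in

  structure(list(
    values = sh,
    r_mm = dv * (seq_len(nr) - 0.5),
    z_mm = dv * (seq_len(nz) - 0.5),
    dr_mm = dv, dz_mm = dv,
    fate_summary = fates,
    heating_fraction = unname(fates["heating"]),
    conservation = (res$heating + res$window + res$skull + res$escaped +
                      res$roulette_net - launched) / launched,
    roulette_net = res$roulette_net / launched,
    n_photons = n_photons,
    beam = beam, tissue = tissue, geom = geom
  ), class = "absorption_grid")
}

#' @export
print.absorption_grid <- function(x, ...) {
  f <- x$fate_summary
  cat(sprintf(
    "<absorption_grid> %g photons, focus %g um, FOV %g um\n  fates: heating %.1f%%, window %.1f%%, skull %.1f%%, escaped %.1f%%\n",
    x$n_photons, x$beam$z_focus_um, x$beam$fov_diameter_um,
    100 * f["heating"], 100 * f["window"], 100 * f["skull"], 100 * f["escaped"]))
  invisible(x)
}
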