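#' Thermal and physiological parameters of gray matter
#'
#' Defaults: density 1.04e-3 g/mm^3, specific heat 3.65e3 mJ/(g C),
#' conductivity 0.527 mW/(mm C), blood density 1.06e-3 g/mm^3, blood
#' specific heat 3.6e3 mJ/(g C), perfusion rate 8.5e-3 /s, metabolic heat
#' 9.5e-3 mW/mm^3, arterial temperature 36.7 C.
#'
#' @param rho,c,k Tissue density, specific heat, thermal conductivity.
#' @param rho_b,c_b,w_b Blood density, specific heat, perfusion rate.
#' @param q_m Metabolic volumetric heat production.
#' @param t_a Arterial blood temperature, C.
#' @return An object of class `thermal_params`. The derived element
#'   `perfusion_mw_mm3_c` is rho_b * c_b * w_b, and `perfusion_length_mm`
#'   is sqrt(k / (rho_b c_b w_b)) (~4 mm), the scale over which perfusion
#'   confines a temperature perturbation.
#' @export
thermal_params <- function(rho = 1.04e-3, c = 3.65e3, k = 0.527,
                           rho_b = 1.06e-3, c_b = 3.6e3, w_b = 8.5e-3,
                           q_m = 9.5e-3, t_a = 36.7) {
  vals <- c(rho, c, k, rho_b, c_b, w_b, q_m, t_a)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thermal parameters must be positive", call. = FALSE)
  pb <- rho_b * c_b * w_b
  structure(list(rho = rho, c = c, k = k, rho_b = rho_b, c_b = c_b,
                 w_b = w_b, q_m = q_m, t_a = t_a,
                 perfusion_mw_mm3_c = pb,
                 perfusion_length_mm = sqrt(k / pb)),
            class = "thermal_params")
}

#' Bio-heat boundary conditions
#'
#' The top surface under the cranial window is held at `top_window_c`
#' (sub-body, representing heat loss through the window and immersion
#' water; this is the main calibration parameter of the model). The top
#' surface outside the window is adiabatic (insulating skull/headpost),
#' and the lateral and deep boundaries are held at the arterial
#' temperature. `dirichlet_fn(r_mm, z_mm)`, when supplied, overrides all
#' outer boundaries with prescribed temperatures (used for analytic
#' benchmarks).
#'
#' @param top_window_c Window surface temperature, C.
#' @param window_radius_mm Cranial window radius, mm.
#' @param boundary_c Lateral/deep boundary temperature; default the
#'   arterial temperature.
#' @param dirichlet_fn Optional `function(r_mm, z_mm)` giving the boundary
#'   temperature on every outer face.
#' @param insulated When TRUE all outer boundaries are adiabatic (the
#'   perfusion term alone anchors the temperature); used for analytic
#'   benchmarks such as the uniform perfusion balance
#'   T = T_A + q_m / (rho_b c_b w_b).
#' @return An object of class `bioheat_bc`.
#' @export
bioheat_bc <- function(top_window_c = 30, window_radius_mm = 2.5,
                       boundary_c = NULL, dirichlet_fn = NULL,
                       insulated = FALSE) {
  structure(list(top_window_c = top_window_c,
                 window_radius_mm = window_radius_mm,
                 boundary_c = boundary_c, dirichlet_fn = dirichlet_fn,
                 insulated = insulated),
            class = "bioheat_bc")
}

# Assemble the symmetric (volume-weighted) finite-volume operator for the
# axisymmetric Pennes equation on the (r, z) grid. Returns the sparse matrix
# A (positive definite), the constant vector b0 (everything except the
# optical source), the Dirichlet-coupling bookkeeping, and cell volumes.
.bioheat_assemble <- function(r_mm, z_mm, dr, dz, thermal, bc) {
  nr <- length(r_mm); nz <- length(z_mm)
  n <- nr * nz
  k <- thermal$k; pb <- thermal$perfusion_mw_mm3_c
  ta <- thermal$t_a
  bnd <- if (is.null(bc$boundary_c)) ta else bc$boundary_c
  vol <- outer(r_mm, rep(dz, nz)) * dr           # per radian; 2*pi dropped

  # radial internal faces: between (i, j) and (i+1, j), face radius i*dr
  i1 <- rep(seq_len(nr - 1), times = nz)
  j1 <- rep(seq_len(nz), each = nr - 1)
  a_r <- i1 + (j1 - 1L) * nr
  b_r <- a_r + 1L
  c_r <- k * i1 * dr * dz / dr
  # axial internal faces: between (i, j) and (i, j+1)
  i2 <- rep(seq_len(nr), times = nz - 1)
  j2 <- rep(seq_len(nz - 1), each = nr)
  a_z <- i2 + (j2 - 1L) * nr
  b_z <- a_z + nr
  c_z <- k * r_mm[i2] * dr / dz

  b0 <- numeric(n)
  dir_cells <- integer(0); dir_cond <- numeric(0); dir_temp <- numeric(0)
  bfun <- bc$dirichlet_fn
  if (isTRUE(bc$insulated)) {
    ii <- c(a_r, b_r, a_z, b_z, a_r, b_r, a_z, b_z, seq_len(n))
    jj <- c(b_r, a_r, b_z, a_z, a_r, b_r, a_z, b_z, seq_len(n))
    xx <- c(-c_r, -c_r, -c_z, -c_z, c_r, c_r, c_z, c_z, pb * as.vector(vol))
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
    b0 <- pb * as.vector(vol) * ta + thermal$q_m * as.vector(vol)
    return(list(A = Matrix::forceSymmetric(A), b0 = b0, vol = vol,
                dir = list(cells = integer(0), cond = numeric(0),
                           temp = numeric(0))))
  }
  # side boundary (r = R)
  cells <- nr + (seq_len(nz) - 1L) * nr
  cond <- rep(k * (nr * dr) * dz / (dr / 2), nz)
  temp <- if (is.null(bfun)) rep(bnd, nz) else rep_len(bfun(nr * dr, z_mm), nz)
  b0[cells] <- b0[cells] + cond * temp
  dir_cells <- c(dir_cells, cells); dir_cond <- c(dir_cond, cond)
  dir_temp <- c(dir_temp, temp)
  # bottom boundary (z = Z)
  cells <- seq_len(nr) + (nz - 1L) * nr
  cond <- k * r_mm * dr / (dz / 2)
  temp <- if (is.null(bfun)) rep(bnd, nr) else rep_len(bfun(r_mm, nz * dz), nr)
  b0[cells] <- b0[cells] + cond * temp
  dir_cells <- c(dir_cells, cells); dir_cond <- c(dir_cond, cond)
  dir_temp <- c(dir_temp, temp)
  # top boundary (z = 0): window Dirichlet, skull adiabatic (unless bfun)
  if (is.null(bfun)) {
    iw <- which(r_mm <= bc$window_radius_mm)
    cells <- iw
    cond <- k * r_mm[iw] * dr / (dz / 2)
    temp <- rep(bc$top_window_c, length(iw))
  } else {
    cells <- seq_len(nr)
    cond <- k * r_mm * dr / (dz / 2)
    temp <- rep_len(bfun(r_mm, 0), nr)
  }
  b0[cells] <- b0[cells] + cond * temp
  dir_cells <- c(dir_cells, cells); dir_cond <- c(dir_cond, cond)
  dir_temp <- c(dir_temp, temp)

  # assemble with duplicate-summing triplets: off-diagonal -c, diagonal +c
  ii <- c(a_r, b_r, a_z, b_z, a_r, b_r, a_z, b_z, dir_cells, seq_len(n))
  jj <- c(b_r, a_r, b_z, a_z, a_r, b_r, a_z, b_z, dir_cells, seq_len(n))
  xx <- c(-c_r, -c_r, -c_z, -c_z, c_r, c_r, c_z, c_z, dir_cond,
          pb * as.vector(vol))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  b0 <- b0 + pb * as.vector(vol) * ta + thermal$q_m * as.vector(vol)
  list(A = Matrix::forceSymmetric(A), b0 = b0, vol = vol,
       dir = list(cells = dir_cells, cond = dir_cond, temp = dir_temp))
}

#' Bare solver grid without a transport source
#'
#' Convenience constructor for running [solve_bioheat()] on a chosen grid
#' with an explicit source (or none), without a transport simulation.
#'
#' @param nr,nz Number of radial / axial cells.
#' @param voxel_um Cell pitch, um.
#' @return A minimal absorption-grid-shaped list (zero source).
#' @export
heat_grid <- function(nr, nz, voxel_um = 50) {
  dv <- voxel_um / 1000
  structure(list(values = matrix(0, nr, nz),
                 r_mm = dv * (seq_len(nr) - 0.5),
                 z_mm = dv * (seq_len(nz) - 0.5),
                 dr_mm = dv, dz_mm = dv, tissue = NULL),
            class = "absorption_grid")
}

#' Solve the Pennes bio-heat equation for a given optical heat source
#'
#' Finite-volume solution of
#' \deqn{\rho c \, \partial T/\partial t = k \nabla^2 T
#'   + \rho_b c_b w_b (T_A - T) + S_h + q_m}
#' on the axisymmetric (r, z) grid of the Monte Carlo absorption field.
#' The steady state is obtained by a direct sparse solve; the transient by
#' implicit time stepping from a uniform arterial-temperature initial
#' condition.
#'
#' @param absorption An [`absorption_grid`][simulate_transport] from the
#'   transport module (its `values` are Sh per watt entering the tissue).
#' @param power_after_objective_mw Average power immediately after the
#'   objective, mW; attenuated to the surface through `water_path_mm` of
#'   immersion water before scaling the source.
#' @param thermal A [thermal_params] object.
#' @param bc A [bioheat_bc] object.
#' @param mode `"steady"` or `"transient"`.
#' @param t_s End time for transient mode, seconds.
#' @param dt_s Implicit time step for transient mode, seconds.
#' @param water_path_mm Immersion-water path length, mm.
#' @param source_mw_mm3 Optional explicit absorbed-power-density matrix
#'   (mW/mm^3, same shape as the grid) overriding
#'   `absorption$values * power`.
#' @return An object of class `temperature_field`: `values` (nr x nz
#'   matrix, C), `r_mm`, `z_mm`, `time_s` (Inf for steady state), and
#'   `balance`, a named vector (mW) with the optical + metabolic input,
#'   the perfusion sink and the net boundary loss.
#' @export
solve_bioheat <- function(absorption, power_after_objective_mw = 0,
                          thermal = thermal_params(), bc = bioheat_bc(),
                          mode = c("steady", "transient"), t_s = 60,
                          dt_s = 1, water_path_mm = 1.0,
                          source_mw_mm3 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(thermal, "thermal_params"), inherits(bc, "bioheat_bc"))
  r_mm <- absorption$r_mm; z_mm <- absorption$z_mm
  dr <- absorption$dr_mm; dz <- absorption$dz_mm
  nr <- length(r_mm); nz <- length(z_mm)

  if (is.null(source_mw_mm3)) {
    wl <- if (!is.null(absorption$tissue)) absorption$tissue$wavelength_nm else 1320
    p_surface_mw <- water_absorption_correction(power_after_objective_mw,
                                                water_path_mm, wl)
    source_mw_mm3 <- absorption$values * (p_surface_mw / 1000)
  } else {
    stopifnot(all(dim(source_mw_mm3) == c(nr, nz)))
  }

  asm <- .bioheat_assemble(r_mm, z_mm, dr, dz, thermal, bc)
  b <- asm$b0 + as.vector(source_mw_mm3 * asm$vol)

  if (mode == "steady") {
    tvec <- as.numeric(Matrix::solve(asm$A, b))
    time_s <- Inf
  } else {
    n <- nr * nz
    m_dt <- thermal$rho * thermal$c * as.vector(asm$vol) / dt_s
    B <- asm$A + Matrix::Diagonal(n, m_dt)
    fac <- Matrix::Cholesky(B)
    tvec <- rep(thermal$t_a, n)
    nsteps <- ceiling(t_s / dt_s)
    for (s in seq_len(nsteps))
      tvec <- as.numeric(Matrix::solve(fac, b + m_dt * tvec))
    time_s <- nsteps * dt_s
  }

  tm <- matrix(tvec, nr, nz)
  two_pi <- 2 * pi
  balance <- c(
    optical_mw = two_pi * sum(source_mw_mm3 * asm$vol),
    metabolic_mw = two_pi * thermal$q_m * sum(asm$vol),
    perfusion_sink_mw = two_pi * thermal$perfusion_mw_mm3_c *
      sum(asm$vol * (tm - thermal$t_a)),
    boundary_loss_mw = two_pi *
      sum(asm$dir$cond * (tvec[asm$dir$cells] - asm$dir$temp))
  )

  structure(list(values = tm, r_mm = r_mm, z_mm = z_mm,
                 dr_mm = dr, dz_mm = dz, time_s = time_s,
                 thermal = thermal, bc = bc, balance = balance),
            class = "temperature_field")
}

#' Maximum-temperature metric over the hottest volume
#'
#' Average temperature over a coaxial cylinder of ~1e7 um^3 (120 um radius
#' by 210 um height) centred axially on the hottest cell, the metric used
#' to summarise heating of the scanned region.
#'
#' @param field A [`temperature_field`][solve_bioheat].
#' @param radius_um,height_um Averaging cylinder dimensions, um.
#' @return Mean temperature in the cylinder, C.
#' @export
max_temperature <- function(field, radius_um = 120, height_um = 210) {
  stopifnot(inherits(field, "temperature_field"))
  w <- which(field$values == max(field$values), arr.ind = TRUE)[1, ]
  zc <- field$z_mm[w[2]]
  half_h <- height_um / 2000
  z_top <- max(field$z_mm) + field$dz_mm / 2
  if (2 * half_h > z_top)
    stop("averaging cylinder extends beyond the solved grid", call. = FALSE)
  # when the hottest cell sits at a boundary, slide the window inside the grid
  zc <- min(max(zc, half_h), z_top - half_h)
  zmin <- zc - half_h; zmax <- zc + half_h
  ir <- which(field$r_mm <= radius_um / 1000)
  iz <- which(field$z_mm >= zmin & field$z_mm <= zmax)
  if (!length(ir) || !length(iz))
    stop("averaging cylinder is smaller than one grid cell", call. = FALSE)
  wts <- field$r_mm[ir]                       # shell volume weight per radian
  sum(field$values[ir, iz, drop = FALSE] * wts) / (sum(wts) * length(iz))
}

#' Maximum temperature versus imaging power
#'
#' Exploits the linearity of the Pennes equation in the heat source: the
#' field is solved once at zero power and once at a reference power, and
#' the temperature at any power is the affine combination. Reports the
#' hottest-volume metric per power, the local slope per 50 mW, and the
#' powers at which the metric crosses 37 C and the safety threshold.
#'
#' @param absorption An [`absorption_grid`][simulate_transport].
#' @param powers_mw Powers after the objective, mW (non-empty).
#' @param thermal,bc,water_path_mm Passed to [solve_bioheat()].
#' @param safety_limit_c Peak-temperature safety threshold, C (default 41).
#' @return A list with `table` (power, tmax), `slope_c_per_50mw` (between
#'   the two highest powers), `p_cross_37_mw`, `p_cross_limit_mw`.
#' @export
power_sweep <- function(absorption, powers_mw, thermal = thermal_params(),
                        bc = bioheat_bc(), water_path_mm = 1.0,
                        safety_limit_c = 41) {
  if (!length(powers_mw)) stop("`powers_mw` must be non-empty", call. = FALSE)
  p_ref <- max(powers_mw, 50)
  f0 <- solve_bioheat(absorption, 0, thermal, bc, water_path_mm = water_path_mm)
  f1 <- solve_bioheat(absorption, p_ref, thermal, bc,
                      water_path_mm = water_path_mm)
  dT <- (f1$values - f0$values) / p_ref            # C per mW after objective
  tmax_at <- function(p) {
    fld <- f0; fld$values <- f0$values + p * dT
    max_temperature(fld)
  }
  tmax <- vapply(sort(powers_mw), tmax_at, numeric(1))
  powers <- sort(powers_mw)
  np <- length(powers)
  slope <- if (np >= 2) {
    (tmax[np] - tmax[np - 1]) / (powers[np] - powers[np - 1]) * 50
  } else NA_real_
  cross <- function(level) {
    pr <- range(c(0, powers, 2 * max(powers, 50)))
    f <- function(p) tmax_at(p) - level
    if (f(pr[1]) > 0) return(0)
    if (f(pr[2]) < 0) return(NA_real_)
    stats::uniroot(f, pr, tol = 0.1)$root
  }
  list(table = data.frame(power_mw = powers, tmax_c = tmax),
       slope_c_per_50mw = slope,
       p_cross_37_mw = cross(37),
       p_cross_limit_mw = cross(safety_limit_c),
       safety_limit_c = safety_limit_c)
}

#' Scan-induced temperature fluctuation
#'
#' Between successive visits of the scanned beam a point in the tissue
#' cools at the bulk cooling rate, so the peak-to-peak fluctuation is the
#' cooling accumulated over one frame period. At the measured ~0.1 C/s
#' cooling rate and a 2 Hz frame rate this is ~0.05 C, justifying the
#' continuous-illumination treatment of brain heating.
#'
#' @param cooling_rate_c_per_s Bulk tissue cooling rate, C/s.
#' @param frame_rate_hz Frame (revisit) rate, Hz.
#' @return Peak-to-peak temperature fluctuation estimate, C.
#' @export
scan_fluctuation <- function(cooling_rate_c_per_s, frame_rate_hz) {
  if (cooling_rate_c_per_s <= 0 || any(frame_rate_hz <= 0))
    stop("inputs must be positive", call. = FALSE)
  cooling_rate_c_per_s / frame_rate_hz
}

# Immersion-water absorption coefficient, 1/mm. Above 1200 nm water
# dominates tissue absorption and the tissue coefficient equals 75% of the
# water value, so the water value is the tissue value / 0.75. At 920 nm the
# tissue coefficient includes non-water absorbers; the pure-water literature
# value (~0.006/mm) applies instead.
.water_mua_per_mm <- function(wavelength_nm) {
  tab <- c(`920` = 0.006, `1280` = 0.078 / 0.75, `1320` = 0.12 / 0.75)
  key <- as.character(wavelength_nm)
  if (!key %in% names(tab))
    stop("no immersion-water absorption value for ", wavelength_nm, " nm",
         call. = FALSE)
  unname(tab[key])
}

#' Immersion-water absorption correction
#'
#' Beer-Lambert attenuation of the average power between the objective and
#' the brain surface through the immersion-water column. At 1320 nm the
#' default 1-mm path transmits ~85% (80 mW after the objective arrives as
#' ~68 mW at the surface); at 920 nm the correction is below 2% even over
#' 2 mm.
#'
#' @param p_after_objective_mw Power after the objective, mW (vectorised).
#' @param water_path_mm Water path length, mm, >= 0.
#' @param wavelength_nm Excitation wavelength (920, 1280 or 1320).
#' @return Power at the brain surface, mW.
#' @export
water_absorption_correction <- function(p_after_objective_mw,
                                        water_path_mm = 1.0,
                                        wavelength_nm = 1320) {
  if (any(water_path_mm < 0)) stop("`water_path_mm` must be >= 0", call. = FALSE)
  p_after_objective_mw * exp(-.water_mua_per_mm(wavelength_nm) * water_path_mm)
}
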