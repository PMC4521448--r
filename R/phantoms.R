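#' Plane-wave interface validation setup
#'
#' Builds a thin-slab ("2D-equivalent") domain containing a grid-aligned
#' planar interface between two media, a phase-ramped, Tukey-tapered hard
#' tone-burst source plane realizing the requested incidence angle, probe
#' locations above and below the interface, and the timing windows in which
#' the incident, reflected and transmitted bursts are cleanly separated.
#' Oblique incidence is realized by per-column source delays rather than by
#' rotating the grid, so the interface stays grid-aligned.
#'
#' @param cA,rhoA,cB,rhoB Speeds of sound (m/s) and densities (kg/m^3) of
#'   the incident (A) and transmitting (B) medium.
#' @param theta_i Incidence angle, degrees, in `[0, 90)`.
#' @param f Frequency, Hz.
#' @param ppw Grid points per wavelength in medium A (default 20; phase
#'   accuracy of the sign detection degrades below ~15).
#' @param burst_periods Tone-burst length, periods.
#' @param d_probe_int Distance from the upper probe to the interface, m
#'   (`NULL`: chosen so incident and reflected bursts separate cleanly).
#' @param pml_layers PML layers on the z faces.
#' @return List of class `interface_setup` with the material volume, source
#'   spec, probe indices, timing windows and geometry; `evanescent` is TRUE
#'   when the angle is at or beyond the critical angle (the transmitted
#'   wave is then evanescent and `measure_interface()` refuses to run).
#' @export
make_interface_setup <- function(cA, rhoA, cB, rhoB, theta_i, f,
                                 ppw = 20, burst_periods = 12,
                                 d_probe_int = NULL, pml_layers = 16) {
  stopifnot(theta_i >= 0, theta_i < 90)
  mA <- acoustic_medium(cA, rhoA, 0)
  mB <- acoustic_medium(cB, rhoB, 0)
  evan <- (cB / cA * sin(theta_i * pi / 180)) >= 1
  lamA <- cA / f
  dx <- lamA / ppw
  th <- theta_i * pi / 180
  Tb <- burst_periods / f
  # probe-interface distance: reflected burst must arrive after the incident
  # has fully passed: 2 d cos(th)/cA > Tb (+ 2 periods margin)
  if (is.null(d_probe_int))
    d_probe_int <- (burst_periods + 4) / f * cA / (2 * cos(th)) / 2 * 1.15
  d1 <- d_probe_int
  d_src_probe <- 2.5e-3 + 2 * lamA
  d2 <- 2 * lamA   # transmitted probe close below the interface, before
                   # edge-diffraction ripple of the finite beam accumulates
  margin <- 4 * lamA
  # lateral walk of the measured rays plus taper aperture
  walk <- 2 * (d_src_probe + d1) * tan(th)
  half_aperture <- walk + 14 * lamA
  nxh <- ceiling(half_aperture / dx)
  nx <- 2 * nxh + 1 + 2 * pml_layers
  ny <- 1
  nzi <- ceiling((d_src_probe + d1 + d2 + 2 * margin) / dx)
  nz <- nzi + 2 * pml_layers
  k_src <- pml_layers + ceiling(margin / dx)
  k_int <- k_src + ceiling((d_src_probe + d1) / dx)
  k_pA <- k_int - round(d1 / dx)
  k_pB <- k_int + round(d2 / dx)
  labels <- array(1L, c(nx, ny, nz))
  labels[, , k_int:nz] <- 2L
  lt <- list("1" = list(acoustic = mA, name = "mediumA"),
             "2" = list(acoustic = mB, name = "mediumB"))
  vol <- build_material_volume(labels, rep(dx, 3), lt,
                               origin = c(-(nx - 1) / 2 * dx, 0, 0))
  xs <- vol$axes[[1]]
  ic <- (nx + 1) / 2                 # center column
  # phase-ramped, tapered source line (kept out of the lateral PML)
  src_i <- (pml_layers + 2):(nx - pml_layers - 1)
  nsrc <- length(src_i)
  delay <- (xs[src_i] - xs[src_i[1]]) * sin(th) / cA
  tap <- rep(1, nsrc)
  n_tap <- round(6 * lamA / dx)
  ramp_in <- seq_len(n_tap)
  tap[ramp_in] <- 0.5 * (1 - cos(pi * (ramp_in - 0.5) / n_tap))
  tap[nsrc + 1 - ramp_in] <- tap[ramp_in]
  src <- acoustic_sources(cbind(src_i, 1L, k_src), amplitude = 1e3 * tap,
                          phase = 0, delay = delay, type = "hard",
                          burst_periods = burst_periods, taper = 0.3)
  # timing (burst-center arrivals at the center column)
  dz_sA <- (k_pA - k_src) * dx
  t0c <- delay[which(src_i == ic)] + Tb / 2
  t_inc <- t0c + dz_sA * cos(th) / cA
  t_ref <- t_inc + 2 * d1 * cos(th) / cA
  t_tra <- t_inc + d1 * cos(th) / cA +
    (if (evan) NA else (k_pB - k_int) * dx * cos(asin(cB / cA * sin(th))) / cB)
  structure(list(
    vol = vol, source = src, f = f, theta_i = theta_i,
    mediumA = mA, mediumB = mB, evanescent = evan,
    probes = rbind(c(ic, 1, k_pA), c(ic, 1, k_pB)),
    t_inc = t_inc, t_ref = t_ref, t_tra = t_tra,
    burst_periods = burst_periods, d1 = d1, dx = dx,
    n_periods_needed = ceiling((max(t_ref, t_tra, na.rm = TRUE) +
                                  0.75 * Tb) * f)),
    class = "interface_setup")
}

#' Run an interface setup and measure R and T
#'
#' Runs the tone-burst simulation of [make_interface_setup()], demodulates
#' the incident, reflected and transmitted bursts at the probes in their
#' non-overlapping time windows, and returns the signed measured
#' coefficients next to the analytic pair.
#'
#' @param setup An `interface_setup`.
#' @param window_periods Half-width of the demodulation windows, periods.
#' @param ... Passed to [simulate_acoustic()].
#' @return List: `measured` and `analytic` `coefficient_pair`s plus the
#'   raw complex amplitudes.
#' @export
measure_interface <- function(setup, window_periods = 3, ...) {
  if (setup$evanescent)
    stop("incidence at/beyond the critical angle: transmitted wave evanescent")
  f <- setup$f
  res <- simulate_acoustic(setup$vol, f, setup$n_periods_needed,
                           sources = setup$source, receivers = setup$probes,
                           pml_layers = c(16, 16, 0, 0, 16, 16),
                           phasor_periods = 0, ...)
  dt <- res$dt
  win <- window_periods / f
  dem <- function(col, tc) demodulate(res$rec[, col], dt, f,
                                      tc - win, tc + win)
  p_i <- dem(1, setup$t_inc)
  p_r <- dem(1, setup$t_ref)
  p_t <- dem(2, setup$t_tra)
  th <- setup$theta_i * pi / 180
  phase_off <- 2 * pi * f * 2 * setup$d1 * cos(th) / setup$mediumA$c
  meas <- measure_coefficients(p_i, p_r, p_t, phase_offset = phase_off)
  list(measured = meas,
       analytic = analytic_coefficients(setup$mediumA, setup$mediumB,
                                        setup$theta_i),
       p_i = p_i, p_r = p_r, p_t = p_t)
}

#' Baffled-piston validation setup
#'
#' Water-tank domain with a circular, rectangular or planar-ring piston on
#' the lower-z rigid baffle, driven at 500 kHz by default (the classical
#' near-field validation configuration: circular radius 10 mm, rectangular
#' 20 x 20 mm, ring 7.5/10 mm; lossless or alpha = 5.756 Np/m).
#' Element coverage weights of edge voxels are computed by 4 x 4
#' supersampling so that the discrete aperture area matches the nominal one.
#'
#' @param kind `"circular"`, `"rectangular"` or `"ring"`.
#' @param dims Aperture dimensions, m (see
#'   [on_axis_piston_reference()]); defaults per kind match the standard
#'   protocol.
#' @param f Frequency, Hz.
#' @param lossy If TRUE the medium attenuates with `alpha` Np/m.
#' @param alpha Attenuation used when `lossy`, Np/m.
#' @param c0,rho0 Medium properties (default 1500 m/s, 1000 kg/m^3).
#' @param lateral,depth Interior domain size, m.
#' @param ppw Points per wavelength (default 10).
#' @param p0 Surface pressure amplitude `rho c u0`, Pa.
#' @param pml_layers PML layers on the absorbing faces.
#' @return List of class `piston_setup`: `vol`, `vel_sources`, aperture
#'   info, and the axis voxel indices/coordinates for profile extraction
#'   (`z_wall` are axial distances measured from the baffle wall, where the
#'   radiating surface sits).
#' @export
make_piston_setup <- function(kind = c("circular", "rectangular", "ring"),
                              dims = NULL, f = 5e5, lossy = FALSE,
                              alpha = 5.756, c0 = 1500, rho0 = 1000,
                              lateral = 40e-3, depth = 40e-3, ppw = 10,
                              p0 = 1e3, pml_layers = 16) {
  kind <- match.arg(kind)
  if (is.null(dims))
    dims <- switch(kind, circular = 10e-3, rectangular = c(20e-3, 20e-3),
                   ring = c(7.5e-3, 10e-3))
  if (any(dims <= 0) && kind != "ring") stop("nonpositive aperture dims")
  med <- acoustic_medium(c0, rho0,
                         a_per_f = if (lossy) alpha / (f / 1e6) else 0)
  lam <- c0 / f
  dx <- lam / ppw
  nxi <- ceiling(lateral / dx); if (nxi %% 2 == 0) nxi <- nxi + 1
  nzi <- ceiling(depth / dx)
  nx <- nxi + 2 * pml_layers
  nz <- nzi + pml_layers
  lt <- list("1" = list(acoustic = med, name = "water"))
  vol <- build_material_volume(array(1L, c(nx, nx, nz)), rep(dx, 3), lt,
                               origin = c(-(nx - 1) / 2 * dx,
                                          -(nx - 1) / 2 * dx, 0))
  xs <- vol$axes[[1]]; ys <- vol$axes[[2]]
  inside <- switch(kind,
    circular = function(x, y) x^2 + y^2 <= dims[1]^2,
    ring = function(x, y) {
      r2 <- x^2 + y^2
      r2 <= dims[2]^2 & r2 >= dims[1]^2
    },
    rectangular = function(x, y)
      abs(x) <= dims[1] / 2 & abs(y) <= dims[2] / 2)
  half <- switch(kind, circular = dims[1], ring = dims[2],
                 rectangular = max(dims) / 2)
  grid <- expand.grid(i = seq_along(xs), j = seq_along(ys))
  rr <- pmax(abs(xs[grid$i]), abs(ys[grid$j]))
  cand <- which(rr <= half + dx)
  off <- (1:4 - 2.5) / 4 * dx
  gg <- expand.grid(ox = off, oy = off)
  w <- vapply(cand, function(q)
    mean(inside(xs[grid$i[q]] + gg$ox, ys[grid$j[q]] + gg$oy)), 0)
  keep <- w > 0
  idx <- cbind(grid$i[cand][keep], grid$j[cand][keep], 1L)
  u0 <- p0 / (rho0 * c0)
  vs <- velocity_sources(idx, u0, weight = w[keep])
  ic <- (nx + 1) / 2
  kz <- seq_len(nz - pml_layers - 2)
  structure(list(vol = vol, vel_sources = vs, kind = kind, dims = dims,
                 f = f, medium = med, p0 = p0, lossy = lossy,
                 alpha = if (lossy) alpha else 0,
                 pml_layers = c(pml_layers, pml_layers, pml_layers,
                                pml_layers, 0, pml_layers),
                 axis_index = cbind(ic, ic, kz),
                 z_wall = vol$axes[[3]][kz] + dx / 2,
                 source_area = sum(w[keep]) * dx^2),
            class = "piston_setup")
}

#' Run a piston validation case
#'
#' Runs [make_piston_setup()] to steady state (order-4 interior scheme) and
#' returns the on-axis pressure magnitude together with the independent
#' reference of [on_axis_piston_reference()] and their [nsd()].
#'
#' @param setup A `piston_setup`.
#' @param n_periods Periods to steady state (default 60).
#' @param ... Passed to [simulate_acoustic()].
#' @return List: `z` (axis positions from the wall, m), `fdtd`, `reference`
#'   (Pa), `nsd_percent`, and the full steady-state result.
#' @export
run_piston_case <- function(setup, n_periods = 60, ...) {
  res <- run_to_steady_state(setup$vol, setup$f, n_periods,
                             vel_sources = setup$vel_sources,
                             pml_layers = setup$pml_layers, order = 4, ...)
  amp <- res$amplitude[setup$axis_index]
  ref <- on_axis_piston_reference(setup$z_wall, setup$f, setup$medium,
                                  setup$p0, setup$kind, setup$dims,
                                  alpha = setup$alpha)
  sel <- setup$z_wall >= 1e-3
  list(z = setup$z_wall[sel], fdtd = amp[sel], reference = ref[sel],
       nsd_percent = nsd(amp[sel], ref[sel]), result = res)
}

#' Spherical-shell skull phantom
#'
#' Three-region head stand-in: water exterior, bone spherical shell, brain
#' interior. The shell thickness can be smoothly perturbed over direction
#' (low-order random spherical harmonics, seeded) to create a reproducible
#' aberrator with per-ray thickness variation.
#'
#' @param grid_half_extent Half-size of the cubic interior domain, m.
#' @param spacing Voxel size, m.
#' @param outer_radius Outer shell radius, m.
#' @param thickness Mean shell thickness, m (0 gives a water/brain-only
#'   phantom).
#' @param center Shell center, m.
#' @param perturb_frac Relative thickness perturbation amplitude (0 = none).
#' @param seed Integer seed for the perturbation coefficients.
#' @param pml_layers Extra PML voxels added on every face.
#' @param label_table Override label table; default uses
#'   [tissue_table()] Water/Bone/Brain as labels 1/2/3.
#' @param z_crop Optional c(zmin, zmax) to crop the domain in z, m.
#' @return A `material_volume`; attribute `skull` holds the geometry
#'   (center, radii, perturbation spec and the thickness function).
#' @export
make_skull_phantom <- function(grid_half_extent = 38e-3, spacing = 0.64e-3,
                               outer_radius = 18e-3, thickness = 4e-3,
                               center = c(0, 0, 0), perturb_frac = 0,
                               seed = 1L, pml_layers = 0,
                               label_table = NULL, z_crop = NULL) {
  stopifnot(thickness >= 0, thickness < outer_radius)
  if (is.null(label_table)) {
    tab <- tissue_table(c("Water", "Bone", "Brain"))
    label_table <- list("1" = c(tab$Water, name = "Water"),
                        "2" = c(tab$Bone, name = "Bone"),
                        "3" = c(tab$Brain, name = "Brain"))
  }
  thick_fun <- skull_thickness_function(thickness, perturb_frac, seed)
  n1 <- ceiling(grid_half_extent / spacing)
  ax1 <- (seq(-n1, n1) - 0) * spacing
  zax <- ax1
  if (!is.null(z_crop)) zax <- ax1[ax1 >= z_crop[1] & ax1 <= z_crop[2]]
  pad <- function(ax) {
    if (pml_layers == 0) return(ax)
    c(ax[1] - (pml_layers:1) * spacing, ax,
      ax[length(ax)] + (1:pml_layers) * spacing)
  }
  ax1 <- pad(ax1); zax <- pad(zax)
  dims <- c(length(ax1), length(ax1), length(zax))
  dx <- array(ax1, dims)
  dy <- aperm(array(ax1, dims[c(2, 1, 3)]), c(2, 1, 3))
  dz <- aperm(array(zax, dims[c(3, 2, 1)]), c(3, 2, 1))
  px <- dx - center[1]; py <- dy - center[2]; pz <- dz - center[3]
  r <- sqrt(px^2 + py^2 + pz^2)
  labels <- array(1L, dims)
  if (thickness > 0) {
    tloc <- array(thick_fun(cbind(as.numeric(px), as.numeric(py),
                                  as.numeric(pz))), dims)
    labels[r <= outer_radius & r > outer_radius - tloc] <- 2L
    labels[r <= outer_radius - tloc] <- 3L
  } else {
    labels[r <= outer_radius] <- 3L
  }
  vol <- build_material_volume(labels, rep(spacing, 3), label_table,
                               origin = c(ax1[1], ax1[1], zax[1]))
  attr(vol, "skull") <- list(center = center, outer_radius = outer_radius,
                             thickness = thickness,
                             perturb_frac = perturb_frac, seed = seed,
                             thick_fun = thick_fun)
  vol
}

#' Direction-dependent shell thickness function (seeded)
#'
#' Thickness field `t(dir) = t0 (1 + amp * s(dir))` where `s` is a fixed
#' random combination of first- and second-order real spherical harmonics
#' normalized to unit RMS over the sphere, so `amp` is the relative RMS
#' thickness variation; deterministic for a given seed. The thickness is
#' clamped to `[0.25 t0, 1.75 t0]` so strong perturbations cannot open
#' holes in the shell.
#'
#' @param t0 Mean thickness, m.
#' @param amp Relative RMS perturbation amplitude.
#' @param seed Integer seed.
#' @return Function mapping an n x 3 matrix of direction vectors (need not
#'   be normalized) to thicknesses.
#' @export
skull_thickness_function <- function(t0, amp = 0, seed = 1L) {
  if (amp == 0 || t0 == 0) return(function(dirs) rep(t0, NROW(dirs)))
  cf <- withr::with_seed(as.integer(seed), rnorm(8))
  harm <- function(x, y, z)
    cf[1] * x + cf[2] * y + cf[3] * z +
      cf[4] * x * y + cf[5] * y * z + cf[6] * x * z +
      cf[7] * (3 * z^2 - 1) / 2 + cf[8] * (x^2 - y^2)
  # RMS over the sphere from a fixed quasi-uniform sample
  gold <- pi * (3 - sqrt(5))
  kk <- seq_len(2000)
  zz <- -1 + (kk - 0.5) / 1000
  rr <- sqrt(pmax(0, 1 - zz^2))
  sc <- sqrt(mean(harm(rr * cos(kk * gold), rr * sin(kk * gold), zz)^2))
  force(t0); force(amp)
  function(dirs) {
    if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
    nrm <- sqrt(rowSums(dirs^2))
    nrm[nrm == 0] <- 1
    s <- harm(dirs[, 1] / nrm, dirs[, 2] / nrm, dirs[, 3] / nrm) / sc
    pmin(pmax(t0 * (1 + amp * s), 0.25 * t0), 1.75 * t0)
  }
}
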