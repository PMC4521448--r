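#' Effective attenuation term of the time-domain wave equation
#'
#' Converts a spatial attenuation coefficient `a` (Np/m) into the temporal
#' damping rate used by the first-order-in-time loss term of the linear
#' solver: `atilde = 2 a sqrt(a^2 c^4 / (4 pi^2 f^2) + c^2)`. For weak
#' attenuation this reduces to `2 a c`, which makes a plane wave decay as
#' `exp(-a x)`.
#'
#' @param a Attenuation coefficient, Np/m (>= 0). Vectorized.
#' @param c Speed of sound, m/s.
#' @param f Frequency, Hz (> 0).
#' @return Damping rate `atilde`, 1/s.
#' @export
effective_attenuation <- function(a, c, f) {
  stopifnot(all(a >= 0), all(c > 0))
  if (any(f <= 0)) stop("f must be > 0")
  2 * a * sqrt(a^2 * c^4 / (4 * pi^2 * f^2) + c^2)
}

#' Sound diffusivity of a thermoviscous fluid
#'
#' `delta = 2 alpha c^3 / (4 pi^2 f^2)`, the diffusivity that makes the
#' third-time-derivative term of the Westervelt-Lighthill equation reproduce
#' an absorption coefficient `alpha` at frequency `f`.
#'
#' @param alpha Absorption coefficient, Np/m.
#' @param c Speed of sound, m/s.
#' @param f Frequency, Hz.
#' @return Diffusivity, m^2/s.
#' @export
sound_diffusivity <- function(alpha, c, f) 2 * alpha * c^3 / (4 * pi^2 * f^2)

#' Nonlinearity coefficient from B/A
#'
#' @param BoverA Nonlinearity parameter of the fluid.
#' @return `beta = 1 + B/(2A)`.
#' @export
nonlinearity_beta <- function(BoverA) 1 + BoverA / 2

#' CFL-limited time step for the explicit 3D scheme
#'
#' `dt = safety * min(spacing) / (c_max * sqrt(3))`. On nonuniform grids the
#' global minimum step is used.
#'
#' @param spacing Numeric vector of grid steps (any mixture of axes), m.
#' @param c_max Largest speed of sound in the domain, m/s.
#' @param safety Safety factor (default 0.95).
#' @return Time step, s.
#' @export
cfl_timestep <- function(spacing, c_max, safety = 0.95) {
  stopifnot(all(spacing > 0), c_max > 0, safety > 0, safety <= 1)
  safety * min(spacing) / (c_max * sqrt(3))
}

# sigma profiles (1/s) for the CPML, polynomial grading of order m targeting
# a theoretical normal-incidence reflection R0. Returns center and face
# profiles for one axis given per-side layer counts.
.pml_sigma_axis <- function(axis, layers_lo, layers_hi, c_ref,
                            R0 = 1e-4, m = 3) {
  n <- length(axis)
  sig_c <- numeric(n)
  sig_f <- numeric(max(n - 1, 1))
  grade <- function(depth_frac, L_phys) {
    smax <- (m + 1) * c_ref * log(1 / R0) / (2 * L_phys)
    smax * depth_frac^m
  }
  if (layers_lo > 0) {
    L <- axis[layers_lo + 1] - axis[1] + (axis[2] - axis[1])
    for (i in seq_len(layers_lo))
      sig_c[i] <- grade((layers_lo - i + 0.5) / layers_lo, L)
    for (i in seq_len(layers_lo - 1))
      sig_f[i] <- grade((layers_lo - i) / layers_lo, L)
  }
  if (layers_hi > 0) {
    L <- axis[n] - axis[n - layers_hi] + (axis[n] - axis[n - 1])
    for (i in seq_len(layers_hi))
      sig_c[n - i + 1] <- pmax(sig_c[n - i + 1],
                               grade((layers_hi - i + 0.5) / layers_hi, L))
    for (i in seq_len(layers_hi - 1))
      sig_f[n - i] <- pmax(sig_f[n - i], grade((layers_hi - i) / layers_hi, L))
  }
  list(center = sig_c, face = sig_f)
}

#' Point pressure sources for the acoustic solver
#'
#' @param index Integer matrix (n x 3) of voxel indices (1-based), or a
#'   vector of length 3 for a single source.
#' @param amplitude Per-source amplitude, Pa (recycled).
#' @param phase Per-source phase, rad (recycled).
#' @param delay Per-source start delay, s (recycled); the drive is
#'   `amplitude * env(t - delay) * sin(2 pi f (t - delay) + phase)`.
#' @param type `"soft"` (additive, default; transparent to returning waves)
#'   or `"hard"` (Dirichlet; reflective while enforced).
#' @param burst_periods If > 0, sources emit a Tukey-windowed tone burst of
#'   this many periods and (for hard sources) stop being enforced
#'   afterwards; if 0 they run continuously with a smooth ramp-up.
#' @param taper Tukey taper fraction of the burst at each end.
#' @param ramp_periods Ramp-up length for continuous drive, periods.
#' @return An object of class `acoustic_sources`.
#' @export
acoustic_sources <- function(index, amplitude = 1, phase = 0, delay = 0,
                             type = c("soft", "hard"), burst_periods = 0,
                             taper = 0.25, ramp_periods = 4) {
  type <- match.arg(type)
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  n <- nrow(index)
  structure(list(index = index,
                 amplitude = rep_len(amplitude, n),
                 phase = rep_len(phase, n), delay = rep_len(delay, n),
                 type = type, burst_periods = burst_periods, taper = taper,
                 ramp_periods = ramp_periods),
            class = "acoustic_sources")
}

#' Normal-velocity (rigid baffle) sources on the lower-z face
#'
#' Models baffled-piston elements: the k = 1 boundary face is a rigid wall
#' and the listed voxels impose a normal surface velocity
#' `u0 * env(t) * sin(2 pi f t + phase)` through the boundary face flux.
#' The per-voxel `weight` scales `u0` (e.g. partial coverage of edge
#' voxels).
#'
#' @param index Integer matrix (n x 3) of voxel indices with k = 1.
#' @param u0 Normal velocity amplitude, m/s.
#' @param weight Per-voxel multiplier (recycled).
#' @param phase Per-voxel phase, rad (recycled).
#' @param ramp_periods Smooth ramp-up, periods.
#' @return An object of class `velocity_sources`.
#' @export
velocity_sources <- function(index, u0, weight = 1, phase = 0,
                             ramp_periods = 4) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  if (any(index[, 3] != 1L))
    stop("velocity sources must lie on the k = 1 boundary plane")
  n <- nrow(index)
  structure(list(index = index, u0 = u0,
                 weight = rep_len(weight, n), phase = rep_len(phase, n),
                 ramp_periods = ramp_periods),
            class = "velocity_sources")
}

# linear (0-based) index from 1-based ijk matrix
.lin0 <- function(idx, dims) {
  (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
}

#' Nearest voxel index of a physical position
#'
#' @param vol A `material_volume`.
#' @param pos Position (m), length 3, or an n x 3 matrix.
#' @return Integer matrix (n x 3) of 1-based voxel indices.
#' @export
position_to_index <- function(vol, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  out <- sapply(1:3, function(d)
    pmin(pmax(1L, vapply(pos[, d], function(p)
      which.min(abs(vol$axes[[d]] - p)), 1L)), vol$dims[d]))
  matrix(as.integer(out), ncol = 3)
}

#' Run the FDTD acoustic solver
#'
#' Advances the linear (LAPWE) or nonlinear (Westervelt-Lighthill) pressure
#' wave equation on the grid of `vol` for a whole number of periods, with
#' CPML absorbing layers, and optionally extracts single-frequency phasor
#' fields by discrete Fourier projection over the final periods.
#'
#' The time step is the CFL-limited step rounded down so that a period is
#' an integer number of steps (required for exact phasor projection).
#'
#' @param vol A [build_material_volume()] material volume.
#' @param f Drive frequency, Hz.
#' @param n_periods Number of periods to simulate.
#' @param sources An [acoustic_sources()] object or `NULL`.
#' @param vel_sources A [velocity_sources()] object or `NULL`. Using one
#'   disables the PML on the lower-z face (rigid baffle).
#' @param receivers Integer matrix (n x 3) of voxel indices whose pressure
#'   time series are recorded, or `NULL`.
#' @param solver `"lapwe"` or `"wle"`.
#' @param pml_layers Layers per face, either a single integer or a vector
#'   of 6 (x-, x+, y-, y+, z-, z+). Default 16.
#' @param phasor_periods Number of final periods used for phasor
#'   projection (0 disables full-grid phasors).
#' @param harmonics Multiples of `f` at which phasors are extracted
#'   (default 1; e.g. `c(1, 2)` adds the second harmonic).
#' @param cfl_safety CFL safety factor.
#' @param air_mode `"pressure_release"` (default) clamps air-labelled
#'   voxels to p = 0; `"full"` keeps air as a propagating medium (the CFL
#'   step then honours its properties).
#' @param BoverA_default B/A used for media lacking one when
#'   `solver = "wle"`.
#' @param pml_R0,pml_order CPML design reflection coefficient and grading
#'   order.
#' @param order Spatial order of accuracy: 2 (default; heterogeneous flux
#'   scheme everywhere) or 4 (4th-order space with Lax-Wendroff 4th-order
#'   time correction in homogeneous uniformly-gridded interior regions,
#'   automatic fallback to the 2nd-order scheme near interfaces, PML and
#'   edges; linear solver only). Order 4 sharpens near-field diffraction
#'   nulls that 2nd-order dispersion would otherwise fill in.
#' @return List with `phasor` (list of complex 3D arrays, one per harmonic;
#'   `amplitude = Mod`, `phase = Arg`), `rec` (time-series matrix, one
#'   column per receiver, rows at `t = dt, 2 dt, ...`), `dt`,
#'   `steps_per_period`, `maxp` (per-step max |p|) and `p_final`.
#' @export
simulate_acoustic <- function(vol, f, n_periods, sources = NULL,
                              vel_sources = NULL, receivers = NULL,
                              solver = c("lapwe", "wle"), pml_layers = 16,
                              phasor_periods = 2, harmonics = 1,
                              cfl_safety = 0.95,
                              air_mode = c("pressure_release", "full"),
                              BoverA_default = 5.0,
                              pml_R0 = 1e-4, pml_order = 3, order = 2) {
  solver <- match.arg(solver)
  air_mode <- match.arg(air_mode)
  stopifnot(n_periods >= 1, f > 0)
  dims <- vol$dims
  flds <- material_fields(vol, f)
  mask_idx <- integer(0)
  if (air_mode == "pressure_release" && any(flds$air_mask)) {
    mask_idx <- which(flds$air_mask) - 1L
    cmax <- max(flds$c[!flds$air_mask])
  } else cmax <- max(flds$c)

  stopifnot(order %in% c(2, 4))
  dt_cfl <- if (order == 4) cfl_safety * min(unlist(vol$widths)) / (2 * cmax)
            else cfl_timestep(unlist(vol$widths), cmax, cfl_safety)
  spp <- ceiling(1 / (f * dt_cfl))
  dt <- 1 / (f * spp)
  nsteps <- as.integer(round(n_periods * spp))

  if (length(pml_layers) == 1) pml_layers <- rep(pml_layers, 6)
  stopifnot(length(pml_layers) == 6)
  if (!is.null(vel_sources)) pml_layers[5] <- 0L
  sx <- .pml_sigma_axis(vol$axes[[1]], pml_layers[1], pml_layers[2], cmax,
                        pml_R0, pml_order)
  sy <- .pml_sigma_axis(vol$axes[[2]], pml_layers[3], pml_layers[4], cmax,
                        pml_R0, pml_order)
  sz <- .pml_sigma_axis(vol$axes[[3]], pml_layers[5], pml_layers[6], cmax,
                        pml_R0, pml_order)

  if (solver == "wle") {
    labs <- as.integer(vol$labels)
    ulab <- sort(unique(labs))
    key <- match(labs, ulab)
    getba <- function(l) {
      e <- vol$label_table[[as.character(l)]]
      ba <- e$acoustic$BoverA
      if (is.null(ba)) BoverA_default else ba
    }
    getal <- function(l) {
      e <- vol$label_table[[as.character(l)]]
      al <- e$acoustic$alpha_abs
      if (is.null(al)) e$acoustic$a_per_f * f / 1e6 else al
    }
    beta <- nonlinearity_beta(vapply(ulab, getba, 0))[key]
    alpha <- vapply(ulab, getal, 0)[key]
    delta <- sound_diffusivity(alpha, as.numeric(flds$c), f)
    solver_i <- 1L
  } else {
    beta <- 0; delta <- 0; solver_i <- 0L
  }

  if (is.null(sources)) {
    s_idx <- integer(0); s_amp <- s_ph <- s_dl <- numeric(0)
    s_type <- 0L; s_burst <- 0; s_taper <- 0.25; s_ramp <- 4
  } else {
    s_idx <- as.integer(.lin0(sources$index, dims))
    s_amp <- sources$amplitude; s_ph <- sources$phase; s_dl <- sources$delay
    s_type <- if (sources$type == "hard") 1L else 0L
    s_burst <- if (sources$burst_periods > 0) sources$burst_periods / f else 0
    s_taper <- sources$taper; s_ramp <- sources$ramp_periods
  }
  if (is.null(vel_sources)) {
    v_idx <- integer(0); v_amp <- v_ph <- numeric(0); v_ramp <- 4
  } else {
    v_idx <- as.integer(.lin0(vel_sources$index, dims))
    v_amp <- vel_sources$u0 * vel_sources$weight
    v_ph <- vel_sources$phase; v_ramp <- vel_sources$ramp_periods
  }
  rec_idx <- if (is.null(receivers)) integer(0)
             else as.integer(.lin0(receivers, dims))

  ph_freqs <- if (phasor_periods > 0) harmonics * f else numeric(0)
  ph_start <- nsteps - as.integer(round(phasor_periods * spp))

  res <- .fdtd_run(as.integer(dims),
                   vol$axes[[1]], vol$axes[[2]], vol$axes[[3]],
                   as.numeric(flds$rho), as.numeric(flds$c),
                   as.numeric(flds$atilde),
                   solver_i, as.numeric(delta), as.numeric(beta),
                   dt, nsteps, f,
                   sx$center, sx$face, sy$center, sy$face, sz$center, sz$face,
                   s_idx, s_amp, s_ph, s_dl, s_type, s_burst, s_taper, s_ramp,
                   v_idx, v_amp, v_ph, v_ramp,
                   mask_idx, rec_idx, ph_freqs, ph_start, as.integer(order))

  phasor <- NULL
  if (length(ph_freqs)) {
    phasor <- lapply(seq_along(ph_freqs), function(m) {
      arr <- complex(real = res$phasor_re[[m]], imaginary = res$phasor_im[[m]])
      array(arr, dims)
    })
    names(phasor) <- paste0("h", harmonics)
  }
  list(phasor = phasor, rec = res$rec, dt = dt, steps_per_period = spp,
       nsteps = nsteps, maxp = res$maxp,
       p_final = array(res$p, dims), f = f, pml_layers = pml_layers)
}

#' Run a drive to steady state and return the phasor field
#'
#' Convenience wrapper over [simulate_acoustic()]: simulates `n_periods`
#' (default 60, which suffices for steady state in domains of a few tens of
#' wavelengths; longer runs change the field by < 0.1 %) and returns the
#' fundamental phasor.
#'
#' @inheritParams simulate_acoustic
#' @param ... Passed to [simulate_acoustic()].
#' @return List with `amplitude` and `phase` 3D arrays, the complex
#'   `phasor`, and the solver bookkeeping fields of [simulate_acoustic()].
#' @export
run_to_steady_state <- function(vol, f, n_periods = 60, ...) {
  res <- simulate_acoustic(vol, f, n_periods, ...)
  ph <- res$phasor[[1]]
  c(list(amplitude = Mod(ph), phase = Arg(ph), phasor = ph), res)
}

#' Quadrature demodulation of a receiver time series
#'
#' Projects `x(t)` onto `exp(-i 2 pi f t)` over `[t0, t1]` and returns the
#' complex amplitude `A exp(i phi)` such that
#' `x(t) ~ Re(A exp(i(2 pi f t + phi - pi/2)))` for a sinusoidal drive
#' (i.e. consistent with the solver's `sin` convention).
#'
#' @param x Numeric series sampled at `t = dt, 2 dt, ...`.
#' @param dt Sample interval, s.
#' @param f Frequency, Hz.
#' @param t0,t1 Window bounds, s (defaults: the final two periods).
#' @return A complex scalar.
#' @export
demodulate <- function(x, dt, f, t0 = NULL, t1 = NULL) {
  n <- length(x)
  tt <- (1:n) * dt
  if (is.null(t1)) t1 <- tt[n]
  if (is.null(t0)) t0 <- t1 - 2 / f
  # half-open window (t0, t1]: an integer number of periods contributes an
  # exact number of samples, which makes the projection of a pure tone exact
  sel <- tt > t0 + dt / 4 & tt <= t1 + dt / 4
  if (!any(sel)) stop("empty demodulation window")
  2 * mean(x[sel] * exp(-2i * pi * f * tt[sel]))
}

#' Inverse (time-reversal recording) propagation from a target point
#'
#' Places a continuously driven point source at the target, propagates for
#' `n_periods` periods (which must exceed the transit time to the farthest
#' element), and records the complex pressure phasor at the surface-center
#' voxel of every array element.
#'
#' @param vol Material volume (head phantom plus water).
#' @param target Target position, m (length 3).
#' @param array A [make_hemispherical_array()] transducer array.
#' @param f Frequency, Hz.
#' @param n_periods Simulated periods (default 60).
#' @param amplitude Source amplitude, Pa (arbitrary; corrections are
#'   normalized later).
#' @param snap_correction Phase-reference each captured phasor from the
#'   recording voxel center to the true element center (the two differ by
#'   up to half a voxel): the phase is advanced by `k (d_c - d_v)` with
#'   `d_c`, `d_v` the target distances of the element center and of the
#'   voxel, and `k` the water wavenumber (elements sit in water). Default
#'   TRUE.
#' @param c_ref Speed of sound used for the snap correction, m/s.
#' @param ... Passed to [simulate_acoustic()].
#' @return Object of class `captured_phasors`: complex vector, one entry
#'   per element, with attribute `target`.
#' @export
inverse_propagate <- function(vol, target, array, f, n_periods = 60,
                              amplitude = 1e3, snap_correction = TRUE,
                              c_ref = 1482.3, ...) {
  ti <- position_to_index(vol, target)
  ei <- position_to_index(vol, array$centers)
  if (any(ei < 1) || any(sweep(ei, 2, vol$dims, ">") ))
    stop("element center outside grid")
  src <- acoustic_sources(ti, amplitude = amplitude)
  res <- simulate_acoustic(vol, f, n_periods, sources = src, receivers = ei,
                           phasor_periods = 0, ...)
  caps <- vapply(seq_len(nrow(ei)), function(j)
    demodulate(res$rec[, j], res$dt, f), complex(1))
  if (snap_correction) {
    vpos <- cbind(vol$axes[[1]][ei[, 1]], vol$axes[[2]][ei[, 2]],
                  vol$axes[[3]][ei[, 3]])
    # distances from the actual (snapped) source voxel
    tpos <- c(vol$axes[[1]][ti[1]], vol$axes[[2]][ti[2]],
              vol$axes[[3]][ti[3]])
    d_c <- sqrt(rowSums(sweep(array$centers, 2, tpos)^2))
    d_v <- sqrt(rowSums(sweep(vpos, 2, tpos)^2))
    caps <- caps * exp(-1i * 2 * pi * f / c_ref * (d_c - d_v))
  }
  structure(caps, class = "captured_phasors", target = target, f = f)
}
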