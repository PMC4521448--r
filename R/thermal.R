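#' Relaxation-absorption heat source from a steady-state pressure field
#'
#' Time-averaged specific absorption rate deposited by a continuous sound
#' field of amplitude `p`: the volumetric heating of a plane wave is
#' `2 alpha I = a p^2 / (rho c)` (W/m^3), so the mass-specific source
#' entering the bioheat equation (which multiplies by `rho`) is
#' `S = a p^2 / (rho^2 c)` in W/kg.
#'
#' @param p Pressure amplitude, Pa (array or vector).
#' @param a Attenuation at the drive frequency, Np/m.
#' @param rho Density, kg/m^3 (> 0).
#' @param c Speed of sound, m/s (> 0).
#' @return Specific heat source `S`, W/kg, same shape as `p`.
#' @export
acoustic_heat_source <- function(p, a, rho, c) {
  if (any(rho <= 0) || any(c <= 0)) stop("rho and c must be positive")
  a * p^2 / (rho^2 * c)
}

#' Heat source field for a material volume
#'
#' Evaluates [acoustic_heat_source()] per voxel from a phasor amplitude
#' field and the volume's material properties at frequency `f`.
#'
#' @param vol Material volume.
#' @param amplitude Pressure amplitude array matching `vol$dims`, Pa.
#' @param f Frequency, Hz.
#' @return 3D array of `S`, W/kg.
#' @export
heat_source_from_phasor <- function(vol, amplitude, f) {
  flds <- material_fields(vol, f)
  S <- acoustic_heat_source(amplitude, flds$a, flds$rho, flds$c)
  S[flds$air_mask] <- 0
  S
}

#' Temperature-dependent perfusion multiplier (vascular shutdown)
#'
#' Perfusion is unaffected up to `shutdown_start`, decreases linearly to
#' zero between `shutdown_start` and `shutdown_end`, and ceases entirely
#' above `shutdown_end` (default 50 to 51 degC).
#'
#' @param T Temperature, degC (vectorized).
#' @param shutdown_start,shutdown_end Threshold temperatures, degC.
#' @return Multiplier in `[0, 1]`.
#' @export
perfusion_factor <- function(T, shutdown_start = 50, shutdown_end = 51) {
  stopifnot(shutdown_start < shutdown_end)
  pmin(1, pmax(0, (shutdown_end - T) / (shutdown_end - shutdown_start)))
}

#' Thermal boundary specification
#'
#' Declares how voxels of a given label behave thermally:
#' `"dirichlet"` pins them to `T_boundary`; `"convective"` removes them
#' from the conduction problem and imposes the mixed flux condition
#' `k dT/dn + h (T - T_outside) = F_boundary` on every interface with
#' adjacent tissue voxels; `"neumann"` is the `h = 0` special case (pure
#' imposed flux `k dT/dn = F_boundary`).
#'
#' @param label Integer label the spec applies to.
#' @param kind `"dirichlet"`, `"neumann"` or `"convective"`.
#' @param T_boundary Pinned temperature (dirichlet), degC.
#' @param h Heat-transfer coefficient, W/m^2/K (convective).
#' @param T_outside Ambient temperature, degC (convective).
#' @param F_boundary Imposed flux into the tissue, W/m^2.
#' @return Object of class `boundary_spec`.
#' @export
boundary_spec <- function(label, kind = c("dirichlet", "neumann",
                                          "convective"),
                          T_boundary = NULL, h = 0, T_outside = NULL,
                          F_boundary = 0) {
  kind <- match.arg(kind)
  stopifnot(h >= 0)
  if (kind == "dirichlet" && is.null(T_boundary))
    stop("dirichlet boundary needs T_boundary")
  if (kind == "convective" && (h > 0) && is.null(T_outside))
    stop("convective boundary needs T_outside")
  structure(list(label = as.integer(label), kind = kind,
                 T_boundary = T_boundary, h = h,
                 T_outside = T_outside %||% 0, F_boundary = F_boundary),
            class = "boundary_spec")
}

# per-voxel boundary arrays from a list of boundary_specs
.thermal_boundary_arrays <- function(vol, boundaries) {
  N <- prod(vol$dims)
  btype <- integer(N); bh <- numeric(N); bF <- numeric(N); bT <- numeric(N)
  for (b in boundaries) {
    sel <- which(as.integer(vol$labels) == b$label)
    if (!length(sel)) next
    if (b$kind == "dirichlet") {
      btype[sel] <- 1L
      bT[sel] <- b$T_boundary
    } else {
      btype[sel] <- 2L
      bh[sel] <- b$h
      bF[sel] <- b$F_boundary
      bT[sel] <- b$T_outside
    }
  }
  list(btype = btype, bh = bh, bF = bF, bT = bT)
}

#' Explicit-stability time step for the bioheat solver
#'
#' `dt = safety * min(rho C dmin^2 / (2 D k))` over conducting voxels, with
#' `D = 3` spatial dimensions.
#'
#' @param vol Material volume (with thermal media in its table).
#' @param safety Safety factor.
#' @return Time step, s.
#' @export
bioheat_timestep <- function(vol, safety = 0.9) {
  tf <- .thermal_fields(vol)
  dmin <- min(unlist(vol$widths))
  cond <- tf$k > 0
  if (!any(cond)) stop("no conducting voxels")
  safety * min(tf$rhoC[cond] * dmin^2 / (6 * tf$k[cond]))
}

# expand thermal per-voxel fields
.thermal_fields <- function(vol) {
  labs <- as.integer(vol$labels)
  ulab <- sort(unique(labs))
  key <- match(labs, ulab)
  g <- function(fun) vapply(ulab, function(l) {
    e <- vol$label_table[[as.character(l)]]
    if (is.null(e$thermal)) stop("label ", l, " has no thermal medium")
    fun(e$thermal)
  }, 0)[key]
  rho <- g(function(t) t$rho)
  list(rhoC = rho * g(function(t) t$C_heat),
       k = g(function(t) t$k_cond),
       rhoQ = rho * g(function(t) t$Q_met),
       rho = rho,
       omega_si = perfusion_to_si(g(function(t) t$omega)))
}

#' Advance the Pennes bioheat equation
#'
#' Explicit finite-difference integration of
#' `rho C dT/dt = div(k grad T) + rho Q + rho S - rho_b c_b rho omega (T - T_b)`
#' with harmonic-mean face conductivities, label-based boundary conditions
#' and optional linear vascular shutdown of the perfusion term between
#' `shutdown_start` and `shutdown_end`.
#'
#' @param vol Material volume (label table must carry thermal media).
#' @param T0 Initial temperature: scalar or array (`vol$dims`), degC.
#' @param S Specific acoustic heat source, W/kg: scalar 0 or array.
#' @param duration Integration time, s.
#' @param boundaries List of [boundary_spec()]s.
#' @param blood [blood_properties()].
#' @param shutdown Enable vascular shutdown.
#' @param shutdown_start,shutdown_end Shutdown thresholds, degC.
#' @param dt Time step, s (default [bioheat_timestep()]).
#' @param probes n x 3 voxel indices whose temperature is traced.
#' @param record_every Record trace every this many steps.
#' @return List: `T` final temperature array, `t` elapsed time, trace
#'   matrices `probes`/`maxT`/`t_trace`, and `dt`, `nsteps`.
#' @export
run_bioheat <- function(vol, T0 = 37, S = 0, duration,
                        boundaries = list(), blood = blood_properties(),
                        shutdown = FALSE, shutdown_start = 50,
                        shutdown_end = 51, dt = NULL, probes = NULL,
                        record_every = NULL) {
  tf <- .thermal_fields(vol)
  N <- prod(vol$dims)
  if (is.null(dt)) dt <- bioheat_timestep(vol)
  nsteps <- max(1L, as.integer(ceiling(duration / dt)))
  dt <- duration / nsteps
  ba <- .thermal_boundary_arrays(vol, boundaries)
  Tinit <- if (length(T0) == 1) rep(as.numeric(T0), N) else as.numeric(T0)
  fixed <- ba$btype != 0L
  Tinit[fixed] <- ba$bT[fixed]
  Svec <- if (length(S) == 1) rep(as.numeric(S), N) else as.numeric(S)
  volSrc <- tf$rhoQ + tf$rho * Svec
  perfC <- blood$rho_b * blood$c_b * tf$rho * tf$omega_si
  if (is.null(record_every))
    record_every <- max(1L, nsteps %/% 200L)
  probe_idx <- if (is.null(probes)) integer(0)
               else as.integer(.lin0(probes, vol$dims))
  res <- .bioheat_run(as.integer(vol$dims),
                      vol$axes[[1]], vol$axes[[2]], vol$axes[[3]],
                      tf$rhoC, tf$k, volSrc, perfC, blood$T_b,
                      ba$btype, ba$bh, ba$bF,
                      as.integer(shutdown), shutdown_start, shutdown_end,
                      Tinit, dt, nsteps, probe_idx,
                      as.integer(record_every))
  nr <- res$nrec
  list(T = array(res$T, vol$dims), t = nsteps * dt,
       probes = res$probes[seq_len(nr), , drop = FALSE],
       maxT = res$maxT[seq_len(nr)], t_trace = res$t[seq_len(nr)],
       dt = dt, nsteps = nsteps)
}

#' Two-phase treatment protocol: equilibration then sonication
#'
#' Reproduces the standard tcFUS thermal protocol: a long equilibration
#' without acoustic heating (default 30 min, by which time the water-bolus
#' cooling has reached steady state, typically within ~10 min), followed by
#' a short sonication (default 20 s) with the acoustic heat source on.
#'
#' @inheritParams run_bioheat
#' @param S Acoustic heat source during sonication, W/kg.
#' @param equilibration_s Length of the pre-sonication phase, s.
#' @param sonication_s Length of the sonication phase, s.
#' @param dt_equilibration,dt_sonication Optional separate time steps, s.
#' @return List with `equilibrium` and `sonicated` results (each as
#'   [run_bioheat()] output).
#' @export
run_treatment_protocol <- function(vol, S, T0 = 37,
                                   equilibration_s = 1800,
                                   sonication_s = 20,
                                   boundaries = list(),
                                   blood = blood_properties(),
                                   shutdown = FALSE,
                                   dt_equilibration = NULL,
                                   dt_sonication = NULL, ...) {
  eq <- run_bioheat(vol, T0 = T0, S = 0, duration = equilibration_s,
                    boundaries = boundaries, blood = blood,
                    shutdown = shutdown, dt = dt_equilibration, ...)
  son <- run_bioheat(vol, T0 = eq$T, S = S, duration = sonication_s,
                     boundaries = boundaries, blood = blood,
                     shutdown = shutdown, dt = dt_sonication, ...)
  list(equilibrium = eq, sonicated = son)
}
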