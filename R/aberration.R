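#' Distance-based phase corrections (DPC)
#'
#' Analytic phase corrections that ignore all heterogeneity: each element is
#' driven with phase `+2 pi f d_i / c_water (mod 2 pi)`, the compensating
#' delay that makes all arrivals cophasal at the target if the medium were
#' uniform water, with a fixed amplitude on every element.
#'
#' The drive-phase sign convention used throughout the package: the drive
#' phase is the negative of the propagation phase (a wave launched with
#' phase `+k d` arrives at distance `d` with zero phase).
#'
#' @param array A [make_hemispherical_array()].
#' @param target Target position, m.
#' @param p_element Per-element amplitude, Pa (e.g. from
#'   [element_surface_pressure()]).
#' @param c_water Speed of sound used for the correction, m/s.
#' @param f Frequency, Hz (default: the array's).
#' @return A [drive_vector()].
#' @export
dpc <- function(array, target, p_element, c_water = 1482.3,
                f = array$frequency) {
  d <- sqrt(rowSums(sweep(array$centers, 2, target)^2))
  phase <- (2 * pi * f * d / c_water) %% (2 * pi)
  drive_vector(rep(p_element, length(d)), phase)
}

#' Straight-ray skull traversal
#'
#' Marches the straight segment from each element's surface center to the
#' target through the label grid and accumulates the path length spent in
#' voxels carrying the bone label (no refraction; the ray model treats the
#' skull as a thin phase plate).
#'
#' @param array A `transducer_array`.
#' @param target Target position, m.
#' @param vol Material volume containing the skull.
#' @param bone_label Integer label of bone voxels (default: the label whose
#'   table entry is named "Bone").
#' @param step Sampling step along the ray, m (default: min spacing / 4).
#' @return Object of class `ray_trace`: data frame with per-element `total`
#'   and `bone` path lengths, m.
#' @export
trace_rays <- function(array, target, vol, bone_label = NULL, step = NULL) {
  if (is.null(bone_label)) {
    nm <- vapply(vol$label_table, function(e) e$name %||% "", "")
    bone_label <- as.integer(names(vol$label_table)[nm == "Bone"])
    if (length(bone_label) != 1)
      stop("bone label not identifiable from label table")
  }
  if (is.null(step)) step <- min(unlist(vol$widths)) / 4
  axes <- vol$axes
  n <- nrow(array$centers)
  total <- bone <- numeric(n)
  for (e in seq_len(n)) {
    a <- array$centers[e, ]
    d <- target - a
    L <- sqrt(sum(d^2))
    total[e] <- L
    ns <- max(2L, ceiling(L / step))
    tt <- (seq_len(ns) - 0.5) / ns
    pts <- outer(tt, d) + rep(a, each = ns)
    ii <- findInterval(pts[, 1], axes[[1]] - c(diff(axes[[1]])[1],
                                               diff(axes[[1]])) / 2,
                       all.inside = TRUE)
    jj <- findInterval(pts[, 2], axes[[2]] - c(diff(axes[[2]])[1],
                                               diff(axes[[2]])) / 2,
                       all.inside = TRUE)
    kk <- findInterval(pts[, 3], axes[[3]] - c(diff(axes[[3]])[1],
                                               diff(axes[[3]])) / 2,
                       all.inside = TRUE)
    labs <- vol$labels[cbind(ii, jj, kk)]
    bone[e] <- sum(labs == bone_label) * (L / ns)
  }
  structure(data.frame(element = seq_len(n), total = total, bone = bone),
            class = c("ray_trace", "data.frame"))
}

#' Ray-tracing-based phase corrections (RTPC)
#'
#' Extends [dpc()] with an effective-path correction: the portion `b_i` of
#' each element-target ray inside bone travels at the bone speed, so
#' `phase_i = 2 pi f ((d_i - b_i)/c_water + b_i/c_bone) (mod 2 pi)`.
#' Amplitudes stay fixed.
#'
#' @inheritParams dpc
#' @param vol Material volume with the skull.
#' @param c_bone Bone speed of sound, m/s (default: Bone table value).
#' @param rays Optional precomputed [trace_rays()] result.
#' @param ... Passed to [trace_rays()].
#' @return A [drive_vector()].
#' @export
rtpc <- function(array, target, vol, p_element, c_water = 1482.3,
                 c_bone = 3183, f = array$frequency, rays = NULL, ...) {
  if (is.null(rays)) rays <- trace_rays(array, target, vol, ...)
  phase <- (2 * pi * f * ((rays$total - rays$bone) / c_water +
                            rays$bone / c_bone)) %% (2 * pi)
  drive_vector(rep(p_element, nrow(rays)), phase)
}

#' Simulation-based phase corrections (SPC, time reversal)
#'
#' Conjugates the phases of the pressure phasors captured during the
#' inverse propagation from the target ([inverse_propagate()]) and fixes
#' all amplitudes to `p_element`. Elements whose captured amplitude is
#' below `min_amp_frac` of the maximum carry no usable phase information
#' (no line of sight) and are deactivated with a warning.
#'
#' @param captured Complex captured phasors (class `captured_phasors`).
#' @param p_element Fixed amplitude, Pa.
#' @param min_amp_frac Deactivation threshold relative to the maximum
#'   captured amplitude.
#' @return A [drive_vector()].
#' @export
spc <- function(captured, p_element, min_amp_frac = 1e-6) {
  amps <- Mod(captured)
  if (all(amps == 0)) stop("all captured amplitudes are zero")
  dead <- amps < min_amp_frac * max(amps)
  if (any(dead))
    warning(sum(dead), " element(s) deactivated (no captured signal)")
  phase <- ifelse(dead, 0, -Arg(captured)) %% (2 * pi)
  drive_vector(ifelse(dead, 0, p_element), phase, active = !dead)
}

#' Simulation-based phase and amplitude corrections (SPAC)
#'
#' As [spc()], but the captured amplitudes are retained and normalized to
#' the given acoustic input power: `amplitude_i = f_norm |p_captured_i|`
#' with `f_norm = sqrt(N p_element^2 / sum |p_captured|^2)` over active
#' elements, so that `sum amplitude_i^2 = N p_element^2` exactly.
#'
#' @inheritParams spc
#' @param P_total Total acoustic power, W; `p_element` is derived via
#'   [element_surface_pressure()] unless given directly.
#' @param N_elements,A_element,Z_water Passed to
#'   [element_surface_pressure()] when `P_total` is used.
#' @param p_element Alternative to `P_total`: the per-element reference
#'   amplitude, Pa.
#' @return A [drive_vector()] with attribute `f_norm`.
#' @export
spac <- function(captured, P_total = NULL, p_element = NULL,
                 N_elements = length(captured), A_element = 1e-4,
                 Z_water = 1.4823e6, min_amp_frac = 1e-6) {
  amps <- Mod(captured)
  if (all(amps == 0)) stop("all captured amplitudes are zero")
  dead <- amps < min_amp_frac * max(amps)
  n_act <- sum(!dead)
  if (is.null(p_element)) {
    if (is.null(P_total)) stop("give P_total or p_element")
    p_element <- element_surface_pressure(P_total, n_act, A_element, Z_water)
  }
  f_norm <- sqrt(n_act * p_element^2 / sum(amps[!dead]^2))
  amp <- ifelse(dead, 0, f_norm * amps)
  phase <- ifelse(dead, 0, -Arg(captured)) %% (2 * pi)
  out <- drive_vector(amp, phase, active = !dead)
  attr(out, "f_norm") <- f_norm
  out
}

#' Compute a drive vector by any of the four correction strategies
#'
#' One-call dispatcher used by the scenario runner: `"dpc"` and `"rtpc"`
#' are analytic/semi-analytic (no inverse simulation needed); `"spc"` and
#' `"spac"` require captured phasors.
#'
#' @param strategy `"dpc"`, `"rtpc"`, `"spc"` or `"spac"`.
#' @param array Transducer array.
#' @param target Target, m.
#' @param vol Material volume.
#' @param p_element Element amplitude, Pa.
#' @param captured Captured phasors (required for spc/spac).
#' @param c_water,f See [dpc()].
#' @param ... Extra arguments for the strategy function.
#' @return A [drive_vector()].
#' @export
aberration_correction <- function(strategy = c("dpc", "rtpc", "spc", "spac"),
                                  array, target, vol, p_element,
                                  captured = NULL, c_water = 1482.3,
                                  f = array$frequency, ...) {
  strategy <- match.arg(strategy)
  switch(strategy,
    dpc = dpc(array, target, p_element, c_water, f),
    rtpc = rtpc(array, target, vol, p_element, c_water, f = f, ...),
    spc = {
      if (is.null(captured)) stop("spc requires captured phasors")
      spc(captured, p_element, ...)
    },
    spac = {
      if (is.null(captured)) stop("spac requires captured phasors")
      spac(captured, p_element = p_element, ...)
    })
}
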