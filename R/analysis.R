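#' Analytic plane-wave reflection and transmission coefficients
#'
#' Pressure-amplitude coefficients at a planar interface between two fluid
#' media, from the characteristic impedances `Z = rho c` and the incidence/
#' transmission angles:
#' `R = (Z2 cos(ti) - Z1 cos(tt)) / (Z2 cos(ti) + Z1 cos(tt))`,
#' `T = 2 Z2 cos(ti) / (Z2 cos(ti) + Z1 cos(tt))`, with the transmission
#' angle from Snell's law. Beyond the critical angle the transmitted wave is
#' evanescent and the pair is flagged.
#'
#' @param mediumA,mediumB [acoustic_medium()] objects (incident wave travels
#'   in A).
#' @param theta_i Incidence angle, degrees, in `[0, 90)`.
#' @return List of class `coefficient_pair`: `R`, `T`, `theta_t` (degrees),
#'   `evanescent` flag.
#' @export
analytic_coefficients <- function(mediumA, mediumB, theta_i) {
  stopifnot(theta_i >= 0, theta_i < 90)
  Z1 <- mediumA$rho * mediumA$c
  Z2 <- mediumB$rho * mediumB$c
  s <- mediumB$c / mediumA$c * sin(theta_i * pi / 180)
  if (s >= 1) {
    return(structure(list(R = NA_real_, T = NA_real_, theta_t = NA_real_,
                          evanescent = TRUE), class = "coefficient_pair"))
  }
  theta_t <- asin(s)
  ci <- cos(theta_i * pi / 180); ct <- cos(theta_t)
  R <- (Z2 * ci - Z1 * ct) / (Z2 * ci + Z1 * ct)
  T <- 2 * Z2 * ci / (Z2 * ci + Z1 * ct)
  structure(list(R = R, T = T, theta_t = theta_t * 180 / pi,
                 evanescent = FALSE), class = "coefficient_pair")
}

#' Snell transmission angle
#'
#' @param cA,cB Speeds of sound in the incident and transmitting medium, m/s.
#' @param theta_i Incidence angle, degrees.
#' @return Transmission angle, degrees; `NA` beyond the critical angle.
#' @export
snell_angle <- function(cA, cB, theta_i) {
  s <- cB / cA * sin(theta_i * pi / 180)
  ifelse(s < 1, asin(s) * 180 / pi, NA_real_)
}

#' Measured reflection and transmission coefficients from complex amplitudes
#'
#' Forms `R = |p_r|/|p_i|` and `T = |p_t|/|p_i|` from demodulated complex
#' wave amplitudes; the sign of `R` is taken from the phase of `p_r/p_i`
#' after removing the known propagation phase `phase_offset` (a residual
#' beyond pi/2 in magnitude marks a pi flip, i.e. a negative reflection
#' coefficient).
#'
#' @param p_i,p_r,p_t Complex amplitudes of the incident, reflected and
#'   transmitted waves (e.g. from [demodulate()] over non-overlapping time
#'   windows).
#' @param phase_offset Propagation phase (rad) accumulated by the reflected
#'   wave relative to the incident at the measurement point.
#' @return List of class `coefficient_pair` with signed `R`, `T`.
#' @export
measure_coefficients <- function(p_i, p_r, p_t, phase_offset = 0) {
  if (Mod(p_i) == 0) stop("zero incident amplitude")
  R <- Mod(p_r) / Mod(p_i)
  T <- Mod(p_t) / Mod(p_i)
  resid <- Arg(p_r / p_i * exp(1i * phase_offset))
  if (abs(resid) > pi / 2) R <- -R
  structure(list(R = R, T = T, theta_t = NA_real_, evanescent = FALSE),
            class = "coefficient_pair")
}

#' Normalized standard deviation between two pressure profiles
#'
#' `100 * l2(|p_test| - |p_ref|) / l2(|p_ref|)`, the percent l2-relative
#' deviation used to score solver agreement along a line or over a field.
#'
#' @param p_test,p_ref Numeric or complex vectors/arrays at identical
#'   sampling locations.
#' @return Percent deviation (scalar).
#' @export
nsd <- function(p_test, p_ref) {
  if (length(p_test) != length(p_ref))
    stop("profiles must share sampling locations")
  nref <- sqrt(sum(Mod(p_ref)^2))
  if (nref == 0) stop("zero reference norm")
  100 * sqrt(sum((Mod(p_test) - Mod(p_ref))^2)) / nref
}

#' On-axis pressure reference for baffled pistons
#'
#' Analytic/semi-analytic steady-state pressure magnitude on the axis of a
#' uniformly vibrating piston in a rigid baffle radiating into a homogeneous
#' (optionally attenuating) medium with surface pressure amplitude
#' `p0 = rho c u0`.
#'
#' Circular and ring apertures use the exact axial integral
#' `p(z) = i k p0 / (alpha + i k) * (exp(-(alpha + i k) R_in) -
#' exp(-(alpha + i k) R_out))` with `R = sqrt(z^2 + r^2)` evaluated at the
#' aperture radii (which reduces to the classical
#' `2 p0 |sin(k(sqrt(z^2+a^2)-z)/2)|` for a lossless disc); rectangular
#' apertures integrate the attenuated Rayleigh-Sommerfeld kernel
#' numerically over the aperture.
#'
#' @param z Axial distances from the baffle, m (vector).
#' @param f Frequency, Hz.
#' @param medium An [acoustic_medium()] (its `c`, `rho` are used).
#' @param p0 Surface pressure amplitude `rho c u0`, Pa.
#' @param kind `"circular"`, `"rectangular"` or `"ring"`.
#' @param dims Aperture dimensions, m: circular `a`; rectangular
#'   `c(Lx, Ly)`; ring `c(r_in, r_out)`.
#' @param alpha Attenuation of the medium, Np/m.
#' @param n_quad Per-side quadrature points for the rectangular aperture.
#' @return Pressure magnitude at each `z`, Pa.
#' @export
on_axis_piston_reference <- function(z, f, medium, p0,
                                     kind = c("circular", "rectangular",
                                              "ring"),
                                     dims, alpha = 0, n_quad = 400) {
  kind <- match.arg(kind)
  c0 <- medium$c
  k <- 2 * pi * f / c0
  g <- complex(real = alpha, imaginary = k)
  axial_annulus <- function(r_in, r_out) {
    Rin <- sqrt(z^2 + r_in^2)
    Rout <- sqrt(z^2 + r_out^2)
    Mod(1i * k * p0 / g * (exp(-g * Rin) - exp(-g * Rout)))
  }
  switch(kind,
    circular = {
      stopifnot(length(dims) >= 1, dims[1] > 0)
      axial_annulus(abs(z) * 0, dims[1]) # inner radius 0 -> R_in = z
    },
    ring = {
      stopifnot(length(dims) == 2, dims[1] >= 0, dims[2] > dims[1])
      axial_annulus(dims[1], dims[2])
    },
    rectangular = {
      stopifnot(length(dims) == 2, all(dims > 0))
      hx <- dims[1] / 2; hy <- dims[2] / 2
      xq <- (seq_len(n_quad) - 0.5) / n_quad * dims[1] - hx
      yq <- (seq_len(n_quad) - 0.5) / n_quad * dims[2] - hy
      dA <- (dims[1] / n_quad) * (dims[2] / n_quad)
      r2 <- outer(xq^2, yq^2, "+")
      vapply(z, function(zz) {
        Rm <- sqrt(zz^2 + r2)
        Mod(1i * k * p0 / (2 * pi) * sum(exp(-g * Rm) / Rm) * dA)
      }, 0)
    })
}

#' Rayleigh-Sommerfeld field of an arbitrary baffled aperture
#'
#' Numeric surface integral `p(r) = i k p0/(2 pi) sum exp(-g R)/R dA` over
#' aperture sample points; used as an independent oracle for off-axis or
#' non-canonical apertures.
#'
#' @param pts Observation points, n x 3 matrix (aperture in plane z = 0), m.
#' @param src_xy Aperture sample points, m x 2 matrix.
#' @param src_w Quadrature weight (area) per sample, m^2.
#' @param f Frequency, Hz.
#' @param medium [acoustic_medium()].
#' @param p0 Surface pressure amplitude, Pa.
#' @param alpha Attenuation, Np/m.
#' @return Complex pressure at each observation point.
#' @export
rayleigh_field <- function(pts, src_xy, src_w, f, medium, p0, alpha = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  k <- 2 * pi * f / medium$c
  g <- complex(real = alpha, imaginary = k)
  w <- rep_len(src_w, nrow(src_xy))
  vapply(seq_len(nrow(pts)), function(i) {
    R <- sqrt((pts[i, 1] - src_xy[, 1])^2 + (pts[i, 2] - src_xy[, 2])^2 +
                pts[i, 3]^2)
    1i * k * p0 / (2 * pi) * sum(exp(-g * R) / R * w)
  }, complex(1))
}

#' Focal-region metrics by nearest-maximum connected-component analysis
#'
#' Mirrors the standard focal/lesion analysis of simulated fields: the field
#' is smoothed with a small box filter, local maxima are located, the
#' maximum nearest the intended target is selected, the field is thresholded
#' at `threshold_frac` of that peak, and the 26-connected component
#' containing the peak is measured.
#'
#' @param field Non-negative 3D array (pressure amplitude, Pa, or
#'   temperature rise, degC).
#' @param axes List of three axis coordinate vectors, m (e.g.
#'   `vol$axes`), or a `material_volume` whose axes are used.
#' @param target Target position, m (length 3).
#' @param threshold_frac Threshold as a fraction of the selected peak
#'   (default 0.5, i.e. FWHM).
#' @param filter_width Box-filter width in voxels used before maxima
#'   detection (default 3; 0 disables smoothing).
#' @return List of class `focal_metrics`: `D` distance target to component
#'   centroid (m); `D_peak` distance target to peak voxel (m); `peak` the
#'   (unsmoothed) field value at the peak voxel; `peak_index` (i,j,k);
#'   `fwhm` per-axis bounding extents of the component (m); `F_shape`
#'   max/min extent ratio; `V` component volume (m^3); `n_voxels`.
#' @export
focal_metrics <- function(field, axes, target, threshold_frac = 0.5,
                          filter_width = 3) {
  if (inherits(axes, "material_volume")) axes <- axes$axes
  dims <- dim(field)
  if (any(!is.finite(field))) stop("field contains non-finite values")
  if (all(field == 0)) stop("empty field")
  sm <- if (filter_width > 1)
    .boxfilter3d(as.numeric(field), as.integer(dims), as.integer(filter_width))
  else array(as.numeric(field), dims)

  # local maxima of the smoothed field (26-neighborhood, interior voxels)
  mx <- array(TRUE, dims)
  for (d in 1:3) for (s in c(-1, 1)) {
    shifted <- .shift3(sm, d, s)
    mx <- mx & (sm >= shifted)
  }
  # strictly require >= all 26 neighbors: check the 6-face shifts above plus
  # diagonal shifts via a dilation comparison
  dil <- .boxmax3(sm)
  mx <- mx & (sm >= dil - .Machine$double.eps * (abs(dil) + 1))
  mx[sm <= 0] <- FALSE
  cand <- which(mx, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no local maxima found")
  pos <- cbind(axes[[1]][cand[, 1]], axes[[2]][cand[, 2]], axes[[3]][cand[, 3]])
  d2 <- colSums((t(pos) - target)^2)
  # nearest local maximum to the intended target
  pk <- cand[which.min(d2), , drop = FALSE]
  peak_sm <- sm[pk]
  thr <- threshold_frac * peak_sm
  lab <- .label_components26(as.vector(sm >= thr), as.integer(dims))
  comp <- lab[pk]
  inb <- which(lab == comp, arr.ind = TRUE)
  widths <- lapply(1:3, function(d) {
    ax <- axes[[d]]
    if (length(ax) > 1) c(diff(ax)[1], diff(ax)) else 1
  })
  fwhm <- vapply(1:3, function(d) {
    rng <- range(inb[, d])
    sum(widths[[d]][rng[1]:rng[2]])
  }, 0)
  vvol <- widths[[1]][inb[, 1]] * widths[[2]][inb[, 2]] * widths[[3]][inb[, 3]]
  centroid <- vapply(1:3, function(d)
    sum(axes[[d]][inb[, d]] * vvol) / sum(vvol), 0)
  peak_pos <- c(axes[[1]][pk[1]], axes[[2]][pk[2]], axes[[3]][pk[3]])
  structure(list(
    D = sqrt(sum((centroid - target)^2)),
    D_peak = sqrt(sum((peak_pos - target)^2)),
    peak = field[pk], peak_index = as.integer(pk),
    fwhm = fwhm, F_shape = max(fwhm) / min(fwhm),
    V = sum(vvol), n_voxels = nrow(inb), centroid = centroid),
    class = "focal_metrics")
}

#' @export
print.focal_metrics <- function(x, ...) {
  cat(sprintf(
    "focal_metrics: D = %.2f mm (peak %.2f mm), peak = %.4g,\n  FWHM = %s mm, F_shape = %.2f, V = %.1f mm^3 (%d voxels)\n",
    x$D * 1e3, x$D_peak * 1e3, x$peak,
    paste(sprintf("%.2f", x$fwhm * 1e3), collapse = " x "),
    x$F_shape, x$V * 1e9, x$n_voxels))
  invisible(x)
}

# shift array along dim d by s voxels with replicate padding
.shift3 <- function(a, d, s) {
  n <- dim(a)[d]
  idx <- pmin(pmax(seq_len(n) + s, 1), n)
  switch(d, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# 3x3x3 neighborhood maximum (for local-maximum detection)
.boxmax3 <- function(a) {
  out <- a
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- pmax(out, .shift3(.shift3(.shift3(a, 1, dx), 2, dy), 3, dz))
  }
  out
}
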