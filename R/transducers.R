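#' Hemispherical phased-array transducer
#'
#' Idealized large-aperture hemispherical array: elements are laid out
#' quasi-uniformly over the lower hemisphere of a sphere by golden-angle
#' (Fibonacci) spiral placement, each modelled as a flat circular piston
#' tangent to the sphere with its normal pointing at the geometric focus
#' (the sphere center). The clinical-scale default is 1024 elements of
#' 1 cm^2 on a 30 cm diameter sphere at 230 kHz.
#'
#' @param n_elements Number of elements.
#' @param diameter Sphere diameter, m.
#' @param element_area Element surface area, m^2.
#' @param f Operating frequency, Hz.
#' @param center Geometric focus (sphere center), m.
#' @param cap_fraction Fraction of the full sphere covered, measured from
#'   the lower pole (0.5 = full hemisphere).
#' @return Object of class `transducer_array`: `centers` (n x 3),
#'   `normals` (unit, toward focus), `areas`, `element_radius`,
#'   `geometric_focus`, `radius`, `frequency`.
#' @export
make_hemispherical_array <- function(n_elements = 1024, diameter = 0.30,
                                     element_area = 1e-4, f = 230e3,
                                     center = c(0, 0, 0),
                                     cap_fraction = 0.5) {
  stopifnot(n_elements >= 1, diameter > 0, element_area > 0,
            cap_fraction > 0, cap_fraction <= 0.5)
  R <- diameter / 2
  r_el <- sqrt(element_area / pi)
  cap_area <- 4 * pi * R^2 * cap_fraction
  if (n_elements * element_area > 0.91 * cap_area)
    stop("infeasible packing: element area exceeds ~91% of cap area")
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_elements)
  # uniform area coverage of the cap z/R in [-1, -1 + 2*cap_fraction),
  # with a pole-repelling offset that improves the worst-pair spacing of
  # the spiral lattice
  eps <- 1.5
  zf <- -1 + (k - 0.5 + eps / 2) / (n_elements + eps) * 2 * cap_fraction
  phi <- k * golden
  rho <- sqrt(pmax(0, 1 - zf^2))
  centers <- cbind(R * rho * cos(phi), R * rho * sin(phi), R * zf)
  centers <- sweep(centers, 2, center, "+")
  normals <- -sweep(centers, 2, center, "-") / R
  structure(list(centers = centers, normals = normals,
                 areas = rep(element_area, n_elements),
                 element_radius = r_el, geometric_focus = center,
                 radius = R, frequency = f, n_elements = n_elements),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf(
    "transducer_array: %d elements, radius %.3g m, element area %.3g cm^2, f = %.3g kHz\n",
    x$n_elements, x$radius, mean(x$areas) * 1e4, x$frequency / 1e3))
  invisible(x)
}

#' Average element surface pressure for a given acoustic input power
#'
#' `p_element = sqrt(P_total Z_water / (N_elements A_element))`: the uniform
#' per-element surface pressure that radiates a total plane-wave acoustic
#' power `P_total` from `N_elements` emitting faces of area `A_element`
#' into water.
#'
#' @param P_total Total acoustic input power, W (>= 0).
#' @param N_elements Number of active elements (> 0).
#' @param A_element Element surface area, m^2 (> 0).
#' @param Z_water Characteristic impedance of water, kg/m^2/s
#'   (default 1.4823e6, i.e. rho = 1000 kg/m^3, c = 1482.3 m/s).
#' @return Element surface pressure amplitude, Pa.
#' @examples
#' element_surface_pressure(1000, 1024, 1e-4)  # ~120.31 kPa
#' @export
element_surface_pressure <- function(P_total, N_elements, A_element,
                                     Z_water = 1.4823e6) {
  stopifnot(P_total >= 0, N_elements > 0, A_element > 0, Z_water > 0)
  sqrt(P_total * Z_water / (N_elements * A_element))
}

#' Map array elements onto grid voxels
#'
#' Each element face (a disc tangent to the array sphere) is rasterized to
#' the grid voxels nearest to it: voxels whose center lies within the disc
#' radius laterally and within half a voxel of the disc plane (a band of
#' thickness one voxel, which makes the rasterized voxel count area-exact
#' regardless of tilt). Conflicting claims are resolved to the nearest
#' element so the per-element voxel sets are disjoint.
#'
#' @param array A [make_hemispherical_array()].
#' @param vol The simulation [build_material_volume()].
#' @return List of class `element_voxels`: `index` per element (list of
#'   1-based n x 3 matrices), `center_index` (n x 3, nearest voxel to each
#'   element center), `n_voxels` per element.
#' @export
voxelize_elements <- function(array, vol) {
  dims <- vol$dims
  axes <- vol$axes
  dmax <- max(vapply(vol$widths, max, 0))
  # +-half a voxel around the element plane: a band of thickness one voxel
  # makes the rasterized voxel count area-exact regardless of tilt
  half_diag <- 0.5 * dmax
  r_el <- array$element_radius
  n <- nrow(array$centers)
  owner <- integer(0); ownd <- numeric(0); ownq <- integer(0)
  per_el <- vector("list", n)
  for (e in seq_len(n)) {
    ctr <- array$centers[e, ]
    nrm <- array$normals[e, ]
    rng <- lapply(1:3, function(d) {
      which(abs(axes[[d]] - ctr[d]) <= r_el + dmax)
    })
    if (any(vapply(rng, length, 1L) == 0))
      stop("element ", e, " outside grid")
    gg <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    pos <- cbind(axes[[1]][gg[, 1]], axes[[2]][gg[, 2]], axes[[3]][gg[, 3]])
    rel <- sweep(pos, 2, ctr)
    dperp <- abs(rel %*% nrm)
    dlat2 <- rowSums(rel^2) - dperp^2
    keep <- dperp <= half_diag & dlat2 <= r_el^2
    if (!any(keep)) stop("element ", e, " rasterized to zero voxels")
    gk <- gg[keep, , drop = FALSE]
    q <- .lin0(gk, dims)
    d2 <- rowSums(sweep(pos[keep, , drop = FALSE], 2, ctr)^2)
    per_el[[e]] <- gk
    owner <- c(owner, rep(e, nrow(gk)))
    ownd <- c(ownd, d2)
    ownq <- c(ownq, q)
  }
  # resolve conflicts: nearest element keeps the voxel
  ord <- order(ownq, ownd)
  dup <- duplicated(ownq[ord])
  drop_rows <- ord[dup]
  if (length(drop_rows)) {
    keep_mask <- rep(TRUE, length(ownq))
    keep_mask[drop_rows] <- FALSE
    per_el <- lapply(seq_len(n), function(e) {
      sel <- owner == e & keep_mask
      m <- matrix(0L, sum(sel), 3)
      qq <- ownq[sel]
      m[, 1] <- qq %% dims[1] + 1L
      m[, 2] <- (qq %/% dims[1]) %% dims[2] + 1L
      m[, 3] <- qq %/% (dims[1] * dims[2]) + 1L
      m
    })
  }
  nv <- vapply(per_el, nrow, 1L)
  if (any(nv == 0)) stop("element(s) lost all voxels to neighbors: ",
                         paste(which(nv == 0), collapse = ", "))
  structure(list(index = per_el, n_voxels = nv,
                 center_index = position_to_index(vol, array$centers)),
            class = "element_voxels")
}

#' Assemble forward-drive sources from a drive vector
#'
#' Converts per-element amplitudes/phases into per-voxel soft sources on
#' the rasterized element faces. Per-voxel amplitudes are scaled by
#' `A_element / n_voxels` (relative to the mean voxel count) so that each
#' element injects energy in proportion to its drive amplitude regardless
#' of rasterization granularity.
#'
#' @param drive A [drive_vector()].
#' @param voxels A [voxelize_elements()] mapping.
#' @return An [acoustic_sources()] object (soft, continuous with ramp).
#' @export
drive_sources <- function(drive, voxels) {
  n <- length(drive$amplitude)
  stopifnot(n == length(voxels$index))
  act <- which(drive$active & drive$amplitude > 0)
  idx <- do.call(rbind, voxels$index[act])
  nv <- voxels$n_voxels[act]
  amp <- rep(drive$amplitude[act] * mean(voxels$n_voxels) / nv, nv)
  ph <- rep(drive$phase[act], nv)
  acoustic_sources(idx, amplitude = amp, phase = ph, type = "soft")
}

#' Per-element drive state
#'
#' @param amplitude Per-element pressure amplitudes, Pa (>= 0).
#' @param phase Per-element phases, rad.
#' @param active Logical mask of driven elements.
#' @return Object of class `drive_vector`.
#' @export
drive_vector <- function(amplitude, phase, active = NULL) {
  n <- length(amplitude)
  stopifnot(length(phase) == n, all(amplitude >= 0))
  if (is.null(active)) active <- rep(TRUE, n)
  structure(list(amplitude = amplitude, phase = phase, active = active),
            class = "drive_vector")
}

#' Write / read drive vectors as CSV
#'
#' @param drive A [drive_vector()].
#' @param path CSV path (columns element, amplitude_Pa, phase_rad, active).
#' @return The path (write) or a `drive_vector` (read).
#' @export
write_drive_vector <- function(drive, path) {
  df <- data.frame(element = seq_along(drive$amplitude),
                   amplitude_Pa = drive$amplitude,
                   phase_rad = drive$phase, active = drive$active)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drive_vector
#' @export
read_drive_vector <- function(path) {
  df <- read.csv(path)
  drive_vector(df$amplitude_Pa, df$phase_rad, as.logical(df$active))
}

#' Write / read array geometry as JSON
#'
#' @param array A `transducer_array`.
#' @param path JSON path.
#' @return The path (write) or a `transducer_array` (read).
#' @export
write_array_json <- function(array, path) {
  jsonlite::write_json(
    list(centers = array$centers, normals = array$normals,
         areas = array$areas, geometric_focus = array$geometric_focus,
         radius = array$radius, frequency = array$frequency),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_array_json
#' @export
read_array_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = j$centers, normals = j$normals, areas = j$areas,
                 element_radius = sqrt(mean(j$areas) / pi),
                 geometric_focus = j$geometric_focus, radius = j$radius,
                 frequency = j$frequency, n_elements = nrow(j$centers)),
            class = "transducer_array")
}
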