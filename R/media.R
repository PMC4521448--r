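#' Acoustic medium definition
#'
#' Bundles the acoustic constants of a (fluid-approximated) material: speed
#' of sound, density, attenuation slope, and optionally the nonlinearity
#' parameter B/A and the absorption coefficient used to derive the sound
#' diffusivity of the nonlinear solver.
#'
#' @param c Speed of sound, m/s. Must be > 0.
#' @param rho Density, kg/m^3. Must be > 0.
#' @param a_per_f Attenuation coefficient slope, Np/m/MHz (>= 0). The
#'   attenuation at frequency `f` Hz is `a_per_f * f / 1e6` Np/m.
#' @param BoverA Nonlinearity parameter B/A (dimensionless), or `NULL`.
#' @param alpha_abs Absorption coefficient used for the diffusivity term of
#'   the nonlinear solver, Np/m, or `NULL` (then `a_per_f` is used).
#' @return An object of class `acoustic_medium`.
#' @export
acoustic_medium <- function(c, rho, a_per_f = 0, BoverA = NULL,
                            alpha_abs = NULL) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0,
            is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(a_per_f), length(a_per_f) == 1L, a_per_f >= 0)
  structure(list(c = c, rho = rho, a_per_f = a_per_f,
                 BoverA = BoverA, alpha_abs = alpha_abs),
            class = "acoustic_medium")
}

#' Thermal medium definition
#'
#' @param C_heat Specific heat capacity, J/kg/K.
#' @param k_cond Thermal conductivity, W/m/K.
#' @param Q_met Metabolic heat generation rate, W/kg.
#' @param omega Blood perfusion rate in ml/min/kg (clinical convention);
#'   converted internally with [perfusion_to_si()] to m^3/kg/s as required
#'   by the bioheat sink term `rho_b c_b rho omega (T - T_b)`.
#' @param rho Density, kg/m^3.
#' @return An object of class `thermal_medium`.
#' @export
thermal_medium <- function(C_heat, k_cond, Q_met = 0, omega = 0, rho = 1000) {
  stopifnot(C_heat >= 0, k_cond >= 0, Q_met >= 0, omega >= 0, rho > 0)
  structure(list(C_heat = C_heat, k_cond = k_cond, Q_met = Q_met,
                 omega = omega, rho = rho),
            class = "thermal_medium")
}

#' Blood properties for the Pennes perfusion sink
#'
#' @param rho_b Blood density, kg/m^3.
#' @param c_b Blood specific heat capacity, J/kg/K.
#' @param T_b Arterial blood temperature, deg C.
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(rho_b = 1050, c_b = 3617, T_b = 37) {
  stopifnot(rho_b > 0, c_b > 0)
  structure(list(rho_b = rho_b, c_b = c_b, T_b = T_b),
            class = "blood_properties")
}

#' Convert a perfusion rate from ml/min/kg to the SI form of the bioheat sink
#'
#' The sink term `rho_b c_b rho omega (T - T_b)` (W/m^3) requires omega in
#' m^3 of blood per kg of tissue per second; 1 ml/min/kg = 1e-6/60 m^3/kg/s.
#'
#' @param omega_ml_min_kg Perfusion in ml/min/kg.
#' @return Perfusion in m^3/kg/s.
#' @export
perfusion_to_si <- function(omega_ml_min_kg) omega_ml_min_kg * 1e-6 / 60

#' Attenuation coefficient of a medium at a given frequency
#'
#' @param medium An [acoustic_medium()].
#' @param f Frequency, Hz.
#' @return Attenuation, Np/m.
#' @export
attenuation_at <- function(medium, f) medium$a_per_f * f / 1e6

# Soft-tissue densities are not part of the acoustic table; they follow the
# IT'IS tissue-properties database (rounded), as is conventional in
# therapeutic-ultrasound modelling.  Thermal constants likewise.  Only the
# water values (c = 1482.3 m/s, rho = 1000 kg/m^3, so Z = 1.4823 MRayl) are
# load-bearing for quantitative results in this package.
.tissue_data <- list(
  #                 c [m/s]  a/f [Np/m/MHz]  rho    C      k      Q      w[ml/min/kg]
  "Air"                 = c(343,     0.04,    1.2, 1004, 0.026,  0,     0),
  "Blood"               = c(1575,    1.7,  1050,   3617, 0.52,   0,     0),
  "Bone"                = c(3183,  164,   1908,    1313, 0.32,   0.15, 10),
  "Brain"               = c(1565,    8.6, 1046,    3630, 0.51,  11.4, 559),
  "Eye (lens)"          = c(1647,    9,   1076,    3133, 0.43,   0,     0),
  "Eye (aqueous humor)" = c(1537,    6,   1003,    4035, 0.58,   0,     0),
  "Eye (vitreous humor)"= c(1532,    5,   1005,    4047, 0.59,   0,     0),
  "Fat"                 = c(1478,    7,    911,    2348, 0.21,   0.51, 33),
  "Muscle"              = c(1581,   11,   1090,    3421, 0.49,   0.91, 37),
  "Skin"                = c(1720,   19.7, 1109,    3391, 0.37,   1.65,106),
  "Tendon"              = c(1750,   43,   1142,    3432, 0.47,   0.07,  6),
  "Water"               = c(1482.3,  0.025, 1000,  4178, 0.60,   0,     0)
)

#' Reference tissue property table
#'
#' Fixed per-tissue acoustic (speed of sound, attenuation slope) and thermal
#' (heat capacity, conductivity, metabolic rate, perfusion) properties for
#' the tissues used in transcranial FUS modelling, plus water and air.
#' Densities and thermal constants follow the IT'IS database convention;
#' they can be overridden per entry.  Water is assigned B/A = 5.0 by default
#' so the nonlinear solver can be exercised; other tissues have no B/A
#' unless supplied.
#'
#' @param tissues Character vector of tissue names to include (default all).
#' @param water_BoverA B/A assigned to water (default 5.0).
#' @return Named list; each entry has elements `acoustic`
#'   ([acoustic_medium()]) and `thermal` ([thermal_medium()]).
#' @examples
#' tab <- tissue_table()
#' tab$Brain$acoustic$c        # 1565
#' attenuation_at(tab$Bone$acoustic, 0.23e6)   # 164 * 0.23 Np/m
#' @export
tissue_table <- function(tissues = names(.tissue_data), water_BoverA = 5.0) {
  unknown <- setdiff(tissues, names(.tissue_data))
  if (length(unknown))
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "))
  out <- lapply(tissues, function(nm) {
    v <- .tissue_data[[nm]]
    ba <- if (nm == "Water") water_BoverA else NULL
    list(acoustic = acoustic_medium(c = v[1], rho = v[3], a_per_f = v[2],
                                    BoverA = ba),
         thermal = thermal_medium(C_heat = v[4], k_cond = v[5], Q_met = v[6],
                                  omega = v[7], rho = v[3]))
  })
  names(out) <- tissues
  out
}

#' Build a labelled material volume
#'
#' A `material_volume` couples a 3D integer label grid with a label table
#' mapping each label to its acoustic and thermal media, on a rectilinear
#' (possibly nonuniform) grid.
#'
#' @param labels 3D integer array of tissue labels.
#' @param spacing Either a numeric vector of length 3 (uniform step per
#'   axis, m) or a list of three numeric vectors of per-cell widths.
#' @param label_table Named list keyed by label value (as character); each
#'   entry a list with elements `acoustic` and (optionally) `thermal`, as
#'   produced by [tissue_table()] entries, plus an optional `name`.
#' @param origin Coordinates of the center of voxel (1,1,1), m.
#' @return An object of class `material_volume` with element `axes`, the
#'   per-axis voxel-center coordinate vectors.
#' @export
build_material_volume <- function(labels, spacing, label_table,
                                  origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3L)
  labs <- sort(unique(as.integer(labels)))
  missing <- setdiff(as.character(labs), names(label_table))
  if (length(missing))
    stop("label(s) missing from label_table: ", paste(missing, collapse = ", "))
  dims <- dim(labels)
  if (is.list(spacing)) {
    stopifnot(length(spacing) == 3L,
              all(vapply(spacing, length, 1L) == dims))
    widths <- spacing
  } else {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    widths <- lapply(1:3, function(d) rep(spacing[d], dims[d]))
  }
  if (any(unlist(widths) <= 0)) stop("spacing must be > 0")
  axes <- lapply(1:3, function(d) {
    w <- widths[[d]]
    origin[d] + cumsum(w) - w
  })
  structure(list(labels = labels, dims = dims, widths = widths,
                 axes = axes, origin = origin, label_table = label_table),
            class = "material_volume")
}

#' @export
print.material_volume <- function(x, ...) {
  cat("material_volume:", paste(x$dims, collapse = " x "), "voxels;",
      length(x$label_table), "labelled media\n")
  ext <- vapply(x$axes, function(a) diff(range(a)), 0)
  cat("  extent [mm]:", paste(signif(ext * 1e3, 4), collapse = " x "), "\n")
  invisible(x)
}

#' Per-voxel material fields of a volume
#'
#' Expands the label grid into per-voxel density, speed of sound,
#' attenuation at the given frequency, and the effective attenuation term
#' of the time-domain solver.
#'
#' @param vol A [build_material_volume()] object.
#' @param f Frequency, Hz (needed for the attenuation fields; may be omitted
#'   if only rho/c are wanted).
#' @return List with 3D arrays `rho`, `c`, and when `f` is given `a`
#'   (Np/m) and `atilde` (1/s), plus `air_mask` (logical) flagging voxels
#'   whose label is acoustically extreme (air) for pressure-release
#'   treatment.
#' @export
material_fields <- function(vol, f = NULL) {
  labs <- as.integer(vol$labels)
  ulab <- sort(unique(labs))
  key <- match(labs, ulab)
  get1 <- function(fun) {
    v <- vapply(ulab, function(l) fun(vol$label_table[[as.character(l)]]), 0)
    array(v[key], vol$dims)
  }
  rho <- get1(function(e) e$acoustic$rho)
  cc <- get1(function(e) e$acoustic$c)
  air <- vapply(ulab, function(l) {
    e <- vol$label_table[[as.character(l)]]
    isTRUE(e$air) || identical(e$name, "Air") || e$acoustic$c < 500
  }, TRUE)
  out <- list(rho = rho, c = cc,
              air_mask = array(air[key], vol$dims))
  if (!is.null(f)) {
    a <- get1(function(e) e$acoustic$a_per_f * f / 1e6)
    out$a <- a
    out$atilde <- effective_attenuation(a, cc, f)
  }
  out
}

#' Write / read a material volume as NIfTI plus a JSON label table
#'
#' The label grid is stored as a NIfTI image (voxel sizes in mm) and the
#' label table as JSON alongside it.
#'
#' @param vol A `material_volume`.
#' @param path Path prefix; writes `<path>.nii` and `<path>_labels.json`.
#' @return `write_material_volume`: the path prefix, invisibly.
#' @export
write_material_volume <- function(vol, path) {
  w <- vapply(vol$widths, function(x) x[1], 0)
  img <- RNifti::asNifti(array(as.integer(vol$labels), vol$dims))
  RNifti::pixdim(img) <- w * 1e3
  RNifti::writeNifti(img, paste0(path, ".nii"))
  tab <- lapply(vol$label_table, function(e) {
    list(name = e$name %||% NA,
         acoustic = e$acoustic[c("c", "rho", "a_per_f")],
         thermal = if (!is.null(e$thermal))
           e$thermal[c("C_heat", "k_cond", "Q_met", "omega", "rho")])
  })
  jsonlite::write_json(list(origin = vol$origin, labels = tab),
                       paste0(path, "_labels.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_material_volume
#' @param label_table Label table to attach on read (the JSON stores plain
#'   numbers; passing a full table preserves classes). If `NULL`, media are
#'   reconstructed from the JSON.
#' @return `read_material_volume`: a `material_volume`.
#' @export
read_material_volume <- function(path, label_table = NULL) {
  img <- RNifti::readNifti(paste0(path, ".nii"))
  meta <- jsonlite::read_json(paste0(path, "_labels.json"))
  if (is.null(label_table)) {
    label_table <- lapply(meta$labels, function(e) {
      th <- if (!is.null(e$thermal))
        thermal_medium(e$thermal$C_heat, e$thermal$k_cond, e$thermal$Q_met,
                       e$thermal$omega, e$thermal$rho)
      nm <- if (!is.null(e$name) && !is.na(e$name)) e$name
      list(name = nm,
           acoustic = acoustic_medium(e$acoustic$c, e$acoustic$rho,
                                      e$acoustic$a_per_f),
           thermal = th)
    })
    names(label_table) <- names(meta$labels)
  }
  spacing <- RNifti::pixdim(img)[1:3] / 1e3
  build_material_volume(array(as.integer(img), dim(img)), spacing,
                        label_table, origin = unlist(meta$origin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
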