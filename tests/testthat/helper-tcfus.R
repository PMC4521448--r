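# Shared fixtures for the tcfus test suite. All fixtures are built in code.

# single-medium label table
one_medium_table <- function(c = 1500, rho = 1000, a_per_f = 0, ...) {
  list("1" = list(acoustic = acoustic_medium(c, rho, a_per_f, ...),
                  name = "medium"))
}

water_table <- function() {
  tab <- tissue_table("Water")
  list("1" = c(tab$Water, name = "Water"))
}

# thin-slab (1-voxel-y) water column for plane-wave runs
thin_slab <- function(nz, dx, table = one_medium_table(), nx = 1) {
  build_material_volume(array(1L, c(nx, max(nx, 1), nz)), rep(dx, 3), table)
}

# uniform water box
water_box <- function(n, dx, table = one_medium_table()) {
  build_material_volume(array(1L, c(n, n, n)), rep(dx, 3), table,
                        origin = -rep((n - 1) / 2 * dx, 3))
}

# isotropic 3D Gaussian field on given axes
gaussian_field <- function(axes, center, sigma, peak = 1) {
  nd <- vapply(axes, length, 1L)
  dx2 <- outer(rep(1, nd[1]), rep(1, nd[2]))
  g1 <- exp(-(axes[[1]] - center[1])^2 / (2 * sigma^2))
  g2 <- exp(-(axes[[2]] - center[2])^2 / (2 * sigma^2))
  g3 <- exp(-(axes[[3]] - center[3])^2 / (2 * sigma^2))
  peak * outer(outer(g1, g2), g3)
}

# analytic chord length of a segment from point a to point b through a
# spherical shell (outer radius R, thickness t, centered at ctr)
shell_chord <- function(a, b, ctr, R, t) {
  seg_sphere <- function(r) {
    d <- b - a
    L <- sqrt(sum(d^2))
    u <- d / L
    oc <- a - ctr
    B <- 2 * sum(u * oc)
    C <- sum(oc^2) - r^2
    disc <- B^2 - 4 * C
    if (disc <= 0) return(0)
    t1 <- (-B - sqrt(disc)) / 2
    t2 <- (-B + sqrt(disc)) / 2
    max(0, min(t2, L) - max(t1, 0))
  }
  seg_sphere(R) - seg_sphere(R - t)
}
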