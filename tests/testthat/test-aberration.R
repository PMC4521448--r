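test_that("distance-based corrections have the textbook structure", {
  arr <- make_hemispherical_array(64, 64e-3, 9e-6, 230e3)
  # at the geometric focus all elements are equidistant: equal phases
  dv <- dpc(arr, arr$geometric_focus, 1e5)
  expect_lt(diff(range(dv$phase)), 1e-9)
  expect_true(all(dv$amplitude == 1e5))
  # two elements whose path difference is half a wavelength differ by pi
  f <- 230e3; cw <- 1482.3; lam <- cw / f
  a2 <- list(centers = rbind(c(0, 0, -30e-3), c(0, 0, -30e-3 - lam / 2)),
             normals = rbind(c(0, 0, 1), c(0, 0, 1)),
             areas = c(1e-4, 1e-4), geometric_focus = c(0, 0, 0),
             radius = 30e-3, frequency = f, n_elements = 2L)
  class(a2) <- "transducer_array"
  dv2 <- dpc(a2, c(0, 0, 0), 1, cw, f)
  dph <- (dv2$phase[2] - dv2$phase[1]) %% (2 * pi)
  expect_equal(dph, pi, tolerance = 1e-6)
})

test_that("ray tracing measures bone chords of a spherical shell", {
  vol <- make_skull_phantom(grid_half_extent = 26e-3, spacing = 0.5e-3,
                            outer_radius = 16e-3, thickness = 6e-3)
  arr <- make_hemispherical_array(24, 48e-3, 4e-6, 230e3)
  # target at center: every radial ray crosses exactly the 6 mm thickness
  rt <- trace_rays(arr, c(0, 0, 0), vol)
  vd <- sqrt(3) * 0.5e-3
  expect_true(all(abs(rt$bone - 6e-3) < vd))
  expect_equal(rt$total,
               sqrt(rowSums(arr$centers^2)), tolerance = 1e-9)
  # oblique rays to an off-center target match the analytic shell chord
  tgt <- c(5e-3, -3e-3, 4e-3)
  rt2 <- trace_rays(arr, tgt, vol)
  chords <- vapply(seq_len(24), function(e)
    shell_chord(arr$centers[e, ], tgt, c(0, 0, 0), 16e-3, 6e-3), 0)
  expect_true(all(abs(rt2$bone - chords) < vd))
  # no bone on the segment -> zero bone path, total = Euclidean distance
  volw <- make_skull_phantom(grid_half_extent = 26e-3, spacing = 0.5e-3,
                             outer_radius = 16e-3, thickness = 0)
  rt3 <- trace_rays(arr, c(0, 0, 0), volw)
  expect_true(all(rt3$bone == 0))
  expect_equal(rt3$total, sqrt(rowSums(arr$centers^2)), tolerance = 1e-9)
})

test_that("ray-traced corrections reduce to and extend the distance-based ones", {
  vol <- make_skull_phantom(grid_half_extent = 26e-3, spacing = 0.5e-3,
                            outer_radius = 16e-3, thickness = 6e-3)
  arr <- make_hemispherical_array(24, 48e-3, 4e-6, 230e3)
  f <- arr$frequency
  p_el <- 2e5
  # zero bone everywhere: rtpc == dpc
  rays0 <- data.frame(element = 1:24,
                      total = sqrt(rowSums(arr$centers^2)), bone = 0)
  dv_r0 <- rtpc(arr, c(0, 0, 0), vol, p_el, rays = rays0, f = f)
  dv_d <- dpc(arr, c(0, 0, 0), p_el, f = f)
  expect_equal(dv_r0$phase, dv_d$phase, tolerance = 1e-9)
  # uniform bone path: constant phase offset relative to dpc
  raysb <- transform(rays0, bone = 4e-3)
  dv_rb <- rtpc(arr, c(0, 0, 0), vol, p_el, rays = raysb, f = f)
  off <- (dv_rb$phase - dv_d$phase) %% (2 * pi)
  expect_lt(diff(range(off)), 1e-9)
  # a thicker-bone ray shifts by 2 pi f b (1/c_bone - 1/c_water)
  rays1 <- rays0; rays1$bone[7] <- 5e-3
  dv_r1 <- rtpc(arr, c(0, 0, 0), vol, p_el, rays = rays1, f = f,
                c_water = 1482.3, c_bone = 3183)
  expected <- (2 * pi * f * 5e-3 * (1 / 3183 - 1 / 1482.3)) %% (2 * pi)
  got <- (dv_r1$phase[7] - dv_d$phase[7]) %% (2 * pi)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("time-reversal drive vectors conjugate the captured phases", {
  # captured phases all zero -> drive phases all zero
  cap0 <- structure(complex(modulus = runif(16, 1, 2), argument = 0),
                    class = "captured_phasors")
  dv <- spc(cap0, 1e5)
  expect_true(all(dv$phase == 0))
  expect_true(all(dv$amplitude == 1e5))
  # general conjugation
  ph <- runif(16, -pi, pi)
  cap <- structure(complex(modulus = 1, argument = ph),
                   class = "captured_phasors")
  dv2 <- spc(cap, 1)
  expect_equal(Arg(exp(1i * (dv2$phase + ph))), rep(0, 16),
               tolerance = 1e-9)
  # dead elements are deactivated with a warning
  capd <- cap; capd[3] <- 1e-9 + 0i
  expect_warning(dv3 <- spc(capd, 1), "deactivated")
  expect_false(dv3$active[3])
  expect_equal(dv3$amplitude[3], 0)
  expect_error(spc(structure(rep(0 + 0i, 4), class = "captured_phasors"), 1),
               "zero")
})

test_that("power normalization of captured amplitudes is exact", {
  p_el <- 120310
  # equal captures at p_element: f_norm = 1
  cap <- structure(rep(complex(modulus = p_el, argument = 0.4), 32),
                   class = "captured_phasors")
  dv <- spac(cap, p_element = p_el)
  expect_equal(attr(dv, "f_norm"), 1, tolerance = 1e-12)
  expect_equal(dv$amplitude, rep(p_el, 32), tolerance = 1e-9)
  # all captures doubled: f_norm = 0.5
  dv2 <- spac(structure(2 * cap, class = "captured_phasors"),
              p_element = p_el)
  expect_equal(attr(dv2, "f_norm"), 0.5, tolerance = 1e-12)
  # normalization identity for random captures, machine precision
  set.seed(11)
  for (i in 1:20) {
    n <- sample(8:1024, 1)
    capr <- structure(complex(modulus = rexp(n, 1e-3) + 1,
                              argument = runif(n, -pi, pi)),
                      class = "captured_phasors")
    dvr <- spac(capr, p_element = p_el)
    expect_equal(sum(dvr$amplitude^2), n * p_el^2,
                 tolerance = 1e-12)
  }
})

test_that("strategy dispatcher routes and validates", {
  arr <- make_hemispherical_array(8, 60e-3, 9e-6, 230e3)
  vol <- make_skull_phantom(grid_half_extent = 20e-3, spacing = 1e-3,
                            outer_radius = 14e-3, thickness = 4e-3)
  dv <- aberration_correction("dpc", arr, c(0, 0, 0), vol, 1e5)
  expect_s3_class(dv, "drive_vector")
  expect_error(aberration_correction("spc", arr, c(0, 0, 0), vol, 1e5),
               "captured")
})

water_cavity <- function(half = 22e-3, dx = 0.8e-3, pml = 8) {
  tab <- tissue_table(c("Water", "Bone"))
  lt <- list("1" = c(tab$Water, name = "Water"),
             "2" = c(tab$Bone, name = "Bone"))  # present, unused
  n <- 2 * ceiling(half / dx) + 1 + 2 * pml
  build_material_volume(array(1L, c(n, n, n)), rep(dx, 3), lt,
                        origin = -rep((n - 1) / 2 * dx, 3))
}

test_that("a global phase constant leaves the forward field unchanged", {
  f <- 230e3
  vol <- water_cavity()
  arr <- make_hemispherical_array(16, 40e-3, 9e-6, f)
  target <- c(2e-3, -1.5e-3, 3e-3)
  dv <- dpc(arr, target, 1e5, f = f)
  dv2 <- drive_vector(dv$amplitude, (dv$phase + 1.234) %% (2 * pi))
  vox <- voxelize_elements(arr, vol)
  amp <- function(d) {
    r <- simulate_acoustic(vol, f, 14, sources = drive_sources(d, vox),
                           pml_layers = 8)
    Mod(r$phasor[[1]])
  }
  a1 <- amp(dv); a2 <- amp(dv2)
  expect_lt(max(abs(a1 - a2)) / max(a1), 0.005)
})

test_that("in water all four strategies focus at the same spot", {
  f <- 230e3
  vol <- water_cavity()
  arr <- make_hemispherical_array(32, 40e-3, 9e-6, f)
  # an on-grid target, so the virtual source sits exactly at the target
  target <- c(2.4e-3, -1.6e-3, 3.2e-3)
  # order-4 interior scheme: in homogeneous water its negligible phase
  # dispersion lets the captured phases match the analytic ones closely
  cap <- inverse_propagate(vol, target, arr, f, n_periods = 12,
                           pml_layers = 8, order = 4)
  # water-only capture: spc phases equal dpc phases up to a global constant
  dv_d <- dpc(arr, target, 1e5, f = f)
  dv_s <- spc(cap, 1e5)
  dphi <- Arg(exp(1i * (dv_s$phase - dv_d$phase)))
  dphi <- Arg(exp(1i * (dphi - Arg(mean(exp(1i * dphi))))))
  expect_lt(max(abs(dphi)), 3 * pi / 180)
  drives <- list(dv_d, rtpc(arr, target, vol, 1e5, f = f), dv_s,
                 spac(cap, p_element = 1e5))
  vox <- voxelize_elements(arr, vol)
  peaks <- sapply(drives, function(d) {
    r <- simulate_acoustic(vol, f, 14, sources = drive_sources(d, vox),
                           pml_layers = 8)
    focal_metrics(Mod(r$phasor[[1]]), vol, target)$peak_index
  })
  # all four peak voxels within one voxel of each other
  expect_true(all(abs(peaks - peaks[, 1]) <= 1))
})
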