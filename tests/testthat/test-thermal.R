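test_that("perfusion factor is exact at the shutdown thresholds", {
  expect_equal(perfusion_factor(37), 1)
  expect_equal(perfusion_factor(50), 1)
  expect_equal(perfusion_factor(50.5), 0.5)
  expect_equal(perfusion_factor(51), 0)
  expect_equal(perfusion_factor(60), 0)
  # vectorized, monotone non-increasing
  tt <- seq(45, 55, 0.1)
  pf <- perfusion_factor(tt)
  expect_true(all(diff(pf) <= 1e-12))
  expect_error(perfusion_factor(40, 51, 50))
})

test_that("acoustic heat source follows the absorption formula", {
  expect_equal(acoustic_heat_source(1e6, 0, 1000, 1500), 0)
  # doubling p quadruples S
  s1 <- acoustic_heat_source(5e5, 2, 1050, 1565)
  s2 <- acoustic_heat_source(1e6, 2, 1050, 1565)
  expect_equal(s2 / s1, 4, tolerance = 1e-12)
  # rho*S equals the plane-wave volumetric heating a p^2/(rho c)
  a <- 8.6 * 0.23; p <- 1e6; rho <- 1046; cc <- 1565
  expect_equal(rho * acoustic_heat_source(p, a, rho, cc),
               a * p^2 / (rho * cc), tolerance = 1e-12)
  expect_error(acoustic_heat_source(1, 1, 0, 1500))
})

test_that("perfused zero-conduction steady state matches the analytic balance", {
  br <- tissue_table("Brain")$Brain
  lt <- list("1" = list(acoustic = br$acoustic,
                        thermal = thermal_medium(br$thermal$C_heat, 0, 0,
                                                 br$thermal$omega,
                                                 br$thermal$rho)))
  vol <- build_material_volume(array(1L, c(4, 4, 4)), rep(1e-3, 3), lt)
  bl <- blood_properties()
  S <- 100
  r <- run_bioheat(vol, T0 = 37, S = S, duration = 1200, dt = 0.5,
                   blood = bl)
  dT_ref <- S / (bl$rho_b * bl$c_b * perfusion_to_si(br$thermal$omega))
  expect_equal(max(r$T) - 37, dT_ref, tolerance = 0.01)
  # equilibrium input stays at equilibrium
  r0 <- run_bioheat(vol, T0 = 37, S = 0, duration = 60, dt = 0.5,
                    blood = bl)
  expect_equal(max(abs(r0$T - 37)), 0, tolerance = 1e-9)
})

test_that("1D conduction matches the half-space heat-kernel solution", {
  Cw <- 4178; kw <- 0.6; rw <- 1000
  med <- function() list(acoustic = acoustic_medium(1500, rw, 0),
                         thermal = thermal_medium(Cw, kw, 0, 0, rw))
  lt <- list("1" = med(), "2" = med())
  nz <- 120; dx <- 0.5e-3
  labs <- array(1L, c(3, 3, nz)); labs[, , 1] <- 2L
  vol <- build_material_volume(labs, rep(dx, 3), lt)
  bc <- list(boundary_spec(2L, "dirichlet", T_boundary = 10))
  tend <- 200
  r <- run_bioheat(vol, T0 = 0, S = 0, duration = tend, boundaries = bc)
  alph <- kw / (rw * Cw)
  z <- (seq_len(nz) - 1) * dx
  ref <- 10 * (1 - pracma::erf(z / (2 * sqrt(alph * tend))))
  sel <- 2:40 # interior, far from the insulated end
  expect_lt(max(abs(r$T[2, 2, sel] - ref[sel])) / 10, 0.01)
  # boundary voxels pinned
  expect_true(all(r$T[, , 1] == 10))
})

test_that("a convective boundary equilibrates the rod to the ambient", {
  Cw <- 4178; kw <- 0.6; rw <- 1000
  med <- function() list(acoustic = acoustic_medium(1500, rw, 0),
                         thermal = thermal_medium(Cw, kw, 0, 0, rw))
  lt <- list("1" = med(), "2" = med())
  labs <- array(1L, c(3, 3, 10)); labs[, , 1] <- 2L
  vol <- build_material_volume(labs, rep(1e-3, 3), lt)
  bc <- list(boundary_spec(2L, "convective", h = 200, T_outside = 25))
  r <- run_bioheat(vol, T0 = 37, S = 0, duration = 8000, boundaries = bc)
  expect_lt(max(abs(r$T[2, 2, 2:10] - 25)), 0.1)
  # h = 0 reduces to a pure imposed-flux condition: with F = 0 the rod
  # is insulated and keeps its temperature
  bc0 <- list(boundary_spec(2L, "neumann", F_boundary = 0))
  r0 <- run_bioheat(vol, T0 = 37, S = 0, duration = 500, boundaries = bc0)
  expect_equal(max(abs(r0$T[, , 2:10] - 37)), 0, tolerance = 1e-9)
})

test_that("insulated diffusion conserves thermal energy", {
  med <- list("1" = list(acoustic = acoustic_medium(1500, 1000, 0),
                         thermal = thermal_medium(4000, 0.6, 0, 0, 1000)))
  vol <- build_material_volume(array(1L, c(8, 8, 8)), rep(1e-3, 3), med)
  T0 <- array(37, c(8, 8, 8)); T0[4, 4, 4] <- 60; T0[2, 6, 3] <- 20
  r <- run_bioheat(vol, T0 = T0, S = 0, duration = 100)
  # uniform rho C V: energy ~ sum(T)
  expect_lt(abs(sum(r$T) - sum(T0)) / sum(T0), 1e-9)
  # heat actually diffused
  expect_lt(max(r$T), 60)
})

test_that("perfusion drives temperature toward blood temperature", {
  br <- tissue_table("Brain")$Brain
  lt <- list("1" = br)
  vol <- build_material_volume(array(1L, c(5, 5, 5)), rep(1e-3, 3), lt)
  T0 <- array(37, c(5, 5, 5)); T0[3, 3, 3] <- 45; T0[2, 2, 2] <- 30
  bl <- blood_properties(T_b = 37)
  r <- run_bioheat(vol, T0 = T0, S = 0, duration = 5, blood = bl,
                   dt = 0.05)
  expect_lt(r$T[3, 3, 3], 45)
  expect_gt(r$T[2, 2, 2], 30)
})

test_that("vascular shutdown steepens heating on identical inputs", {
  br <- tissue_table("Brain")$Brain
  lt <- list("1" = list(acoustic = br$acoustic,
                        thermal = thermal_medium(3630, 0.51, 0, 559, 1046)))
  vol <- build_material_volume(array(1L, c(9, 9, 9)), rep(1e-3, 3), lt)
  S <- array(0, c(9, 9, 9)); S[4:6, 4:6, 4:6] <- 3e4
  on <- run_bioheat(vol, 37, S, duration = 25, shutdown = TRUE)
  off <- run_bioheat(vol, 37, S, duration = 25, shutdown = FALSE)
  expect_gt(max(on$T), max(off$T))
  # identical below the shutdown threshold
  short_on <- run_bioheat(vol, 37, S, duration = 1, shutdown = TRUE)
  short_off <- run_bioheat(vol, 37, S, duration = 1, shutdown = FALSE)
  expect_lt(max(short_on$T), 50)
  expect_equal(short_on$T, short_off$T, tolerance = 1e-12)
})

test_that("the treatment protocol composes equilibration and sonication", {
  tab <- tissue_table(c("Water", "Brain"))
  lt <- list("1" = c(tab$Water, name = "Water"),
             "2" = c(tab$Brain, name = "Brain"))
  labs <- array(2L, c(9, 9, 9))
  labs[, , 1] <- 1L # water bolus face
  vol <- build_material_volume(labs, rep(1e-3, 3), lt)
  bc <- list(boundary_spec(1L, "convective", h = 70, T_outside = 16))
  S <- array(0, c(9, 9, 9)); S[5, 5, 5] <- 2e4
  # zero power at equilibrium: the sonication phase changes nothing
  # (uniform state with no metabolic source, no perfusion, insulated)
  vol_iso <- build_material_volume(array(1L, c(9, 9, 9)), rep(1e-3, 3), lt)
  tp_iso <- run_treatment_protocol(vol_iso, S = 0, equilibration_s = 60,
                                   sonication_s = 20, blood =
                                     blood_properties(T_b = 37))
  expect_equal(tp_iso$sonicated$T, tp_iso$equilibrium$T, tolerance = 1e-9)
  tp0 <- run_treatment_protocol(vol, S = 0, equilibration_s = 120,
                                sonication_s = 20, boundaries = bc)
  # zero-power sonication continues the same cooling trajectory: small
  # drift, no heating anywhere
  expect_true(all(tp0$sonicated$T <= tp0$equilibrium$T + 1e-9))
  # bolus cooling pulls the near-water tissue below core temperature
  expect_lt(tp0$equilibrium$T[5, 5, 2], 37)
  # with power: peak dT grows monotonically during sonication
  tp <- run_treatment_protocol(vol, S = S, equilibration_s = 120,
                               sonication_s = 20, boundaries = bc,
                               probes = matrix(c(5, 5, 5), 1))
  tr <- tp$sonicated$probes[, 1]
  expect_true(all(diff(tr) > 0))
  expect_gt(max(tp$sonicated$T - tp$equilibrium$T), 0.5)
})
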