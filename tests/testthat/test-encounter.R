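test_that("calm kernel handles zero, equal and general speed pairs", {
  p <- reference_params()
  expect_equal(gs_rate(p, 0), 0)

  # removable point x = y: the general bracket is continuous there and
  # equals 86400 * pi R^2 N * (4x/3)
  p_eq <- encounter_params(R = 0.003, x = 0.150, y = 0.150)
  p_near <- encounter_params(R = 0.003, x = 0.150, y = 0.1499999)
  expect_equal(gs_rate(p_eq, 100), 86400 * pi * 0.003^2 * 100 * (4 * 0.150 / 3),
               tolerance = 1e-12)
  expect_equal(gs_rate(p_eq, 100), gs_rate(p_near, 100), tolerance = 1e-6)

  # one zero speed: algebraic limit max(x, y)
  expect_equal(gs_rate(p, 205.2), 86400 * pi * 0.003^2 * 205.2 * 0.150,
               tolerance = 1e-12)
  p_swap <- encounter_params(R = 0.003, x = 0, y = 0.150)
  expect_equal(gs_rate(p_swap, 205.2), gs_rate(p, 205.2))

  expect_error(gs_rate(encounter_params(x = 0, y = 0), 10), "relative motion")
  expect_error(encounter_params(R = -1), "R must be")
  expect_error(gs_rate(p, -5), ">= 0")
})

test_that("calm kernel is symmetric in speeds and linear in density", {
  set.seed(42)
  for (i in 1:20) {
    R <- runif(1, 1e-4, 1e-2)
    x <- runif(1, 0.01, 0.5)
    y <- runif(1, 0.01, 0.5)
    N <- runif(1, 1, 500)
    expect_equal(gs_rate(encounter_params(R, x, y), N),
                 gs_rate(encounter_params(R, y, x), N), tolerance = 1e-12)
    expect_equal(gs_rate(encounter_params(R, x, y), 2 * N),
                 2 * gs_rate(encounter_params(R, x, y), N), tolerance = 1e-12)
  }
})

test_that("turbulent kernel dominates the calm one and matches its closed form", {
  set.seed(7)
  for (i in 1:30) {
    x <- runif(1, 0.01, 0.5)
    w <- runif(1, 0, 0.5)
    N <- runif(1, 1, 500)
    p <- encounter_params(R = 0.003, x = x, y = 0)
    ro <- ro_rate(p, N, w)
    expect_gte(ro, gs_rate(p, N) * (1 - 1e-12))
    closed <- 86400 * pi * 0.003^2 * N * (3 * x^2 + 4 * w^2) /
      (3 * sqrt(x^2 + w^2))
    expect_equal(ro, closed, tolerance = 1e-10)
  }
  p <- reference_params()
  expect_identical(ro_rate(p, 205.2, 0), gs_rate(p, 205.2))
  expect_error(ro_rate(p, 10, -0.1), ">= 0")
})

test_that("turbulent kernel grows asymptotically linearly in w", {
  p <- reference_params()
  r10 <- ro_rate(p, 100, 10)
  r20 <- ro_rate(p, 100, 20)
  # for w >> x the closed form tends to 86400 pi R^2 N * (4/3) w
  expect_equal(r20 / r10, 2, tolerance = 1e-3)
  expect_equal(r20, 86400 * pi * 0.003^2 * 100 * (4 / 3) * 20, tolerance = 1e-3)
})

test_that("enhancement factor and its calibration inverse round-trip", {
  expect_equal(enhancement_factor(0.150, 0), 1)
  expect_equal(enhancement_factor(0.150, 0.150), 1.650, tolerance = 1e-3)
  expect_error(enhancement_factor(0, 0.1), "x must be")

  expect_equal(calibrate_surface_w(1, 0.150), 0)
  expect_error(calibrate_surface_w(0.9, 0.150), ">= 1")

  f_grid <- seq(1, 3, by = 0.05)
  w <- calibrate_surface_w(f_grid, 0.150)
  expect_equal(enhancement_factor(0.150, w), f_grid, tolerance = 1e-10)

  # enhancement strictly increasing in w
  w_grid <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(enhancement_factor(0.150, w_grid)) > 0))
})

test_that("turbulence profiles respect the surface value and monotone decay", {
  sp <- turbulence_spec(w0 = 0.132, decay_depth = 12)
  z <- c(0, 5, 12, 27.6, 50)
  w <- turbulence_profile(sp, z)
  expect_equal(w[1], 0.132)
  expect_true(all(diff(w) < 0))
  expect_equal(w[4], 0.132 * exp(-2.3), tolerance = 1e-12)

  lin <- turbulence_spec(w0 = 0.1, decay_depth = 30,
                         profile_mode = "linear_cutoff")
  expect_equal(turbulence_profile(lin, c(0, 15, 30, 60)), c(0.1, 0.05, 0, 0))

  const <- turbulence_spec(w0 = 0.1, profile_mode = "constant")
  expect_equal(turbulence_profile(const, c(0, 100)), c(0.1, 0.1))
  expect_error(turbulence_spec(w0 = 0.1, profile_mode = "sigmoid"))
  expect_error(turbulence_profile(sp, c(-1, 0)), "depths")
})

test_that("encounter profiles are calm-constant, turbulence-dominated and decay to calm", {
  p <- reference_params()
  w0 <- calibrate_surface_w(115.1 / 75.4, 0.150)
  sp <- turbulence_spec(w0 = w0, decay_depth = 12)
  prof <- encounter_profile(p, N = 205.2, spec = sp,
                            depths = seq(0, 120, by = 5))
  expect_equal(length(unique(prof$c_gs)), 1L)
  expect_true(all(prof$c_ro >= prof$c_gs - 1e-12))
  expect_true(all(diff(prof$c_ro) <= 1e-12))
  expect_equal(prof$c_ro[1] / prof$c_gs[1], 115.1 / 75.4, tolerance = 1e-10)
  expect_equal(prof$c_ro[nrow(prof)] / prof$c_gs[nrow(prof)], 1,
               tolerance = 1e-4)

  calm <- encounter_profile(p, 205.2,
                            turbulence_spec(w0 = 0, decay_depth = 12),
                            depths = c(0, 10, 50))
  expect_equal(calm$c_ro, calm$c_gs)
})

test_that("ambush-encounter simulation agrees with the kernel at reduced scale", {
  # quick mechanistic check at modest particle count; the full-resolution
  # convergence run lives with the acceptance checks
  sim <- simulate_ambush_encounters(R = 0.05, x = 1, n_particles = 600,
                                    box = 0.5, t_total = 60, dt = 0.05,
                                    seed = 11)
  expect_lt(sim$rel_error, 0.05)
})
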