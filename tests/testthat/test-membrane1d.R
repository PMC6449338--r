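test_that("thermo state carries RT = R*T with the molar gas constant", {
  th <- thermo_state()
  expect_equal(th$temperature, 320)
  expect_equal(th$RT, 8.314462e-3 * 320, tolerance = 1e-12)
  expect_equal(th$RT, 2.6606, tolerance = 1e-4)
  expect_error(thermo_state(-1), "positive")
})

test_that("presets reproduce the labelled barrier heights and vanish in water", {
  for (case in list(c("dopc-like", 40), c("normal-0chl-like", 62),
                    c("normal-33chl-like", 70))) {
    m <- membrane_model(case[1])
    expect_equal(free_energy(m, 0), as.numeric(case[2]), tolerance = 1e-9)
    expect_lt(abs(free_energy(m, m$half_width)), 1e-6)
    expect_lt(abs(free_energy(m, -m$half_width)), 1e-6)
  }
})

test_that("a flat explicit model has W = 0 and constant D everywhere", {
  m <- membrane_model(barrier_height = 0, bulk_diffusivity = 3e-3,
                      core_diffusivity = 3e-3)
  z <- seq(-2.5, 2.5, length.out = 41)
  expect_equal(free_energy(m, z), rep(0, 41))
  expect_equal(diffusivity(m, z), rep(3e-3, 41))
})

test_that("analytic derivatives match central differences", {
  m <- membrane_model("normal-33chl-like", well_depth = 4)
  z <- seq(-2.4, 2.4, length.out = 33)
  h <- 1e-6
  expect_equal(free_energy_deriv(m, z),
               (free_energy(m, z + h) - free_energy(m, z - h)) / (2 * h),
               tolerance = 1e-6)
  expect_equal(diffusivity_deriv(m, z),
               (diffusivity(m, z + h) - diffusivity(m, z - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("invalid model parameters are rejected", {
  expect_error(membrane_model(barrier_height = -5), ">= 0")
  expect_error(membrane_model(barrier_width = 0), "positive")
  expect_error(membrane_model(bulk_diffusivity = -1e-3), "positive")
  expect_error(membrane_model("no-such-membrane"), "Unknown preset")
})

test_that("reference permeability: flat-landscape closed form and stability", {
  m <- membrane_model(bulk_diffusivity = 0.046, core_diffusivity = 0.046)
  p <- reference_permeability(m, z1 = -2.3, z2 = 2.3)
  expect_equal(p, 0.046 / 4.6 * 1e3, tolerance = 1e-10) # 10 m/s
  m2 <- membrane_model("normal-0chl-like")
  p1 <- reference_permeability(m2, n_quad = 4001)
  p2 <- reference_permeability(m2, n_quad = 8001)
  expect_lt(abs(p2 - p1) / p1, 1e-3)
})

test_that("reference permeability matches adaptive-quadrature oracle", {
  m <- membrane_model("normal-0chl-like")
  th <- thermo_state()
  oracle <- stats::integrate(function(z) {
    exp(free_energy(m, z) / th$RT) / diffusivity(m, z)
  }, -2.3, 2.3, rel.tol = 1e-10)$value
  expect_equal(reference_permeability(m, th), 1e3 / oracle,
               tolerance = 1e-5)
})

test_that("reference permeability is monotone in barrier, linear in D, symmetric", {
  p <- vapply(c(10, 30, 50), function(w0) {
    reference_permeability(membrane_model(barrier_height = w0))
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  m1 <- membrane_model(barrier_height = 20, bulk_diffusivity = 2e-3,
                       core_diffusivity = 1e-3)
  m2 <- membrane_model(barrier_height = 20, bulk_diffusivity = 4e-3,
                       core_diffusivity = 2e-3)
  expect_equal(reference_permeability(m2),
               2 * reference_permeability(m1), tolerance = 1e-10)
  expect_equal(reference_permeability(m1, z1 = -2.3, z2 = 1.7),
               reference_permeability(m1, z1 = -1.7, z2 = 2.3),
               tolerance = 1e-9)
  expect_error(reference_permeability(m1, z1 = 2, z2 = -2), "smaller")
  expect_error(reference_permeability(m1, n_quad = 10), "1000")
})

test_that("umbrella window sampling matches the biased Boltzmann density", {
  th <- thermo_state()
  flat <- membrane_model(bulk_diffusivity = 5e-3, core_diffusivity = 5e-3)
  w <- simulate_window(flat, 0.3, spring = 1000,
                       config = langevin_config(n_steps = 1e6,
                                                sample_stride = 1,
                                                seed = 42))
  expect_equal(var(w$position), th$RT / 1000, tolerance = 0.05)
  expect_equal(mean(w$position), 0.3, tolerance = 0.01)
  # decorrelated subsample vs the exact biased Gaussian
  sub <- w$position[seq(1, nrow(w), by = 500)]
  ks <- suppressWarnings(
    stats::ks.test(sub, "pnorm", 0.3, sqrt(th$RT / 1000)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("divergence drift keeps the stationary density Boltzmann under varying D", {
  th <- thermo_state()
  m <- membrane_model(barrier_height = 0, bulk_diffusivity = 5e-3,
                      core_diffusivity = 5e-4, diffusivity_width = 0.3)
  w <- simulate_window(m, 0, spring = 10,
                       config = langevin_config(n_steps = 2e6,
                                                sample_stride = 20,
                                                seed = 99))
  # Without the D'(z) term the 10x diffusivity dip at the centre would
  # overweight the core by an order of magnitude; Boltzmann statistics
  # of the bias alone must hold.
  expect_equal(mean(w$position), 0, tolerance = 0.04)
  expect_equal(var(w$position), th$RT / 10, tolerance = 0.07)
})

test_that("free diffusion has MSD-consistent increments and 2 D t growth", {
  flat <- membrane_model(bulk_diffusivity = 5e-3, core_diffusivity = 5e-3)
  w <- simulate_window(flat, 0, spring = 0,
                       config = langevin_config(n_steps = 2e5,
                                                sample_stride = 10,
                                                seed = 8))
  dz <- diff(w$position)
  expect_equal(var(dz), 2 * 5e-3 * 0.1, tolerance = 0.03)
})

test_that("simulation is deterministic and guards against too-large steps", {
  m <- membrane_model("dopc-like")
  cfg <- langevin_config(n_steps = 2000, seed = 123)
  w1 <- simulate_window(m, 0.5, config = cfg)
  w2 <- simulate_window(m, 0.5, config = cfg)
  expect_identical(w1$position, w2$position)
  expect_identical(w1$force, w2$force)
  expect_error(
    simulate_window(m, 0, config = langevin_config(timestep = 50,
                                                   n_steps = 100)),
    "timestep", ignore.case = TRUE)
})

test_that("window ladders have the expected centre counts", {
  m <- membrane_model(bulk_diffusivity = 5e-3, core_diffusivity = 5e-3)
  cfg <- langevin_config(n_steps = 100, equilibration_steps = 0, seed = 1)
  w <- simulate_windows(m, -2.5, 2.5, spacing = 0.1, config = cfg)
  expect_equal(dplyr::n_distinct(w$center), 51)
  w3 <- simulate_windows(m, -2.5, 2.5, spacing = 0.1, n_replicates = 3,
                         config = cfg)
  expect_equal(nrow(dplyr::distinct(w3, center, replicate)), 153)
  w47 <- simulate_windows(m, -2.3, 2.3, spacing = 0.1, config = cfg)
  expect_equal(dplyr::n_distinct(w47$center), 47)
  expect_error(simulate_windows(m, -1, 1, spacing = 0), "positive")
})

test_that("recorded force is the total systematic force", {
  m <- membrane_model("normal-0chl-like")
  w <- simulate_window(m, 1.0, spring = 500,
                       config = langevin_config(n_steps = 500, seed = 5))
  expect_equal(w$force,
               -free_energy_deriv(m, w$position) -
                 500 * (w$position - 1.0),
               tolerance = 1e-12)
})

test_that("first-passage trivia: zero distance and flat closed form", {
  th <- thermo_state()
  flat <- membrane_model(bulk_diffusivity = 5e-3, core_diffusivity = 5e-3)
  z0 <- first_passage_time(flat, th, langevin_config(seed = 2),
                           start = 1, absorbing = 1, reflecting = 0)
  expect_equal(z0$mean, 0)
  fp <- first_passage_time(flat, th, langevin_config(seed = 3),
                           start = 0, absorbing = 1, reflecting = 0,
                           n_particles = 400)
  expect_lt(abs(fp$mean - 1 / (2 * 5e-3)), 3 * fp$sem)
  expect_equal(mean_first_passage_theory(flat, th, 0, 1, 0), 100,
               tolerance = 1e-4)
  expect_error(first_passage_time(flat, th, langevin_config(),
                                  start = 0, absorbing = 1,
                                  reflecting = -1, n_particles = 1),
               "at least 2")
})

test_that("uptake generator reproduces the exact first-order curve", {
  u <- simulate_uptake(2e-4, c(0, log(2) / 2e-4, 1e5))
  expect_equal(u$value[1], 0)
  expect_equal(u$value[2], 0.5, tolerance = 1e-12)
  expect_error(simulate_uptake(-1, 1:5), "positive")
  expect_error(simulate_uptake(1e-4, c(3, 2, 1)), "increasing")
})
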