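## uniform-tissue geometry with no CSF and brain everywhere: diffusion tests
open_box <- function(shape = c(16, 16, 8), spacing = c(1, 1, 2)) {
  g <- image_grid(shape, spacing)
  list(grid = g, labels = array(1L, g$shape),
       brain = array(TRUE, g$shape))
}

test_that("the explicit stability bound follows the 7-point stencil formula", {
  g <- image_grid(c(10, 10, 10), c(1, 1, 5))
  expect_equal(stable_dt(0, g), Inf)
  expect_equal(stable_dt(0.2, g), stable_dt(0.1, g) / 2)
  expect_equal(stable_dt(0.1, g, safety = 0.9),
               0.9 * 0.5 / (0.1 * (1 + 1 + 1 / 25)))
})

test_that("null dynamics leave the state unchanged", {
  bx <- open_box()
  phi <- array(runif(prod(bx$grid$shape), 0, 0.5), bx$grid$shape)
  out <- step_single_species(phi, array(0, bx$grid$shape), k_p = 0, theta = 1,
                             grid = bx$grid, dt = 0.5)
  expect_equal(out, phi)
})

test_that("the zero-diffusion limit matches the logistic closed form voxelwise", {
  bx <- open_box(c(4, 4, 2))
  set.seed(5)
  phi0 <- array(runif(prod(bx$grid$shape), 0.01, 0.5), bx$grid$shape)
  ## forward Euler needs dt well under the 0.01-day cap to reach 1e-4
  k <- 0.1; theta <- 1; t_end <- 10; dt <- 0.002
  phi <- phi0
  D0 <- array(0, bx$grid$shape)
  for (i in seq_len(t_end / dt))
    phi <- step_single_species(phi, D0, k, theta, bx$grid, dt)
  analytic <- theta * phi0 * exp(k * t_end) /
    (theta + phi0 * (exp(k * t_end) - 1))
  expect_lt(max(abs(phi - analytic) / analytic), 1e-4)
  ## the single-voxel instance: phi0 = 0.1 -> 0.23197 at t = 10 d
  p <- 0.1
  for (i in seq_len(t_end / dt)) p <- p + dt * k * p * (1 - p)
  expect_rel(p, 0.23197, 1e-4)
})

test_that("pure no-flux diffusion conserves fraction mass", {
  bx <- open_box(c(12, 12, 6))
  D <- gliomaRx:::tissuewise_diffusion(0.15, 0.1, bx$labels, bx$brain)
  faces <- gliomaRx:::precompute_faces(D, bx$grid)
  phi <- array(0, bx$grid$shape)
  phi[5:8, 5:8, 3:4] <- 0.6
  m0 <- sum(phi)
  dt <- 0.9 * stable_dt(0.15, bx$grid)
  for (i in 1:500)
    phi <- step_single_species(phi, faces, 0, 1, bx$grid, dt)
  expect_lt(abs(sum(phi) - m0) / m0, 1e-10)
  expect_true(min(phi) >= 0)
})

test_that("two-species reduces to single species without competition", {
  bx <- open_box(c(10, 10, 4))
  set.seed(2)
  phiE <- array(runif(prod(bx$grid$shape), 0, 0.4), bx$grid$shape)
  zero <- array(0, bx$grid$shape)
  p <- growth_params("two_species", D_E_w = 0.1, D_E_g = 0.1, k_pE = 0.07,
                     theta_E = 0.8, beta_NE = 0, beta_EN = 0)
  D <- gliomaRx:::tissuewise_diffusion(0.1, 0.1, bx$labels, bx$brain)
  two <- step_two_species(phiE, zero, D, D, p, bx$grid, 0.4)
  one <- step_single_species(phiE, D, 0.07, 0.8, bx$grid, 0.4)
  expect_lt(max(abs(two$phi_E - one)), 1e-12)
  expect_equal(two$phi_N, zero)            # extinction is absorbing
  ## logistic zero-crossing of the enhancing species: stationary without
  ## diffusion when phi_E = theta_E - beta_NE * phi_N
  p4 <- growth_params("two_species", k_pE = 0.1, theta_E = 0.9, beta_NE = 4)
  phiN <- array(0.05, bx$grid$shape)
  phiE0 <- array(0.9 - 4 * 0.05, bx$grid$shape)
  st <- step_two_species(phiE0, phiN, zero, zero, p4, bx$grid, 0.5)
  expect_equal(st$phi_E, phiE0, tolerance = 1e-12)
})

test_that("anisotropic diffusion of a Gaussian matches the analytic spread", {
  g <- image_grid(c(64, 64, 8), c(1, 1, 5))
  labels <- array(1L, g$shape)
  brain <- array(TRUE, g$shape)
  D_val <- 0.3; t_end <- 10
  s0 <- c(4, 4, 6)                     # initial standard deviations, mm
  ctr <- (g$shape - 1) * g$spacing / 2
  tmpl <- array(0, g$shape)
  coord <- function(ax) (slice.index(tmpl, ax) - 1) * g$spacing[ax]
  ## separable Gaussian; the thin slice direction needs reflected images at
  ## the no-flux planes half a voxel beyond the first/last slice centres
  gauss1 <- function(ax, s, images = FALSE) {
    x <- coord(ax)
    acc <- exp(-0.5 * ((x - ctr[ax]) / s)^2)
    if (images) {
      lo <- -g$spacing[ax] / 2
      hi <- (g$shape[ax] - 0.5) * g$spacing[ax]
      for (c_img in c(2 * lo - ctr[ax], 2 * hi - ctr[ax],
                      2 * (lo - hi) + ctr[ax], 2 * (hi - lo) + ctr[ax]))
        acc <- acc + exp(-0.5 * ((x - c_img) / s)^2)
    }
    acc * s0[ax] / s
  }
  field <- function(s) 0.5 * gauss1(1, s[1]) * gauss1(2, s[2]) *
    gauss1(3, s[3], images = TRUE)
  phi <- field(s0)
  D <- gliomaRx:::tissuewise_diffusion(D_val, D_val, labels, brain)
  faces <- gliomaRx:::precompute_faces(D, g)
  dt <- 0.9 * stable_dt(D_val, g)
  n <- ceiling(t_end / dt); dt <- t_end / n
  for (i in seq_len(n))
    phi <- phi + gliomaRx:::diffusion_increment(phi, faces, g, dt)
  analytic <- field(sqrt(s0^2 + 2 * D_val * t_end))
  expect_lt(sqrt(sum((phi - analytic)^2) / sum(analytic^2)), 0.02)
})

test_that("a frozen system records a constant trajectory", {
  syn <- cached_synth("tiny")
  cfg <- tiny_phantom_config()
  v <- syn$dataset$visits[[1]]
  init <- assign_initial_state(v, "single", cfg$cellularity)
  spec <- model_spec("single", 10)
  par <- growth_params("single", D_w = 0, D_g = 0, k_p = 0, lambda1 = 0)
  sets <- simulation_settings(record_times = c(10, 20), dt = 1)
  geom <- list(grid = cfg$grid, tissue_labels = v$tissue_labels,
               brain_mask = v$brain_mask)
  out <- simulate_tumor(spec, par, init,
                        treatment_schedule("RT", numeric(0)),
                        treatment_schedule("CT", numeric(0)), sets, geom)
  expect_equal(out[[1]]$phi_T, init$phi_T)
  expect_equal(out[[2]]$phi_T, init$phi_T)
  expect_equal(vapply(out, `[[`, 1, "time"), c(10, 20))
})

test_that("a single uniform RT event halves the total fraction mass", {
  syn <- cached_synth("tiny")
  cfg <- tiny_phantom_config()
  v <- syn$dataset$visits[[1]]
  init <- assign_initial_state(v, "single", cfg$cellularity)
  spec <- model_spec("single", 10)        # C4/C4: uniform efficacy
  par <- growth_params("single", D_w = 0, D_g = 0, k_p = 0, lambda1 = 0,
                       sf_rt_min = 0.5, sf_ct_min = 1)
  sets <- simulation_settings(record_times = 10, dt = 1)
  geom <- list(grid = cfg$grid, tissue_labels = v$tissue_labels,
               brain_mask = v$brain_mask)
  out <- simulate_tumor(spec, par, init, treatment_schedule("RT", 5),
                        treatment_schedule("CT", numeric(0)), sets, geom)
  expect_rel(sum(out[[1]]$phi_T), 0.5 * sum(init$phi_T), 1e-12)
})

test_that("stress damping never accelerates growth", {
  cfg <- small_phantom_config()
  cfg_nodamp <- small_phantom_config()
  cfg_nodamp$truth_params$lambda1 <- 0
  cfg_damp <- small_phantom_config()
  cfg_damp$truth_params$lambda1 <- 1000
  s_free <- synthesize_visits(cfg_nodamp)$truth$states
  s_damp <- synthesize_visits(cfg_damp)$truth$states
  for (i in seq_along(s_free)) {
    vol_free <- sum(gliomaRx:::state_total(s_free[[i]]) >= 0.05)
    vol_damp <- sum(gliomaRx:::state_total(s_damp[[i]]) >= 0.05)
    expect_lte(vol_damp, vol_free)
  }
})

test_that("fractions remain within [0, theta] along a treated trajectory", {
  syn <- cached_synth("small")
  p <- small_phantom_config()$truth_params
  for (s in syn$truth$states) {
    expect_true(all(s$phi_E >= 0 & s$phi_E <= p$theta_E))
    expect_true(all(s$phi_N >= 0 & s$phi_N <= p$theta_N))
  }
})

test_that("instability and timing violations are reported", {
  bx <- open_box(c(8, 8, 4))
  spec <- model_spec("single", 10)
  par <- growth_params("single", D_w = 0.3, D_g = 0.3, lambda1 = 0)
  init <- tumor_state("single", 5, phi_T = array(0.1, bx$grid$shape))
  sets <- simulation_settings(record_times = 1)  # before start
  geom <- list(grid = bx$grid, tissue_labels = bx$labels, brain_mask = bx$brain)
  expect_error(simulate_tumor(spec, par, init,
                              treatment_schedule("RT", numeric(0)),
                              treatment_schedule("CT", numeric(0)),
                              sets, geom), "before")
  sets2 <- simulation_settings(record_times = 10, dt = 5)  # unstable dt
  expect_error(simulate_tumor(spec, par, init,
                              treatment_schedule("RT", numeric(0)),
                              treatment_schedule("CT", numeric(0)),
                              sets2, geom), "stability")
})
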