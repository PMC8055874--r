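test_that("scenario partitions follow the calibration/prediction designs", {
  syn <- cached_synth("small")          # visits at 0, 30, 90
  ds <- syn$dataset
  s1 <- partition_visits(ds, 1)
  expect_equal(s1$calibration_idx, c(2L, 3L))   # all follow-ups
  expect_length(s1$prediction_idx, 0)
  s2 <- partition_visits(ds, 2)
  expect_equal(s2$calibration_idx, 2L)          # 1-month only
  expect_equal(s2$prediction_idx, 3L)
  s3 <- partition_visits(ds, 3)
  expect_equal(s3$calibration_idx, c(2L, 3L))   # 1- and 3-month
  expect_length(s3$prediction_idx, 0)
  ## partitions are disjoint and exhaustive over follow-ups
  for (s in list(s1, s2, s3)) {
    expect_length(intersect(s$calibration_idx, s$prediction_idx), 0)
    expect_setequal(c(s$calibration_idx, s$prediction_idx),
                    seq_along(ds$visits)[-1])
  }
  ## scenario 3 without a 3-month follow-up is insufficient data
  two_visit <- patient_dataset("p", ds$visits[1:2], ds$rt_schedule,
                               ds$ct_schedule)
  expect_error(partition_visits(two_visit, 3), "insufficient")
})

test_that("residuals have the contracted shape and vanish at the truth", {
  syn <- cached_synth("small")
  cfg <- small_phantom_config()
  spec <- cfg$truth_spec
  pset <- parameter_set(spec)
  tv <- gliomaRx:::truth_vector(cfg)
  sc <- partition_visits(syn$dataset, 1)
  sets <- simulation_settings(record_times = 1, dt = 1, mechanics_stride = 5L)
  ## self-consistency: the generating parameters reproduce the measured maps
  r <- residuals_vector(tv[pset$names], pset, syn$dataset, sc,
                        cparams = cfg$cellularity, settings = sets,
                        species_term = FALSE)
  expect_lt(max(abs(r)), 1e-6)
  n_brain <- sum(syn$dataset$visits[[1]]$brain_mask)
  expect_length(r, 2L * n_brain)          # brain voxels x calibration visits
  ## with the species term, residual rows extend over the enhancing masks
  r2 <- residuals_vector(tv[pset$names], pset, syn$dataset, sc,
                         cparams = cfg$cellularity, settings = sets,
                         species_term = TRUE)
  n_enh <- sum(vapply(sc$calibration_idx, function(i)
    sum(syn$dataset$visits[[i]]$enhancing_mask), 0))
  expect_length(r2, 2L * n_brain + n_enh)
  ## single-species: brain voxels per calibration visit only
  pset1 <- parameter_set(model_spec("single", 8))
  r1 <- residuals_vector(pset1$init, pset1, syn$dataset, sc,
                         cparams = cfg$cellularity, settings = sets)
  expect_length(r1, 2L * n_brain)
})

test_that("starting at the truth stays at the truth", {
  syn <- cached_synth("small")
  cfg <- small_phantom_config()
  tv <- gliomaRx:::truth_vector(cfg)
  sets <- simulation_settings(record_times = 1, dt = 1, mechanics_stride = 5L)
  res <- calibrate(cfg$truth_spec, syn$dataset, 1, init = tv,
                   cparams = cfg$cellularity, settings = sets,
                   species_term = FALSE, maxiter = 3, refine_maxiter = 0)
  expect_lt(res$sse, 1e-12)
  expect_lt(max(abs(res$par[names(tv)] - tv) / tv), 0.02)
})

test_that("forecasts freeze the calibrated parameters and honor scenarios", {
  syn <- cached_synth("small")
  cfg <- small_phantom_config()
  tv <- gliomaRx:::truth_vector(cfg)
  sets <- simulation_settings(record_times = 1, dt = 1, mechanics_stride = 5L)
  ## scenario 2: calibrate on the 1-month visit, predict the 3-month visit
  res2 <- calibrate(cfg$truth_spec, syn$dataset, 2, init = tv,
                    cparams = cfg$cellularity, settings = sets,
                    species_term = FALSE, maxiter = 2, refine_maxiter = 0)
  pred <- forecast(res2)
  expect_length(pred, 1)
  expect_equal(pred[[1]]$time, 90)
  truth90 <- syn$truth$states[[3]]
  num <- sqrt(sum((gliomaRx:::state_total(pred[[1]]) -
                     gliomaRx:::state_total(truth90))^2))
  expect_lt(num / sqrt(sum(gliomaRx:::state_total(truth90)^2)), 0.02)
  ## scenario 1 has no held-out visits
  res1 <- calibrate(cfg$truth_spec, syn$dataset, 1, init = tv,
                    cparams = cfg$cellularity, settings = sets,
                    species_term = FALSE, maxiter = 1, refine_maxiter = 0)
  expect_length(forecast(res1), 0)
})

test_that("field proliferation expands lattice values onto the grid", {
  syn <- cached_synth("small")
  cfg <- small_phantom_config()
  v <- syn$dataset$visits[[1]]
  btm <- v$enhancing_mask | v$nonenhancing_mask
  spec_f <- model_spec("two_species", 8, "field")
  pset <- parameter_set(spec_f, baseline_tumor_mask = btm, grid = cfg$grid,
                        field_cell = 4L)
  n_cells <- pset$field_map$n_cells
  expect_gt(n_cells, 1)
  expect_equal(sum(grepl("k_pE_cell", pset$names)), n_cells)
  par <- pset$init
  par[grep("k_pE_cell", names(par))] <- seq(0.01, 0.2, length.out = n_cells)
  gp <- gliomaRx:::params_from_vector(par, pset)
  expect_true(is.array(gp$k_pE))
  ## every voxel inherits the value of its (nearest) active cell
  expect_setequal(unique(as.numeric(gp$k_pE)),
                  seq(0.01, 0.2, length.out = n_cells))
  ## uniform cell values collapse to a uniform field
  par[grep("k_pE_cell", names(par))] <- 0.07
  gp2 <- gliomaRx:::params_from_vector(par, pset)
  expect_true(all(gp2$k_pE == 0.07))
})

test_that("noise-robustness tables are deterministic and tight at zero noise", {
  cfg <- small_phantom_config()
  tv <- gliomaRx:::truth_vector(cfg)
  sets <- simulation_settings(record_times = 1, dt = 1, mechanics_stride = 5L)
  tab1 <- noise_robustness(cfg, noise_levels = 0, replicates = 1, seed = 4L,
                           scenario_id = 2, init = tv, settings = sets,
                           species_term = FALSE, maxiter = 2,
                           refine_maxiter = 0)
  tab2 <- noise_robustness(cfg, noise_levels = 0, replicates = 1, seed = 4L,
                           scenario_id = 2, init = tv, settings = sets,
                           species_term = FALSE, maxiter = 2,
                           refine_maxiter = 0)
  expect_identical(tab1, tab2)
  expect_true(all(abs(tab1$percent_error) < 2))
})
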