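#' Free-parameter roster for a model specification
#'
#' Builds the calibration parameter set for one family member: names, default
#' initial guesses, and box bounds. Calibrated parameters are the tissue-wise
#' diffusion coefficients, proliferation rate(s), the (enhancing) carrying
#' capacity, the stress-diffusion coupling `lambda1`, and the two minimum
#' surviving fractions. Fixed constants (`beta_NE = 4`, `beta_EN = 1`,
#' `theta_N = 0.16`, `lambda2 = 1`, `nu = 0.45`, tissue shear moduli) are
#' carried by [growth_params()] / [elasticity_params()] defaults.
#'
#' For the field proliferation parameterization, the scalar proliferation
#' rate is replaced by one value per coarse lattice cell (cell edge
#' `field_cell` voxels in-plane, 1 slice thick) intersecting the baseline
#' tumor region; every voxel takes the value of its nearest active cell, so
#' voxels invaded later inherit the nearest calibrated rate.
#'
#' @param spec a [model_spec()].
#' @param baseline_tumor_mask logical array (union of baseline tumor masks);
#'   required for `proliferation = "field"`.
#' @param grid the [image_grid()] (field mode).
#' @param field_cell lattice cell edge, voxels (field mode).
#' @param init,lower,upper named numeric vectors overriding defaults.
#' @return An object of class `parameter_set` with `names`, `init`, `lower`,
#'   `upper`, and the lattice map for field mode.
#' @export
parameter_set <- function(spec, baseline_tumor_mask = NULL, grid = NULL,
                          field_cell = 4L, init = NULL, lower = NULL,
                          upper = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  def <- function(nm) {
    if (grepl("^D_", nm)) c(0.05, 0, 1)          # mm^2/day
    else if (grepl("^k_p", nm)) c(0.05, 0, 0.5)  # 1/day
    else if (grepl("^theta", nm)) c(1, 0.5, 1)
    else if (nm == "lambda1") c(0.1, 0, 10)      # 1/kPa
    else c(0.8, 0.01, 1)                         # surviving fractions
  }
  base_names <- if (spec$base == "single")
    c("D_w", "D_g", "k_p", "theta", "lambda1", "sf_rt_min", "sf_ct_min")
  else
    c("D_E_w", "D_E_g", "D_N_w", "D_N_g", "k_pE", "k_pN", "theta_E",
      "lambda1", "sf_rt_min", "sf_ct_min")
  kp_name <- if (spec$base == "single") "k_p" else "k_pE"
  field_map <- NULL
  nm_all <- base_names
  if (spec$proliferation == "field") {
    if (is.null(baseline_tumor_mask) || is.null(grid))
      stop("field proliferation needs the baseline tumor mask and grid")
    field_map <- build_field_map(baseline_tumor_mask, grid, field_cell)
    nm_all <- c(setdiff(base_names, kp_name),
                sprintf("%s_cell%03d", kp_name, seq_len(field_map$n_cells)))
  }
  tab <- t(vapply(nm_all, function(nm) {
    d <- def(sub("_cell[0-9]+$", "", nm))
    d
  }, numeric(3)))
  p_init <- stats::setNames(tab[, 1], nm_all)
  p_lower <- stats::setNames(tab[, 2], nm_all)
  p_upper <- stats::setNames(tab[, 3], nm_all)
  for (nm in intersect(names(init), nm_all)) p_init[nm] <- init[[nm]]
  for (nm in intersect(names(lower), nm_all)) p_lower[nm] <- lower[[nm]]
  for (nm in intersect(names(upper), nm_all)) p_upper[nm] <- upper[[nm]]
  if (any(p_init < p_lower - 1e-12) || any(p_init > p_upper + 1e-12))
    stop("initial guess outside bounds")
  structure(list(spec = spec, names = nm_all, init = p_init,
                 lower = p_lower, upper = p_upper, kp_name = kp_name,
                 field_map = field_map),
            class = "parameter_set")
}

## coarse lattice over the grid; active cells intersect the baseline tumor.
## cell_of: for every voxel, the index of its (nearest) active cell.
build_field_map <- function(mask, grid, field_cell) {
  d <- grid$shape
  ij <- which(array(TRUE, d), arr.ind = TRUE)
  cell_coord <- cbind((ij[, 1] - 1L) %/% field_cell,
                      (ij[, 2] - 1L) %/% field_cell,
                      ij[, 3] - 1L)
  key <- cell_coord[, 1] + 1000L * (cell_coord[, 2] + 1000L * cell_coord[, 3])
  active_keys <- sort(unique(key[as.logical(mask)]))
  if (length(active_keys) == 0L) stop("baseline tumor mask is empty")
  ## centres of active cells (voxel units)
  dec <- function(k) cbind(k %% 1000L, (k %/% 1000L) %% 1000L, k %/% 1000000L)
  ac <- dec(active_keys)
  centers <- cbind((ac[, 1] + 0.5) * field_cell * grid$spacing[1],
                   (ac[, 2] + 0.5) * field_cell * grid$spacing[2],
                   (ac[, 3] + 0.5) * grid$spacing[3])
  idx <- match(key, active_keys)
  todo <- which(is.na(idx))
  if (length(todo)) {
    vox <- cbind((cell_coord[todo, 1] + 0.5) * field_cell * grid$spacing[1],
                 (cell_coord[todo, 2] + 0.5) * field_cell * grid$spacing[2],
                 (cell_coord[todo, 3] + 0.5) * grid$spacing[3])
    step <- max(1L, floor(2e6 / nrow(centers)))
    for (s in seq(1L, length(todo), by = step)) {
      e <- min(length(todo), s + step - 1L)
      d2 <- outer(rowSums(vox[s:e, , drop = FALSE]^2), rep(1, nrow(centers))) +
        outer(rep(1, e - s + 1L), rowSums(centers^2)) -
        2 * vox[s:e, , drop = FALSE] %*% t(centers)
      idx[todo[s:e]] <- max.col(-d2, ties.method = "first")
    }
  }
  list(n_cells = length(active_keys), cell_of = array(idx, d))
}

## expand a calibration vector into growth_params
params_from_vector <- function(par, pset) {
  spec <- pset$spec
  vals <- as.list(par)
  names(vals) <- pset$names
  if (!is.null(pset$field_map)) {
    cells <- unlist(vals[grep("_cell", names(vals))], use.names = FALSE)
    kfield <- array(cells[pset$field_map$cell_of], dim(pset$field_map$cell_of))
    vals <- vals[!grepl("_cell", names(vals))]
    vals[[pset$kp_name]] <- kfield
  }
  do.call(growth_params, c(list(kind = spec$base), vals))
}

#' Calibration/prediction scenarios
#'
#' Partition a patient's follow-up visits into calibration targets and
#' held-out prediction visits. The baseline visit is always the initial
#' condition, never a residual target. Scenario 1 calibrates to all
#' follow-ups (no predictions); scenario 2 calibrates to the first follow-up
#' (1-month) and predicts the rest; scenario 3 calibrates to the first two
#' follow-ups (1- and 3-month) and predicts the rest.
#'
#' @param dataset a [patient_dataset()].
#' @param scenario_id 1, 2, or 3.
#' @return list with `id`, `calibration_idx`, `prediction_idx` (visit
#'   indices into `dataset$visits`).
#' @export
partition_visits <- function(dataset, scenario_id) {
  stopifnot(scenario_id %in% 1:3)
  nfollow <- length(dataset$visits) - 1L
  follow <- seq_len(nfollow) + 1L
  need <- c(1L, 1L, 2L)[scenario_id]
  if (nfollow < need)
    stop(sprintf("insufficient data: scenario %d needs >= %d follow-up visit(s), dataset has %d",
                 scenario_id, need, nfollow))
  cal <- switch(scenario_id, follow, follow[1], follow[1:2])
  list(id = scenario_id, calibration_idx = cal,
       prediction_idx = setdiff(follow, cal))
}

## measured cellularity maps for one visit. `total_from = "adc"` reads the
## total map from the ADC everywhere in the brain (appropriate when ADC is
## informative brain-wide, as in the phantom); "masks" uses the piecewise
## assignment map (Eq.-based inside the enhancing region, fixed 0.16 in the
## non-enhancing region, zero elsewhere).
measured_maps <- function(visit, kind, cparams, total_from = c("adc", "masks")) {
  total_from <- match.arg(total_from)
  total <- if (total_from == "adc")
    estimate_cell_fraction(visit$adc, cparams, visit$brain_mask)
  else
    state_total(assign_initial_state(visit, kind, cparams))
  phi_E <- if (kind == "two_species" && any(visit$enhancing_mask))
    estimate_cell_fraction(visit$adc, cparams, visit$enhancing_mask)
  else NULL
  list(total = total, phi_E = phi_E)
}

## static context reused across every residual evaluation of one calibration
calibration_context <- function(spec, dataset, scenario, cparams, settings,
                                elasticity, total_from, geometry = NULL,
                                species_term = TRUE) {
  base_visit <- dataset$visits[[1]]
  grid <- base_visit$grid
  if (is.null(geometry)) {
    geometry <- list(grid = grid, tissue_labels = base_visit$tissue_labels,
                     brain_mask = array(as.logical(base_visit$brain_mask),
                                        grid$shape))
  }
  if (is.null(geometry$mech_op))
    geometry$mech_op <- build_mechanics_operator(grid, geometry$tissue_labels,
                                                 geometry$brain_mask, elasticity)
  init_state <- assign_initial_state(base_visit, spec$base, cparams)
  cal_times <- visit_times(dataset)[scenario$calibration_idx]
  if (is.null(settings))
    settings <- simulation_settings(record_times = cal_times)
  else {
    settings$record_times <- sort(cal_times)
  }
  er_fields <- lapply(dataset$visits, function(v)
    compute_enhancement_ratio(v$t1_post, v$t1_pre, v$brain_mask))
  er_sched <- list(times = visit_times(dataset), fields = er_fields)
  brain_idx <- which(geometry$brain_mask)
  meas <- lapply(scenario$calibration_idx, function(i) {
    v <- dataset$visits[[i]]
    mm <- measured_maps(v, spec$base, cparams, total_from)
    list(total_b = mm$total[brain_idx],
         enh_idx = which(as.logical(v$enhancing_mask)),
         phi_E_e = if (!is.null(mm$phi_E)) mm$phi_E[as.logical(v$enhancing_mask)])
  })
  list(spec = spec, dataset = dataset, scenario = scenario,
       geometry = geometry, init_state = init_state, settings = settings,
       er = er_sched, brain_idx = brain_idx, meas = meas,
       elasticity = elasticity, cparams = cparams,
       species_term = isTRUE(species_term))
}

residuals_from_context <- function(par, pset, ctx) {
  params <- params_from_vector(par, pset)
  states <- simulate_tumor(ctx$spec, params, ctx$init_state,
                           ctx$dataset$rt_schedule, ctx$dataset$ct_schedule,
                           ctx$settings, ctx$geometry, er = ctx$er,
                           elasticity = ctx$elasticity)
  res <- vector("list", 2 * length(states))
  for (i in seq_along(states)) {
    st <- states[[i]]
    m <- ctx$meas[[i]]
    tot <- state_total(st)
    res[[2 * i - 1]] <- tot[ctx$brain_idx] - m$total_b
    if (ctx$species_term && ctx$spec$base == "two_species" && length(m$enh_idx))
      res[[2 * i]] <- st$phi_E[m$enh_idx] - m$phi_E_e
  }
  unlist(res, use.names = FALSE)
}

#' Model-measurement residuals
#'
#' Simulates the model from the baseline initial condition through the
#' calibration visit times and returns the concatenated voxelwise residual
#' vector: simulated minus measured total cell fraction at every brain-mask
#' voxel of every calibration visit, plus (two-species model) simulated minus
#' measured enhancing fraction over each visit's measured enhancing mask.
#'
#' @param par named parameter vector (see [parameter_set()]).
#' @param pset the [parameter_set()].
#' @param dataset a [patient_dataset()].
#' @param scenario from [partition_visits()].
#' @param cparams a [cellularity_params()].
#' @param settings optional [simulation_settings()] (record times are set to
#'   the calibration visit times).
#' @param elasticity an [elasticity_params()].
#' @param total_from `"adc"` (default) or `"masks"`: construction of the
#'   measured total-cellularity map (see Details in the package vignette).
#' @return numeric residual vector.
#' @export
residuals_vector <- function(par, pset, dataset, scenario,
                             cparams = cellularity_params(), settings = NULL,
                             elasticity = elasticity_params(),
                             total_from = "adc", species_term = TRUE) {
  ctx <- calibration_context(pset$spec, dataset, scenario, cparams, settings,
                             elasticity, total_from,
                             species_term = species_term)
  residuals_from_context(par, pset, ctx)
}

#' Calibrate a model to a patient dataset
#'
#' Bounded Levenberg-Marquardt (via \code{minpack.lm::nls.lm}) minimizing
#' the residual sum of squares of [residuals_vector()], in two stages: a
#' box-bounded descent from the initial guess, then an optional bound-free
#' refinement in a scaled-logistic reparameterization of the box (kept only
#' if it lowers the SSE; see the methods vignette). Stops on
#' gradient/step/SSE tolerances or the iteration caps; on non-convergence the
#' best-so-far parameters are returned with `converged = FALSE`.
#'
#' @param spec a [model_spec()].
#' @param dataset a [patient_dataset()].
#' @param scenario from [partition_visits()] (or a scenario id 1-3).
#' @param pset optional [parameter_set()] (defaults built from `spec`).
#' @param init optional named initial values overriding the set's defaults.
#' @param cparams,settings,elasticity,total_from as in [residuals_vector()].
#' @param maxiter Levenberg-Marquardt iteration cap for the box-bounded
#'   stage.
#' @param refine_maxiter iteration cap for the bound-free refinement stage
#'   (0 disables it).
#' @param ftol,ptol relative SSE / step stopping tolerances.
#' @param geometry optional prebuilt geometry list (with a cached
#'   `mech_op`), re-used across calibrations on one patient.
#' @param lower,upper named bound overrides forwarded to [parameter_set()]
#'   when `pset` is not supplied (names outside the model's roster are
#'   ignored). Tighten the diffusion bounds when pinning `dt` so every
#'   admissible parameter vector stays inside the stability region.
#' @return A `calibration_result`: `par` (named vector), `params`
#'   ([growth_params()]), `sse`, `n_obs`, `n_params`, `niter`, `converged`,
#'   `message`, `fitted` (states at calibration times), `aic`, plus the
#'   scenario and spec.
#' @export
calibrate <- function(spec, dataset, scenario, pset = NULL, init = NULL,
                      cparams = cellularity_params(), settings = NULL,
                      elasticity = elasticity_params(), total_from = "adc",
                      species_term = TRUE, maxiter = 50, refine_maxiter = 50,
                      ftol = 1e-10, ptol = 1e-8, geometry = NULL,
                      lower = NULL, upper = NULL) {
  if (is.numeric(scenario)) scenario <- partition_visits(dataset, scenario)
  if (is.null(pset)) {
    btm <- dataset$visits[[1]]$enhancing_mask | dataset$visits[[1]]$nonenhancing_mask
    pset <- parameter_set(spec, baseline_tumor_mask = btm,
                          grid = dataset$visits[[1]]$grid,
                          lower = lower, upper = upper)
  }
  par0 <- pset$init
  if (!is.null(init)) for (nm in names(init)) par0[nm] <- init[[nm]]
  par0 <- pmin(pmax(par0, pset$lower), pset$upper)
  ctx <- calibration_context(spec, dataset, scenario, cparams, settings,
                             elasticity, total_from, geometry = geometry,
                             species_term = species_term)
  ## Stage 1: box-bounded Levenberg-Marquardt. The start is kept strictly
  ## inside the box because a parameter sitting on a bound has its
  ## forward-difference Jacobian column clamped to zero and never moves.
  rng <- pset$upper - pset$lower
  par0 <- pmin(pmax(par0, pset$lower + 1e-3 * rng), pset$upper - 1e-3 * rng)
  ## iteration caps are routinely exercised on purpose (fixed optimization
  ## budgets); the cap is reported through `converged`/`niter`, so the
  ## solver's own maxiter warning is muffled
  quiet_lm <- function(...) withCallingHandlers(
    minpack.lm::nls.lm(...),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fit <- quiet_lm(
    par = par0, lower = pset$lower, upper = pset$upper,
    fn = function(p) residuals_from_context(p, pset, ctx),
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = ptol, nprint = 0))
  par_hat <- stats::setNames(as.numeric(fit$par), pset$names)
  niter <- fit$niter
  ## Stage 2 (optional refinement): re-minimize through a scaled-logistic
  ## reparameterization in which the bounds are asymptotes. This frees
  ## parameters that stage 1 parked on a bound (their clamped Jacobian
  ## columns otherwise keep them there) and lets the optimizer crawl along
  ## weakly identified ridges (e.g. diffusion vs. stress-coupling
  ## compensation). Kept only if it improves the SSE.
  if (refine_maxiter > 0) {
    to_external <- function(tt) pset$lower + rng * stats::plogis(tt)
    ## snap bound-parked parameters slightly into the box: the logistic
    ## slope at 0.999 of the range is ~1e-3 of the range, leaving the
    ## refinement stage too flat to pull a parameter off a bound
    frac1 <- pmin(pmax((par_hat - pset$lower) / rng, 0.02), 0.98)
    fit2 <- quiet_lm(
      par = stats::qlogis(frac1),
      fn = function(tt) residuals_from_context(to_external(tt), pset, ctx),
      control = minpack.lm::nls.lm.control(maxiter = refine_maxiter,
                                           ftol = ftol, ptol = ptol,
                                           nprint = 0))
    niter <- niter + fit2$niter
    if (fit2$deviance <= fit$deviance) {
      par_hat <- stats::setNames(to_external(as.numeric(fit2$par)), pset$names)
      fit <- fit2
    }
  }
  r <- residuals_from_context(par_hat, pset, ctx)
  sse <- sum(r^2)
  n_obs <- length(r)
  n_par <- length(par_hat)
  params_hat <- params_from_vector(par_hat, pset)
  fitted <- simulate_tumor(spec, params_hat, ctx$init_state,
                           dataset$rt_schedule, dataset$ct_schedule,
                           ctx$settings, ctx$geometry, er = ctx$er,
                           elasticity = elasticity)
  aic <- tryCatch(compute_aic(max(sse, 1e-12), n_obs, n_par),
                  error = function(e) NA_real_)
  structure(list(par = par_hat, params = params_hat, sse = sse,
                 n_obs = n_obs, n_params = n_par, niter = niter,
                 converged = fit$info %in% 1:4, message = fit$message,
                 fitted = fitted, aic = aic, spec = spec,
                 scenario = scenario, pset = pset, cparams = cparams,
                 total_from = total_from, context = ctx),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s, scenario %d: SSE %.4g over %d residuals, %d LM iterations (%s)\n",
              x$spec$id, x$scenario$id, x$sse, x$n_obs, x$niter,
              if (x$converged) "converged" else "not converged"))
  print(signif(x$par, 4))
  invisible(x)
}

#' Forecast held-out visits from a calibration
#'
#' Runs the calibrated model forward from the baseline initial condition with
#' frozen parameters and records the state at every prediction visit time.
#'
#' @param result a `calibration_result` from [calibrate()].
#' @return list of predicted [tumor_state()] objects (empty for scenario 1).
#' @export
forecast <- function(result) {
  ctx <- result$context
  pred_idx <- result$scenario$prediction_idx
  if (!length(pred_idx)) return(list())
  pred_times <- visit_times(result$context$dataset)[pred_idx]
  settings <- ctx$settings
  settings$record_times <- sort(pred_times)
  simulate_tumor(result$spec, result$params, ctx$init_state,
                 ctx$dataset$rt_schedule, ctx$dataset$ct_schedule, settings,
                 ctx$geometry, er = ctx$er, elasticity = ctx$elasticity)
}

#' Noise robustness of parameter estimation
#'
#' Re-creates the measurement-noise experiment on a phantom: for each
#' relative ADC noise level and replicate, a dataset is synthesized with that
#' noise, the generating model is recalibrated (scenario 2 by default:
#' baseline + 1-month), and the signed percent error of every recovered
#' parameter against the generating truth is recorded. Deterministic given
#' `seed`.
#'
#' @param config a [phantom_config()] carrying the ground truth.
#' @param noise_levels relative ADC noise standard deviations.
#' @param replicates replicates per level.
#' @param seed base RNG seed.
#' @param scenario_id calibration scenario (default 2).
#' @param init optional named initial values for each calibration.
#' @param ... further arguments to [calibrate()].
#' @return data.frame: noise_level, replicate, parameter, truth, estimate,
#'   percent_error (NA rows record failed calibrations).
#' @export
noise_robustness <- function(config, noise_levels = c(0, 0.01, 0.03),
                             replicates = 3, seed = 1L, scenario_id = 2,
                             init = NULL, ...) {
  truth_par <- truth_vector(config)
  rows <- list()
  for (lv in noise_levels) for (rep in seq_len(replicates)) {
    cfg <- config
    cfg$noise_adc_sd <- lv
    cfg$seed <- as.integer((seed * 131L + round(lv * 1e4) * 17L + rep) %% .Machine$integer.max)
    syn <- synthesize_visits(cfg)
    res <- tryCatch(
      calibrate(cfg$truth_spec, syn$dataset,
                partition_visits(syn$dataset, scenario_id), init = init,
                cparams = cfg$cellularity, elasticity = cfg$elasticity, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        noise_level = lv, replicate = rep, parameter = NA_character_,
        truth = NA_real_, estimate = NA_real_, percent_error = NA_real_,
        error = conditionMessage(res))
      next
    }
    est <- res$par[names(truth_par)]
    rows[[length(rows) + 1L]] <- data.frame(
      noise_level = lv, replicate = rep, parameter = names(truth_par),
      truth = as.numeric(truth_par), estimate = as.numeric(est),
      percent_error = 100 * (as.numeric(est) - as.numeric(truth_par)) /
        as.numeric(truth_par),
      error = NA_character_)
  }
  do.call(rbind, rows)
}

## the generating parameters as a named vector matching parameter_set names
truth_vector <- function(config) {
  p <- config$truth_params
  if (p$kind == "single")
    c(D_w = p$D_w, D_g = p$D_g, k_p = p$k_p, theta = p$theta,
      lambda1 = p$lambda1, sf_rt_min = p$sf_rt_min, sf_ct_min = p$sf_ct_min)
  else
    c(D_E_w = p$D_E_w, D_E_g = p$D_E_g, D_N_w = p$D_N_w, D_N_g = p$D_N_g,
      k_pE = p$k_pE, k_pN = p$k_pN, theta_E = p$theta_E,
      lambda1 = p$lambda1, sf_rt_min = p$sf_rt_min, sf_ct_min = p$sf_ct_min)
}

#' Calibrate a family subset and rank by AIC
#'
#' Calibrates each model specification on the dataset under one scenario and
#' ranks the members by AIC (per-dataset; use [rank_models()] across patients
#' for a cohort).
#'
#' @param specs list of [model_spec()] objects.
#' @param dataset a [patient_dataset()].
#' @param scenario_id scenario (default 1: fit to all follow-ups).
#' @param ... further arguments to [calibrate()].
#' @return data.frame sorted by AIC: model, aic, sse, n_params, converged.
#' @export
select_models <- function(specs, dataset, scenario_id = 1, ...) {
  rows <- lapply(specs, function(sp) {
    res <- calibrate(sp, dataset, partition_visits(dataset, scenario_id), ...)
    data.frame(model = sp$id, base = sp$base, combination = sp$coupling$id,
               proliferation = sp$proliferation, aic = res$aic, sse = res$sse,
               n_params = res$n_params, converged = res$converged)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic, out$n_params, out$model), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
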