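#' Tumor growth and response parameters
#'
#' Parameters of the reaction-diffusion models. The single-species model
#' evolves one fraction `phi_T` with logistic growth
#' `k_p phi (1 - phi/theta)`; the two-species model evolves the enhancing
#' (`phi_E`) and non-enhancing (`phi_N`) fractions with competitive logistic
#' terms `(phi_E + beta_NE phi_N)/theta_E` and `(phi_N + beta_EN phi_E)/
#' theta_N`. Diffusion coefficients are tissue-wise (white/gray matter, zero
#' in CSF) and are exponentially damped by the von Mises stress with coupling
#' `lambda1`. Surviving-fraction minima parameterize the instantaneous
#' treatment events.
#'
#' Proliferation (`k_p`, `k_pE`) may be a scalar (global parameterization) or
#' a 3-D per-voxel field defined on the baseline tumor region (field
#' parameterization).
#'
#' Competition terms `beta_NE = 4`, `beta_EN = 1` and the non-enhancing
#' carrying capacity `theta_N = 0.16` are fixed model constants.
#'
#' @param kind `"single"` or `"two_species"`.
#' @param D_w,D_g tumor cell diffusion in white/gray matter, mm^2/day
#'   (single-species model).
#' @param k_p proliferation rate, 1/day, scalar or per-voxel array (single).
#' @param theta carrying capacity in (0, 1] (single).
#' @param D_E_w,D_E_g,D_N_w,D_N_g per-species tissue-wise diffusion, mm^2/day.
#' @param k_pE,k_pN per-species proliferation rates, 1/day (`k_pE` may be a
#'   field).
#' @param theta_E,theta_N per-species carrying capacities.
#' @param beta_NE,beta_EN competition coefficients.
#' @param lambda1 stress-diffusion coupling, 1/kPa.
#' @param sf_rt_min,sf_ct_min minimum surviving fractions in (0, 1].
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(kind = c("single", "two_species"),
                          D_w = 0.1, D_g = 0.05, k_p = 0.05, theta = 1,
                          D_E_w = 0.1, D_E_g = 0.05, D_N_w = 0.2, D_N_g = 0.1,
                          k_pE = 0.05, k_pN = 0.08, theta_E = 0.9,
                          theta_N = 0.16, beta_NE = 4, beta_EN = 1,
                          lambda1 = 5, sf_rt_min = 0.97, sf_ct_min = 0.99) {
  kind <- match.arg(kind)
  p <- if (kind == "single") {
    list(kind = kind, D_w = D_w, D_g = D_g, k_p = k_p, theta = theta,
         lambda1 = lambda1, sf_rt_min = sf_rt_min, sf_ct_min = sf_ct_min)
  } else {
    list(kind = kind, D_E_w = D_E_w, D_E_g = D_E_g, D_N_w = D_N_w,
         D_N_g = D_N_g, k_pE = k_pE, k_pN = k_pN, theta_E = theta_E,
         theta_N = theta_N, beta_NE = beta_NE, beta_EN = beta_EN,
         lambda1 = lambda1, sf_rt_min = sf_rt_min, sf_ct_min = sf_ct_min)
  }
  validate_growth_params(structure(p, class = "growth_params"))
}

validate_growth_params <- function(p) {
  dnames <- grep("^D_", names(p), value = TRUE)
  for (nm in dnames)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) stop(nm, " must be >= 0")
  for (nm in intersect(c("theta", "theta_E", "theta_N"), names(p)))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1)
      stop(nm, " must be in (0, 1]")
  for (nm in intersect(c("beta_NE", "beta_EN"), names(p)))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) stop(nm, " must be >= 0")
  if (!is.finite(p$lambda1) || p$lambda1 < 0) stop("lambda1 must be >= 0")
  for (nm in c("sf_rt_min", "sf_ct_min"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1)
      stop(nm, " must be in (0, 1]")
  for (nm in intersect(c("k_p", "k_pE", "k_pN"), names(p)))
    if (any(!is.finite(p[[nm]]))) stop(nm, " must be finite")
  p
}

max_diffusion <- function(params) {
  nms <- grep("^D_", names(params), value = TRUE)
  max(unlist(params[nms]))
}

#' Stability bound for the explicit diffusion update
#'
#' Forward-Euler stability for the anisotropic 7-point diffusion stencil:
#' dt <= 0.5 / (D_max * sum(1/h_i^2)). Returns `Inf` when `D_max` is zero
#' (proliferation-only dynamics impose no diffusion limit).
#'
#' @param D_max largest diffusion coefficient, mm^2/day.
#' @param grid an [image_grid()].
#' @param safety multiplicative safety factor in (0, 1].
#' @return maximum stable time step, days.
#' @export
stable_dt <- function(D_max, grid, safety = 0.9) {
  stopifnot(D_max >= 0, safety > 0, safety <= 1)
  if (D_max == 0) return(Inf)
  safety * 0.5 / (D_max * sum(1 / grid$spacing^2))
}

## harmonic face diffusivity: zero if either neighbour is zero, which makes
## the flux form no-flux at the brain/CSF boundary automatically
face_diffusivity <- function(D, axis) {
  array(cpp_face_harmonic_zero(as.numeric(D), dim(D), as.integer(axis)),
        dim(D))
}

## conservative flux-form diffusion increment: div(D grad phi) * dt
diffusion_increment <- function(phi, D_faces, grid, dt) {
  dt * array(cpp_div_d_grad(as.numeric(phi), D_faces[[1]], D_faces[[2]],
                            D_faces[[3]], dim(phi), 1 / grid$spacing^2),
             dim(phi))
}

precompute_faces <- function(D, grid) lapply(1:3, function(ax) face_diffusivity(D, ax))

#' One explicit step of the single-species model
#'
#' Conservative flux-form diffusion (no-flux at the brain boundary; zero
#' diffusivity in CSF) plus logistic growth, followed by clamping to
#' `[0, theta]` to guard logistic overshoot at finite dt.
#'
#' @param phi current volume-fraction array.
#' @param D_faces precomputed face diffusivities ([solve_displacement()]-damped
#'   diffusion passed through `precompute_faces`), or a diffusion array.
#' @param k_p proliferation rate (scalar or array), 1/day.
#' @param theta carrying capacity.
#' @param grid an [image_grid()].
#' @param dt time step, days (must satisfy [stable_dt()]).
#' @return updated volume-fraction array.
#' @export
step_single_species <- function(phi, D_faces, k_p, theta, grid, dt) {
  if (is.array(D_faces) || (is.numeric(D_faces) && !is.list(D_faces)))
    D_faces <- precompute_faces(D_faces, grid)
  phi_new <- phi + diffusion_increment(phi, D_faces, grid, dt) +
    dt * k_p * phi * (1 - phi / theta)
  pmin(pmax(phi_new, 0), theta)
}

#' One explicit step of the two-species model
#'
#' Both species diffuse independently (tissue-wise, mechanically damped
#' diffusivities) and grow logistically with cross-competition:
#' `(phi_E + beta_NE phi_N)/theta_E` for the enhancing species and
#' `(phi_N + beta_EN phi_E)/theta_N` for the non-enhancing species.
#'
#' @param phi_E,phi_N current species volume-fraction arrays.
#' @param D_E_faces,D_N_faces per-species face diffusivities (or arrays).
#' @param params a two-species [growth_params()].
#' @param grid an [image_grid()].
#' @param dt time step, days.
#' @return list with updated `phi_E`, `phi_N`.
#' @export
step_two_species <- function(phi_E, phi_N, D_E_faces, D_N_faces, params,
                             grid, dt) {
  if (is.array(D_E_faces)) D_E_faces <- precompute_faces(D_E_faces, grid)
  if (is.array(D_N_faces)) D_N_faces <- precompute_faces(D_N_faces, grid)
  gE <- params$k_pE * phi_E * (1 - (phi_E + params$beta_NE * phi_N) / params$theta_E)
  gN <- params$k_pN * phi_N * (1 - (phi_N + params$beta_EN * phi_E) / params$theta_N)
  pE <- phi_E + diffusion_increment(phi_E, D_E_faces, grid, dt) + dt * gE
  pN <- phi_N + diffusion_increment(phi_N, D_N_faces, grid, dt) + dt * gN
  list(phi_E = pmin(pmax(pE, 0), params$theta_E),
       phi_N = pmin(pmax(pN, 0), params$theta_N))
}

#' Simulation settings
#'
#' @param record_times days at which states are recorded (sampled at the
#'   nearest simulation step).
#' @param dt explicit time step in days, or `NULL` to use
#'   `min(dt_max, stable_dt(...))`.
#' @param dt_max upper bound on the automatic step (default 1 day, so
#'   treatment events resolve to the day).
#' @param safety stability safety factor.
#' @param mechanics_stride re-solve the mechanics every this many steps
#'   (1 = every step).
#' @param damp_nonenhancing also apply mechanical damping to the
#'   non-enhancing species' diffusion (default TRUE).
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(record_times, dt = NULL, dt_max = 1,
                                safety = 0.9, mechanics_stride = 1L,
                                damp_nonenhancing = TRUE) {
  stopifnot(length(record_times) >= 1, all(is.finite(record_times)))
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  structure(list(record_times = sort(as.numeric(record_times)), dt = dt,
                 dt_max = dt_max, safety = safety,
                 mechanics_stride = as.integer(mechanics_stride),
                 damp_nonenhancing = isTRUE(damp_nonenhancing)),
            class = "simulation_settings")
}

## tissue-wise uninhibited diffusion field: D_w in white, D_g in gray,
## zero in CSF and outside the brain (tumor cells do not invade CSF)
tissuewise_diffusion <- function(D_w, D_g, tissue_labels, brain_mask) {
  D <- array(0, dim(tissue_labels))
  D[tissue_labels == TISSUE_CODES["white"]] <- D_w
  D[tissue_labels == TISSUE_CODES["gray"]] <- D_g
  D[!brain_mask] <- 0
  D
}

## resolve the ER field at time t from a fixed array or a piecewise schedule
er_segment <- function(er, t) {
  if (is.null(er) || is.array(er)) return(1L)
  i <- which(er$times <= t + 1e-9)
  if (length(i)) max(i) else 1L
}

er_field <- function(er, seg) {
  if (is.null(er)) return(NULL)
  if (is.array(er)) return(er)
  er$fields[[seg]]
}

er_at_time <- function(er, t) er_field(er, er_segment(er, t))

#' Simulate a model through a treatment course
#'
#' Explicit forward-Euler time integration of the chosen family member from
#' an initial state. Each step interleaves (i) the quasi-static mechanics
#' solve, von Mises stress, and diffusion damping (skipped when
#' `lambda1 = 0`; optionally re-solved every `mechanics_stride` steps), (ii)
#' the reaction-diffusion update, and (iii) instantaneous treatment events:
#' every scheduled therapy day maps to the first simulation step at or after
#' that day, where the surviving-fraction fields of the model's coupling
#' approaches multiply the state.
#'
#' @param spec a [model_spec()].
#' @param params a [growth_params()] matching `spec$base`.
#' @param initial a [tumor_state()] giving the state at the start time.
#' @param rt_schedule,ct_schedule [treatment_schedule()] objects (may have
#'   zero events).
#' @param settings a [simulation_settings()].
#' @param geometry list with `grid`, `tissue_labels`, `brain_mask`, and
#'   optionally a prebuilt `mech_op` ([build_mechanics_operator()]).
#' @param er enhancement-ratio array in [1, 2], or a piecewise schedule
#'   `list(times =, fields =)` holding the most recent measured ER.
#' @param elasticity an [elasticity_params()] (used if `mech_op` absent).
#' @return list of [tumor_state()] objects, one per record time.
#' @export
simulate_tumor <- function(spec, params, initial, rt_schedule, ct_schedule,
                           settings, geometry, er = NULL,
                           elasticity = elasticity_params()) {
  stopifnot(inherits(spec, "model_spec"), inherits(params, "growth_params"),
            params$kind == spec$base, inherits(initial, "tumor_state"),
            initial$kind == spec$base)
  grid <- geometry$grid
  labels <- geometry$tissue_labels
  brain <- geometry$brain_mask
  t0 <- initial$time
  rec <- settings$record_times
  if (any(rec < t0 - 1e-9)) stop("record time before the simulation start")
  t_end <- max(rec)

  ## time step: explicit stability bound, capped for day-resolved treatment
  dmax <- max_diffusion(params)
  dt_target <- settings$dt
  if (is.null(dt_target))
    dt_target <- min(settings$dt_max, stable_dt(dmax, grid, settings$safety))
  if (dt_target > stable_dt(dmax, grid, 1))
    stop("dt violates the explicit stability bound")
  out <- vector("list", length(rec))
  if (t_end <= t0 + 1e-12) {
    for (i in seq_along(rec)) { s <- initial; s$time <- rec[i]; out[[i]] <- s }
    return(out)
  }
  nsteps <- max(1L, ceiling((t_end - t0) / dt_target - 1e-9))
  dt <- (t_end - t0) / nsteps
  step_times <- t0 + dt * seq_len(nsteps)

  ## map record times and treatment days to steps
  rec_step <- vapply(rec, function(tt) which.min(abs(step_times - tt)), 1L)
  map_days <- function(days) {
    days <- days[days > t0 & days <= t_end + 1e-9]
    vapply(days, function(d) which(step_times >= d - 1e-9)[1], 1L)
  }
  rt_steps <- map_days(rt_schedule$days)
  ct_steps <- map_days(ct_schedule$days)

  ## uninhibited tissue-wise diffusion
  if (spec$base == "single") {
    D0 <- list(tissuewise_diffusion(params$D_w, params$D_g, labels, brain))
  } else {
    D0 <- list(tissuewise_diffusion(params$D_E_w, params$D_E_g, labels, brain),
               tissuewise_diffusion(params$D_N_w, params$D_N_g, labels, brain))
  }
  use_mech <- params$lambda1 > 0 && any(vapply(D0, max, 0) > 0)
  mech_op <- geometry$mech_op
  if (use_mech && is.null(mech_op))
    mech_op <- build_mechanics_operator(grid, labels, brain, elasticity)

  state <- initial
  sf_cache <- list()
  faces <- lapply(D0, precompute_faces, grid = grid)
  theta_for_c1 <- if (spec$base == "single") params$theta else params$theta_E

  record_if_due <- function(k) {
    hit <- which(rec_step == k)
    for (i in hit) { s <- state; s$time <- rec[i]; out[[i]] <<- s }
  }
  ## a record time at/below the start samples the initial state
  for (i in which(rec <= t0 + 1e-12)) { s <- state; s$time <- rec[i]; out[[i]] <- s }
  rec_step[rec <= t0 + 1e-12] <- 0L

  for (k in seq_len(nsteps)) {
    if (use_mech && ((k - 1L) %% settings$mechanics_stride == 0L)) {
      ## growth-induced forcing saturates at full occupancy: the two species
      ## together may nominally exceed 1 (theta_E + theta_N > 1) in overlap
      ## regions, but a voxel cannot be more than full
      u <- solve_displacement(pmin(state_total(state), 1), op = mech_op)
      svm <- von_mises(u, mech_op)
      damp <- exp(-params$lambda1 * svm)
      dampN <- if (settings$damp_nonenhancing) damp else 1
      faces <- if (spec$base == "single")
        list(precompute_faces(D0[[1]] * damp, grid))
      else
        list(precompute_faces(D0[[1]] * damp, grid),
             precompute_faces(D0[[2]] * dampN, grid))
    }
    if (spec$base == "single") {
      state$phi_T <- step_single_species(state$phi_T, faces[[1]], params$k_p,
                                         params$theta, grid, dt)
    } else {
      upd <- step_two_species(state$phi_E, state$phi_N, faces[[1]], faces[[2]],
                              params, grid, dt)
      state$phi_E <- upd$phi_E
      state$phi_N <- upd$phi_N
    }
    n_rt <- sum(rt_steps == k)
    n_ct <- sum(ct_steps == k)
    if (n_rt + n_ct > 0L) {
      seg <- er_segment(er, step_times[k])
      er_now <- er_field(er, seg)
      if (spec$coupling$rt == "C1" || spec$coupling$ct == "C1") {
        tot <- state_total(state)
        msk <- tot > 0
        ## C1 occupancy: total burden over the (enhancing) capacity,
        ## saturated where the two species together exceed it
        occ <- pmin(tot, theta_for_c1)
      }
      ## fields of the phi-independent approaches (C2-C4) depend only on the
      ## current ER segment, so they are computed once per segment; their
      ## values at phi = 0 voxels are irrelevant (the update multiplies phi)
      get_sf <- function(side, appr, sf_min) {
        if (appr == "C1")
          return(surviving_fraction("C1", sf_min, phi = occ,
                                    theta = theta_for_c1, mask = msk))
        key <- paste0(side, seg)
        if (is.null(sf_cache[[key]]))
          sf_cache[[key]] <<- if (appr == "C4") array(sf_min, grid$shape)
            else surviving_fraction(appr, sf_min, er = er_now,
                                    mask = array(TRUE, grid$shape))
        sf_cache[[key]]
      }
      sf_rt <- if (n_rt > 0)
        get_sf("rt", spec$coupling$rt, params$sf_rt_min)^n_rt
      sf_ct <- if (n_ct > 0)
        get_sf("ct", spec$coupling$ct, params$sf_ct_min)^n_ct
      state <- apply_treatment(state, sf_rt, sf_ct)
    }
    record_if_due(k)
    if (k %% 50L == 0L || k == nsteps) {
      mx <- max(abs(state_total(state)))
      if (!is.finite(mx))
        stop(sprintf("instability at step %d (t = %.2f d): non-finite state",
                     k, step_times[k]))
    }
  }
  out
}
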