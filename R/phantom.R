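#' Digital-phantom configuration
#'
#' Describes a synthetic virtual patient: an ellipsoidal brain with a CSF
#' core, a gray-matter shell and a white-matter interior; a tumor seed with a
#' smooth enhancing core and a non-enhancing rim at the fixed cellularity
#' 0.16; a ground-truth model specification and parameter set; the imaging
#' visit times; and the measurement-noise levels. The generator emulates the
#' statistical and geometric structure of the longitudinal MRI inputs (ADC
#' decreasing with cellularity, enhancement ratio in [1, 2], nested tumor
#' masks) - not MR physics.
#'
#' Defaults mirror the study conditions: a 64 x 64 x 8 voxel grid at
#' 1 x 1 x 5 mm (isotropic in-plane, thick slices), visits at 0, 30, 90, 150
#' days (baseline and 1-, 3-, 5-month visits), standard-of-care
#' chemoradiation starting the day after baseline, 3% multiplicative ADC
#' noise and 2% T1 intensity noise, and a two-species ground truth with both
#' therapies coupled to the enhancement ratio (coupling combination 8).
#'
#' @param grid an [image_grid()].
#' @param brain_semi_axes ellipsoid semi-axes, mm.
#' @param gm_thickness gray-matter shell thickness, mm (normalized against
#'   the smallest semi-axis).
#' @param csf_radius CSF core radius, mm.
#' @param tumor_center_offset tumor centre offset from the brain centre, mm.
#' @param enhancing_radius radius of the enhancing core, mm.
#' @param rim_width width of the non-enhancing rim, mm.
#' @param peak_fraction peak cell volume fraction of the enhancing core.
#' @param truth_spec ground-truth [model_spec()].
#' @param truth_params ground-truth [growth_params()].
#' @param visit_times days (must include 0).
#' @param schedules list with `rt`, `ct` ([build_standard_schedule()]).
#' @param cellularity a [cellularity_params()].
#' @param elasticity an [elasticity_params()].
#' @param noise_adc_sd relative (multiplicative Gaussian) ADC noise s.d.
#' @param noise_t1_sd relative T1 intensity noise s.d.
#' @param mask_threshold volume-fraction threshold deriving tumor masks from
#'   the noiseless fields.
#' @param t1_pre_level baseline pre-contrast T1 intensity (arbitrary units).
#' @param mechanics_stride mechanics re-solve cadence for the ground-truth
#'   simulation.
#' @param dt explicit integrator step in days, or `NULL` for the automatic
#'   stability-bounded step. Pin this when the same dataset will be
#'   recalibrated, so generator and calibration share one discretization.
#' @param seed RNG seed fixing every emitted array.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = image_grid(c(64, 64, 8), c(1, 1, 5)),
                           brain_semi_axes = c(28, 28, 17),
                           gm_thickness = 3,
                           csf_radius = 5,
                           tumor_center_offset = c(14, 6, 0),
                           enhancing_radius = 6,
                           rim_width = 4,
                           peak_fraction = 0.8,
                           truth_spec = model_spec("two_species", 8, "global"),
                           truth_params = growth_params("two_species"),
                           visit_times = c(0, 30, 90, 150),
                           schedules = build_standard_schedule(start_day = 1),
                           cellularity = cellularity_params(),
                           elasticity = elasticity_params(),
                           noise_adc_sd = 0.03,
                           noise_t1_sd = 0.02,
                           mask_threshold = 0.05,
                           t1_pre_level = 100,
                           mechanics_stride = 1L,
                           dt = NULL,
                           seed = 1L) {
  if (!(0 %in% visit_times)) stop("visit times must include the baseline 0")
  if (peak_fraction <= 0 || peak_fraction > 1)
    stop("peak fraction must be in (0, 1]")
  if (noise_adc_sd < 0 || noise_t1_sd < 0) stop("noise s.d. must be >= 0")
  structure(list(grid = grid, brain_semi_axes = brain_semi_axes,
                 gm_thickness = gm_thickness, csf_radius = csf_radius,
                 tumor_center_offset = tumor_center_offset,
                 enhancing_radius = enhancing_radius, rim_width = rim_width,
                 peak_fraction = peak_fraction, truth_spec = truth_spec,
                 truth_params = truth_params,
                 visit_times = sort(unique(as.numeric(visit_times))),
                 schedules = schedules, cellularity = cellularity,
                 elasticity = elasticity, noise_adc_sd = noise_adc_sd,
                 noise_t1_sd = noise_t1_sd, mask_threshold = mask_threshold,
                 t1_pre_level = t1_pre_level,
                 mechanics_stride = as.integer(mechanics_stride),
                 dt = dt,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

brain_center <- function(config) {
  config$grid$origin + (config$grid$shape - 1) * config$grid$spacing / 2
}

#' Build the phantom brain geometry
#'
#' Concentric ellipsoidal compartments: a CSF core at the brain centre, a
#' gray-matter shell at the brain surface, white matter in between. The
#' labels partition the brain mask.
#'
#' @param config a [phantom_config()].
#' @return list with `tissue_labels` (codes 0-3) and `brain_mask`.
#' @export
make_brain_phantom <- function(config) {
  g <- config$grid
  bc <- brain_center(config)
  ext_lo <- g$origin
  ext_hi <- g$origin + (g$shape - 1) * g$spacing
  for (ax in 1:3) {
    if (bc[ax] - config$brain_semi_axes[ax] < ext_lo[ax] - 1e-9 ||
        bc[ax] + config$brain_semi_axes[ax] > ext_hi[ax] + 1e-9)
      stop(sprintf("brain geometry exceeds the grid along axis %d", ax))
  }
  r <- ellipsoid_radius_field(g, bc, config$brain_semi_axes)
  brain <- r <= 1
  d_center <- distance_field(g, bc)
  labels <- array(TISSUE_CODES["background"], g$shape)
  labels[brain] <- TISSUE_CODES["white"]
  if (config$gm_thickness > 0) {
    gm_norm <- config$gm_thickness / min(config$brain_semi_axes)
    labels[brain & r > 1 - gm_norm] <- TISSUE_CODES["gray"]
  }
  if (config$csf_radius > 0)
    labels[brain & d_center <= config$csf_radius] <- TISSUE_CODES["csf"]
  list(tissue_labels = labels, brain_mask = brain)
}

## baseline tumor seed: truncated quadratic enhancing profile and a uniform
## 0.16 rim, restricted to brain parenchyma (white/gray). Truncation at the
## mask threshold makes the baseline enhancing mask equal the support of
## phi_E, so the imaging assignment rules reproduce this state exactly.
phantom_seed_fields <- function(config, tissue_labels, brain_mask) {
  g <- config$grid
  tc <- brain_center(config) + config$tumor_center_offset
  d <- distance_field(g, tc)
  allowed <- brain_mask & (tissue_labels == TISSUE_CODES["white"] |
                           tissue_labels == TISSUE_CODES["gray"])
  raw <- config$peak_fraction * pmax(0, 1 - (d / config$enhancing_radius)^2)
  phi_E <- ifelse(raw >= config$mask_threshold & allowed, raw, 0)
  rim <- allowed & (d <= config$enhancing_radius + config$rim_width) &
    (phi_E == 0)
  cp <- config$cellularity
  phi_N <- array(0, g$shape)
  phi_N[rim] <- cp$phi_fixed_nonenhancing
  ## radially decreasing perfusion surrogate: ER 2 at the core, 1 at the rim
  er <- array(1 + pmax(0, 1 - d / (config$enhancing_radius + config$rim_width)),
              g$shape)
  list(phi_E = array(phi_E, g$shape), phi_N = phi_N, er = er)
}

derive_masks <- function(state, threshold) {
  if (state$kind == "single") {
    e <- state$phi_T >= threshold
    list(enhancing = e, nonenhancing = array(FALSE, dim(state$phi_T)))
  } else {
    e <- state$phi_E >= threshold
    list(enhancing = e, nonenhancing = (state$phi_N >= threshold) & !e)
  }
}

## run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a virtual patient's longitudinal dataset
#'
#' Builds the baseline tumor state from the seed geometry, runs the
#' ground-truth model forward through the treatment schedule to every visit
#' time, converts each noiseless state to imaging: ADC by inverting the
#' cellularity mapping on the total tumor fraction (multiplicative Gaussian
#' noise of the configured s.d.), pre/post-contrast T1 realizing the
#' prescribed enhancement-ratio field (plus intensity noise), and tumor masks
#' by thresholding the noiseless fields.
#'
#' @param config a [phantom_config()].
#' @return list with `dataset` (a [patient_dataset()]) and `truth` (ground
#'   truth: `params`, `spec`, noiseless `states`, `er`, `tissue_labels`,
#'   `brain_mask`, `mech_op`).
#' @export
synthesize_visits <- function(config) {
  g <- config$grid
  geomr <- make_brain_phantom(config)
  labels <- geomr$tissue_labels
  brain <- geomr$brain_mask
  seed_f <- phantom_seed_fields(config, labels, brain)
  spec <- config$truth_spec
  params <- config$truth_params
  init <- if (spec$base == "single")
    tumor_state("single", 0, phi_T = seed_f$phi_E + seed_f$phi_N)
  else
    tumor_state("two_species", 0, phi_E = seed_f$phi_E, phi_N = seed_f$phi_N)

  geometry <- list(grid = g, tissue_labels = labels, brain_mask = brain)
  if (params$lambda1 > 0)
    geometry$mech_op <- build_mechanics_operator(g, labels, brain,
                                                 config$elasticity)
  settings <- simulation_settings(record_times = config$visit_times,
                                  dt = config$dt,
                                  mechanics_stride = config$mechanics_stride)
  states <- simulate_tumor(spec, params, init, config$schedules$rt,
                           config$schedules$ct, settings, geometry,
                           er = seed_f$er, elasticity = config$elasticity)

  cp <- config$cellularity
  visits <- with_seed(config$seed, lapply(seq_along(states), function(i) {
    st <- states[[i]]
    total <- state_total(st)
    adc <- adc_from_fraction(total, cp)
    if (config$noise_adc_sd > 0)
      adc <- adc * (1 + config$noise_adc_sd * array(stats::rnorm(prod(g$shape)),
                                                    g$shape))
    adc <- pmax(adc, 1e-6)
    t1_pre <- array(config$t1_pre_level, g$shape)
    t1_post <- seed_f$er * t1_pre
    if (config$noise_t1_sd > 0) {
      t1_pre <- pmax(t1_pre * (1 + config$noise_t1_sd *
                                 array(stats::rnorm(prod(g$shape)), g$shape)), 1e-3)
      t1_post <- pmax(t1_post * (1 + config$noise_t1_sd *
                                   array(stats::rnorm(prod(g$shape)), g$shape)), 1e-3)
    }
    m <- derive_masks(st, config$mask_threshold)
    imaging_visit(g, st$time, adc, t1_pre, t1_post,
                  m$enhancing & brain, m$nonenhancing & brain, brain, labels)
  }))
  dataset <- patient_dataset(sprintf("phantom-%d", config$seed), visits,
                             config$schedules$rt, config$schedules$ct)
  truth <- list(params = params, spec = spec, states = states,
                er = seed_f$er, tissue_labels = labels, brain_mask = brain,
                mech_op = geometry$mech_op, config = config)
  list(dataset = dataset, truth = truth)
}
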