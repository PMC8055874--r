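## Desk-scale phantom configurations shared across test files. The 32x32x4
## "small" phantom keeps the geometric structure of the default 64x64x8
## virtual patient (ellipsoidal brain with CSF core and gray shell, offset
## tumor with enhancing core + 0.16 rim) at a quarter of the voxel count.
## dt is pinned so generator and calibration share one discretization.
small_phantom_config <- function(seed = 7L, noise_adc_sd = 0,
                                 noise_t1_sd = 0, ...) {
  phantom_config(
    grid = image_grid(c(32, 32, 4), c(2, 2, 5)),
    brain_semi_axes = c(26, 26, 7), gm_thickness = 3, csf_radius = 4,
    tumor_center_offset = c(13, 5, 0), enhancing_radius = 6, rim_width = 4,
    visit_times = c(0, 30, 90), noise_adc_sd = noise_adc_sd,
    noise_t1_sd = noise_t1_sd, mechanics_stride = 5L, dt = 1,
    seed = seed, ...)
}

## an even smaller configuration for I/O and pipeline plumbing tests
tiny_phantom_config <- function(seed = 3L, ...) {
  phantom_config(
    grid = image_grid(c(16, 16, 4), c(2, 2, 5)),
    brain_semi_axes = c(13, 13, 7), gm_thickness = 2, csf_radius = 3,
    tumor_center_offset = c(5, 2, 0), enhancing_radius = 4, rim_width = 3,
    visit_times = c(0, 30, 60), noise_adc_sd = 0, noise_t1_sd = 0,
    mechanics_stride = 5L, dt = 1, seed = seed, ...)
}

## memoized syntheses (several files exercise the same virtual patient)
.synth_cache <- new.env(parent = emptyenv())

cached_synth <- function(key = "small", cfg = NULL) {
  if (is.null(.synth_cache[[key]])) {
    if (is.null(cfg))
      cfg <- switch(key, small = small_phantom_config(),
                    tiny = tiny_phantom_config(),
                    stop("unknown phantom cache key"))
    .synth_cache[[key]] <- synthesize_visits(cfg)
  }
  .synth_cache[[key]]
}

## tighter D bounds used by the recovery experiments: keeps the fixed 1-day
## (small grid) / 0.5-day (full grid) step inside the explicit stability
## bound for every admissible parameter vector
recovery_upper_bounds <- function() {
  c(D_E_w = 0.4, D_E_g = 0.4, D_N_w = 0.4, D_N_g = 0.4, D_w = 0.4,
    D_g = 0.4, k_pE = 0.5, k_pN = 0.5, k_p = 0.5, theta = 1, theta_E = 1,
    lambda1 = 10, sf_rt_min = 1, sf_ct_min = 1)
}

## the "x2 from truth" initial guess, clipped into the box (the optimizer
## nudges exact-bound starts strictly inside). Halving instead of clipping
## is catastrophic for the surviving fractions: ~100 treatment events at
## SF ~ 0.5 annihilate the tumor and flatten every other gradient.
perturbed_init <- function(truth, upper) {
  pmin(truth * 2, upper[names(truth)])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
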