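#' One co-registered imaging visit
#'
#' Bundles the four MRI-derived inputs of one scan session on a common grid:
#' the ADC map (mm^2/s, from diffusion-weighted imaging), pre- and
#' post-contrast T1-weighted intensities, the enhancing tumor mask (contrast
#' uptake on post-contrast T1), the non-enhancing clinical tumor volume mask
#' (non-enhancing T2-hyperintense region), the brain mask, and the tissue
#' label map.
#'
#' Tissue labels are integer-coded: 0 background, 1 white matter, 2 gray
#' matter, 3 CSF.
#'
#' @param grid an [image_grid()].
#' @param time days since baseline (>= 0).
#' @param adc ADC array, mm^2/s, > 0 inside the brain mask.
#' @param t1_pre,t1_post T1-weighted intensity arrays (>= 0, arbitrary units).
#' @param enhancing_mask,nonenhancing_mask,brain_mask logical arrays.
#' @param tissue_labels integer array with codes 0-3.
#' @return An object of class `imaging_visit`.
#' @export
imaging_visit <- function(grid, time, adc, t1_pre, t1_post,
                          enhancing_mask, nonenhancing_mask, brain_mask,
                          tissue_labels) {
  v <- structure(list(grid = grid, time = as.numeric(time), adc = adc,
                      t1_pre = t1_pre, t1_post = t1_post,
                      enhancing_mask = enhancing_mask,
                      nonenhancing_mask = nonenhancing_mask,
                      brain_mask = brain_mask, tissue_labels = tissue_labels),
                 class = "imaging_visit")
  validate_visit(v)
}

TISSUE_CODES <- c(background = 0L, white = 1L, gray = 2L, csf = 3L)

validate_visit <- function(v) {
  stopifnot(inherits(v$grid, "image_grid"))
  if (!is.finite(v$time) || v$time < 0) stop("visit time must be >= 0 days")
  for (nm in c("adc", "t1_pre", "t1_post", "enhancing_mask",
               "nonenhancing_mask", "brain_mask", "tissue_labels"))
    check_field(v[[nm]], v$grid, nm)
  em <- as.logical(v$enhancing_mask)
  nem <- as.logical(v$nonenhancing_mask)
  bm <- as.logical(v$brain_mask)
  if (any(em & nem))
    stop("enhancing and non-enhancing masks overlap")
  if (any(em & !bm) || any(nem & !bm))
    stop("tumor masks extend outside the brain mask")
  if (any(!is.finite(v$adc[bm])) || any(v$adc[bm] <= 0))
    stop("adc must be finite and > 0 inside the brain mask")
  if (!all(v$tissue_labels %in% TISSUE_CODES))
    stop("tissue_labels must use codes 0 (background), 1 (white), 2 (gray), 3 (csf)")
  invisible(v)
}

#' A patient's longitudinal dataset
#'
#' Ordered imaging visits (baseline at day 0, strictly increasing times) plus
#' the radiotherapy and chemotherapy schedules.
#'
#' @param patient_id character identifier.
#' @param visits list of [imaging_visit()] objects; sorted by time on
#'   construction.
#' @param rt_schedule,ct_schedule [treatment_schedule()] objects.
#' @return An object of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, visits, rt_schedule, ct_schedule) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (length(visits) < 2L)
    stop("need >= 2 visits (baseline + at least one follow-up)")
  times <- vapply(visits, function(v) v$time, numeric(1))
  visits <- visits[order(times)]
  times <- sort(times)
  if (any(diff(times) <= 0)) stop("visit times must be strictly increasing")
  if (times[1] != 0) stop("first visit must be the baseline at t = 0")
  g0 <- visits[[1]]$grid
  for (v in visits)
    if (!grids_equal(g0, v$grid)) stop("visits do not share one image grid")
  structure(list(patient_id = patient_id, visits = visits,
                 rt_schedule = rt_schedule, ct_schedule = ct_schedule),
            class = "patient_dataset")
}

visit_times <- function(dataset) {
  vapply(dataset$visits, function(v) v$time, numeric(1))
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset> %s: %d visits at days %s; %d RT / %d CT events\n",
              x$patient_id, length(x$visits),
              paste(visit_times(x), collapse = ", "),
              length(x$rt_schedule$days), length(x$ct_schedule$days)))
  invisible(x)
}
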