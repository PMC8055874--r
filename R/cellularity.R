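#' Cellularity-mapping parameters
#'
#' Parameters of the ADC-to-cell-volume-fraction mapping and the fixed
#' cellularity assigned inside the non-enhancing clinical tumor volume.
#'
#' The mapping assumes water mobility decreases as cell density increases:
#' phi = (ADC_w - ADC) / (ADC_w - ADC_min). `adc_w` is the apparent diffusion
#' coefficient of free water; the default 3.0e-3 mm^2/s corresponds to free
#' water at body temperature. `adc_min` is the minimum ADC attributed to
#' maximally packed tumor tissue; by convention it is taken as the minimum
#' ADC measured over the tumor voxels of a patient (a per-patient choice;
#' pass an explicit value to override).
#'
#' @param adc_w ADC of free water, mm^2/s.
#' @param adc_min minimum (maximum-cellularity) ADC, mm^2/s; must be < adc_w.
#' @param phi_fixed_nonenhancing cell volume fraction assigned uniformly
#'   inside the non-enhancing clinical tumor volume (default 0.16).
#' @return An object of class `cellularity_params`.
#' @export
cellularity_params <- function(adc_w = 3.0e-3, adc_min = 0.6e-3,
                               phi_fixed_nonenhancing = 0.16) {
  if (!is.finite(adc_w) || !is.finite(adc_min) || adc_min <= 0 ||
      adc_w <= adc_min)
    stop("invalid parameters: need adc_w > adc_min > 0")
  if (!is.finite(phi_fixed_nonenhancing) || phi_fixed_nonenhancing <= 0 ||
      phi_fixed_nonenhancing >= 1)
    stop("invalid parameters: phi_fixed_nonenhancing must be in (0, 1)")
  structure(list(adc_w = adc_w, adc_min = adc_min,
                 phi_fixed_nonenhancing = phi_fixed_nonenhancing),
            class = "cellularity_params")
}

#' Estimate tumor cell volume fraction from an ADC map
#'
#' Applies phi = (ADC_w - ADC) / (ADC_w - ADC_min) inside `mask`, clamped to
#' the physical range [0, 1] (ADC above free water would otherwise give a
#' negative fraction). Voxels outside `mask` are set to 0.
#'
#' @param adc 3-D ADC array, mm^2/s; finite and > 0 inside `mask`.
#' @param params a [cellularity_params()] object.
#' @param mask logical 3-D array of voxels where the mapping applies.
#' @return numeric 3-D array of cell volume fractions in [0, 1].
#' @export
estimate_cell_fraction <- function(adc, params, mask) {
  stopifnot(inherits(params, "cellularity_params"))
  if (!identical(dim(adc), dim(mask)))
    stop("adc and mask dimensions differ")
  m <- as.logical(mask)
  if (!any(m)) {
    warning("empty mask: returning an all-zero field")
    return(array(0, dim(adc)))
  }
  v <- adc[m]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("adc must be finite and > 0 inside the mask")
  phi <- array(0, dim(adc))
  phi[m] <- pmin(1, pmax(0, (params$adc_w - v) / (params$adc_w - params$adc_min)))
  phi
}

## inverse of the ADC mapping, used by the phantom generator
adc_from_fraction <- function(phi, params) {
  params$adc_w - phi * (params$adc_w - params$adc_min)
}

#' Compute the voxelwise enhancement ratio
#'
#' ER = post-contrast T1 / pre-contrast T1, bounded between 1 and 2; a
#' perfusion surrogate (contrast uptake indicates blood-tumor-barrier
#' breakdown). Set to 1 outside `mask`.
#'
#' @param t1_post,t1_pre 3-D intensity arrays (arbitrary units).
#' @param mask logical 3-D array; `t1_pre` must be > 0 inside it.
#' @return numeric 3-D array with values in [1, 2].
#' @export
compute_enhancement_ratio <- function(t1_post, t1_pre, mask) {
  if (!identical(dim(t1_post), dim(t1_pre)) ||
      !identical(dim(t1_post), dim(mask)))
    stop("t1_post, t1_pre, mask dimensions differ")
  m <- as.logical(mask)
  nzero <- sum(m & (!is.finite(t1_pre) | t1_pre <= 0))
  if (nzero > 0)
    stop(sprintf("t1_pre is zero or non-finite at %d in-mask voxel(s); cannot form the ratio",
                 nzero))
  er <- array(1, dim(t1_post))
  er[m] <- pmin(2, pmax(1, t1_post[m] / t1_pre[m]))
  er
}

#' Tumor state on the image grid
#'
#' A `tumor_state` holds the volume-fraction field(s) at one time: `phi_T`
#' for the single-species model, or `phi_E` (enhancing) and `phi_N`
#' (non-enhancing) for the two-species model. Fractions lie in [0, 1] and are
#' zero outside the brain.
#'
#' @param kind `"single"` or `"two_species"`.
#' @param time days since baseline.
#' @param phi_T,phi_E,phi_N 3-D volume-fraction arrays.
#' @return An object of class `tumor_state`.
#' @export
tumor_state <- function(kind, time, phi_T = NULL, phi_E = NULL, phi_N = NULL) {
  kind <- match.arg(kind, c("single", "two_species"))
  st <- if (kind == "single") {
    stopifnot(!is.null(phi_T))
    list(kind = kind, time = time, phi_T = phi_T)
  } else {
    stopifnot(!is.null(phi_E), !is.null(phi_N))
    list(kind = kind, time = time, phi_E = phi_E, phi_N = phi_N)
  }
  structure(st, class = "tumor_state")
}

state_fields <- function(state) {
  if (state$kind == "single") list(phi_T = state$phi_T)
  else list(phi_E = state$phi_E, phi_N = state$phi_N)
}

state_total <- function(state) {
  if (state$kind == "single") state$phi_T else state$phi_E + state$phi_N
}

validate_tumor_state <- function(state, brain_mask = NULL) {
  for (nm in names(state_fields(state))) {
    f <- state[[nm]]
    if (any(!is.finite(f))) stop(nm, " contains non-finite values")
    if (min(f) < 0 || max(f) > 1) stop(nm, " outside [0, 1]")
    if (!is.null(brain_mask) && any(f[!brain_mask] != 0))
      stop(nm, " is nonzero outside the brain mask")
  }
  invisible(state)
}

#' Build the model initial condition from an imaging visit
#'
#' Region-assignment rules: inside the enhancing tumor volume the cell
#' fraction is estimated from ADC via [estimate_cell_fraction()]; inside the
#' non-enhancing clinical tumor volume it is assigned the fixed value
#' `params$phi_fixed_nonenhancing` (default 0.16); it is zero elsewhere. For
#' the two-species model the ADC-derived fraction initializes `phi_E` (zero
#' outside the enhancing region) and the fixed value initializes `phi_N`
#' (zero outside the non-enhancing region), so the two species start on
#' disjoint supports.
#'
#' An alternative assignment (`nonenhancing = "decay"`) replaces the fixed
#' rim value with a linear decay, from the mean ADC-derived fraction on the
#' enhancing interface down to `decay_periphery` at the voxel most distant
#' from the enhancing region.
#'
#' @param visit an `imaging_visit` (see [read_dataset()] / [phantom_config()]).
#' @param kind `"single"` or `"two_species"`.
#' @param params a [cellularity_params()] object.
#' @param nonenhancing `"fixed"` (default) or `"decay"`.
#' @param decay_periphery peripheral fraction for the decay mode.
#' @return a [tumor_state()] at the visit time.
#' @export
assign_initial_state <- function(visit, kind = c("single", "two_species"),
                                 params = cellularity_params(),
                                 nonenhancing = c("fixed", "decay"),
                                 decay_periphery = 0.02) {
  kind <- match.arg(kind)
  nonenhancing <- match.arg(nonenhancing)
  em <- visit$enhancing_mask
  nm <- visit$nonenhancing_mask
  if (any(em & nm))
    stop("enhancing and non-enhancing masks overlap: invariant violation")
  phi_e <- if (any(em)) estimate_cell_fraction(visit$adc, params, em)
           else array(0, dim(em))
  phi_n <- array(0, dim(nm))
  if (nonenhancing == "fixed") {
    phi_n[nm] <- params$phi_fixed_nonenhancing
  } else if (any(nm)) {
    ## linear decay with distance from the enhancing region
    d_if <- distance_to_mask(nm, em, visit$grid)
    dmax <- max(d_if)
    iface_val <- if (any(em)) mean(phi_e[em]) else params$phi_fixed_nonenhancing
    w <- if (dmax > 0) d_if / dmax else 0
    phi_n[nm] <- iface_val * (1 - w[nm]) + decay_periphery * w[nm]
  }
  if (kind == "single") {
    tumor_state("single", visit$time, phi_T = phi_e + phi_n)
  } else {
    tumor_state("two_species", visit$time, phi_E = phi_e, phi_N = phi_n)
  }
}

## euclidean distance (mm) from each TRUE voxel of `from` to the nearest TRUE
## voxel of `to`; zero elsewhere. Brute force over mask voxels (masks are
## small relative to the grid).
distance_to_mask <- function(from, to, grid) {
  out <- array(0, dim(from))
  if (!any(from) || !any(to)) return(out)
  idx_f <- which(from, arr.ind = TRUE)
  idx_t <- which(to, arr.ind = TRUE)
  pf <- sweep(idx_f - 1, 2, grid$spacing, "*")
  pt <- sweep(idx_t - 1, 2, grid$spacing, "*")
  ## chunk to bound memory
  step <- max(1L, floor(2e6 / nrow(pt)))
  dmin <- numeric(nrow(pf))
  for (s in seq(1L, nrow(pf), by = step)) {
    e <- min(nrow(pf), s + step - 1L)
    d2 <- outer(rowSums(pf[s:e, , drop = FALSE]^2), rep(1, nrow(pt))) +
      outer(rep(1, e - s + 1L), rowSums(pt^2)) -
      2 * pf[s:e, , drop = FALSE] %*% t(pt)
    dmin[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out[from] <- dmin
  out
}
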