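#' Akaike information criterion for a least-squares fit
#'
#' Gaussian-residual form: AIC = n ln(SSE/n) + 2 (k + 1), counting the
#' residual variance as one estimated parameter alongside the k model
#' parameters. Set `corrected = TRUE` for the small-sample AICc variant.
#'
#' @param sse residual sum of squares (> 0).
#' @param n_obs number of residuals (> n_params).
#' @param n_params number of calibrated model parameters (>= 1).
#' @param corrected apply the AICc small-sample correction.
#' @return AIC value.
#' @export
compute_aic <- function(sse, n_obs, n_params, corrected = FALSE) {
  if (!is.finite(sse) || sse < 0) stop("sse must be finite and >= 0")
  if (sse == 0)
    stop("sse is exactly 0: AIC diverges; add an epsilon floor to the SSE")
  if (n_params < 1 || n_obs <= n_params)
    stop("need n_obs > n_params >= 1")
  k <- n_params + 1
  aic <- n_obs * log(sse / n_obs) + 2 * k
  if (corrected) aic <- aic + 2 * k * (k + 1) / max(n_obs - k - 1, 1)
  aic
}

#' Rank a model family by mean AIC across patients
#'
#' Models are ordered by ascending arithmetic-mean AIC over patients; ties
#' are broken by fewer parameters, then by model id. Models with any
#' non-finite AIC are excluded with a warning.
#'
#' @param aic_matrix numeric matrix, models x patients, with rownames naming
#'   the models.
#' @param n_params optional integer vector of parameter counts per model
#'   (tie-breaking); defaults to zero for all.
#' @return data.frame with columns `model`, `mean_aic`, `rank`, ordered by
#'   rank.
#' @export
rank_models <- function(aic_matrix, n_params = NULL) {
  stopifnot(is.matrix(aic_matrix), !is.null(rownames(aic_matrix)))
  if (is.null(n_params)) n_params <- rep(0L, nrow(aic_matrix))
  ok <- apply(aic_matrix, 1, function(r) all(is.finite(r)))
  if (!all(ok)) {
    warning(sprintf("excluding %d model(s) with non-finite AIC: %s",
                    sum(!ok), paste(rownames(aic_matrix)[!ok], collapse = ", ")))
    aic_matrix <- aic_matrix[ok, , drop = FALSE]
    n_params <- n_params[ok]
  }
  mean_aic <- rowMeans(aic_matrix)
  o <- order(mean_aic, n_params, rownames(aic_matrix))
  data.frame(model = rownames(aic_matrix)[o],
             mean_aic = mean_aic[o],
             n_params = n_params[o],
             rank = seq_along(o),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap and agreement metrics
#'
#' `dice()` computes 2|A n B| / (|A| + |B|); two empty masks are defined as
#' perfect (vacuous) agreement, 1, with a warning. `percent_volume_error()`
#' is the signed percent error 100 (pred - meas)/meas. `voxel_agreement()`
#' returns the Pearson correlation coefficient and Lin's concordance
#' correlation coefficient CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean_x -
#' mean_y)^2) over in-mask voxels (population moments); CCC penalizes
#' location/scale shifts, so |CCC| <= |PCC|. `kcc()` is the Kendall rank
#' correlation (tau-b, tie-corrected).
#'
#' @param mask_a,mask_b logical arrays on one grid.
#' @return `dice()`: value in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask grids differ")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    warning("both masks empty: Dice defined as 1 (vacuous agreement)")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice
#' @param pred_volume,meas_volume predicted and measured volumes (mm^3);
#'   `meas_volume` must be > 0.
#' @return `percent_volume_error()`: signed percent.
#' @export
percent_volume_error <- function(pred_volume, meas_volume) {
  if (!is.finite(meas_volume) || meas_volume <= 0)
    stop("measured volume must be > 0")
  100 * (pred_volume - meas_volume) / meas_volume
}

#' @rdname dice
#' @param pred_field,meas_field numeric arrays.
#' @param mask logical array (>= 3 in-mask voxels, nonzero variance in both).
#' @return `voxel_agreement()`: list with `pcc` and `ccc`.
#' @export
voxel_agreement <- function(pred_field, meas_field, mask) {
  m <- as.logical(mask)
  if (sum(m) < 3) stop("need >= 3 in-mask voxels")
  x <- pred_field[m]; y <- meas_field[m]
  if (stats::var(x) == 0) stop("undefined metric: predicted field has zero variance in mask")
  if (stats::var(y) == 0) stop("undefined metric: measured field has zero variance in mask")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  list(pcc = stats::cor(x, y),
       ccc = 2 * sxy / (sx2 + sy2 + (mx - my)^2))
}

#' @rdname dice
#' @param x,y numeric vectors of equal length >= 2.
#' @return `kcc()`: Kendall tau-b in [-1, 1].
#' @export
kcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need equal lengths >= 2")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined metric: all values tied")
  stats::cor(x, y, method = "kendall")
}

#' Total cell burden of a state
#'
#' Sum over voxels of the (total) volume fraction times the voxel volume: a
#' relative cellularity measure, valid for rank comparisons of predicted vs
#' measured cell counts.
#'
#' @param state a [tumor_state()].
#' @param grid an [image_grid()].
#' @return scalar, relative cellularity units (fraction * mm^3).
#' @export
cell_count <- function(state, grid) {
  sum(state_total(state)) * voxel_volume(grid)
}

measured_region_masks <- function(visit) {
  d <- dim(visit$enhancing_mask)
  list(enhancing = array(as.logical(visit$enhancing_mask), d),
       nonenhancing = array(as.logical(visit$nonenhancing_mask), d),
       total = array(as.logical(visit$enhancing_mask) |
                       as.logical(visit$nonenhancing_mask), d))
}

predicted_region_masks <- function(state, threshold) {
  if (state$kind == "single") {
    tot <- state$phi_T >= threshold
    list(enhancing = tot, nonenhancing = array(FALSE, dim(state$phi_T)),
         total = tot)
  } else {
    e <- state$phi_E >= threshold
    n <- (state$phi_N >= threshold) & !e
    list(enhancing = e, nonenhancing = n, total = e | n)
  }
}

#' Evaluate predicted states against measured visits
#'
#' For each predicted state aligned (by time) with a measured visit, computes
#' global metrics per region (enhancing, non-enhancing, total) - percent
#' volume error and Dice between the thresholded predicted field and the
#' measured mask - and local voxel-level agreement (PCC, CCC of predicted vs
#' measured cellularity over the union of predicted and measured tumor
#' masks). Across visits, Kendall rank correlations of predicted vs measured
#' volumes and cell counts summarize trend agreement (reported when >= 2
#' visits align).
#'
#' @param predicted list of [tumor_state()] objects.
#' @param dataset a [patient_dataset()].
#' @param params a [cellularity_params()] (measured-map construction).
#' @param threshold volume-fraction threshold defining predicted masks
#'   (default 0.05, consistent with the phantom's mask derivation).
#' @param time_tol visit/state alignment tolerance, days.
#' @return An `error_report`: list with `metrics` (long data.frame: time,
#'   region, metric, value) and `summary` (KCC of volumes and cell counts).
#' @export
evaluate_predictions <- function(predicted, dataset,
                                 params = cellularity_params(),
                                 threshold = 0.05, time_tol = 0.51) {
  times_p <- vapply(predicted, function(s) s$time, numeric(1))
  times_m <- visit_times(dataset)
  pairs <- list()
  for (i in seq_along(times_p)) {
    j <- which(abs(times_m - times_p[i]) <= time_tol)
    if (length(j)) pairs[[length(pairs) + 1L]] <- c(i, j[1])
  }
  if (!length(pairs)) stop("no predicted states align with measured visits")
  grid <- dataset$visits[[1]]$grid
  vv <- voxel_volume(grid)
  rows <- list()
  vol_p <- vol_m <- cc_p <- cc_m <- numeric(0)
  for (pr in pairs) {
    st <- predicted[[pr[1]]]
    vis <- dataset$visits[[pr[2]]]
    pm <- predicted_region_masks(st, threshold)
    mm <- measured_region_masks(vis)
    meas_state <- assign_initial_state(vis, st$kind, params)
    for (rg in names(mm)) {
      if (st$kind == "single" && rg != "total") next
      pv <- sum(pm[[rg]]) * vv
      mv <- sum(mm[[rg]]) * vv
      rows[[length(rows) + 1L]] <- data.frame(
        time = vis$time, region = rg,
        metric = c("percent_volume_error", "dice"),
        value = c(if (mv > 0) percent_volume_error(pv, mv) else NA_real_,
                  dice(pm[[rg]], mm[[rg]])))
    }
    um <- pm$total | mm$total
    ag <- tryCatch(voxel_agreement(state_total(st), state_total(meas_state), um),
                   error = function(e) list(pcc = NA_real_, ccc = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      time = vis$time, region = "total",
      metric = c("pcc", "ccc"), value = c(ag$pcc, ag$ccc))
    vol_p <- c(vol_p, sum(pm$total) * vv)
    vol_m <- c(vol_m, sum(mm$total) * vv)
    cc_p <- c(cc_p, cell_count(st, grid))
    cc_m <- c(cc_m, cell_count(meas_state, grid))
  }
  summary <- list(
    kcc_volume = if (length(vol_p) >= 2)
      tryCatch(kcc(vol_p, vol_m), error = function(e) NA_real_) else NA_real_,
    kcc_cell_count = if (length(cc_p) >= 2)
      tryCatch(kcc(cc_p, cc_m), error = function(e) NA_real_) else NA_real_)
  structure(list(metrics = do.call(rbind, rows), summary = summary,
                 threshold = threshold),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report>\n")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("KCC volume: %.3f, KCC cell count: %.3f\n",
              x$summary$kcc_volume, x$summary$kcc_cell_count))
  invisible(x)
}
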