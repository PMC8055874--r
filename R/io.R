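REQUIRED_VISIT_KEYS <- c("time_days", "adc", "t1_pre", "t1_post",
                         "enhancing_mask", "nonenhancing_mask", "brain_mask",
                         "tissue_labels")

#' Write a patient dataset to disk
#'
#' One NIfTI volume per sequence/mask per visit plus a JSON manifest listing
#' visit times, file names, treatment schedules, and the grid origin. Voxel
#' spacing travels in the NIfTI headers; continuous fields are stored as
#' float64 and masks/labels as uint8, so a write/read round trip reproduces
#' every array bit-exactly.
#'
#' @param dataset a [patient_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- dataset$visits[[1]]$grid
  manifest <- list(patient_id = dataset$patient_id,
                   origin_mm = g$origin,
                   rt_schedule = list(days = dataset$rt_schedule$days,
                                      dose = dataset$rt_schedule$dose),
                   ct_schedule = list(days = dataset$ct_schedule$days,
                                      dose = dataset$ct_schedule$dose),
                   visits = list())
  for (i in seq_along(dataset$visits)) {
    v <- dataset$visits[[i]]
    entry <- list(time_days = v$time)
    for (key in setdiff(REQUIRED_VISIT_KEYS, "time_days")) {
      fname <- sprintf("visit%02d_%s.nii.gz", i, key)
      arr <- v[[key]]
      dt <- if (key %in% c("adc", "t1_pre", "t1_post")) "double" else "uint8"
      img <- RNifti::asNifti(arr + 0) # coerce logical to numeric
      RNifti::pixdim(img) <- g$spacing
      RNifti::writeNifti(img, file.path(dir, fname), datatype = dt)
      entry[[key]] <- fname
    }
    manifest$visits[[i]] <- entry
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Read a patient dataset from a manifest
#'
#' Accepts a JSON or YAML manifest (see [write_dataset()]). Visits are
#' returned sorted by time; all volumes are validated against a single image
#' grid, with errors naming the offending volume or the missing manifest
#' keys.
#'
#' @param manifest_path path to `manifest.json` (or `.yaml`).
#' @return a [patient_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  origin <- if (!is.null(man$origin_mm)) as.numeric(unlist(man$origin_mm))
            else c(0, 0, 0)
  vis_list <- man$visits
  if (length(vis_list) == 0) stop("manifest lists no visits")
  grid <- NULL
  visits <- lapply(seq_along(vis_list), function(i) {
    entry <- vis_list[[i]]
    missing_keys <- setdiff(REQUIRED_VISIT_KEYS, names(entry))
    missing_keys <- c(missing_keys,
                      names(entry)[vapply(entry, function(x)
                        length(x) == 1 && is.na(x), logical(1))])
    missing_keys <- intersect(unique(missing_keys), REQUIRED_VISIT_KEYS)
    if (length(missing_keys))
      stop(sprintf("visit %d is missing required key(s): %s", i,
                   paste(missing_keys, collapse = ", ")))
    vols <- list()
    for (key in setdiff(REQUIRED_VISIT_KEYS, "time_days")) {
      f <- file.path(dir, entry[[key]])
      if (!file.exists(f))
        stop(sprintf("visit %d: file not found for '%s': %s", i, key, f))
      img <- RNifti::readNifti(f)
      sp <- RNifti::pixdim(img)[1:3]
      arr <- array(as.numeric(img), dim(img)[1:3])
      this_grid <- image_grid(dim(arr), sp, origin)
      if (is.null(grid)) grid <<- this_grid
      else if (!grids_equal(grid, this_grid))
        stop(sprintf("grid mismatch in volume '%s' of visit %d: %s vs %s",
                     entry[[key]], i, format(this_grid), format(grid)))
      vols[[key]] <- arr
    }
    imaging_visit(grid, as.numeric(entry$time_days), vols$adc, vols$t1_pre,
                  vols$t1_post,
                  array(vols$enhancing_mask > 0, grid$shape),
                  array(vols$nonenhancing_mask > 0, grid$shape),
                  array(vols$brain_mask > 0, grid$shape),
                  array(as.integer(vols$tissue_labels), grid$shape))
  })
  rt <- treatment_schedule("RT", as.numeric(unlist(man$rt_schedule$days)),
                           as.numeric(unlist(man$rt_schedule$dose)))
  ct <- treatment_schedule("CT", as.numeric(unlist(man$ct_schedule$days)),
                           as.numeric(unlist(man$ct_schedule$dose)))
  patient_dataset(man$patient_id, visits, rt, ct)
}

#' Per-visit scalar summaries
#'
#' @param dataset a [patient_dataset()].
#' @param path optional CSV output path.
#' @param params a [cellularity_params()].
#' @return data.frame with one row per visit: time, region volumes (mm^3),
#'   and measured cell counts.
#' @export
visit_summary <- function(dataset, path = NULL,
                          params = cellularity_params()) {
  g <- dataset$visits[[1]]$grid
  vv <- voxel_volume(g)
  rows <- lapply(dataset$visits, function(v) {
    st <- assign_initial_state(v, "two_species", params)
    data.frame(time_days = v$time,
               enhancing_volume_mm3 = sum(v$enhancing_mask) * vv,
               nonenhancing_volume_mm3 = sum(v$nonenhancing_mask) * vv,
               cell_count = cell_count(st, g))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Export a simulated trajectory as NIfTI volumes
#'
#' @param states list of [tumor_state()] objects.
#' @param grid the [image_grid()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return data.frame of per-state total fraction-mass summaries, invisibly
#'   written alongside as `<prefix>_summary.csv`.
#' @export
write_trajectory <- function(states, grid, dir, prefix = "state") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (i in seq_along(states)) {
    st <- states[[i]]
    for (nm in names(state_fields(st))) {
      img <- RNifti::asNifti(st[[nm]])
      RNifti::pixdim(img) <- grid$spacing
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_%03d_%s.nii.gz",
                                                     prefix, i, nm)),
                         datatype = "double")
    }
    rows[[i]] <- data.frame(index = i, time_days = st$time,
                            cell_count = cell_count(st, grid))
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(dir, paste0(prefix, "_summary.csv")),
                   row.names = FALSE)
  invisible(out)
}
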