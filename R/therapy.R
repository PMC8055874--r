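#' Treatment schedule
#'
#' Days on which a therapy is delivered. Dose metadata (Gy per RT fraction,
#' mg/kg per CT administration) is informational: treatment efficacy enters
#' the model only through the surviving-fraction parameters.
#'
#' @param kind `"RT"` or `"CT"`.
#' @param days numeric vector of event days (unique; sorted on construction).
#' @param dose per-event dose metadata (scalar, recycled).
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(kind = c("RT", "CT"), days, dose = NA_real_) {
  kind <- match.arg(kind)
  days <- as.numeric(days)
  if (anyDuplicated(days)) stop("treatment days must be unique per therapy")
  o <- order(days)
  structure(list(kind = kind, days = days[o],
                 dose = rep_len(as.numeric(dose), length(days))[o]),
            class = "treatment_schedule")
}

#' Standard-of-care chemoradiation schedule
#'
#' Radiotherapy delivered per weekday (5 fractions/week) for `weeks` weeks at
#' `fraction_gy` per fraction (defaults: 6 weeks x 2 Gy = 60 Gy total),
#' concurrently with daily chemotherapy (temozolomide) over the full
#' radiotherapy window, followed by adjuvant chemotherapy given on the first
#' 5 days of each 28-day cycle.
#'
#' @param start_day day of the first RT fraction (a Monday by convention).
#' @param weeks number of RT weeks.
#' @param fraction_gy dose per RT fraction, Gy.
#' @param concurrent_ct_dose daily concurrent CT dose metadata, mg/kg.
#' @param adjuvant_cycles number of 28-day adjuvant CT cycles (default 6).
#' @param adjuvant_gap_days days between the last concurrent CT day and the
#'   first adjuvant cycle.
#' @param adjuvant_dose adjuvant CT dose metadata, mg/kg.
#' @return list with elements `rt` and `ct`, both [treatment_schedule()].
#' @export
#' @examples
#' sched <- build_standard_schedule()
#' length(sched$rt$days)    # 30 fractions
#' sum(sched$rt$dose)       # 60 Gy
build_standard_schedule <- function(start_day = 1, weeks = 6, fraction_gy = 2,
                                    concurrent_ct_dose = 75,
                                    adjuvant_cycles = 6,
                                    adjuvant_gap_days = 28,
                                    adjuvant_dose = 150) {
  stopifnot(weeks >= 1)
  rt_days <- as.vector(outer(0:4, seq_len(weeks) * 7 - 7, "+")) + start_day
  rt <- treatment_schedule("RT", sort(rt_days), dose = fraction_gy)
  conc_days <- start_day + 0:(7 * weeks - 1)
  adj_days <- numeric(0)
  if (adjuvant_cycles > 0) {
    adj_start <- max(conc_days) + adjuvant_gap_days
    adj_days <- as.vector(outer(0:4, (seq_len(adjuvant_cycles) - 1) * 28, "+")) +
      adj_start
  }
  ct <- treatment_schedule("CT", c(conc_days, sort(adj_days)),
                           dose = c(rep(concurrent_ct_dose, length(conc_days)),
                                    rep(adjuvant_dose, length(adj_days))))
  list(rt = rt, ct = ct)
}

#' Treatment efficacy coupling and the model family
#'
#' Four approaches (C1-C4) spatially vary the surviving fraction of a therapy
#' between its minimum `sf_min` and 1:
#' \itemize{
#' \item C1: SF = sf_min + (1 - sf_min) (1 - phi/theta). Cells near the
#'   carrying capacity proliferate slowly and are less susceptible, so
#'   efficacy decreases with occupancy.
#' \item C2: SF = sf_min + ((1 - sf_min)/0.5) (1/ER - 0.5). Efficacy falls in
#'   poorly perfused regions; ER is the enhancement ratio in [1, 2].
#' \item C3: SF = sf_min + ((1 - sf_min)/0.5) (1 - ER/2). A linear-in-ER
#'   variant of C2.
#' \item C4: SF = sf_min uniformly throughout the tumor.
#' }
#' Ten (RT, CT) combinations are evaluated: combinations 1-3 apply C1-C3 to
#' RT with C4 for CT; 4-6 apply C1-C3 to CT with C4 for RT; 7-10 apply
#' C1-C4 to both. Crossed with two base models (single, two-species) and two
#' proliferation parameterizations (global scalar or voxelwise field), this
#' yields the 40-member model family.
#'
#' @return `enumerate_coupling_combinations()`: a list of 10 `coupling_spec`
#'   objects (fields `id`, `rt`, `ct`).
#' @export
enumerate_coupling_combinations <- function() {
  pairs <- list(c("C1", "C4"), c("C2", "C4"), c("C3", "C4"),
                c("C4", "C1"), c("C4", "C2"), c("C4", "C3"),
                c("C1", "C1"), c("C2", "C2"), c("C3", "C3"), c("C4", "C4"))
  lapply(seq_along(pairs), function(i) {
    structure(list(id = i, rt = pairs[[i]][1], ct = pairs[[i]][2]),
              class = "coupling_spec")
  })
}

#' @rdname enumerate_coupling_combinations
#' @param base `"single"` or `"two_species"`.
#' @param combination coupling combination id, 1-10.
#' @param proliferation `"global"` or `"field"`.
#' @return `model_spec()`: one family member, class `model_spec`.
#' @export
model_spec <- function(base = c("single", "two_species"), combination = 10,
                       proliferation = c("global", "field")) {
  base <- match.arg(base)
  proliferation <- match.arg(proliferation)
  combos <- enumerate_coupling_combinations()
  if (!(combination %in% 1:10)) stop("combination id must be in 1..10")
  structure(list(base = base, coupling = combos[[combination]],
                 proliferation = proliferation,
                 id = sprintf("%s_c%02d_%s", base, combination, proliferation)),
            class = "model_spec")
}

#' @rdname enumerate_coupling_combinations
#' @return `build_model_family()`: list of the 40 `model_spec` objects.
#' @export
build_model_family <- function() {
  out <- list()
  for (base in c("single", "two_species"))
    for (cid in 1:10)
      for (prolif in c("global", "field"))
        out[[length(out) + 1L]] <- model_spec(base, cid, prolif)
  out
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, coupling %d (RT:%s, CT:%s), %s proliferation\n",
              x$base, x$coupling$id, x$coupling$rt, x$coupling$ct,
              x$proliferation))
  invisible(x)
}

#' Spatially varying surviving fraction
#'
#' Evaluates one coupling approach (see
#' [enumerate_coupling_combinations()]) as a field. Outside `mask` (where no
#' tumor is present the factor is vacuous) SF is set to 1.
#'
#' @param approach `"C1"`, `"C2"`, `"C3"`, or `"C4"`.
#' @param sf_min minimum surviving fraction, in (0, 1].
#' @param phi occupancy field used by C1 (total tumor fraction).
#' @param theta carrying capacity used by C1.
#' @param er enhancement-ratio field in [1, 2], used by C2/C3.
#' @param mask logical array delimiting where the therapy acts (default:
#'   phi > 0 where `phi` is given, otherwise everywhere).
#' @return surviving-fraction array with in-mask values in [sf_min, 1].
#' @export
surviving_fraction <- function(approach, sf_min, phi = NULL, theta = NULL,
                               er = NULL, mask = NULL) {
  approach <- match.arg(approach, c("C1", "C2", "C3", "C4"))
  if (!is.finite(sf_min) || sf_min <= 0 || sf_min > 1)
    stop("sf_min must be in (0, 1]")
  ref <- if (!is.null(phi)) phi else er
  if (is.null(ref)) stop("need phi (C1) or er (C2/C3) to shape the field")
  if (is.null(mask)) mask <- if (!is.null(phi)) phi > 0 else array(TRUE, dim(er))
  sf <- array(1, dim(ref))
  m <- as.logical(mask)
  if (!any(m)) return(sf)
  val <- switch(approach,
    C1 = {
      if (is.null(phi) || is.null(theta)) stop("C1 needs phi and theta")
      if (max(phi[m]) > theta + 1e-12) stop("phi exceeds theta: invariant violation")
      sf_min + (1 - sf_min) * (1 - phi[m] / theta)
    },
    C2 = {
      check_er(er, m)
      sf_min + ((1 - sf_min) / 0.5) * (1 / er[m] - 0.5)
    },
    C3 = {
      check_er(er, m)
      sf_min + ((1 - sf_min) / 0.5) * (1 - er[m] / 2)
    },
    C4 = rep(sf_min, sum(m))
  )
  ## guard rounding at the endpoints
  sf[m] <- pmin(1, pmax(sf_min, val))
  sf
}

check_er <- function(er, m) {
  if (is.null(er)) stop("C2/C3 need the enhancement-ratio field")
  if (min(er[m]) < 1 - 1e-12 || max(er[m]) > 2 + 1e-12)
    stop("ER outside [1, 2]: clamp upstream with compute_enhancement_ratio()")
  invisible(er)
}

#' Apply an instantaneous treatment event
#'
#' The state is reduced multiplicatively: phi_post = phi_pre * SF_RT * SF_CT
#' voxelwise, applied to `phi_T` (single species) or to both `phi_E` and
#' `phi_N` (two species). Pass an all-ones field (or `NULL`) for a therapy
#' not delivered that day.
#'
#' @param state a [tumor_state()].
#' @param sf_rt,sf_ct surviving-fraction arrays in [0, 1] (or `NULL` for 1).
#' @return the post-treatment [tumor_state()].
#' @export
apply_treatment <- function(state, sf_rt = NULL, sf_ct = NULL) {
  f <- 1
  for (sf in list(sf_rt, sf_ct)) {
    if (is.null(sf)) next
    if (min(sf) < 0 || max(sf) > 1)
      stop("surviving fraction outside [0, 1]: invariant violation")
    f <- f * sf
  }
  for (nm in names(state_fields(state))) state[[nm]] <- state[[nm]] * f
  state
}
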