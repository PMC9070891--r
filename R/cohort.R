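#' State distribution at the end of the initial CBT phase
#'
#' When the low-intensity programme ends, the cohort (all mild at entry)
#' redistributes over well, mild, moderate and severe according to the
#' programme-level recovery and deterioration probabilities. Two strata are
#' mixed: the effective stratum (accepted and adhered, weight
#' `p_effective`) receives the low-intensity CBT rates (times the i-CBT
#' relative differences in that arm); everyone else receives the
#' no-intervention rates. The deterioration mass is split between moderate
#' and severe by `cfg$deterioration_split_rule`.
#'
#' @param values Named numeric vector of point values.
#' @param cfg A [structural_config()] object.
#' @param arm `"icbt"` or `"fcbt"`.
#' @return Named numeric 4-vector over `(well, mild, moderate, severe)`
#'   summing to one.
#' @export
initial_phase_split <- function(values, cfg = structural_config(),
                                arm = c("icbt", "fcbt")) {
  arm <- match.arg(arm)
  up <- effective_uptake(values, arm)
  rec_eff <- values[["recovery_licbt"]]
  det_eff <- values[["deterioration_licbt"]]
  if (arm == "icbt") {
    rec_eff <- min(1, rec_eff * values[["rr_recovery_icbt"]])
    det_eff <- min(1, det_eff * values[["rr_deterioration_icbt"]])
  }
  mod_share <- .det_mod_share(values, cfg)
  stratum <- function(rec, det, label) {
    if (rec + det > 1)
      stop("recovery + deterioration exceed 1 in the ", label, " stratum")
    c(well = rec, mild = 1 - rec - det,
      moderate = det * mod_share, severe = det * (1 - mod_share))
  }
  up[["p_effective"]] * stratum(rec_eff, det_eff, "effective") +
    (1 - up[["p_effective"]]) *
      stratum(values[["recovery_none"]], values[["deterioration_none"]],
              "non-effective")
}

# Moderate share of the deterioration mass. The proportional rule follows
# the background mild-to-moderate : mild-to-severe ratio; an even split is
# the degenerate-input fallback when both background probabilities vanish.
.det_mod_share <- function(values, cfg) {
  if (cfg$deterioration_split_rule == "all_moderate") return(1)
  denom <- values[["p_mild_mod"]] + values[["p_mild_sev"]]
  if (denom <= 0) 0.5 else values[["p_mild_mod"]] / denom
}

# Fraction of the phase-end survivors escalated to high-intensity CBT.
.escalation_fraction <- function(values, cfg, arm) {
  if (!cfg$escalation_enabled) return(0)
  up <- effective_uptake(values, arm)
  rec_eff <- values[["recovery_licbt"]]
  if (arm == "icbt") rec_eff <- min(1, rec_eff * values[["rr_recovery_icbt"]])
  switch(cfg$escalation_recipients,
    accepters_not_well =
      up[["p_accept"]] * up[["p_adhere"]] * (1 - rec_eff) +
      up[["p_accept"]] * (1 - up[["p_adhere"]]) *
        (1 - values[["recovery_none"]]),
    all_not_well = {
      split <- initial_phase_split(values, cfg, arm)
      1 - split[["well"]]
    }
  )
}

# Core occupancy recursion shared by run_cohort() and the fast evaluator.
.run_occupancy <- function(values, cfg, arm, M = NULL) {
  H <- as.integer(values[["horizon_cycles"]])
  ph <- cfg$phase_cycles
  if (ph >= H) stop("phase_cycles must be smaller than horizon_cycles")
  if (is.null(M)) M <- build_monthly_matrix(values, cfg)
  d_mild <- M["mild", "dead"]
  occ <- matrix(0, H + 1, 5, dimnames = list(NULL, STATES))
  occ[1, "mild"] <- 1
  for (t in seq_len(ph)) {
    occ[t + 1, "mild"] <- occ[t, "mild"] * (1 - d_mild)
    occ[t + 1, "dead"] <- occ[t, "dead"] + occ[t, "mild"] * d_mild
  }
  alive <- occ[ph + 1, "mild"]
  split <- initial_phase_split(values, cfg, arm)
  # the post-programme distribution occupies cycle ph+1 ...
  occ[ph + 2, ] <- c(alive * split, occ[ph + 1, "dead"])
  # ... and background monthly transitions run from there to the horizon
  if (ph + 2 <= H) {
    for (t in (ph + 2):H) occ[t + 1, ] <- occ[t, ] %*% M
  }
  list(occ = occ, alive_phase_end = unname(alive),
       escalation_fraction =
         unname(alive * .escalation_fraction(values, cfg, arm)))
}

#' Run the cohort through the model horizon
#'
#' The hypothetical cohort enters all-mild, spends `cfg$phase_cycles`
#' monthly cycles in the low-intensity CBT programme (state unchanged
#' except background mortality), redistributes at programme end per
#' [initial_phase_split()], and then follows the monthly background
#' transition matrix to the horizon.
#'
#' @param values Named numeric vector of point values.
#' @param cfg A [structural_config()] object.
#' @param arm `"icbt"` or `"fcbt"`.
#' @return An object of class `cohort_trace`: a list with `arm`,
#'   `occupancy` (`horizon_cycles + 1` rows by 5 states; row `t + 1` is the
#'   occupancy during cycle `t`, row 1 the entry condition),
#'   `phase_end_cycle` and `escalation_fraction` (fraction of the entry
#'   cohort charged the high-intensity course).
#' @export
run_cohort <- function(values, cfg = structural_config(),
                       arm = c("icbt", "fcbt")) {
  arm <- match.arg(arm)
  r <- .run_occupancy(values, cfg, arm)
  structure(list(
    arm = arm,
    occupancy = r$occ,
    phase_end_cycle = cfg$phase_cycles,
    escalation_fraction = r$escalation_fraction
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1
  cat("Cohort trace (", x$arm, "), ", H, " monthly cycles\n", sep = "")
  show <- unique(c(0, x$phase_end_cycle, x$phase_end_cycle + 1, 12, H))
  show <- show[show <= H]
  print(round(cbind(cycle = show, x$occupancy[show + 1, , drop = FALSE]), 4))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(
    cycle = 0:(nrow(x$occupancy) - 1),
    p_well = x$occupancy[, "well"],
    p_mild = x$occupancy[, "mild"],
    p_moderate = x$occupancy[, "moderate"],
    p_severe = x$occupancy[, "severe"],
    p_dead = x$occupancy[, "dead"]
  )
}

#' Export a cohort trace as CSV
#'
#' @param trace A `cohort_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
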