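#' Discount factor for a monthly cycle
#'
#' @param cycle Cycle index (0 = model entry).
#' @param annual_rate Annual discount rate.
#' @return `(1 + annual_rate)^(-cycle / 12)`.
#' @export
discount_factor <- function(cycle, annual_rate) {
  stopifnot(all(cycle >= 0))
  (1 + annual_rate)^(-cycle / 12)
}

#' Age-adjusted utility of a Markov state
#'
#' Age-specific utility times the state-specific utility; the well state
#' uses the remission utility and death carries zero by definition.
#'
#' @param values Named numeric vector of point values.
#' @param state One of `"well"`, `"mild"`, `"moderate"`, `"severe"`,
#'   `"dead"`.
#' @return Utility weight in `[0, 1]`.
#' @export
state_utility <- function(values, state = STATES) {
  state <- match.arg(state)
  if (state == "dead") return(0)
  key <- switch(state, well = "utility_well", mild = "utility_mild",
                moderate = "utility_mod", severe = "utility_sev")
  values[["utility_age"]] * values[[key]]
}

# utility vector over the five states
.utility_vector <- function(values) {
  values[["utility_age"]] *
    c(values[["utility_well"]], values[["utility_mild"]],
      values[["utility_mod"]], values[["utility_sev"]], 0)
}

# per-cycle course-cost instalment charged during the CBT phase
.course_instalment <- function(values, cfg, arm) {
  up <- effective_uptake(values, arm)
  cc <- course_cost(values, if (arm == "icbt") "i_low" else "f_low")
  charged <- switch(cfg$course_cost_nonadherent,
    full = up[["p_accept"]] * cc,
    half = up[["p_accept"]] * cc *
      (up[["p_adhere"]] + (1 - up[["p_adhere"]]) * 0.5)
  )
  charged / cfg$phase_cycles
}

#' Discounted value of one model cycle
#'
#' Values a single occupancy row: direct medical cost (monthly outpatient
#' cost for the states in `cfg$outpatient_states`, expected hospitalization
#' cost among the severe, plus course-cost instalments during the CBT phase
#' and the one-time escalation charge at phase end), friction-cost indirect
#' cost (employed fraction of moderate/severe occupancy, student wage times
#' monthly hours), and QALYs (age-adjusted state utility / 12). All three
#' are multiplied by the cycle's discount factor.
#'
#' @param occ_row Numeric 5-vector of state occupancy for the cycle.
#' @param cycle Cycle index (1-based).
#' @param values Named numeric vector of point values.
#' @param cfg A [structural_config()] object.
#' @param arm `"icbt"` or `"fcbt"`; determines the course cost charged
#'   during the phase.
#' @param escalation_mass Fraction of the entry cohort charged the
#'   high-intensity course at phase end (see `cohort_trace`); the charge is
#'   applied when `cycle == cfg$phase_cycles`.
#' @return Named numeric vector `(direct, indirect, qaly)`, discounted.
#' @export
cycle_value <- function(occ_row, cycle, values, cfg = structural_config(),
                        arm = c("icbt", "fcbt"), escalation_mass = 0) {
  arm <- match.arg(arm)
  df <- discount_factor(cycle, values[["discount_annual"]])
  occ <- as.numeric(occ_row)
  names(occ) <- STATES
  direct <- sum(occ[cfg$outpatient_states]) * values[["outpatient_monthly"]] +
    occ[["severe"]] * values[["p_hosp_severe"]] * values[["hosp_cost_episode"]]
  if (cycle <= cfg$phase_cycles)
    direct <- direct + .course_instalment(values, cfg, arm)
  if (cycle == cfg$phase_cycles && escalation_mass > 0)
    direct <- direct + escalation_mass * course_cost(values, "f_high")
  indirect <- (occ[["moderate"]] + occ[["severe"]]) *
    employment_fraction(values) * values[["student_wage"]] *
    values[["hours_per_month"]]
  qaly <- sum(occ * .utility_vector(values)) / 12
  c(direct = direct * df, indirect = indirect * df, qaly = qaly * df)
}

# Vectorized valuation of a whole occupancy matrix; the workhorse behind
# summarize_trace() and every sensitivity-analysis evaluation.
.value_occupancy <- function(occ, values, cfg, arm, escalation_mass) {
  H <- nrow(occ) - 1L
  ph <- cfg$phase_cycles
  d <- discount_factor(seq_len(H), values[["discount_annual"]])
  occM <- occ[-1, , drop = FALSE]
  if (cfg$half_cycle_correction)
    occM <- (occ[-(H + 1), , drop = FALSE] + occM) / 2
  out_idx <- match(cfg$outpatient_states, STATES)
  direct_cyc <- rowSums(occM[, out_idx, drop = FALSE]) *
    values[["outpatient_monthly"]] +
    occM[, 4] * values[["p_hosp_severe"]] * values[["hosp_cost_episode"]]
  direct_cyc[seq_len(ph)] <- direct_cyc[seq_len(ph)] +
    .course_instalment(values, cfg, arm)
  direct_cyc[ph] <- direct_cyc[ph] +
    escalation_mass * course_cost(values, "f_high")
  indirect_cyc <- (occM[, 3] + occM[, 4]) * employment_fraction(values) *
    values[["student_wage"]] * values[["hours_per_month"]]
  qaly_cyc <- as.numeric(occM %*% .utility_vector(values)) / 12
  direct <- sum(direct_cyc * d)
  indirect <- sum(indirect_cyc * d)
  c(direct_cost = direct, indirect_cost = indirect,
    total_cost = direct + indirect, qalys = sum(qaly_cyc * d))
}

# Evaluate one arm end to end: occupancy recursion + valuation.
.eval_arm <- function(values, cfg, arm, M = NULL) {
  r <- .run_occupancy(values, cfg, arm, M = M)
  .value_occupancy(r$occ, values, cfg, arm, r$escalation_fraction)
}

#' Discounted per-person outcomes of one strategy
#'
#' Sums the discounted cycle values of a cohort trace over the full
#' horizon: direct medical cost, friction-cost indirect cost, their total,
#' and QALYs.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param values Named numeric vector of point values.
#' @param cfg A [structural_config()] object.
#' @return An object of class `strategy_outcome` with fields `arm`,
#'   `direct_cost`, `indirect_cost`, `total_cost`, `qalys`.
#' @export
summarize_trace <- function(trace, values, cfg = structural_config()) {
  v <- .value_occupancy(trace$occupancy, values, cfg, trace$arm,
                        trace$escalation_fraction)
  structure(c(list(arm = trace$arm), as.list(v)), class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf(
    "%s: direct %0.0f + indirect %0.0f = total US$ %0.0f; %0.4f QALYs\n",
    x$arm, x$direct_cost, x$indirect_cost, x$total_cost, x$qalys))
  invisible(x)
}

#' Incremental comparison of two strategies
#'
#' Deltas are intervention minus comparator. A strategy gaining QALYs at
#' lower cost dominates; the ICER is reported only in the trade-off case
#' (both deltas sharing a sign). The incremental net monetary benefit is
#' `wtp * delta_qaly - delta_cost`.
#'
#' @param intervention,comparator `strategy_outcome` objects.
#' @param wtp Willingness to pay per QALY.
#' @return An object of class `ce_result` with `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` unless trade-off), `dominance` (one of
#'   `"intervention_dominant"`, `"comparator_dominant"`, `"trade_off"`) and
#'   `inmb`.
#' @export
compare_strategies <- function(intervention, comparator, wtp) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qalys - comparator$qalys
  if (dq > 0 && dc <= 0) {
    dominance <- "intervention_dominant"; icer <- NA_real_
  } else if (dq < 0 && dc >= 0) {
    dominance <- "comparator_dominant"; icer <- NA_real_
  } else if (dq == 0) {
    # equal effect: cheaper strategy dominates; equal cost is a tie
    dominance <- if (dc < 0) "intervention_dominant"
                 else if (dc > 0) "comparator_dominant" else "trade_off"
    icer <- NA_real_
  } else {
    dominance <- "trade_off"; icer <- dc / dq
  }
  structure(list(
    delta_cost = dc, delta_qaly = dq, icer = icer,
    dominance = dominance, wtp = wtp, inmb = wtp * dq - dc
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("incremental cost %0.2f US$, incremental QALY %0.5f\n",
              x$delta_cost, x$delta_qaly))
  cat("  ", switch(x$dominance,
    intervention_dominant = "intervention dominates (cheaper, more effective)",
    comparator_dominant = "comparator dominates",
    trade_off = sprintf("trade-off: ICER %0.0f US$/QALY", x$icer)), "\n")
  cat(sprintf("  INMB at WTP %0.0f: %0.2f US$\n", x$wtp, x$inmb))
  invisible(x)
}
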