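#' Individual-level Monte Carlo simulation of one strategy
#'
#' First-order microsimulation of the identical decision process as the
#' cohort engine: each simulated student samples acceptance, adherence and
#' the phase outcome, then monthly categorical state transitions and
#' Bernoulli hospitalization events, and accrues the same discounted costs
#' and QALYs. Large-n averages converge to [run_cohort()] plus
#' [summarize_trace()] by construction; the function exists to validate
#' the cohort engine.
#'
#' Randomness comes from a single seeded stream consumed in fixed-width
#' blocks, one block per individual, so enlarging `n` extends the
#' population without replaying earlier individuals.
#'
#' @param inputs A `cea_inputs` object.
#' @param arm `"icbt"` or `"fcbt"`.
#' @param n Number of individuals.
#' @param seed RNG seed.
#' @param values Optional point values; defaults to [base_values()].
#' @param report_cycles Cycles at which state occupancy is estimated.
#' @param record_file Optional CSV path for a per-individual dump
#'   (id, arm, accepted, adhered, final_state, cost, qaly).
#' @return An object of class `microsim_result`: mean outcome (`direct_cost`,
#'   `indirect_cost`, `total_cost`, `qalys`) with standard errors, and
#'   occupancy estimates (rows = `report_cycles`, columns = states) with
#'   their standard errors.
#' @export
simulate_individuals <- function(inputs, arm = c("icbt", "fcbt"), n, seed,
                                 values = NULL,
                                 report_cycles = c(3, 12, 60),
                                 record_file = NULL) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  if (is.null(values)) values <- base_values(inputs)
  cfg <- inputs$structural
  H <- as.integer(values[["horizon_cycles"]])
  ph <- cfg$phase_cycles
  report_cycles <- report_cycles[report_cycles <= H]
  M <- build_monthly_matrix(values, cfg)
  Mc <- t(apply(M, 1, cumsum))[, 1:4]  # first four cumulative columns
  up <- effective_uptake(values, arm)
  rec_eff <- values[["recovery_licbt"]]
  det_eff <- values[["deterioration_licbt"]]
  if (arm == "icbt") {
    rec_eff <- min(1, rec_eff * values[["rr_recovery_icbt"]])
    det_eff <- min(1, det_eff * values[["rr_deterioration_icbt"]])
  }
  mod_share <- .det_mod_share(values, cfg)

  # fixed per-individual block of uniforms:
  # [accept | adhere | phase mortality (ph) | phase outcome |
  #  transitions (H-1-ph) | hospitalization (H)]
  W <- 2L + ph + 1L + (H - 1L - ph) + H
  set.seed(seed)
  U <- matrix(stats::runif(as.double(n) * W), nrow = n, byrow = TRUE)

  acc <- U[, 1] < up[["p_accept"]]
  adh <- U[, 2] < up[["p_adhere"]]
  eff <- acc & adh
  d_mild <- M["mild", "dead"]

  S <- matrix(2L, n, H + 1L)  # states by cycle (column = cycle + 1)
  dead <- rep(FALSE, n)
  for (t in seq_len(ph)) {
    dead <- dead | (!dead & U[, 2L + t] < d_mild)
    S[, t + 1L] <- ifelse(dead, 5L, 2L)
  }
  u0 <- U[, 2L + ph + 1L]
  rec <- ifelse(eff, rec_eff, values[["recovery_none"]])
  det <- ifelse(eff, det_eff, values[["deterioration_none"]])
  s4 <- 1L + (u0 >= rec) + (u0 >= 1 - det) + (u0 >= 1 - det * (1 - mod_share))
  S[, ph + 2L] <- ifelse(dead, 5L, s4)
  off <- 2L + ph + 1L
  if (ph + 1L <= H - 1L) {
    for (cyc in (ph + 1L):(H - 1L)) {
      u <- U[, off + (cyc - ph)]
      s <- S[, cyc + 1L]
      S[, cyc + 2L] <- 1L + (u > Mc[cbind(s, 1L)]) + (u > Mc[cbind(s, 2L)]) +
        (u > Mc[cbind(s, 3L)]) + (u > Mc[cbind(s, 4L)])
    }
  }

  # valuation, mirroring the cohort economics exactly
  disc <- discount_factor(seq_len(H), values[["discount_annual"]])
  uvec <- .utility_vector(values)
  empf_wage <- employment_fraction(values) * values[["student_wage"]] *
    values[["hours_per_month"]]
  out_idx <- match(cfg$outpatient_states, STATES)
  hoff <- off + (H - 1L - ph)
  qaly <- direct <- indirect <- numeric(n)
  for (cyc in seq_len(H)) {
    s <- S[, cyc + 1L]
    qaly <- qaly + disc[cyc] * uvec[s] / 12
    dc <- (s %in% out_idx) * values[["outpatient_monthly"]] +
      (s == 4L & U[, hoff + cyc] < values[["p_hosp_severe"]]) *
        values[["hosp_cost_episode"]]
    direct <- direct + disc[cyc] * dc
    indirect <- indirect + disc[cyc] * (s == 3L | s == 4L) * empf_wage
  }
  cc <- course_cost(values, if (arm == "icbt") "i_low" else "f_low")
  course_charge <- switch(cfg$course_cost_nonadherent,
    full = acc * cc,
    half = acc * cc * ifelse(adh, 1, 0.5))
  direct <- direct + course_charge / ph * sum(disc[seq_len(ph)])
  if (cfg$escalation_enabled) {
    escalated <- switch(cfg$escalation_recipients,
      accepters_not_well = acc & !dead & s4 != 1L,
      all_not_well = !dead & s4 != 1L)
    direct <- direct + escalated * course_cost(values, "f_high") * disc[ph]
  }
  total <- direct + indirect

  se <- function(x) stats::sd(x) / sqrt(n)
  occ <- t(vapply(report_cycles, function(cyc)
    vapply(1:5, function(k) mean(S[, cyc + 1L] == k), numeric(1)),
    numeric(5)))
  dimnames(occ) <- list(paste0("cycle_", report_cycles), STATES)
  occ_se <- sqrt(occ * (1 - occ) / n)

  if (!is.null(record_file)) {
    utils::write.csv(data.frame(
      id = seq_len(n), arm = arm, accepted = acc, adhered = adh,
      final_state = STATES[S[, H + 1L]], cost = total, qaly = qaly
    ), record_file, row.names = FALSE)
  }

  structure(list(
    arm = arm, n = n, seed = seed,
    outcome = c(direct_cost = mean(direct), indirect_cost = mean(indirect),
                total_cost = mean(total), qalys = mean(qaly)),
    se = c(direct_cost = se(direct), indirect_cost = se(indirect),
           total_cost = se(total), qalys = se(qaly)),
    occupancy = occ, occupancy_se = occ_se,
    report_cycles = report_cycles
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("Microsimulation (", x$arm, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  total cost %0.1f (SE %0.2f), QALYs %0.4f (SE %0.5f)\n",
              x$outcome[["total_cost"]], x$se[["total_cost"]],
              x$outcome[["qalys"]], x$se[["qalys"]]))
  invisible(x)
}

#' Random scenario generator for property testing
#'
#' Draws a jointly valid random parameter set (every uncertain input
#' uniform over its declared range, so transition-row sums stay feasible)
#' and a random structural configuration. Used to fuzz the engine
#' invariants: occupancy conservation, transition-matrix validity, trace
#' monotonicity.
#'
#' @param seed RNG seed.
#' @return A `cea_inputs` object whose base values are the drawn scenario.
#' @export
generate_random_scenario <- function(seed) {
  set.seed(seed)
  inputs <- default_model_inputs()
  inputs$params <- lapply(inputs$params, function(s) {
    if (s$family == "fixed") return(s)
    dist_spec(s$family, stats::runif(1, s$low, s$high),
              s$low, s$high)
  })
  states <- c("mild", "moderate", "severe")
  inputs$structural <- structural_config(
    phase_cycles = sample(1:3, 1),
    deterioration_split_rule = sample(c("proportional", "all_moderate"), 1),
    outpatient_states = sample(states, sample(1:3, 1)),
    escalation_enabled = sample(c(TRUE, FALSE), 1),
    escalation_recipients = sample(c("accepters_not_well", "all_not_well"), 1),
    course_cost_nonadherent = sample(c("full", "half"), 1),
    half_cycle_correction = sample(c(TRUE, FALSE), 1)
  )
  validate_inputs(inputs)
}
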