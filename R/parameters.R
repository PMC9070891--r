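#' @keywords internal
"_PACKAGE"

# Canonical Markov state ordering used everywhere in the package.
STATES <- c("well", "mild", "moderate", "severe", "dead")
ARMS <- c("icbt", "fcbt")

# Canonical input definitions: every model input with its base value,
# sensitivity range and sampling family. Fixed inputs carry a degenerate
# range. This table is the single source of truth for the shipped default
# configuration, the completeness checks and the sensitivity machinery.
.param_defs <- function() {
  defs <- rbind(
    # key,                     family,       base,      low,      high
    c("accept_fcbt",           "beta",       0.633,     0.506,    0.760),
    c("rr_accept_icbt",        "triangular", 1.19,      0.952,    1.428),
    c("adhere_fcbt",           "beta",       0.775,     0.62,     0.93),
    c("rr_adhere_icbt",        "triangular", 0.99,      0.84,     1.0),
    c("recovery_none",         "beta",       0.25,      0.20,     0.30),
    c("recovery_licbt",        "beta",       0.639,     0.511,    0.767),
    c("rr_recovery_icbt",      "triangular", 1.00,      0.95,     1.05),
    c("deterioration_none",    "beta",       0.174,     0.139,    0.209),
    c("deterioration_licbt",   "beta",       0.053,     0.042,    0.064),
    c("rr_deterioration_icbt", "triangular", 1.00,      0.95,     1.05),
    c("p_well_mild",           "beta",       0.0044,    0.0035,   0.0053),
    c("p_well_mod",            "beta",       0.0053,    0.0042,   0.0064),
    c("p_well_sev",            "beta",       0.0166,    0.0133,   0.0199),
    c("p_mild_well",           "beta",       0.0239,    0.0191,   0.0287),
    c("p_mild_mod",            "beta",       0.0073,    0.0058,   0.0088),
    c("p_mild_sev",            "beta",       0.0067,    0.0054,   0.0080),
    c("p_mod_well",            "beta",       0.0448,    0.0358,   0.0538),
    c("p_mod_mild",            "beta",       0.0801,    0.0641,   0.0961),
    c("p_mod_sev",             "beta",       0.0275,    0.0220,   0.0330),
    c("p_sev_well",            "beta",       0.0387,    0.0310,   0.0464),
    c("p_sev_mild",            "beta",       0.0314,    0.0251,   0.0377),
    c("p_sev_mod",             "beta",       0.0391,    0.0313,   0.0469),
    c("p_hosp_severe",         "beta",       0.0114,    0.0091,   0.0137),
    c("mortality_monthly",     "beta",       0.000025,  0.000020, 0.000030),
    c("rr_mortality_anxiety",  "triangular", 1.66,      1.56,     1.77),
    c("age_years",             "triangular", 21,        19,       23),
    c("utility_age",           "fixed",      0.92,      0.92,     0.92),
    c("utility_well",          "triangular", 0.72,      0.69,     0.75),
    c("utility_mild",          "triangular", 0.64,      0.62,     0.66),
    c("utility_mod",           "triangular", 0.60,      0.58,     0.62),
    c("utility_sev",           "triangular", 0.53,      0.50,     0.56),
    c("wage_psych",            "triangular", 52,        42,       62),
    c("li_sessions",           "triangular", 8,         5,        10),
    c("li_session_hours",      "fixed",      0.5,       0.5,      0.5),
    c("hi_sessions",           "triangular", 14,        12,       15),
    c("hi_session_hours",      "fixed",      1.0,       1.0,      1.0),
    c("platform_cost_icbt",    "triangular", 19,        15,       23),
    c("time_fraction_icbt",    "triangular", 0.22,      0.17,     0.26),
    c("outpatient_monthly",    "triangular", 220,       185,      348),
    c("hosp_cost_episode",     "triangular", 1278,      1022,     1534),
    c("labor_participation",   "beta",       0.364,     0.353,    0.387),
    c("unemployment",          "beta",       0.13,      0.114,    0.144),
    c("student_wage",          "triangular", 10,        8,        12),
    c("hours_per_month",       "triangular", 56,        40,       72),
    c("discount_annual",       "fixed",      0.03,      0.03,     0.03),
    c("horizon_cycles",        "fixed",      60,        60,       60),
    c("wtp",                   "fixed",      46070,     46070,    46070)
  )
  data.frame(
    key = defs[, 1], family = defs[, 2],
    base = as.numeric(defs[, 3]), low = as.numeric(defs[, 4]),
    high = as.numeric(defs[, 5]), stringsAsFactors = FALSE
  )
}

# keys that must lie in [0, 1]
.prob_keys <- c(
  "accept_fcbt", "adhere_fcbt", "recovery_none", "recovery_licbt",
  "deterioration_none", "deterioration_licbt",
  "p_well_mild", "p_well_mod", "p_well_sev",
  "p_mild_well", "p_mild_mod", "p_mild_sev",
  "p_mod_well", "p_mod_mild", "p_mod_sev",
  "p_sev_well", "p_sev_mild", "p_sev_mod",
  "p_hosp_severe", "mortality_monthly",
  "utility_age", "utility_well", "utility_mild", "utility_mod", "utility_sev",
  "labor_participation", "unemployment", "time_fraction_icbt"
)
.nonneg_keys <- c(
  "wage_psych", "li_sessions", "li_session_hours", "hi_sessions",
  "hi_session_hours", "platform_cost_icbt", "outpatient_monthly",
  "hosp_cost_episode", "student_wage", "hours_per_month", "wtp",
  "rr_accept_icbt", "rr_adhere_icbt", "rr_recovery_icbt",
  "rr_deterioration_icbt", "rr_mortality_anxiety"
)

#' Distribution specification for one model input
#'
#' A single uncertain input: a base-case value, the sensitivity range, and
#' the sampling family used in probabilistic analysis.
#'
#' @param family One of `"beta"`, `"triangular"`, `"fixed"`.
#' @param base Base-case value; for triangular sampling it is the mode.
#' @param low,high Sensitivity range. Must bracket `base`. Ignored (taken
#'   equal to `base`) for `family = "fixed"`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family, base, low = base, high = base) {
  family <- match.arg(family, c("beta", "triangular", "fixed"))
  if (family == "fixed") low <- high <- base
  stopifnot(is.numeric(base), is.numeric(low), is.numeric(high))
  if (low > base || base > high)
    stop("dist_spec requires low <= base <= high, got (",
         low, ", ", base, ", ", high, ")")
  if (family == "beta" && (low < 0 || high > 1))
    stop("beta family requires the range to lie in [0, 1]")
  structure(list(family = family, base = base, low = low, high = high),
            class = "dist_spec")
}

#' Default model inputs
#'
#' The shipped parameter set: every model input with its base value,
#' sensitivity range and distribution family, plus the default structural
#' configuration. Values reproduce the package's default configuration file
#' (`system.file("extdata", "default_config.yaml", package = "cbtcea")`).
#'
#' @param structural Optional named list overriding structural settings,
#'   see [structural_config()].
#' @return An object of class `cea_inputs`: a list with elements `params`
#'   (named list of [dist_spec()] objects) and `structural`.
#' @export
default_model_inputs <- function(structural = list()) {
  defs <- .param_defs()
  params <- lapply(seq_len(nrow(defs)), function(i)
    dist_spec(defs$family[i], defs$base[i], defs$low[i], defs$high[i]))
  names(params) <- defs$key
  out <- structure(
    list(params = params, structural = do.call(structural_config, structural)),
    class = "cea_inputs"
  )
  validate_inputs(out)
}

#' Structural model configuration
#'
#' Settings the model structure leaves open: length of the initial CBT
#' phase, how the deterioration mass is split between moderate and severe,
#' which states incur the monthly outpatient cost, who is escalated to
#' high-intensity CBT, course-cost proration for non-adherers, half-cycle
#' correction and which states carry the anxiety mortality rate ratio.
#'
#' @param phase_cycles Number of monthly cycles spent in the low-intensity
#'   CBT programme (1-3; default 3, approximating a 12-week course).
#' @param deterioration_split_rule `"proportional"` (moderate:severe in the
#'   ratio of the background mild-to-moderate and mild-to-severe
#'   probabilities) or `"all_moderate"`.
#' @param outpatient_states Character subset of
#'   `c("mild", "moderate", "severe")` incurring the monthly psychiatric
#'   outpatient cost. Default `"mild"` (calibrated; see the methods
#'   vignette).
#' @param escalation_enabled Charge a one-time high-intensity CBT course to
#'   non-recovered students at phase end?
#' @param escalation_recipients `"accepters_not_well"` or `"all_not_well"`.
#' @param course_cost_nonadherent `"full"` (accepters pay the full
#'   low-intensity course regardless of adherence) or `"half"`.
#' @param half_cycle_correction Use mid-cycle (trapezoid) occupancy for
#'   state-driven costs and QALYs?
#' @param mortality_rr_states States whose monthly mortality is multiplied
#'   by the anxiety mortality rate ratio.
#' @return A named list of class `cea_structural`.
#' @export
structural_config <- function(phase_cycles = 3,
                              deterioration_split_rule = c("proportional", "all_moderate"),
                              outpatient_states = "mild",
                              escalation_enabled = TRUE,
                              escalation_recipients = c("accepters_not_well", "all_not_well"),
                              course_cost_nonadherent = c("full", "half"),
                              half_cycle_correction = FALSE,
                              mortality_rr_states = c("mild", "moderate", "severe")) {
  deterioration_split_rule <- match.arg(deterioration_split_rule)
  escalation_recipients <- match.arg(escalation_recipients)
  course_cost_nonadherent <- match.arg(course_cost_nonadherent)
  phase_cycles <- as.integer(phase_cycles)
  if (phase_cycles < 1L)
    stop("phase_cycles must be at least 1")
  bad <- setdiff(outpatient_states, c("mild", "moderate", "severe"))
  if (length(bad))
    stop("unknown outpatient_states: ", paste(bad, collapse = ", "))
  bad <- setdiff(mortality_rr_states, c("mild", "moderate", "severe"))
  if (length(bad))
    stop("unknown mortality_rr_states: ", paste(bad, collapse = ", "))
  structure(list(
    phase_cycles = phase_cycles,
    deterioration_split_rule = deterioration_split_rule,
    outpatient_states = outpatient_states,
    escalation_enabled = isTRUE(escalation_enabled),
    escalation_recipients = escalation_recipients,
    course_cost_nonadherent = course_cost_nonadherent,
    half_cycle_correction = isTRUE(half_cycle_correction),
    mortality_rr_states = mortality_rr_states
  ), class = "cea_structural")
}

#' Validate a `cea_inputs` object
#'
#' Checks completeness against the canonical input list, range ordering,
#' probability and cost bounds, and the structural invariants. Called by
#' [default_model_inputs()] and [load_model_inputs()].
#'
#' @param inputs A `cea_inputs` object.
#' @return `inputs`, invisibly usable, after validation (errors name the
#'   offending key).
#' @export
validate_inputs <- function(inputs) {
  defs <- .param_defs()
  keys <- names(inputs$params)
  missing <- setdiff(defs$key, keys)
  if (length(missing))
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(keys, defs$key)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  for (k in keys) {
    s <- inputs$params[[k]]
    if (!inherits(s, "dist_spec"))
      stop("parameter '", k, "' is not a dist_spec")
    if (s$low > s$base || s$base > s$high)
      stop("parameter '", k, "': requires low <= base <= high")
    vals <- c(s$base, s$low, s$high)
    if (k %in% .prob_keys && (any(vals < 0) || any(vals > 1)))
      stop("parameter '", k, "': probability outside [0, 1]")
    if (k %in% .nonneg_keys && any(vals < 0))
      stop("parameter '", k, "': must be non-negative")
  }
  h <- inputs$params$horizon_cycles$base
  if (inputs$structural$phase_cycles > h)
    stop("phase_cycles exceeds horizon_cycles")
  invisible(inputs)
}

#' Base-case point values
#'
#' @param inputs A `cea_inputs` object.
#' @return Named numeric vector of base-case values, one per model input.
#' @export
base_values <- function(inputs) {
  vapply(inputs$params, function(s) s$base, numeric(1))
}

#' Load model inputs from a configuration file
#'
#' Reads a YAML configuration with a `parameters:` block (one
#' `{family, base, low, high}` entry per input) and an optional
#' `structural:` block; missing structural keys take their documented
#' defaults. The shipped default configuration reproduces
#' [default_model_inputs()] exactly.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `cea_inputs` object.
#' @seealso [write_model_inputs()] for the inverse operation.
#' @export
load_model_inputs <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters))
    stop("configuration lacks a 'parameters' block")
  params <- lapply(cfg$parameters, function(e) {
    if (is.null(e$family) || is.null(e$base))
      stop("each parameter entry needs at least 'family' and 'base'")
    dist_spec(e$family, e$base,
              if (is.null(e$low)) e$base else e$low,
              if (is.null(e$high)) e$base else e$high)
  })
  structural <- if (is.null(cfg$structural)) list() else cfg$structural
  out <- structure(
    list(params = params, structural = do.call(structural_config, structural)),
    class = "cea_inputs"
  )
  validate_inputs(out)
}

#' Write model inputs to a configuration file
#'
#' @param inputs A `cea_inputs` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_model_inputs <- function(inputs, path) {
  params <- lapply(inputs$params, function(s)
    list(family = s$family, base = s$base, low = s$low, high = s$high))
  structural <- unclass(inputs$structural)
  yaml::write_yaml(list(parameters = params, structural = structural), path,
                   precision = 12L)
  invisible(path)
}

#' Tabulate model inputs
#'
#' @param inputs A `cea_inputs` object.
#' @param path Optional CSV path; when given the table is also written out.
#' @return A data frame with columns `key`, `family`, `base`, `low`, `high`.
#' @export
parameter_table <- function(inputs, path = NULL) {
  df <- data.frame(
    key = names(inputs$params),
    family = vapply(inputs$params, `[[`, character(1), "family"),
    base = vapply(inputs$params, `[[`, numeric(1), "base"),
    low = vapply(inputs$params, `[[`, numeric(1), "low"),
    high = vapply(inputs$params, `[[`, numeric(1), "high"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' @export
print.cea_inputs <- function(x, ...) {
  n_unc <- sum(vapply(x$params, `[[`, character(1), "family") != "fixed")
  cat("Markov cost-effectiveness model inputs\n")
  cat("  ", length(x$params), " inputs (", n_unc, " uncertain)\n", sep = "")
  cat("  phase cycles: ", x$structural$phase_cycles,
      "; outpatient cost states: ",
      paste(x$structural$outpatient_states, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' Cost of one CBT course
#'
#' Course costs are priced from the psychotherapist's hourly wage, the
#' session duration and the number of sessions. The internet-delivered
#' course replaces most therapist time (a fraction `time_fraction_icbt`
#' remains) and adds a platform overhead.
#'
#' @param values Named numeric vector of point values, see [base_values()].
#' @param mode `"f_low"` (face-to-face low intensity), `"i_low"`
#'   (internet-delivered low intensity) or `"f_high"` (face-to-face high
#'   intensity).
#' @return Course cost in US dollars.
#' @examples
#' v <- base_values(default_model_inputs())
#' course_cost(v, "f_low")   # 52 * 0.5 * 8  = 208
#' course_cost(v, "i_low")   # 19 + 0.22 * 208 = 64.76
#' course_cost(v, "f_high")  # 52 * 1.0 * 14 = 728
#' @export
course_cost <- function(values, mode = c("f_low", "i_low", "f_high")) {
  mode <- match.arg(mode)
  f_low <- values[["wage_psych"]] * values[["li_session_hours"]] *
    values[["li_sessions"]]
  switch(mode,
    f_low = f_low,
    i_low = values[["platform_cost_icbt"]] +
      values[["time_fraction_icbt"]] * f_low,
    f_high = values[["wage_psych"]] * values[["hi_session_hours"]] *
      values[["hi_sessions"]]
  )
}

#' Acceptance, adherence and effective uptake per arm
#'
#' i-CBT probabilities are the f-CBT probabilities times the relative
#' differences, capped at 1. Effective uptake is the product of acceptance
#' and adherence: the fraction of the cohort that actually completes the
#' programme and receives its recovery/deterioration profile.
#'
#' @param values Named numeric vector of point values.
#' @param arm `"icbt"` or `"fcbt"`.
#' @return Named numeric vector `(p_accept, p_adhere, p_effective)`.
#' @export
effective_uptake <- function(values, arm = c("icbt", "fcbt")) {
  arm <- match.arg(arm)
  p_accept <- values[["accept_fcbt"]]
  p_adhere <- values[["adhere_fcbt"]]
  if (arm == "icbt") {
    p_accept <- min(1, p_accept * values[["rr_accept_icbt"]])
    p_adhere <- min(1, p_adhere * values[["rr_adhere_icbt"]])
  }
  c(p_accept = p_accept, p_adhere = p_adhere,
    p_effective = p_accept * p_adhere)
}

#' Fraction of students in employment
#'
#' Labor-force participation times one minus the unemployment rate; the
#' employed fraction of the cohort accrues friction-cost productivity
#' losses while in the moderate or severe state.
#'
#' @param values Named numeric vector of point values.
#' @return Employment fraction in `[0, 1]`.
#' @export
employment_fraction <- function(values) {
  values[["labor_participation"]] * (1 - values[["unemployment"]])
}
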