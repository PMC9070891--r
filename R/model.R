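#' Deterministic evaluation of the cost-effectiveness model
#'
#' Runs both strategies (guided internet-based CBT and face-to-face CBT)
#' through the Markov cohort engine at a set of point values and compares
#' them at the willingness-to-pay threshold.
#'
#' @param inputs A `cea_inputs` object, see [default_model_inputs()].
#' @param values Optional named numeric vector of point values; defaults to
#'   the base case, [base_values()]. Sensitivity analyses pass perturbed or
#'   sampled vectors here.
#' @param wtp Willingness to pay per QALY; defaults to the configured
#'   `wtp` input.
#' @return An object of class `cea_model`: a list with the two
#'   `cohort_trace`s (`trace_icbt`, `trace_fcbt`), the two
#'   `strategy_outcome`s (`icbt`, `fcbt`) and the `ce_result` comparison
#'   (`comparison`, intervention = i-CBT).
#' @examples
#' fit <- cea_model(default_model_inputs())
#' summary(fit)
#' @export
cea_model <- function(inputs, values = NULL, wtp = NULL) {
  stopifnot(inherits(inputs, "cea_inputs"))
  if (is.null(values)) values <- base_values(inputs)
  if (is.null(wtp)) wtp <- values[["wtp"]]
  cfg <- inputs$structural
  ti <- run_cohort(values, cfg, "icbt")
  tf <- run_cohort(values, cfg, "fcbt")
  oi <- summarize_trace(ti, values, cfg)
  of <- summarize_trace(tf, values, cfg)
  structure(list(
    values = values, structural = cfg, wtp = wtp,
    trace_icbt = ti, trace_fcbt = tf,
    icbt = oi, fcbt = of,
    comparison = compare_strategies(oi, of, wtp)
  ), class = "cea_model")
}

#' @export
print.cea_model <- function(x, ...) {
  cat("Markov cost-effectiveness model: i-CBT vs f-CBT\n")
  print(x$icbt); print(x$fcbt)
  print(x$comparison)
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, comparison = object$comparison),
            class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 6)
  print(x$comparison)
  invisible(x)
}

#' @export
as.data.frame.cea_model <- function(x, ...) {
  cmp <- x$comparison
  data.frame(
    strategy = c("icbt", "fcbt"),
    direct_cost = c(x$icbt$direct_cost, x$fcbt$direct_cost),
    indirect_cost = c(x$icbt$indirect_cost, x$fcbt$indirect_cost),
    total_cost = c(x$icbt$total_cost, x$fcbt$total_cost),
    qalys = c(x$icbt$qalys, x$fcbt$qalys),
    incremental_cost = c(cmp$delta_cost, NA),
    incremental_qaly = c(cmp$delta_qaly, NA)
  )
}
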