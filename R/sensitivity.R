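#' Method-of-moments beta fit from a mean and a range
#'
#' Fits a beta distribution whose mean equals the base-case value and whose
#' standard deviation is the sensitivity range width divided by 3.92 (the
#' range read as a 95 per cent interval): `alpha = mean * (mean (1 - mean)
#' / sd^2 - 1)` and `beta` scaled accordingly.
#'
#' @param mean Mean in (0, 1).
#' @param lo,hi Range bounds, `lo < hi`.
#' @return Named numeric vector `(alpha, beta)`. When the implied shape
#'   parameters are non-positive (range too wide for the mean), both are
#'   returned as `NA` with a warning; samplers fall back to a triangular
#'   distribution in that case.
#' @export
fit_beta <- function(mean, lo, hi) {
  stopifnot(mean > 0, mean < 1, lo < hi)
  s <- (hi - lo) / 3.92
  k <- mean * (1 - mean) / s^2 - 1
  alpha <- mean * k
  beta <- (1 - mean) * k
  if (alpha <= 0 || beta <= 0) {
    warning("beta fit infeasible for mean ", mean, " on (", lo, ", ", hi,
            "); falling back to triangular sampling")
    return(c(alpha = NA_real_, beta = NA_real_))
  }
  c(alpha = alpha, beta = beta)
}

#' Triangular random deviates
#'
#' Inverse-CDF sampler for the triangular distribution used for inputs
#' whose uncertainty is given as a mode and a range.
#'
#' @param n Number of deviates.
#' @param lo,mode,hi Minimum, mode and maximum.
#' @return Numeric vector of length `n`.
#' @export
rtriangular <- function(n, lo, mode, hi) {
  stopifnot(lo <= mode, mode <= hi)
  if (hi == lo) return(rep(mode, n))
  u <- stats::runif(n)
  f <- (mode - lo) / (hi - lo)
  ifelse(u < f,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

# draw a single value from one dist_spec
.sample_spec <- function(s) {
  if (s$family == "fixed" || s$high == s$low) return(s$base)
  if (s$family == "beta") {
    ab <- suppressWarnings(fit_beta(s$base, s$low, s$high))
    if (!anyNA(ab)) return(stats::rbeta(1, ab[["alpha"]], ab[["beta"]]))
  }
  rtriangular(1, s$low, s$base, s$high)
}

#' Draw one parameter set from the input distributions
#'
#' Each input is drawn independently from its family: beta via the
#' method-of-moments fit of [fit_beta()], triangular with mode at the base
#' value, fixed inputs unchanged. Uses (and advances) R's current RNG
#' stream; seed it for reproducibility. If a drawn set makes any state's
#' outgoing morbidity probabilities sum to 1 or more, that row is rescaled
#' proportionally (with a message) so the transition matrix stays valid.
#'
#' @param inputs A `cea_inputs` object.
#' @return Named numeric vector of point values, same layout as
#'   [base_values()].
#' @export
sample_parameters <- function(inputs) {
  v <- vapply(inputs$params, .sample_spec, numeric(1))
  rows <- list(
    c("p_well_mild", "p_well_mod", "p_well_sev"),
    c("p_mild_well", "p_mild_mod", "p_mild_sev"),
    c("p_mod_well", "p_mod_mild", "p_mod_sev"),
    c("p_sev_well", "p_sev_mild", "p_sev_mod")
  )
  death <- v[["mortality_monthly"]] * max(1, v[["rr_mortality_anxiety"]])
  for (r in rows) {
    s <- sum(v[r]) + death
    if (s >= 1) {
      v[r] <- v[r] * (1 - death) * 0.999 / sum(v[r])
      message("rescaled transition row (", paste(r, collapse = ", "),
              ") whose draw summed to ", signif(s, 4))
    }
  }
  v
}

# evaluate the incremental comparison at point values; fast path
.compare_at <- function(inputs, values, wtp) {
  cfg <- inputs$structural
  oi <- .eval_arm(values, cfg, "icbt")
  of <- .eval_arm(values, cfg, "fcbt")
  c(delta_cost = oi[["total_cost"]] - of[["total_cost"]],
    delta_qaly = oi[["qalys"]] - of[["qalys"]],
    inmb = wtp * (oi[["qalys"]] - of[["qalys"]]) -
      (oi[["total_cost"]] - of[["total_cost"]]),
    total_icbt = oi[["total_cost"]], total_fcbt = of[["total_cost"]],
    qaly_icbt = oi[["qalys"]], qaly_fcbt = of[["qalys"]])
}

#' Bisection threshold search on one model input
#'
#' Finds the value of `key` at which the chosen objective (incremental
#' QALYs, or incremental net monetary benefit at `wtp`) crosses zero, all
#' other inputs held at base case. Bisection runs until the bracketing
#' interval is narrower than `1e-5`.
#'
#' @param inputs A `cea_inputs` object.
#' @param key Parameter key to vary.
#' @param objective `"delta_qaly_zero"` or `"inmb_zero"`.
#' @param lo,hi Search bracket; defaults to the input's declared range.
#' @param wtp Willingness to pay (used by the INMB objective).
#' @return The crossing value, or `NA` when the objective does not change
#'   sign over the bracket (a valid "no threshold" answer).
#' @export
find_threshold <- function(inputs, key,
                           objective = c("delta_qaly_zero", "inmb_zero"),
                           lo = NULL, hi = NULL, wtp = NULL) {
  objective <- match.arg(objective)
  if (!key %in% names(inputs$params))
    stop("unknown parameter key: ", key)
  s <- inputs$params[[key]]
  if (is.null(lo)) lo <- s$low
  if (is.null(hi)) hi <- s$high
  base <- base_values(inputs)
  if (is.null(wtp)) wtp <- base[["wtp"]]
  pick <- if (objective == "delta_qaly_zero") "delta_qaly" else "inmb"
  f <- function(x) {
    v <- base; v[[key]] <- x
    .compare_at(inputs, v, wtp)[[pick]]
  }
  bisect_root(f, lo, hi)
}

# Bisection root finder shared by the threshold and frontier searches.
# Returns NA when f does not change sign over [lo, hi].
bisect_root <- function(f, lo, hi, tol = 1e-5) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' One-way sensitivity analysis on a single input
#'
#' Evaluates the incremental comparison across the input's declared range,
#' reports the endpoint results, flags non-monotone responses, and locates
#' any incremental-QALY sign change by bisection.
#'
#' @param inputs A `cea_inputs` object.
#' @param key Parameter key to vary.
#' @param n_points Number of evaluation points across the range.
#' @param wtp Willingness to pay; defaults to the configured input.
#' @return A list of class `owsa_result`: `key`, `fixed` (degenerate-range
#'   no-op flag), `grid` (data frame of value, delta_cost, delta_qaly,
#'   inmb), `low`, `high` (endpoint rows), `monotone` (are both deltas
#'   monotone across the grid), `threshold` (delta-QALY crossing or `NA`).
#' @export
one_way <- function(inputs, key, n_points = 11, wtp = NULL) {
  if (!key %in% names(inputs$params))
    stop("unknown parameter key: ", key, "; valid keys: ",
         paste(names(inputs$params), collapse = ", "))
  s <- inputs$params[[key]]
  base <- base_values(inputs)
  if (is.null(wtp)) wtp <- base[["wtp"]]
  if (s$low == s$high) {
    return(structure(list(key = key, fixed = TRUE, grid = NULL,
                          low = NULL, high = NULL, monotone = NA,
                          threshold = NA_real_), class = "owsa_result"))
  }
  xs <- seq(s$low, s$high, length.out = n_points)
  res <- t(vapply(xs, function(x) {
    v <- base; v[[key]] <- x
    .compare_at(inputs, v, wtp)[c("delta_cost", "delta_qaly", "inmb")]
  }, numeric(3)))
  grid <- data.frame(value = xs, res)
  mono <- function(y) all(diff(y) >= -1e-12) || all(diff(y) <= 1e-12)
  threshold <- NA_real_
  if (sign(grid$delta_qaly[1]) != sign(grid$delta_qaly[n_points]))
    threshold <- find_threshold(inputs, key, "delta_qaly_zero",
                                s$low, s$high, wtp)
  structure(list(
    key = key, fixed = FALSE, grid = grid,
    low = grid[1, ], high = grid[n_points, ],
    monotone = mono(grid$delta_qaly) && mono(grid$delta_cost),
    threshold = threshold
  ), class = "owsa_result")
}

#' @export
print.owsa_result <- function(x, ...) {
  if (x$fixed) {
    cat("one-way:", x$key, "- fixed input, no-op\n"); return(invisible(x))
  }
  cat("one-way:", x$key, "over (", x$low$value, ",", x$high$value, ")\n")
  cat(sprintf("  delta QALY %+0.5f .. %+0.5f; delta cost %+0.1f .. %+0.1f\n",
              x$low$delta_qaly, x$high$delta_qaly,
              x$low$delta_cost, x$high$delta_cost))
  if (!is.na(x$threshold))
    cat(sprintf("  delta-QALY threshold at %0.4f\n", x$threshold))
  if (!x$monotone) cat("  response non-monotone across the grid\n")
  invisible(x)
}

#' Tornado table: one-way analysis over every uncertain input
#'
#' @param inputs A `cea_inputs` object.
#' @param keys Keys to include; defaults to every non-fixed input.
#' @param n_points,wtp Passed to [one_way()].
#' @return Data frame with one row per input: endpoint incremental costs
#'   and QALYs, monotonicity flag and delta-QALY threshold (`NA` when the
#'   sign never changes).
#' @export
tornado <- function(inputs, keys = NULL, n_points = 5, wtp = NULL) {
  if (is.null(keys)) {
    fam <- vapply(inputs$params, `[[`, character(1), "family")
    rng <- vapply(inputs$params, function(s) s$high > s$low, logical(1))
    keys <- names(inputs$params)[fam != "fixed" & rng]
  }
  rows <- lapply(keys, function(k) {
    r <- one_way(inputs, k, n_points = n_points, wtp = wtp)
    data.frame(param = k,
               low_delta_cost = r$low$delta_cost,
               high_delta_cost = r$high$delta_cost,
               low_delta_qaly = r$low$delta_qaly,
               high_delta_qaly = r$high$delta_qaly,
               monotone = r$monotone,
               threshold = r$threshold)
  })
  do.call(rbind, rows)
}

#' Two-way sensitivity analysis
#'
#' Classifies the cost-effective strategy over a grid of two inputs at the
#' willingness-to-pay threshold (dominance, else net monetary benefit) and
#' extracts the decision frontier by a per-row bisection along `key1`.
#'
#' @param inputs A `cea_inputs` object.
#' @param key1,key2 Parameter keys to vary (`key1` on rows of the search).
#' @param grid_n Grid resolution per axis.
#' @param wtp Willingness to pay; defaults to the configured input.
#' @param range1,range2 Optional `c(lo, hi)` overrides of the declared
#'   ranges.
#' @return An object of class `twsa_result`: `grid` (long data frame of
#'   `key1` value, `key2` value, `inmb`, `winner`) and `frontier` (data
#'   frame of `key2` value and the `key1` value where the preferred
#'   strategy switches, `NA` where one strategy wins the whole row).
#' @export
two_way <- function(inputs, key1, key2, grid_n = 50, wtp = NULL,
                    range1 = NULL, range2 = NULL) {
  for (k in c(key1, key2))
    if (!k %in% names(inputs$params))
      stop("unknown parameter key: ", k)
  s1 <- inputs$params[[key1]]; s2 <- inputs$params[[key2]]
  if (is.null(range1)) range1 <- c(s1$low, s1$high)
  if (is.null(range2)) range2 <- c(s2$low, s2$high)
  base <- base_values(inputs)
  if (is.null(wtp)) wtp <- base[["wtp"]]
  x1 <- seq(range1[1], range1[2], length.out = grid_n)
  x2 <- seq(range2[1], range2[2], length.out = grid_n)
  inmb_at <- function(a, b) {
    v <- base; v[[key1]] <- a; v[[key2]] <- b
    .compare_at(inputs, v, wtp)[["inmb"]]
  }
  grid <- expand.grid(v1 = x1, v2 = x2)
  grid$inmb <- mapply(inmb_at, grid$v1, grid$v2)
  grid$winner <- ifelse(grid$inmb > 0, "icbt", "fcbt")
  names(grid)[1:2] <- c(key1, key2)
  frontier <- data.frame(v2 = x2, frontier = NA_real_)
  names(frontier)[1] <- key2
  for (i in seq_along(x2)) {
    frontier$frontier[i] <- bisect_root(function(a) inmb_at(a, x2[i]),
                                        range1[1], range1[2])
  }
  structure(list(key1 = key1, key2 = key2, wtp = wtp,
                 grid = grid, frontier = frontier),
            class = "twsa_result")
}

#' @export
print.twsa_result <- function(x, ...) {
  share <- mean(x$grid$winner == "icbt")
  cat("two-way:", x$key1, "x", x$key2, "at WTP", x$wtp, "\n")
  cat(sprintf("  i-CBT cost-effective in %0.1f%% of grid cells\n", 100 * share))
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Re-evaluates both strategies `n_draws` times, each time at a shared
#' random parameter draw ([sample_parameters()]), and summarizes the
#' incremental distribution: means with normal-approximation 95 per cent
#' confidence intervals of the mean, and the cost-effectiveness
#' acceptability curve `CEAC(w) = P(w * dQALY - dCost > 0)` over a
#' willingness-to-pay grid.
#'
#' @param inputs A `cea_inputs` object.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed RNG seed; fixed seed gives a bitwise-identical result.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; defaults to 0 to
#'   138,210 in steps of 2,000 plus the GDP-per-capita anchors.
#' @return An object of class `psa_result`: `n_draws`, `seed`, `draws`
#'   (per-draw arm costs/QALYs and deltas), `summary` (means, standard
#'   errors and CIs), `ceac` (data frame of `wtp`, `p_icbt`, `p_fcbt`).
#' @export
run_psa <- function(inputs, n_draws = 10000, seed = 1, wtp_grid = NULL) {
  stopifnot(n_draws >= 1)
  if (is.null(wtp_grid))
    wtp_grid <- sort(unique(c(seq(0, 138210, by = 2000),
                              0, 46070, 92140, 138210)))
  set.seed(seed)
  cfg <- inputs$structural
  out <- matrix(0, n_draws, 4,
                dimnames = list(NULL, c("cost_icbt", "qaly_icbt",
                                        "cost_fcbt", "qaly_fcbt")))
  for (i in seq_len(n_draws)) {
    v <- sample_parameters(inputs)
    oi <- .eval_arm(v, cfg, "icbt")
    of <- .eval_arm(v, cfg, "fcbt")
    out[i, ] <- c(oi[["total_cost"]], oi[["qalys"]],
                  of[["total_cost"]], of[["qalys"]])
  }
  draws <- data.frame(draw_id = seq_len(n_draws), out)
  draws$delta_cost <- draws$cost_icbt - draws$cost_fcbt
  draws$delta_qaly <- draws$qaly_icbt - draws$qaly_fcbt
  msum <- function(x) {
    se <- stats::sd(x) / sqrt(length(x))
    c(mean = mean(x), se = se,
      ci_lo = mean(x) - 1.96 * se, ci_hi = mean(x) + 1.96 * se)
  }
  summary <- rbind(
    delta_cost = msum(draws$delta_cost),
    delta_qaly = msum(draws$delta_qaly),
    cost_icbt = msum(draws$cost_icbt), qaly_icbt = msum(draws$qaly_icbt),
    cost_fcbt = msum(draws$cost_fcbt), qaly_fcbt = msum(draws$qaly_fcbt)
  )
  p_icbt <- vapply(wtp_grid, function(w)
    mean(w * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  ceac <- data.frame(wtp = wtp_grid, p_icbt = p_icbt, p_fcbt = 1 - p_icbt)
  structure(list(n_draws = n_draws, seed = seed, draws = draws,
                 summary = summary, ceac = ceac),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws (seed",
      x$seed, ")\n")
  cat(sprintf("  mean incremental cost %0.1f US$ (95%% CI %0.1f to %0.1f)\n",
              s["delta_cost", "mean"], s["delta_cost", "ci_lo"],
              s["delta_cost", "ci_hi"]))
  cat(sprintf("  mean incremental QALY %0.5f (95%% CI %0.5f to %0.5f)\n",
              s["delta_qaly", "mean"], s["delta_qaly", "ci_lo"],
              s["delta_qaly", "ci_hi"]))
  for (w in c(0, 46070, 138210)) {
    i <- which(x$ceac$wtp == w)
    if (length(i))
      cat(sprintf("  P(i-CBT cost-effective | WTP %6.0f) = %0.3f\n",
                  w, x$ceac$p_icbt[i]))
  }
  invisible(x)
}

#' Plot a PSA result
#'
#' @param x A `psa_result`.
#' @param type `"scatter"` (incremental cost-effectiveness plane) or
#'   `"ceac"` (acceptability curves).
#' @param ... Passed to the underlying plotting call.
#' @return `x`, invisibly.
#' @export
plot.psa_result <- function(x, type = c("scatter", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost, pch = ".",
                   xlab = "incremental QALYs (i-CBT vs f-CBT)",
                   ylab = "incremental cost (US$)", ...)
    graphics::abline(h = 0, v = 0, col = "grey")
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$p_icbt, type = "l", ylim = c(0, 1),
                   xlab = "willingness to pay (US$/QALY)",
                   ylab = "P(cost-effective)", ...)
    graphics::lines(x$ceac$wtp, x$ceac$p_fcbt, lty = 2)
    graphics::legend("right", c("i-CBT", "f-CBT"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
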