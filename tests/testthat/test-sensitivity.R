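test_that("beta fits match the method-of-moments closed form", {
  ab <- fit_beta(0.633, 0.506, 0.760)
  sd <- (0.760 - 0.506) / 3.92
  k <- 0.633 * (1 - 0.633) / sd^2 - 1
  expect_equal(ab[["alpha"]], 0.633 * k)
  expect_equal(ab[["beta"]], (1 - 0.633) * k)
  expect_equal(ab[["alpha"]], 34.39, tolerance = 1e-3)
  expect_equal(ab[["beta"]], 19.94, tolerance = 1e-3)
  # fitted mean is exact
  expect_equal(ab[["alpha"]] / sum(ab), 0.633, tolerance = 1e-12)
  # symmetric mean gives symmetric shapes
  s <- fit_beta(0.5, 0.3, 0.7)
  expect_equal(s[["alpha"]], s[["beta"]])
  # infeasible fit warns and signals the triangular fallback
  expect_warning(bad <- fit_beta(0.01, 0, 0.9), "falling back")
  expect_true(all(is.na(bad)))
})

test_that("beta sampling reproduces the target mean", {
  ab <- fit_beta(0.633, 0.506, 0.760)
  set.seed(3)
  x <- rbeta(50000, ab[["alpha"]], ab[["beta"]])
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.633), 3 * se)
})

test_that("triangular sampling respects bounds, mode and mean", {
  set.seed(4)
  x <- rtriangular(50000, 0.84, 0.99, 1.0)
  expect_true(all(x >= 0.84 & x <= 1.0))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - (0.84 + 0.99 + 1.0) / 3), 3 * se)
  expect_equal(rtriangular(5, 2, 2, 2), rep(2, 5))
})

test_that("parameter draws are reproducible and fix degenerate inputs", {
  inputs <- base_inputs()
  set.seed(99); v1 <- sample_parameters(inputs)
  set.seed(99); v2 <- sample_parameters(inputs)
  expect_identical(v1, v2)
  expect_equal(v1[["discount_annual"]], 0.03)  # fixed inputs untouched
  expect_equal(v1[["wtp"]], 46070)
  set.seed(1)
  vf <- sample_parameters(all_fixed_inputs())
  expect_equal(vf, base_values(base_inputs()))
})

test_that("the bisection root finder solves a known linear root", {
  expect_equal(cbtcea:::bisect_root(function(x) x - 0.5, 0, 1), 0.5,
               tolerance = 1e-5)
  expect_true(is.na(cbtcea:::bisect_root(function(x) x + 1, 0, 1)))
})

test_that("threshold search finds the uptake break-even ratios", {
  inputs <- base_inputs()
  th_acc <- find_threshold(inputs, "rr_accept_icbt", "delta_qaly_zero")
  th_adh <- find_threshold(inputs, "rr_adhere_icbt", "delta_qaly_zero")
  # QALY gains vanish when the effective-uptake products equalize:
  # rr_accept * rr_adhere = 1
  expect_equal(th_acc, 1 / 0.99, tolerance = 1e-4)
  expect_equal(th_adh, 1 / 1.19, tolerance = 1e-4)
  # no sign change -> no threshold
  expect_true(is.na(find_threshold(inputs, "outpatient_monthly",
                                   "delta_qaly_zero")))
  expect_error(find_threshold(inputs, "no_such_key"), "unknown parameter key")
})

test_that("one-way analysis reports endpoints, monotonicity and thresholds", {
  inputs <- base_inputs()
  r <- one_way(inputs, "rr_accept_icbt", n_points = 7)
  expect_false(r$fixed)
  expect_lt(r$low$delta_qaly, 0)
  expect_gt(r$high$delta_qaly, 0)
  expect_true(r$monotone)
  expect_equal(r$threshold, 1.0101, tolerance = 2e-3)
  # base-case result lies between the endpoints for a monotone response
  base_dq <- cea_model(inputs)$comparison$delta_qaly
  expect_true(base_dq >= min(r$grid$delta_qaly) &&
                base_dq <= max(r$grid$delta_qaly))
  # degenerate range is a flagged no-op
  expect_true(one_way(inputs, "utility_age")$fixed)
})

test_that("cost-only inputs never move the QALY difference", {
  inputs <- base_inputs()
  for (k in c("outpatient_monthly", "hosp_cost_episode", "wage_psych",
              "student_wage", "platform_cost_icbt", "hours_per_month")) {
    r <- one_way(inputs, k, n_points = 5)
    expect_lte(diff(range(r$grid$delta_qaly)), 1e-15)
    expect_true(is.na(r$threshold))
  }
})

test_that("the tornado table covers every uncertain input", {
  inputs <- base_inputs()
  tor <- tornado(inputs, n_points = 3)
  fam <- vapply(inputs$params, function(s) s$family, character(1))
  expect_equal(nrow(tor), sum(fam != "fixed"))
  expect_named(tor, c("param", "low_delta_cost", "high_delta_cost",
                      "low_delta_qaly", "high_delta_qaly", "monotone",
                      "threshold"))
  # only the two uptake ratios carry a QALY threshold
  with_th <- tor$param[!is.na(tor$threshold)]
  expect_setequal(with_th, c("rr_accept_icbt", "rr_adhere_icbt"))
})

test_that("two-way classification marks the base-case corner and a frontier", {
  inputs <- base_inputs()
  tw <- two_way(inputs, "rr_accept_icbt", "rr_adhere_icbt", grid_n = 7)
  expect_equal(nrow(tw$grid), 49)
  expect_setequal(unique(tw$grid$winner), c("icbt", "fcbt"))
  # at the base-case corner i-CBT is the cost-effective strategy
  corner <- tw$grid[abs(tw$grid$rr_accept_icbt - 1.19) < 0.01 &
                      abs(tw$grid$rr_adhere_icbt - 0.99) < 0.014, ]
  expect_true(all(corner$winner == "icbt"))
  # frontier values, where present, lie inside the declared range
  fr <- tw$frontier$frontier
  expect_true(all(is.na(fr) | (fr >= 0.952 & fr <= 1.428)))
})

test_that("PSA is reproducible, complementary and degenerate-safe", {
  inputs <- base_inputs()
  p1 <- run_psa(inputs, n_draws = 150, seed = 42)
  p2 <- run_psa(inputs, n_draws = 150, seed = 42)
  expect_identical(p1, p2)
  p3 <- run_psa(inputs, n_draws = 150, seed = 43)
  expect_false(identical(p1$draws, p3$draws))
  expect_equal(p1$ceac$p_icbt + p1$ceac$p_fcbt, rep(1, nrow(p1$ceac)))
  expect_true(all(p1$ceac$p_icbt >= 0 & p1$ceac$p_icbt <= 1))
  # anchors present on the WTP grid
  expect_true(all(c(0, 46070, 92140, 138210) %in% p1$ceac$wtp))

  single <- run_psa(inputs, n_draws = 1, seed = 5)
  expect_true(all(single$ceac$p_icbt %in% c(0, 1)))
  expect_equal(single$summary["delta_cost", "se"], NA_real_,
               ignore_attr = TRUE)
})

test_that("PSA means sit near the deterministic result scaled by the skewed ratios", {
  inputs <- base_inputs()
  p <- run_psa(inputs, n_draws = 400, seed = 7)
  expect_lt(p$summary["delta_cost", "mean"], 0)  # i-CBT saves on average
  expect_gt(p$summary["delta_qaly", "mean"], 0)
  # triangular adherence ratio is left-skewed, so the mean QALY gain
  # falls below the base case
  expect_lt(p$summary["delta_qaly", "mean"],
            cea_model(inputs)$comparison$delta_qaly)
})
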