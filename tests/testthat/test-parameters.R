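test_that("shipped defaults are complete and carry the published base values", {
  inputs <- base_inputs()
  expected_keys <- c(
    "accept_fcbt", "rr_accept_icbt", "adhere_fcbt", "rr_adhere_icbt",
    "recovery_none", "recovery_licbt", "rr_recovery_icbt",
    "deterioration_none", "deterioration_licbt", "rr_deterioration_icbt",
    "p_well_mild", "p_well_mod", "p_well_sev",
    "p_mild_well", "p_mild_mod", "p_mild_sev",
    "p_mod_well", "p_mod_mild", "p_mod_sev",
    "p_sev_well", "p_sev_mild", "p_sev_mod",
    "p_hosp_severe", "mortality_monthly", "rr_mortality_anxiety",
    "age_years", "utility_age", "utility_well", "utility_mild",
    "utility_mod", "utility_sev",
    "wage_psych", "li_sessions", "li_session_hours", "hi_sessions",
    "hi_session_hours", "platform_cost_icbt", "time_fraction_icbt",
    "outpatient_monthly", "hosp_cost_episode",
    "labor_participation", "unemployment", "student_wage", "hours_per_month",
    "discount_annual", "horizon_cycles", "wtp"
  )
  expect_setequal(names(inputs$params), expected_keys)
  v <- base_values(inputs)
  expect_equal(v[["accept_fcbt"]], 0.633)
  expect_equal(v[["rr_accept_icbt"]], 1.19)
  expect_equal(v[["recovery_licbt"]], 0.639)
  expect_equal(v[["deterioration_none"]], 0.174)
  expect_equal(v[["mortality_monthly"]], 0.000025)
  expect_equal(v[["wtp"]], 46070)
  expect_equal(inputs$params$outpatient_monthly$low, 185)
  expect_equal(inputs$params$outpatient_monthly$high, 348)
})

test_that("the shipped configuration file reproduces the defaults and round-trips", {
  cfg_path <- system.file("extdata", "default_config.yaml", package = "cbtcea")
  expect_true(nzchar(cfg_path))
  loaded <- load_model_inputs(cfg_path)
  expect_equal(base_values(loaded), base_values(base_inputs()))
  expect_equal(loaded$structural, base_inputs()$structural)

  tmp <- withr::local_tempfile(fileext = ".yaml")
  inputs <- base_inputs(phase_cycles = 2, outpatient_states = c("moderate", "severe"))
  write_model_inputs(inputs, tmp)
  re <- load_model_inputs(tmp)
  expect_equal(base_values(re), base_values(inputs))
  for (k in names(inputs$params))
    expect_equal(re$params[[k]], inputs$params[[k]], info = k)
  expect_equal(re$structural, inputs$structural)
})

test_that("validation rejects malformed inputs by key name", {
  inputs <- base_inputs()
  inputs$params$p_mild_well <- structure(
    list(family = "beta", base = 1.5, low = 0, high = 1.5),
    class = "dist_spec")
  expect_error(validate_inputs(inputs), "p_mild_well")

  expect_error(dist_spec("triangular", 0.5, low = 0.8, high = 1), "low <= base")
  expect_error(dist_spec("beta", 0.5, low = -0.1, high = 1), "\\[0, 1\\]")

  inputs <- base_inputs()
  inputs$params$not_a_real_input <- dist_spec("fixed", 1)
  expect_error(validate_inputs(inputs), "unknown parameter key")

  inputs <- base_inputs()
  inputs$params$wage_psych <- NULL
  expect_error(validate_inputs(inputs), "missing parameter key")
})

test_that("missing structural keys take documented defaults", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  inputs <- base_inputs()
  params <- lapply(inputs$params, function(s)
    list(family = s$family, base = s$base, low = s$low, high = s$high))
  yaml::write_yaml(list(parameters = params), tmp)  # no structural block
  loaded <- load_model_inputs(tmp)
  expect_equal(loaded$structural$phase_cycles, 3L)
  expect_equal(loaded$structural$outpatient_states, "mild")
  expect_equal(loaded$structural$deterioration_split_rule, "proportional")
  expect_false(loaded$structural$half_cycle_correction)
})

test_that("course costs follow the wage x duration x sessions pricing", {
  v <- base_values(base_inputs())
  expect_equal(course_cost(v, "f_low"), 52 * 0.5 * 8)      # 208
  expect_equal(course_cost(v, "i_low"), 19 + 0.22 * 208)   # 64.76
  expect_equal(course_cost(v, "f_high"), 52 * 1.0 * 14)    # 728
})

test_that("effective uptake multiplies the relative differences and caps at 1", {
  v <- base_values(base_inputs())
  f <- effective_uptake(v, "fcbt")
  expect_equal(unname(f), c(0.633, 0.775, 0.633 * 0.775))
  i <- effective_uptake(v, "icbt")
  expect_equal(i[["p_accept"]], 0.633 * 1.19)
  expect_equal(i[["p_adhere"]], 0.775 * 0.99)
  expect_equal(i[["p_effective"]], 0.633 * 1.19 * 0.775 * 0.99)

  v2 <- values_with(rr_accept_icbt = 2.0)
  expect_equal(effective_uptake(v2, "icbt")[["p_accept"]], 1.0)
})

test_that("uptake probabilities never exceed 1 for draws within the ranges", {
  inputs <- base_inputs()
  set.seed(7)
  for (i in 1:200) {
    v <- sample_parameters(inputs)
    up <- effective_uptake(v, "icbt")
    expect_true(all(up <= 1 & up >= 0))
  }
})

test_that("employment fraction combines participation and unemployment", {
  v <- base_values(base_inputs())
  expect_equal(employment_fraction(v), 0.364 * 0.87)  # 0.31668
  expect_equal(employment_fraction(values_with(unemployment = 1)), 0)
  expect_equal(employment_fraction(values_with(labor_participation = 0)), 0)
})

test_that("parameter_table dumps key/family/base/low/high as CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- parameter_table(base_inputs(), tmp)
  expect_named(df, c("key", "family", "base", "low", "high"))
  back <- utils::read.csv(tmp)
  expect_equal(nrow(back), length(base_inputs()$params))
  expect_equal(back$base[back$key == "outpatient_monthly"], 220)
})
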