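# Deterministic three-group fixture whose log-model predictions are exact
# group constants (no residual variation within group).
exact_models <- function(ft_income = 50000, pt_income = 20000,
                         nilf_income = 10000) {
  df <- data.frame(
    group = rep(c("FT-no-condition", "PT-no-condition", "NILF-diabetes"),
                each = 2),
    income = rep(c(ft_income, pt_income, nilf_income), each = 2),
    welfare = rep(c(0, 100, 6000), each = 2),
    tax = rep(c(12000, 1000, 0), each = 2))
  list(income = fit_log_model(df, "income", covariates = "group"),
       welfare = fit_log_model(df, "welfare", covariates = "group",
                               offset = 1),
       tax = fit_log_model(df, "tax", covariates = "group", offset = 1))
}

nilf_fixture <- function(income = 10000, welfare = 6000, tax = 0) {
  data.frame(record_id = "S000001", group = "NILF-diabetes",
             income = income, welfare = welfare, tax = tax,
             stringsAsFactors = FALSE)
}

test_that("a pure non-employment counterfactual changes nothing", {
  models <- exact_models()
  nilf <- nilf_fixture()
  cf <- counterfactual_economics(nilf, models, counterfactual_spec(0, 0, 1))
  expect_equal(cf$cf_income, nilf$income)
  expect_equal(cf$cf_welfare, nilf$welfare)
  expect_equal(cf$cf_tax, nilf$tax)
  expect_equal(cf$loss_income, 0)
  expect_equal(cf$extra_welfare, 0)
  expect_equal(cf$loss_tax, 0)
})

test_that("counterfactual outcomes are convex combinations of state values", {
  models <- exact_models(ft_income = 60000, pt_income = 20000)
  nilf <- nilf_fixture()
  cf <- counterfactual_economics(nilf, models,
                                 counterfactual_spec(0.75, 0.25, 0))
  expect_equal(cf$cf_income, 0.75 * 60000 + 0.25 * 20000, tolerance = 1e-6)

  # single record, full-time share 1: weighted loss follows directly
  models2 <- exact_models(ft_income = 50000)
  cf2 <- counterfactual_economics(nilf_fixture(income = 10000), models2,
                                  counterfactual_spec(1, 0, 0))
  expect_equal(cf2$loss_income, 40000, tolerance = 1e-6)
  imp <- national_losses(cf2, weights = 100)
  expect_equal(imp$lost_income * 1e6, 4000000, tolerance = 1)
})

test_that("income and tax losses are floored at zero", {
  # NILF actual income above the counterfactual: no negative loss
  models <- exact_models(ft_income = 20000, pt_income = 10000,
                         nilf_income = 90000)
  cf <- counterfactual_economics(nilf_fixture(income = 90000), models,
                                 counterfactual_spec(1, 0, 0))
  expect_equal(cf$loss_income, 0)
})

test_that("national totals aggregate weighted losses, order-invariantly", {
  losses <- data.frame(record_id = c("a", "b"),
                       loss_income = c(40000, 40000),
                       extra_welfare = c(1000, 3000),
                       loss_tax = c(5000, 1000))
  imp <- national_losses(losses, weights = c(100, 100))
  expect_equal(imp$lost_income, 8.0)
  expect_equal(imp$n_out_of_lf, 200)
  imp_rev <- national_losses(losses[2:1, ], weights = c(100, 100))
  expect_equal(imp$lost_income, imp_rev$lost_income)
  expect_equal(imp$extra_welfare, imp_rev$extra_welfare)
  expect_error(national_losses(losses, weights = 1), "lengths differ")

  # zero persons out of the labour force: all totals zero
  none <- national_losses(losses[0, ], weights = numeric(0))
  expect_equal(none$lost_income, 0)
  expect_equal(none$n_out_of_lf, 0)
})

test_that("national figures are linear in the weights", {
  losses <- data.frame(record_id = letters[1:5],
                       loss_income = runif(5, 0, 5e4),
                       extra_welfare = runif(5, 0, 5e3),
                       loss_tax = runif(5, 0, 1e4))
  w <- runif(5, 50, 150)
  a <- national_losses(losses, w)
  b <- national_losses(losses, 3 * w)
  expect_equal(b$lost_income, 3 * a$lost_income)
  expect_equal(b$extra_welfare, 3 * a$extra_welfare)
  expect_equal(b$lost_tax, 3 * a$lost_tax)
})

test_that("GDP loss follows the identity's marginal form", {
  params <- gdp_parameters(gdp_per_hour = 100, hours_per_worker = 1600)
  expect_equal(gdp_loss(0, params), 0)
  expect_equal(gdp_loss(11310, params), 1809.6)
  expect_equal(gdp_loss(2 * 11310, params), 2 * gdp_loss(11310, params))
  expect_error(gdp_loss(-1, params), ">= 0")
  expect_error(gdp_parameters(employment_rate = 1.2), "rates")
})

test_that("marginal and difference forms of the GDP identity agree exactly", {
  params <- gdp_parameters(gdp_per_hour = 55, hours_per_worker = 1750,
                           employment_rate = 0.93,
                           participation_rate = 0.66,
                           population_15plus = 1e7)
  for (n in c(0, 1, 500, 11310))
    expect_equal(gdp_loss(n, params), gdp_loss_difference_form(n, params))
})

test_that("the preventable fraction scales persons and money with reporting rounding", {
  base <- national_impact(n_out_of_lf = 11310, lost_income = 383.9,
                          extra_welfare = 3.5, lost_tax = 56.4,
                          gdp_loss = 1324)
  prev <- apply_preventable_fraction(base, 0.89)
  expect_equal(prev$n_out_of_lf, 10066)
  expect_equal(prev$lost_income, 341.7)
  expect_equal(prev$extra_welfare, 3.1)
  expect_equal(prev$lost_tax, 50.2)
  expect_equal(prev$scenario, "preventable")

  ident <- apply_preventable_fraction(base, 1)
  expect_equal(ident$n_out_of_lf, base$n_out_of_lf)
  expect_equal(ident$lost_income, base$lost_income)
  expect_error(apply_preventable_fraction(base, 1.01), "fraction")
  expect_error(apply_preventable_fraction(base, -0.1), "fraction")
  # linearity at reporting precision across fractions
  for (f in c(0.2, 0.5, 0.75))
    expect_equal(apply_preventable_fraction(base, f)$lost_income,
                 round(base$lost_income * f, 1))
})

test_that("per-record consistency: tax loss bounded by counterfactual tax", {
  spec <- default_population_spec(seed = 61)
  survey <- generate_survey(spec)
  donors <- generate_donors(spec, 10000)
  data <- impute_economics(survey, donors, seed = 62)$data
  data$weight <- data$design_weight
  analysis <- data[data$group %in% analysis_groups(), ]
  models <- lapply(stats::setNames(nm = c("income", "welfare", "tax")),
                   function(y) fit_log_model(analysis, y,
                                             offset = if (y == "income") 0
                                             else 1))
  nilf <- data[data$group == "NILF-diabetes", ]
  cf <- counterfactual_economics(nilf, models, counterfactual_spec(0.7, 0.2))
  expect_true(all(cf$loss_tax <= cf$cf_tax + 1e-9))
  expect_true(all(cf$loss_income >= 0))
  w_extra <- nilf$welfare >= cf$cf_welfare
  expect_true(all(cf$extra_welfare[w_extra] >= 0))
  # reference employment state missing from the fitted effects
  no_pt <- analysis[analysis$group != "PT-no-condition", ]
  models_no_pt <- lapply(models, function(m) m)
  models_no_pt$income <- fit_log_model(no_pt, "income")
  expect_error(counterfactual_economics(nilf, models_no_pt,
                                        counterfactual_spec(0.7, 0.2)),
               "absent")
})
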