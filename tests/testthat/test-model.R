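test_that("weighted statistics follow their stated conventions", {
  expect_equal(weighted_mean(7, 3), 7)
  expect_equal(weighted_sd(7, 3), 0)
  expect_equal(weighted_median(7, 3), 7)

  x <- c(10, 20, 30); w <- c(1, 1, 2)
  expect_equal(weighted_mean(x, w), 22.5)
  # enumeration oracle for "smallest value with cumulative weight >= half":
  # cumulative weights 1, 2, 4 against half-total 2 select 20
  oracle <- function(x, w) {
    o <- order(x); cw <- cumsum(w[o])
    x[o][min(which(cw >= sum(w) / 2))]
  }
  expect_equal(weighted_median(x, w), oracle(x, w))
  expect_equal(weighted_median(x, w), 20)

  # weighted mean of a constant is that constant, for any weights
  set.seed(1)
  for (i in 1:10) {
    w <- stats::runif(sample(2:30, 1), 0.1, 5)
    expect_equal(weighted_mean(rep(3.7, length(w)), w), 3.7)
  }
})

test_that("group summaries report the analysis groups in printed order", {
  spec <- default_population_spec(seed = 2)
  survey <- generate_survey(spec)
  donors <- generate_donors(spec, 10000)
  data <- impute_economics(survey, donors, seed = 3)$data
  data$weight <- data$design_weight
  tab <- summarize_by_group(data, groups = analysis_groups())
  expect_equal(tab$group, analysis_groups())
  expect_true(all(tab$N > 0))
  expect_true(all(tab[, grep("_sd$", names(tab))] >= 0))
  for (g in tab$group) {
    v <- data$income[data$group == g]
    med <- tab$income_median[tab$group == g]
    expect_gte(med, min(v)); expect_lte(med, max(v))
  }
  expect_warning(summarize_by_group(data[data$group != "PT-diabetes", ],
                                    groups = analysis_groups()),
                 "PT-diabetes")
})

test_that("log-model coefficients match the normal-equations oracle", {
  df <- data.frame(
    group = c("FT-no-condition", "FT-no-condition", "NILF-diabetes",
              "NILF-diabetes", "PT-no-condition", "PT-no-condition"),
    age_group = "45-49", sex = c("male", "female", "male", "female",
                                 "male", "female"),
    education = "university",
    income = c(60000, 52000, 9000, 12000, 25000, 21000))
  m <- fit_log_model(df, "income", covariates = c("group", "sex"))
  X <- cbind(1, df$group == "NILF-diabetes", df$group == "PT-no-condition",
             df$sex == "male")
  beta <- solve(t(X) %*% X, t(X) %*% log(df$income))
  expect_equal(unname(coef(m$fit)), as.vector(beta), tolerance = 1e-10)
})

test_that("the design uses main effects only, with the stated reference", {
  spec <- default_population_spec(seed = 4)
  donors <- generate_donors(spec, 5000)
  donors <- donors[donors$group %in% analysis_groups(), ]
  m <- fit_log_model(donors, "income")
  expect_false(any(grepl(":", names(coef(m$fit)))))
  expect_false("groupFT-no-condition" %in% names(coef(m$fit)))
  expect_equal(m$reference, "FT-no-condition")
  expect_error(fit_log_model(donors, "income", reference = "no-such-group"),
               "absent")
  # legitimate zeros need the offset
  donors$welfare0 <- 0
  expect_error(fit_log_model(donors, "welfare0", offset = 0), "> 0")
})

test_that("collinear designs are rejected naming the aliased column", {
  df <- data.frame(group = rep(c("FT-no-condition", "NILF-diabetes"), 4),
                   sex = rep(c("male", "female"), 4),
                   dup = rep(c("a", "b"), 4),
                   income = exp(rnorm(8) + 10))
  expect_error(fit_log_model(df, "income", covariates = c("group", "sex",
                                                          "dup")),
               "collinear|aliased")
})

test_that("percent differences back-transform log coefficients exactly", {
  expect_equal(percent_difference(0)$pct, 0)
  expect_equal(round(percent_difference(log(0.117))$pct, 1), -88.3)
  expect_equal(percent_difference(log(2))$pct, 100)
  pd <- percent_difference(-2.1456, 0.3)
  expect_lt(pd$ci_low, pd$pct); expect_gt(pd$ci_high, pd$pct)
  # round trip: beta = log(1 + p/100) recovers p
  for (p in c(-99.8, -88.3, -56.3, -6.5, 24.9, 112.3, 3819.8))
    expect_equal(percent_difference(log(1 + p / 100))$pct, p,
                 tolerance = 1e-9)
})

test_that("null group effects are covered by the 95% CI at nominal rate", {
  set.seed(42)
  covered <- matrix(NA, 100, 2)
  for (r in 1:100) {
    n <- 600
    df <- data.frame(
      group = sample(c("FT-no-condition", "PT-no-condition",
                       "NILF-diabetes"), n, replace = TRUE),
      age_group = sample(c("45-49", "60-64"), n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      education = "university")
    df$income <- exp(10 + 0.1 * (df$sex == "male") + rnorm(n, 0, 0.5))
    m <- fit_log_model(df, "income",
                       covariates = c("group", "age_group", "sex"))
    eff <- group_effects(m)
    covered[r, ] <- eff$ci_low <= 0 & eff$ci_high >= 0
  }
  expect_gte(sum(covered[, 1]), 93)
  expect_gte(sum(covered[, 2]), 93)
})

test_that("fitted percent differences recover generating effects", {
  spec <- population_spec_from_effects(seed = 50)
  truth <- load_group_effects()$percent_difference$income
  ests <- replicate(30, {
    d <- generate_donors(spec, 10000,
                         seed = sample.int(1e6, 1))
    d <- d[d$group %in% analysis_groups(), ]
    eff <- group_effects(fit_log_model(d, "income"))
    eff$pct_diff[eff$group == "NILF-diabetes"]
  })
  expect_lt(abs(mean(ests) - truth[["NILF-diabetes"]]), 2)
})

test_that("diagnostics calibrate on normal residuals and flag departures", {
  set.seed(7)
  n_ok <- 0
  for (r in 1:100) {
    df <- data.frame(group = rep(c("FT-no-condition", "NILF-diabetes"), 100),
                     income = exp(10 + rnorm(200, 0, 0.4)))
    m <- fit_log_model(df, "income", covariates = "group")
    d <- model_diagnostics(m)
    if (d$normality$p.value > 0.05) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 90)

  n_rej <- 0
  for (r in 1:20) {
    df <- data.frame(group = rep(c("FT-no-condition", "NILF-diabetes"), 250),
                     income = exp(10 + rt(500, df = 2) * 0.4))
    m <- fit_log_model(df, "income", covariates = "group")
    if (model_diagnostics(m)$normality$p.value < 0.05) n_rej <- n_rej + 1
  }
  expect_gt(n_rej, 10)

  # perfect fit flags a degenerate report
  df <- data.frame(group = rep(c("FT-no-condition", "NILF-diabetes"), 2),
                   income = rep(c(50000, 10000), 2))
  d <- model_diagnostics(fit_log_model(df, "income", covariates = "group"))
  expect_true(d$degenerate)
  expect_null(d$normality)
})
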