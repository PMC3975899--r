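#' Piecewise-linear marginal income tax schedule
#'
#' @param thresholds Lower bounds (AU$/yr) of each marginal-rate bracket,
#'   starting at 0, strictly increasing.
#' @param rates Marginal rate applying above each threshold; must be in
#'   `[0, 1)` and the implied tax function is non-decreasing in income.
#' @return Object of class `tax_schedule`.
#' @export
tax_schedule <- function(thresholds = c(0, 6000, 35000, 80000, 180000),
                         rates = c(0, 0.165, 0.315, 0.395, 0.465)) {
  if (length(thresholds) != length(rates))
    stop("tax_schedule: thresholds and rates must have equal length")
  if (thresholds[1] != 0 || any(diff(thresholds) <= 0))
    stop("tax_schedule: thresholds must start at 0 and be strictly increasing")
  if (any(rates < 0) || any(rates >= 1))
    stop("tax_schedule: rates must lie in [0, 1)")
  structure(list(thresholds = thresholds, rates = rates),
            class = "tax_schedule")
}

#' Tax liability implied by a schedule
#'
#' Integrates the marginal-rate schedule from 0 up to each income.
#'
#' @param income Numeric vector of annual incomes (AU$/yr), >= 0.
#' @param schedule A [tax_schedule()].
#' @return Numeric vector of tax liabilities (AU$/yr); always `<= income`.
#' @export
tax_from_income <- function(income, schedule) {
  stopifnot(inherits(schedule, "tax_schedule"))
  th <- schedule$thresholds
  r <- schedule$rates
  tax <- numeric(length(income))
  upper <- c(th[-1], Inf)
  for (b in seq_along(th)) {
    taxable <- pmin(pmax(income - th[b], 0), upper[b] - th[b])
    tax <- tax + r[b] * taxable
  }
  tax
}

# Log-normal parameters from a (mean, sd, median) anchor:
# location ties the median, scale comes from the coefficient of variation.
lognormal_anchor <- function(mean, sd, median) {
  stopifnot(mean > 0, sd >= 0, median > 0)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(median), sdlog = sdlog)
}

# Zero-inflated log-normal parameters from a (mean, sd, median) anchor and a
# zero mass p_zero. If the anchor median is 0 (consistent with p_zero >= 0.5
# ... or simply a majority-zero group), the positive part is moment-matched
# to the mixture mean and sd. If the median is positive (requires
# p_zero < 0.5), location and scale are solved so the mixture median and mean
# both match; the sd is then implied rather than matched.
zi_lognormal_anchor <- function(mean, sd, median, p_zero) {
  stopifnot(p_zero >= 0, p_zero < 1)
  if (median <= 0) {
    mp <- mean / (1 - p_zero)
    vp <- (sd^2 + mean^2) / (1 - p_zero) - mp^2
    if (vp <= 0) vp <- mp^2  # degenerate anchor: fall back to unit CV
    sdlog <- sqrt(log(1 + vp / mp^2))
    meanlog <- log(mp) - sdlog^2 / 2
  } else {
    if (p_zero >= 0.5)
      stop("zi_lognormal_anchor: positive median requires p_zero < 0.5")
    z <- stats::qnorm((0.5 - p_zero) / (1 - p_zero))
    cc <- log(mean / ((1 - p_zero) * median))
    if (cc <= 0)
      stop("zi_lognormal_anchor: mean must exceed (1 - p_zero) * median")
    sdlog <- z + sqrt(z^2 + 2 * cc)  # positive root of s^2/2 - z s - cc = 0
    meanlog <- log(median) - sdlog * z
  }
  list(p_zero = p_zero, meanlog = meanlog, sdlog = sdlog)
}

#' Construct a population specification for the synthetic generators
#'
#' A `population_spec` fully determines the synthetic survey and donor
#' microdata: group sample sizes and weighted population sizes, per-group
#' log-normal annual-income parameters, per-group zero-inflated log-normal
#' welfare parameters, a marginal tax schedule, per-group categorical
#' covariate mixes, common log-scale covariate effects on income, and the
#' income-quintile band edges.
#'
#' @param groups data.frame with columns `group`, `sample_size` (unweighted
#'   records), `pop_size` (target weighted persons).
#' @param income_params data.frame with columns `group`, `meanlog`, `sdlog`.
#' @param welfare_params data.frame with columns `group`, `p_zero`,
#'   `meanlog`, `sdlog`.
#' @param tax A [tax_schedule()].
#' @param covariate_mixes Named list (one element per group) of named lists
#'   of probability vectors over the [category_sets()] levels.
#' @param covariate_effects Named list with elements `age_group`, `sex`,
#'   `education`: named numeric vectors of additive log-income effects.
#'   They are centred against the population-share-weighted covariate mix so
#'   the group medians stay anchored to `income_params`.
#' @param quintile_edges Increasing numeric vector of 6 income band edges
#'   (first 0, last `Inf`) defining the income quintile bands.
#' @param condition_count_probs Named list per group: probability vector over
#'   counts of chronic conditions 0:4 (4 meaning four or more).
#' @param seed Default integer seed used by the generators.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(groups, income_params, welfare_params,
                            tax = tax_schedule(), covariate_mixes,
                            covariate_effects, quintile_edges =
                              c(0, 16000, 30000, 48000, 70000, Inf),
                            condition_count_probs = NULL, seed = 1L) {
  spec <- structure(
    list(groups = groups, income_params = income_params,
         welfare_params = welfare_params, tax = tax,
         covariate_mixes = covariate_mixes,
         covariate_effects = covariate_effects,
         quintile_edges = quintile_edges,
         condition_count_probs = condition_count_probs,
         seed = as.integer(seed)),
    class = "population_spec")
  spec$covariate_effects <- center_effects(spec)
  validate_population_spec(spec)
  spec
}

# Centre log-income covariate effects against the population-share-weighted
# covariate mix so that the group-level income_params keep their median
# interpretation (approximately).
center_effects <- function(spec) {
  shares <- spec$groups$pop_size / sum(spec$groups$pop_size)
  eff <- spec$covariate_effects
  for (v in names(eff)) {
    lv <- names(eff[[v]])
    overall <- numeric(length(lv))
    names(overall) <- lv
    for (g in seq_len(nrow(spec$groups))) {
      mix <- spec$covariate_mixes[[spec$groups$group[g]]][[v]]
      overall <- overall + shares[g] * mix[lv]
    }
    eff[[v]] <- eff[[v]] - sum(overall * eff[[v]])
  }
  eff
}

#' @export
print.population_spec <- function(x, ...) {
  cat("population_spec:", nrow(x$groups), "groups,",
      sum(x$groups$sample_size), "records,",
      format(sum(x$groups$pop_size), big.mark = ","),
      "weighted persons; seed", x$seed, "\n")
  invisible(x)
}

#' Validate a population specification
#'
#' Checks every invariant the generators rely on; stops with an error naming
#' the first failing field.
#'
#' @param spec A [population_spec()].
#' @return `spec`, invisibly, if valid.
#' @export
validate_population_spec <- function(spec) {
  cats <- category_sets()
  g <- spec$groups
  if (!all(c("group", "sample_size", "pop_size") %in% names(g)))
    stop("invalid spec: groups must have columns group, sample_size, pop_size")
  if (any(g$sample_size <= 0) || any(g$pop_size <= 0))
    stop("invalid spec: groups: all sample_size and pop_size must be > 0")
  if (!all(g$group %in% cats$group))
    stop("invalid spec: groups: unknown group label")
  ip <- spec$income_params
  if (any(ip$sdlog <= 0))
    stop("invalid spec: income_params: sdlog must be > 0")
  if (!all(g$group %in% ip$group))
    stop("invalid spec: income_params: missing group")
  wp <- spec$welfare_params
  if (any(wp$p_zero < 0 | wp$p_zero > 1) || any(wp$sdlog <= 0))
    stop("invalid spec: welfare_params: p_zero in [0,1] and sdlog > 0 required")
  if (!all(g$group %in% wp$group))
    stop("invalid spec: welfare_params: missing group")
  if (!inherits(spec$tax, "tax_schedule"))
    stop("invalid spec: tax: not a tax_schedule")
  qe <- spec$quintile_edges
  if (length(qe) != 6 || qe[1] != 0 || any(diff(qe) <= 0))
    stop("invalid spec: quintile_edges: need 6 increasing edges from 0")
  mix_vars <- c("age_group", "sex", "education", "income_unit", "hours_band",
                "age_pension", "dsp", "home_owner")
  for (grp in g$group) {
    mixes <- spec$covariate_mixes[[grp]]
    if (is.null(mixes))
      stop("invalid spec: covariate_mixes: missing group ", grp)
    for (v in mix_vars) {
      p <- mixes[[v]]
      if (is.null(p))
        stop("invalid spec: covariate_mixes: group ", grp, " missing ", v)
      if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
        stop("invalid spec: covariate_mixes: group ", grp, " variable ", v,
             " does not sum to 1")
      lv <- if (v == "hours_band") c(cats$hours_band, "none") else cats[[v]]
      if (!all(names(p) %in% lv))
        stop("invalid spec: covariate_mixes: group ", grp, " variable ", v,
             " has unknown level")
    }
  }
  invisible(spec)
}

# Descriptive anchors (mean, sd, median of annual AU$) for the five analysis
# groups' income, welfare and tax in the 2010 study population, plus invented
# but realistic anchors for the unemployed and other-NILF groups the
# published tables omit.
default_anchors <- function() {
  list(
    income = data.frame(
      group = c("FT-no-condition", "PT-no-condition", "FT-diabetes",
                "PT-diabetes", "NILF-diabetes", "unemployed", "NILF-other"),
      mean = c(63190, 29068, 60389, 30857, 13900, 17500, 18500),
      sd = c(35182, 30037, 30117, 25743, 16727, 15000, 19000),
      median = c(54795, 21257, 52655, 26032, 11784, 14000, 14500)),
    welfare = data.frame(
      group = c("FT-no-condition", "PT-no-condition", "FT-diabetes",
                "PT-diabetes", "NILF-diabetes", "unemployed", "NILF-other"),
      mean = c(593, 1960, 305, 2377, 6048, 8000, 5200),
      sd = c(2462, 4351, 1728, 5048, 7296, 6000, 6800),
      median = c(0, 0, 0, 0, 986, 7400, 800),
      p_zero = c(0.75, 0.70, 0.80, 0.65, 0.25, 0.10, 0.40))
  )
}

default_covariate_mixes <- function() {
  employed_age <- c("45-49" = 0.30, "50-54" = 0.28, "55-59" = 0.24,
                    "60-64" = 0.18)
  nilf_age <- c("45-49" = 0.10, "50-54" = 0.20, "55-59" = 0.30,
                "60-64" = 0.40)
  ft_hours <- c("1-15" = 0, "16-24" = 0, "25-34" = 0, "35-40" = 0.65,
                "41+" = 0.35, "none" = 0)
  pt_hours <- c("1-15" = 0.35, "16-24" = 0.40, "25-34" = 0.25, "35-40" = 0,
                "41+" = 0, "none" = 0)
  no_hours <- c("1-15" = 0, "16-24" = 0, "25-34" = 0, "35-40" = 0,
                "41+" = 0, "none" = 1)
  emp_unit <- c("couple-dependents" = 0.35, "couple-only" = 0.35,
                "lone-parent" = 0.08, "lone-person" = 0.22)
  nilf_unit <- c("couple-dependents" = 0.20, "couple-only" = 0.45,
                 "lone-parent" = 0.08, "lone-person" = 0.27)
  flag <- function(p1) c("0" = 1 - p1, "1" = p1)
  mk <- function(age, sex_m, edu_u, unit, hours, pension1, dsp1, own1) {
    list(age_group = age,
         sex = c(male = sex_m, female = 1 - sex_m),
         education = c(university = edu_u, "non-university" = 1 - edu_u),
         income_unit = unit, hours_band = hours,
         age_pension = flag(pension1), dsp = flag(dsp1),
         home_owner = flag(own1))
  }
  list(
    "FT-no-condition" = mk(employed_age, 0.65, 0.35, emp_unit, ft_hours,
                           0.01, 0.005, 0.80),
    "PT-no-condition" = mk(employed_age, 0.25, 0.28, emp_unit, pt_hours,
                           0.01, 0.005, 0.80),
    "FT-diabetes" = mk(employed_age, 0.70, 0.25, emp_unit, ft_hours,
                       0.01, 0.01, 0.78),
    "PT-diabetes" = mk(employed_age, 0.35, 0.20, emp_unit, pt_hours,
                       0.02, 0.02, 0.76),
    "NILF-diabetes" = mk(nilf_age, 0.55, 0.10, nilf_unit, no_hours,
                         0.15, 0.55, 0.65),
    "unemployed" = mk(c("45-49" = 0.25, "50-54" = 0.25, "55-59" = 0.25,
                        "60-64" = 0.25), 0.55, 0.15, nilf_unit, no_hours,
                      0.02, 0.05, 0.60),
    "NILF-other" = mk(nilf_age, 0.40, 0.15, nilf_unit, no_hours,
                      0.20, 0.25, 0.75)
  )
}

default_condition_probs <- function() {
  diab <- c("0" = 0, "1" = 0.13, "2" = 0.11, "3" = 0.26, "4" = 0.50)
  none <- c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4" = 0)
  list("FT-no-condition" = none, "PT-no-condition" = none,
       "FT-diabetes" = diab, "PT-diabetes" = diab, "NILF-diabetes" = diab,
       "unemployed" = c("0" = 0.60, "1" = 0.25, "2" = 0.15, "3" = 0, "4" = 0),
       "NILF-other" = c("0" = 0, "1" = 0.35, "2" = 0.30, "3" = 0.20,
                        "4" = 0.15))
}

#' Default population specification for the 2010 study population
#'
#' Group record counts and weighted population sizes follow the published
#' study population of Australians aged 45-64 in 2010 (e.g. 46 survey records
#' and 11,310 weighted persons out of the labour force due to diabetes).
#' Income is log-normal per group with the location tied to the group median
#' and the scale derived from the group SD/mean ratio; welfare is a
#' zero-inflated log-normal whose mixing weight and parameters reproduce the
#' group median (0 for employed groups, positive for early retirees); tax is
#' computed from income through the marginal schedule. The unemployed and
#' other-NILF groups are included so counterfactual-employment calculations
#' have a complete labour-force denominator.
#'
#' @param seed Integer seed stored in the spec.
#' @return A [population_spec()].
#' @export
default_population_spec <- function(seed = 1L) {
  anchors <- default_anchors()
  inc <- do.call(rbind, lapply(seq_len(nrow(anchors$income)), function(i) {
    a <- anchors$income[i, ]
    p <- lognormal_anchor(a$mean, a$sd, a$median)
    data.frame(group = a$group, meanlog = p$meanlog, sdlog = p$sdlog)
  }))
  wel <- do.call(rbind, lapply(seq_len(nrow(anchors$welfare)), function(i) {
    a <- anchors$welfare[i, ]
    p <- zi_lognormal_anchor(a$mean, a$sd, a$median, a$p_zero)
    data.frame(group = a$group, p_zero = p$p_zero, meanlog = p$meanlog,
               sdlog = p$sdlog)
  }))
  population_spec(
    groups = data.frame(
      group = c("FT-no-condition", "PT-no-condition", "FT-diabetes",
                "PT-diabetes", "NILF-diabetes", "unemployed", "NILF-other"),
      sample_size = c(6606, 2373, 345, 105, 46, 300, 2000),
      pop_size = c(1413511, 467796, 88889, 25329, 11310, 80000, 600000)),
    income_params = inc,
    welfare_params = wel,
    tax = tax_schedule(),
    covariate_mixes = default_covariate_mixes(),
    covariate_effects = list(
      age_group = c("45-49" = 0.05, "50-54" = 0.08, "55-59" = 0.02,
                    "60-64" = -0.15),
      sex = c(male = 0.12, female = -0.12),
      education = c(university = 0.25, "non-university" = -0.08)),
    condition_count_probs = default_condition_probs(),
    seed = seed)
}

#' Load the bundled adjusted group-effect configuration
#'
#' Reads the adjusted percent differences (income, welfare, tax liability;
#' each group versus full-time employed with no chronic condition) estimated
#' for the 2010 study population, shipped with the package as JSON.
#'
#' @param path Path to the JSON file; defaults to the bundled configuration.
#' @return List with elements `reference` and `percent_difference`.
#' @export
load_group_effects <- function(path = system.file("extdata",
                                                  "group_effects_2010.json",
                                                  package = "retiresim")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Population spec with income effects set from an adjusted-effect table
#'
#' Builds a spec identical to [default_population_spec()] except that
#' per-group log-income locations are set to `log(ref_median) +
#' log(1 + pct/100)` from an adjusted percent-difference configuration, so
#' the generating group effects on log income are known exactly, and the
#' log-income scale is common to all groups (the reference group's), matching
#' the homoscedasticity assumption of the fitted regression. Used for
#' parameter-recovery studies of the regression stage.
#'
#' @param effects As returned by [load_group_effects()].
#' @param ref_median Median annual income (AU$/yr) of the reference group.
#' @param seed Integer seed stored in the spec.
#' @return A [population_spec()].
#' @export
population_spec_from_effects <- function(effects = load_group_effects(),
                                         ref_median = 54795, seed = 1L) {
  spec <- default_population_spec(seed = seed)
  pct <- effects$percent_difference$income
  spec$income_params$meanlog[
    spec$income_params$group == effects$reference] <- log(ref_median)
  for (g in names(pct)) {
    spec$income_params$meanlog[spec$income_params$group == g] <-
      log(ref_median) + log1p(pct[[g]] / 100)
  }
  spec$income_params$sdlog <- spec$income_params$sdlog[
    spec$income_params$group == effects$reference]
  validate_population_spec(spec)
  spec
}
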