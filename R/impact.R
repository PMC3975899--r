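#' Counterfactual employment structure
#'
#' Shares of full-time employment, part-time employment and non-employment
#' that persons out of the labour force due to the condition would have had
#' under the counterfactual — by default the structure observed among persons
#' with no chronic health condition.
#'
#' @param ft_share,pt_share,nonemp_share Proportions in `[0, 1]` summing to 1
#'   (within 1e-8); `nonemp_share` defaults to the residual.
#' @return Object of class `counterfactual_spec`.
#' @export
counterfactual_spec <- function(ft_share, pt_share,
                                nonemp_share = 1 - ft_share - pt_share) {
  s <- c(ft_share, pt_share, nonemp_share)
  if (any(s < -1e-8) || any(s > 1 + 1e-8) || abs(sum(s) - 1) > 1e-8)
    stop("counterfactual_spec: shares must lie in [0,1] and sum to 1")
  structure(list(ft_share = ft_share, pt_share = pt_share,
                 nonemp_share = nonemp_share),
            class = "counterfactual_spec")
}

#' Reference employment shares observed in weighted survey data
#'
#' Computes the full-time / part-time / non-employed split of the reference
#' (no-chronic-condition) population from weighted records: full- and
#' part-time employed with no condition, with the unemployed and other-NILF
#' groups as the non-employed pool.
#'
#' @param records Survey records with a `group` column.
#' @param weights Calibrated weights aligned with `records`.
#' @return A [counterfactual_spec()].
#' @export
reference_shares <- function(records, weights) {
  ft <- sum(weights[records$group == "FT-no-condition"])
  pt <- sum(weights[records$group == "PT-no-condition"])
  ne <- sum(weights[records$group %in% c("unemployed", "NILF-other")])
  tot <- ft + pt + ne
  if (tot <= 0) stop("reference_shares: no reference-population records")
  counterfactual_spec(ft / tot, pt / tot, ne / tot)
}

# Median-scale prediction exp(X beta) - offset for records re-assigned to
# `as_group`, floored at 0.
predict_in_state <- function(model, records, as_group) {
  nd <- records
  nd$group <- as_group
  for (v in model$covariates) {
    lev <- levels(model$fit$model[[v]])
    bad <- !(as.character(nd[[v]]) %in% lev)
    if (any(bad))
      stop("predict_in_state: level(s) of '", v,
           "' absent from fitted model: ",
           paste(unique(nd[[v]][bad]), collapse = ", "))
    nd[[v]] <- factor(as.character(nd[[v]]), levels = lev)
  }
  pmax(exp(as.vector(stats::predict(model$fit, newdata = nd))) -
         model$offset, 0)
}

#' Per-record counterfactual economics for early retirees
#'
#' For each person out of the labour force due to the condition, computes the
#' counterfactual annual income, welfare and tax as the mixture, with the
#' reference employment shares, of the covariate-adjusted median-scale model
#' prediction in the full-time and part-time states and the person's actual
#' values in the non-employed state. Losses are `counterfactual - actual`,
#' floored at 0 for income and tax; the welfare difference is sign-flipped
#' into "extra welfare" (actual - counterfactual).
#'
#' @param nilf_records Records of persons out of the labour force due to the
#'   condition, carrying the model covariates and actual `income`, `welfare`,
#'   `tax`.
#' @param models Named list of fitted [fit_log_model()] objects: `income`,
#'   `welfare`, `tax`, each fitted with group levels including the full-time
#'   and part-time reference states.
#' @param spec A [counterfactual_spec()].
#' @param ft_group,pt_group Group labels of the employed reference states.
#' @return data.frame: per record the counterfactual outcomes (`cf_income`,
#'   `cf_welfare`, `cf_tax`), `loss_income`, `extra_welfare`, `loss_tax`.
#' @export
counterfactual_economics <- function(nilf_records, models, spec,
                                     ft_group = "FT-no-condition",
                                     pt_group = "PT-no-condition") {
  stopifnot(inherits(spec, "counterfactual_spec"))
  for (y in c("income", "welfare", "tax")) {
    m <- models[[y]]
    if (is.null(m) || !inherits(m, "log_model"))
      stop("counterfactual_economics: models$", y, " must be a log_model")
    glev <- levels(m$fit$model$group)
    if (!all(c(ft_group, pt_group) %in% glev))
      stop("counterfactual_economics: reference employment group(s) absent ",
           "from fitted effects for ", y)
  }
  cf <- function(y) {
    pred_ft <- predict_in_state(models[[y]], nilf_records, ft_group)
    pred_pt <- predict_in_state(models[[y]], nilf_records, pt_group)
    spec$ft_share * pred_ft + spec$pt_share * pred_pt +
      spec$nonemp_share * nilf_records[[y]]
  }
  out <- data.frame(record_id = nilf_records$record_id,
                    cf_income = cf("income"), cf_welfare = cf("welfare"),
                    cf_tax = cf("tax"), stringsAsFactors = FALSE)
  out$loss_income <- pmax(out$cf_income - nilf_records$income, 0)
  out$extra_welfare <- nilf_records$welfare - out$cf_welfare
  out$loss_tax <- pmax(out$cf_tax - nilf_records$tax, 0)
  out
}

#' National impact container
#'
#' @param n_out_of_lf Weighted persons out of the labour force due to the
#'   condition.
#' @param lost_income,extra_welfare,lost_tax,gdp_loss National totals in
#'   AU$ million per year (`gdp_loss` may be `NA` until computed).
#' @param scenario `"base"` or `"preventable"`.
#' @return Object of class `national_impact`.
#' @export
national_impact <- function(n_out_of_lf, lost_income, extra_welfare,
                            lost_tax, gdp_loss = NA_real_,
                            scenario = "base") {
  vals <- c(n_out_of_lf, lost_income, extra_welfare, lost_tax)
  if (any(vals < 0) || (!is.na(gdp_loss) && gdp_loss < 0))
    stop("national_impact: all components must be >= 0")
  structure(list(n_out_of_lf = n_out_of_lf, lost_income = lost_income,
                 extra_welfare = extra_welfare, lost_tax = lost_tax,
                 gdp_loss = gdp_loss, scenario = scenario),
            class = "national_impact")
}

#' @export
print.national_impact <- function(x, ...) {
  cat("national_impact [", x$scenario, "]: n = ",
      format(round(x$n_out_of_lf), big.mark = ","),
      "; lost income ", round(x$lost_income, 1),
      " AU$M; extra welfare ", round(x$extra_welfare, 1),
      " AU$M; lost tax ", round(x$lost_tax, 1), " AU$M; GDP loss ",
      if (is.na(x$gdp_loss)) "NA" else round(x$gdp_loss, 1), " AU$M\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.national_impact <- function(x, ...) {
  data.frame(scenario = x$scenario, n_out_of_lf = round(x$n_out_of_lf),
             lost_income = round(x$lost_income, 1),
             extra_welfare = round(x$extra_welfare, 1),
             lost_tax = round(x$lost_tax, 1),
             gdp_loss = round(x$gdp_loss, 1), stringsAsFactors = FALSE)
}

#' Aggregate per-record losses to national totals
#'
#' Each national figure is the weight-summed per-record loss, expressed in
#' AU$ million per year. Values are kept unrounded internally; rounding to
#' 0.1 AU$ million happens only at reporting.
#'
#' @param losses Output of [counterfactual_economics()].
#' @param weights Calibrated weights aligned with `losses`.
#' @param scenario Scenario label.
#' @return A [national_impact()] (without GDP; see [gdp_loss()]).
#' @export
national_losses <- function(losses, weights, scenario = "base") {
  if (length(weights) != nrow(losses))
    stop("national_losses: weights and losses lengths differ")
  national_impact(
    n_out_of_lf = sum(weights),
    lost_income = sum(weights * losses$loss_income) / 1e6,
    extra_welfare = sum(weights * losses$extra_welfare) / 1e6,
    lost_tax = sum(weights * losses$loss_tax) / 1e6,
    scenario = scenario)
}

#' GDP identity parameters
#'
#' Parameters of the output decomposition
#' `GDP = GDP/H x H/EMP x EMP/LF x LF/Pop15+ x Pop15+` (productivity per
#' hour, hours per worker, employment rate, participation rate, adult
#' population). The shipped defaults are illustrative 2010-era values for
#' Australia — an assumption, since the hourly-productivity and average-hours
#' components are not published alongside the study estimates — and should be
#' replaced with official aggregates when available.
#'
#' @param gdp_per_hour AU$ of GDP per hour worked (GDP/H).
#' @param hours_per_worker Hours worked per employed person per year (H/EMP).
#' @param employment_rate EMP/LF, in (0, 1].
#' @param participation_rate LF/Pop15+, in (0, 1].
#' @param population_15plus Persons aged 15+.
#' @return Object of class `gdp_parameters`.
#' @export
gdp_parameters <- function(gdp_per_hour = 68.5, hours_per_worker = 1710,
                           employment_rate = 0.948,
                           participation_rate = 0.657,
                           population_15plus = 17.8e6) {
  vals <- c(gdp_per_hour, hours_per_worker, employment_rate,
            participation_rate, population_15plus)
  if (any(vals <= 0))
    stop("gdp_parameters: all parameters must be strictly positive")
  if (employment_rate > 1 || participation_rate > 1)
    stop("gdp_parameters: rates must lie in (0, 1]")
  structure(list(gdp_per_hour = gdp_per_hour,
                 hours_per_worker = hours_per_worker,
                 employment_rate = employment_rate,
                 participation_rate = participation_rate,
                 population_15plus = population_15plus),
            class = "gdp_parameters")
}

#' GDP loss from removing workers (marginal form of the identity)
#'
#' Values `n` workers removed from employment at the identity's fixed
#' productivity and hours components: `dGDP = GDP/H x H/EMP x n`, in AU$
#' million per year. This equals the difference form (total GDP before minus
#' after reducing EMP and LF by `n` with GDP/H and H/EMP held fixed) exactly,
#' since GDP depends on EMP only through the product.
#'
#' @param n_workers_removed Persons removed from employment, >= 0.
#' @param params A [gdp_parameters()].
#' @return AU$ million per year.
#' @export
gdp_loss <- function(n_workers_removed, params = gdp_parameters()) {
  stopifnot(inherits(params, "gdp_parameters"))
  if (any(n_workers_removed < 0))
    stop("gdp_loss: n_workers_removed must be >= 0")
  params$gdp_per_hour * params$hours_per_worker * n_workers_removed / 1e6
}

#' @rdname gdp_loss
#' @details `gdp_loss_difference_form()` recomputes the loss as total GDP
#'   before minus after the worker removal, propagating `n` through the full
#'   identity (EMP and LF both reduced by `n`; GDP/H and H/EMP fixed).
#' @export
gdp_loss_difference_form <- function(n_workers_removed,
                                     params = gdp_parameters()) {
  stopifnot(inherits(params, "gdp_parameters"))
  emp <- params$employment_rate * params$participation_rate *
    params$population_15plus
  if (any(n_workers_removed < 0) || any(n_workers_removed > emp))
    stop("gdp_loss_difference_form: n_workers_removed must be in [0, EMP]")
  before <- params$gdp_per_hour * params$hours_per_worker * emp
  after <- params$gdp_per_hour * params$hours_per_worker *
    (emp - n_workers_removed)
  (before - after) / 1e6
}

#' Preventable-fraction sensitivity scenario
#'
#' Scales a national impact by the fraction of cases with the preventable
#' form of the condition: the person count and every monetary field are
#' multiplied by `fraction`, with persons rounded to the nearest integer and
#' money to 0.1 AU$ million (the reporting precision).
#'
#' @param base A [national_impact()].
#' @param fraction Proportion in `[0, 1]` (0.89 for Type 2 diabetes among
#'   people aged 40-59).
#' @return A [national_impact()] with `scenario = "preventable"`.
#' @export
apply_preventable_fraction <- function(base, fraction) {
  stopifnot(inherits(base, "national_impact"))
  if (fraction < 0 || fraction > 1)
    stop("apply_preventable_fraction: fraction must lie in [0, 1]")
  national_impact(
    n_out_of_lf = round(base$n_out_of_lf * fraction),
    lost_income = round(base$lost_income * fraction, 1),
    extra_welfare = round(base$extra_welfare * fraction, 1),
    lost_tax = round(base$lost_tax * fraction, 1),
    gdp_loss = if (is.na(base$gdp_loss)) NA_real_ else
      round(base$gdp_loss * fraction, 1),
    scenario = "preventable")
}
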