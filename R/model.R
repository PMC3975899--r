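#' Weighted mean, SD and median
#'
#' The weighted median uses the convention: the smallest observed value whose
#' cumulative weight reaches at least half the total weight. The weighted SD
#' comes from the weighted second moment (population form).
#'
#' @param x Numeric values.
#' @param w Strictly positive weights.
#' @return Single numeric.
#' @export
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(pmax(sum(w * (x - m)^2) / sum(w), 0))
}

#' @rdname weighted_mean
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2)[1]]
}

#' Weighted descriptive statistics by labour-force/condition group
#'
#' Produces the descriptive table: per group, the unweighted record count,
#' weighted population size, and weighted mean, SD and median of each
#' economic outcome. Groups are reported in the conventional printed order
#' (the five analysis groups first); requested groups with no records are
#' omitted with a warning.
#'
#' @param data Records carrying `group`, the outcomes, and a weight column.
#' @param outcomes Character vector of outcome columns.
#' @param weight_col Name of the weight column.
#' @param groups Groups to report, in order.
#' @return data.frame, one row per non-empty group: `group`, `n`, `N`, then
#'   `<outcome>_mean`, `<outcome>_sd`, `<outcome>_median` per outcome.
#' @export
summarize_by_group <- function(data, outcomes = c("income", "welfare", "tax"),
                               weight_col = "weight",
                               groups = intersect(
                                 c(analysis_groups(),
                                   "unemployed", "NILF-other"),
                                 unique(data$group))) {
  w_all <- data[[weight_col]]
  if (is.null(w_all) || any(w_all <= 0))
    stop("summarize_by_group: weight column '", weight_col,
         "' must exist and be strictly positive")
  empty <- setdiff(groups, unique(data$group))
  if (length(empty)) {
    warning("summarize_by_group: omitting empty group(s): ",
            paste(empty, collapse = ", "))
    groups <- setdiff(groups, empty)
  }
  rows <- lapply(groups, function(g) {
    idx <- data$group == g
    w <- w_all[idx]
    row <- data.frame(group = g, n = sum(idx), N = sum(w),
                      stringsAsFactors = FALSE)
    for (y in outcomes) {
      v <- data[[y]][idx]
      row[[paste0(y, "_mean")]] <- weighted_mean(v, w)
      row[[paste0(y, "_sd")]] <- weighted_sd(v, w)
      row[[paste0(y, "_median")]] <- weighted_median(v, w)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the log-linear outcome regression
#'
#' Ordinary least squares on `log(outcome + offset)` with categorical dummies
#' for labour-force/condition group (reference: full-time employed, no
#' chronic condition), age group, sex and education — main effects only, no
#' interactions. By default the regression is unweighted on person records
#' (survey weights enter only descriptives and national totals); pass
#' `weights` for a weighted-least-squares fit.
#'
#' @param data Records carrying the outcome and covariates.
#' @param outcome One of `"income"`, `"welfare"`, `"tax"` (or any numeric
#'   column).
#' @param covariates Covariate columns; must include `group`.
#' @param offset Added inside the log; defaults to 0 for income (the
#'   generator guarantees income >= 1) and 1 AU$ for welfare and tax, which
#'   have legitimate zeros.
#' @param reference Reference level of `group`.
#' @param weights Optional case weights for weighted least squares.
#' @return Object of class `log_model`: the `lm` fit plus metadata.
#' @export
fit_log_model <- function(data, outcome = "income",
                          covariates = c("group", "age_group", "sex",
                                         "education"),
                          offset = if (outcome == "income") 0 else 1,
                          reference = "FT-no-condition", weights = NULL) {
  if (!outcome %in% names(data) || !is.numeric(data[[outcome]]))
    stop("fit_log_model: outcome '", outcome, "' is not a numeric column")
  y <- data[[outcome]]
  if (any(y + offset <= 0))
    stop("fit_log_model: outcome + offset must be > 0 for all records")
  groups_present <- unique(data$group)
  if (length(groups_present) < 2)
    stop("fit_log_model: need at least 2 groups")
  if (!reference %in% groups_present)
    stop("fit_log_model: reference group '", reference, "' absent")
  df <- data.frame(.logy = log(y + offset))
  for (v in covariates) df[[v]] <- factor(as.character(data[[v]]))
  df$group <- stats::relevel(df$group, ref = reference)
  fml <- stats::as.formula(paste(".logy ~", paste(covariates,
                                                  collapse = " + ")))
  fit <- stats::lm(fml, data = df, weights = weights)
  if (anyNA(stats::coef(fit)))
    stop("fit_log_model: collinear design; aliased column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  structure(list(fit = fit, outcome = outcome, offset = offset,
                 reference = reference, covariates = covariates),
            class = "log_model")
}

#' @export
print.log_model <- function(x, ...) {
  cat("log_model: log(", x$outcome, if (x$offset != 0)
    paste0(" + ", x$offset), ") ~ ",
    paste(x$covariates, collapse = " + "), ", reference = ", x$reference,
    "\n", sep = "")
  invisible(x)
}

#' Percent difference from a log-scale coefficient
#'
#' Back-transforms a log-scale regression coefficient to a percent difference
#' versus the reference: point estimate `(exp(beta) - 1) * 100`, 95% CI
#' endpoints `(exp(beta +/- 1.96 se) - 1) * 100`. Vectorised.
#'
#' @param beta Log-scale coefficient(s).
#' @param se Standard error(s), >= 0.
#' @return data.frame: `pct`, `ci_low`, `ci_high`.
#' @export
percent_difference <- function(beta, se = 0) {
  stopifnot(all(se >= 0))
  data.frame(pct = (exp(beta) - 1) * 100,
             ci_low = (exp(beta - 1.96 * se) - 1) * 100,
             ci_high = (exp(beta + 1.96 * se) - 1) * 100)
}

#' Adjusted group effects from a fitted log-linear model
#'
#' Extracts the group dummies from a [fit_log_model()] fit and back-transforms
#' them to adjusted percent differences with 95% CIs and two-sided p-values.
#'
#' @param model A `log_model`.
#' @return data.frame: `group`, `outcome`, `pct_diff`, `ci_low`, `ci_high`,
#'   `p_value`, with attribute `reference`.
#' @export
group_effects <- function(model) {
  stopifnot(inherits(model, "log_model"))
  sm <- summary(model$fit)$coefficients
  rows <- grep("^group", rownames(sm))
  pd <- percent_difference(sm[rows, 1], sm[rows, 2])
  out <- data.frame(group = sub("^group", "", rownames(sm)[rows]),
                    outcome = model$outcome, pct_diff = pd$pct,
                    ci_low = pd$ci_low, ci_high = pd$ci_high,
                    p_value = sm[rows, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference") <- model$reference
  out
}

#' Residual diagnostics for a fitted log-linear model
#'
#' Advisory checks of the regression assumptions: residual normality
#' (Shapiro-Wilk up to n = 5000, Anderson-Darling beyond), Breusch-Pagan
#' heteroscedasticity test, and QQ data. A perfect fit (all residuals
#' numerically zero) is flagged as degenerate and the tests are skipped.
#'
#' @param model A `log_model`.
#' @return List: `degenerate`, `normality` (htest or NULL),
#'   `heteroscedasticity` (htest or NULL), `qq` (data.frame of theoretical
#'   and sample quantiles).
#' @export
model_diagnostics <- function(model) {
  stopifnot(inherits(model, "log_model"))
  r <- stats::residuals(model$fit)
  degenerate <- max(abs(r)) < 1e-10
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(r))),
                   sample = sort(r))
  if (degenerate)
    return(list(degenerate = TRUE, normality = NULL,
                heteroscedasticity = NULL, qq = qq))
  normality <- if (length(r) <= 5000) stats::shapiro.test(r)
  else nortest::ad.test(r)
  list(degenerate = FALSE, normality = normality,
       heteroscedasticity = lmtest::bptest(model$fit), qq = qq)
}
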