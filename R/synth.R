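# Draw the categorical covariates for n records of one group.
draw_covariates <- function(spec, group, n) {
  mixes <- spec$covariate_mixes[[group]]
  draw <- function(p) names(p)[sample.int(length(p), n, replace = TRUE,
                                          prob = p)]
  out <- data.frame(
    age_group = draw(mixes$age_group),
    sex = draw(mixes$sex),
    education = draw(mixes$education),
    income_unit = draw(mixes$income_unit),
    hours_band = draw(mixes$hours_band),
    age_pension = draw(mixes$age_pension),
    dsp = draw(mixes$dsp),
    home_owner = draw(mixes$home_owner),
    stringsAsFactors = FALSE)
  cc <- spec$condition_count_probs
  out$n_conditions <- if (is.null(cc)) 0L else
    as.integer(names(cc[[group]])[sample.int(5, n, replace = TRUE,
                                             prob = cc[[group]])])
  out
}

# Covariate-dependent log-income location for given records of one group.
income_meanlog <- function(spec, group, cov) {
  eff <- spec$covariate_effects
  base <- spec$income_params$meanlog[spec$income_params$group == group]
  base + eff$age_group[cov$age_group] + eff$sex[cov$sex] +
    eff$education[cov$education]
}

draw_income <- function(spec, group, cov) {
  sdlog <- spec$income_params$sdlog[spec$income_params$group == group]
  mu <- income_meanlog(spec, group, cov)
  pmax(exp(mu + sdlog * stats::rnorm(nrow(cov))), 1)
}

draw_welfare <- function(spec, group, n) {
  wp <- spec$welfare_params[spec$welfare_params$group == group, ]
  positive <- stats::runif(n) >= wp$p_zero
  w <- numeric(n)
  w[positive] <- stats::rlnorm(sum(positive), wp$meanlog, wp$sdlog)
  w
}

income_to_quintile <- function(income, edges) {
  as.character(findInterval(income, edges, rightmost.closed = TRUE))
}

#' Generate synthetic survey microdata
#'
#' Produces one person-level record per unit of `spec$groups$sample_size`,
#' with categorical covariates drawn from the per-group mixes, an income
#' quintile derived from a latent income draw (so quintiles are consistent
#' with the income band ordering), and strictly positive design weights
#' jittered around `pop_size / sample_size` and renormalised so each group's
#' weighted total equals its target population exactly. Non-employed records
#' carry the sentinel hours band `"none"`. Fully reproducible under
#' `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return data.frame of survey records with one row per person.
#' @export
generate_survey <- function(spec) {
  validate_population_spec(spec)
  set.seed(spec$seed)
  parts <- lapply(seq_len(nrow(spec$groups)), function(i) {
    g <- spec$groups$group[i]
    n <- spec$groups$sample_size[i]
    cov <- draw_covariates(spec, g, n)
    latent <- draw_income(spec, g, cov)
    w <- stats::runif(n, 0.8, 1.2)
    w <- w * spec$groups$pop_size[i] / sum(w)
    cbind(data.frame(group = g, lfs = group_to_lfs(g),
                     stringsAsFactors = FALSE),
          cov,
          data.frame(income_quintile = income_to_quintile(
                       latent, spec$quintile_edges),
                     design_weight = w))
  })
  out <- do.call(rbind, parts)
  out <- cbind(record_id = sprintf("S%06d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Generate synthetic donor microdata with exact economic variables
#'
#' Donor records carry the same ten matching variables as survey records plus
#' exact annual income, welfare payments and tax liability. Group membership
#' is drawn with probability proportional to the weighted population sizes;
#' income is drawn from the group- and covariate-dependent log-normal in
#' `spec`; welfare from the group's zero-inflated log-normal; tax is computed
#' from income through `spec$tax`, so `tax <= income` always holds.
#'
#' @param spec A [population_spec()].
#' @param n Number of donor records, > 0.
#' @param seed Seed; defaults to `spec$seed + 1` so survey and donor draws
#'   differ under the same spec.
#' @return data.frame of donor records.
#' @export
generate_donors <- function(spec, n, seed = spec$seed + 1L) {
  validate_population_spec(spec)
  if (n <= 0) stop("generate_donors: n must be > 0")
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(
    1, n, spec$groups$pop_size / sum(spec$groups$pop_size)))
  parts <- lapply(seq_len(nrow(spec$groups)), function(i) {
    ni <- counts[i]
    if (ni == 0) return(NULL)
    g <- spec$groups$group[i]
    cov <- draw_covariates(spec, g, ni)
    income <- draw_income(spec, g, cov)
    welfare <- draw_welfare(spec, g, ni)
    cbind(data.frame(group = g, lfs = group_to_lfs(g),
                     stringsAsFactors = FALSE),
          cov,
          data.frame(income_quintile = income_to_quintile(
                       income, spec$quintile_edges),
                     income = income, welfare = welfare,
                     tax = tax_from_income(income, spec$tax)))
  })
  out <- do.call(rbind, parts)
  out <- cbind(donor_id = sprintf("D%06d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Population benchmark totals implied by a spec
#'
#' Computes, for one or more margins (cross-classifications of categorical
#' record variables), the expected weighted population total of every cell
#' under the spec's group sizes and covariate mixes (covariates independent
#' within group). Each margin partitions the population, so its cell totals
#' sum to the overall target population.
#'
#' @param spec A [population_spec()].
#' @param strata Character vector naming the variables of one margin, or a
#'   list of such vectors for several margins. `"group"` is allowed.
#' @return A [benchmark_table()].
#' @export
generate_benchmarks <- function(spec, strata) {
  validate_population_spec(spec)
  if (!is.list(strata)) strata <- list(strata)
  cats <- category_sets()
  cells <- list()
  for (m in seq_along(strata)) {
    vars <- strata[[m]]
    known <- c("group", names(spec$covariate_mixes[[1]]))
    bad <- setdiff(vars, known)
    if (length(bad))
      stop("generate_benchmarks: unknown stratum variable: ",
           paste(bad, collapse = ", "))
    levels_of <- function(v) {
      if (v == "group") spec$groups$group
      else if (v == "hours_band") c(cats$hours_band, "none")
      else cats[[v]]
    }
    grid <- expand.grid(lapply(vars, levels_of), stringsAsFactors = FALSE)
    names(grid) <- vars
    target <- numeric(nrow(grid))
    for (g in seq_len(nrow(spec$groups))) {
      grp <- spec$groups$group[g]
      p <- rep(1, nrow(grid))
      for (v in vars) {
        p <- p * if (v == "group") as.numeric(grid[[v]] == grp) else
          spec$covariate_mixes[[grp]][[v]][grid[[v]]]
      }
      target <- target + spec$groups$pop_size[g] * p
    }
    keep <- target > 0
    cell <- apply(grid[keep, , drop = FALSE], 1, function(r)
      paste(paste0(vars, "=", r), collapse = "|"))
    cells[[m]] <- data.frame(margin = m, cell = unname(cell),
                             target = target[keep],
                             stringsAsFactors = FALSE)
  }
  benchmark_table(do.call(rbind, cells),
                  total_population = sum(spec$groups$pop_size))
}
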