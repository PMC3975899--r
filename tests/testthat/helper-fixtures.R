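# Independent oracle for the calibration program: solve the full KKT block
# system of  min sum_i (w_i - d_i)^2 / (2 d_i)  s.t.  A w = b  directly.
# (The implementation under test uses the reduced GREG normal equations.)
qp_oracle <- function(d, A, b) {
  n <- length(d)
  m <- nrow(A)
  H <- diag(1 / d, n)
  K <- rbind(cbind(H, -t(A)), cbind(A, matrix(0, m, m)))
  rhs <- c(H %*% d, b)
  sol <- MASS::ginv(K) %*% rhs
  as.vector(sol[seq_len(n)])
}

# Chi-squared calibration distance.
chisq_distance <- function(w, d) sum((w - d)^2 / (2 * d))

# Random small calibration instance with consistent two-margin benchmarks
# (joint-table construction keeps the margins mutually consistent).
random_instance <- function(n, seed) {
  set.seed(seed)
  rec <- data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_group = sample(c("45-49", "50-54", "55-59"), n, replace = TRUE),
    design_weight = stats::runif(n, 0.5, 3))
  # guarantee every level occurs
  rec$sex[1:2] <- c("male", "female")
  rec$age_group[1:3] <- c("45-49", "50-54", "55-59")
  joint <- tapply(rec$design_weight, list(rec$sex, rec$age_group), sum)
  joint[is.na(joint)] <- 0
  joint <- joint * matrix(stats::runif(length(joint), 0.9, 1.1),
                          nrow(joint))
  tot <- sum(joint)
  cells <- rbind(
    data.frame(margin = 1, cell = paste0("sex=", rownames(joint)),
               target = rowSums(joint)),
    data.frame(margin = 2, cell = paste0("age_group=", colnames(joint)),
               target = colSums(joint)))
  list(records = rec, benchmarks = benchmark_table(cells, tot))
}

# A small two-group spec (one employed, one non-employed group) for fast
# structural tests.
tiny_spec <- function(seed = 1L, sample_sizes = c(40, 10),
                      pop_sizes = c(1.5e6, 5e5)) {
  spec <- default_population_spec(seed = seed)
  keep <- c("FT-no-condition", "NILF-diabetes")
  idx <- spec$groups$group %in% keep
  spec$groups <- spec$groups[idx, ]
  spec$groups$sample_size <- sample_sizes
  spec$groups$pop_size <- pop_sizes
  spec$income_params <- spec$income_params[spec$income_params$group %in%
                                             keep, ]
  spec$welfare_params <- spec$welfare_params[spec$welfare_params$group %in%
                                               keep, ]
  spec$covariate_mixes <- spec$covariate_mixes[keep]
  spec$condition_count_probs <- spec$condition_count_probs[keep]
  validate_population_spec(spec)
  spec
}

# A fully specified survey/donor record with every matching variable, for
# matching fixtures. Values can be overridden per field.
fixture_record <- function(id = "S000001", ...) {
  rec <- data.frame(record_id = id, group = "FT-no-condition", lfs = "FT",
                    age_group = "45-49", sex = "male",
                    education = "university",
                    income_unit = "couple-only", income_quintile = "3",
                    age_pension = "0", dsp = "0", hours_band = "35-40",
                    home_owner = "1", n_conditions = 0L,
                    design_weight = 1, stringsAsFactors = FALSE)
  over <- list(...)
  for (v in names(over)) rec[[v]] <- over[[v]]
  rec
}

fixture_records <- function(n, id_prefix = "S", ...) {
  rows <- lapply(seq_len(n), function(i)
    fixture_record(id = sprintf("%s%06d", id_prefix, i)))
  out <- do.call(rbind, rows)
  over <- list(...)
  for (v in names(over)) out[[v]] <- over[[v]]
  out
}

# Brute-force matching oracle: for one recipient, enumerate the donor pool at
# each prefix length of the priority list and return the first non-empty one.
brute_force_pool <- function(recipient, donors, priority = match_variables()) {
  if (is.null(donors$lfs) && !is.null(donors$group))
    donors$lfs <- group_to_lfs(donors$group)
  if (is.null(recipient$lfs) && !is.null(recipient$group))
    recipient$lfs <- group_to_lfs(recipient$group)
  for (k in length(priority):1) {
    vars <- priority[seq_len(k)]
    ok <- rep(TRUE, nrow(donors))
    for (v in vars)
      ok <- ok & (as.character(donors[[v]]) == as.character(recipient[[v]]))
    if (any(ok)) return(list(pool = which(ok), relaxed = length(priority) - k))
  }
  list(pool = integer(0), relaxed = NA_integer_)
}
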