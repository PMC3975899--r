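#' Benchmark table of population totals
#'
#' Holds the calibration constraints: one or more margins, each a partition
#' of the population into cells with target totals. A cell is written as
#' `"var=value"` pairs joined by `"|"`, e.g. `"age_group=45-49|sex=male"`.
#'
#' @param cells data.frame with columns `margin` (integer margin id), `cell`
#'   (cell descriptor string) and `target` (persons, > 0).
#' @param total_population Overall target population; every margin's targets
#'   must sum to it (relative tolerance 1e-6).
#' @return Object of class `benchmark_table`.
#' @export
benchmark_table <- function(cells, total_population) {
  stopifnot(all(c("margin", "cell", "target") %in% names(cells)))
  if (any(cells$target <= 0))
    stop("benchmark_table: all targets must be > 0")
  if (anyDuplicated(cells$cell))
    stop("benchmark_table: duplicated cell descriptor")
  for (m in unique(cells$margin)) {
    s <- sum(cells$target[cells$margin == m])
    if (abs(s - total_population) > 1e-6 * total_population)
      stop("benchmark_table: margin ", m, " sums to ", s,
           ", not the total population ", total_population)
  }
  structure(list(cells = cells, total_population = total_population),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("benchmark_table:", nrow(x$cells), "cells in",
      length(unique(x$cells$margin)), "margin(s), total population",
      format(x$total_population, big.mark = ","), "\n")
  invisible(x)
}

# Parse "var=val|var2=val2" into a named character vector.
parse_cell <- function(cell) {
  parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

# n x m indicator matrix of record membership in each benchmark cell.
cell_indicator_matrix <- function(records, benchmarks) {
  cells <- benchmarks$cells
  X <- matrix(0, nrow(records), nrow(cells))
  colnames(X) <- cells$cell
  for (j in seq_len(nrow(cells))) {
    def <- parse_cell(cells$cell[j])
    bad <- setdiff(names(def), names(records))
    if (length(bad))
      stop("cell ", cells$cell[j], ": variable not in records: ",
           paste(bad, collapse = ", "))
    ind <- rep(TRUE, nrow(records))
    for (v in names(def)) ind <- ind & (as.character(records[[v]]) == def[v])
    X[, j] <- as.numeric(ind)
  }
  X
}

#' Calibrate survey weights to benchmark totals (bounded GREG)
#'
#' Adjusts design weights so that weighted cell totals hit the benchmark
#' targets, minimising the truncated chi-squared distance
#' \eqn{\sum_i (w_i - d_i)^2 / (2 d_i)} subject to the calibration equations
#' and to per-record bounds \eqn{w_i \in [L d_i, U d_i]}. The unconstrained
#' step is the generalized-regression (GREG) solution
#' \eqn{w = d (1 + x^\top \lambda)}; weights that violate a bound are fixed
#' at the bound and the regression is re-solved on the remaining records
#' until no new truncations occur (truncate-and-resolve). Records belonging
#' to no benchmark cell pass through unchanged with a warning.
#'
#' @param records data.frame of survey records with a `design_weight` column.
#' @param benchmarks A [benchmark_table()].
#' @param bounds Length-2 numeric `(L, U)` with `0 < L <= 1 <= U`: allowed
#'   range of the weight adjustment ratio `w/d`.
#' @param tol Relative tolerance on every benchmark cell.
#' @param max_iter Maximum truncate-and-resolve iterations.
#' @return Object of class `calibration_result`: `weights`, `iterations`,
#'   `max_constraint_violation` (largest relative cell error, reported even
#'   on non-convergence), `truncated_count`, `converged`.
#' @export
calibrate_weights <- function(records, benchmarks, bounds = c(0.3, 3),
                              tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(benchmarks, "benchmark_table"))
  if (!(bounds[1] > 0 && bounds[1] <= 1 && bounds[2] >= 1))
    stop("calibrate_weights: bounds must satisfy 0 < L <= 1 <= U")
  if (tol <= 0) stop("calibrate_weights: tol must be > 0")
  d <- records$design_weight
  if (is.null(d) || any(d <= 0))
    stop("calibrate_weights: records need strictly positive design_weight")
  X <- cell_indicator_matrix(records, benchmarks)
  T_ <- benchmarks$cells$target
  empty <- colSums(X) == 0
  if (any(empty))
    stop("calibrate_weights: benchmark cell(s) with no survey records: ",
         paste(colnames(X)[empty], collapse = ", "))
  uncovered <- rowSums(X) == 0
  if (any(uncovered))
    warning(sum(uncovered), " record(s) belong to no benchmark cell; ",
            "their weights pass through unchanged")

  lo <- bounds[1] * d
  hi <- bounds[2] * d
  w <- d
  at_bound <- rep(FALSE, length(d))
  violation <- function(w) max(abs(crossprod(X, w) - T_) / T_)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    free <- !at_bound & !uncovered
    rhs <- T_ - as.vector(crossprod(X[!free, , drop = FALSE], w[!free]))
    Xf <- X[free, , drop = FALSE]
    M <- crossprod(Xf, Xf * d[free])
    resid <- rhs - as.vector(crossprod(Xf, d[free]))
    lambda <- tryCatch(solve(M, resid),
                       error = function(e) MASS::ginv(M) %*% resid)
    w[free] <- d[free] * (1 + as.vector(Xf %*% lambda))
    newly <- free & (w < lo | w > hi)
    w <- pmin(pmax(w, lo), hi)
    if (!any(newly)) {
      converged <- violation(w) <= tol
      break
    }
    at_bound <- at_bound | newly
  }
  structure(list(weights = w, iterations = iter,
                 max_constraint_violation = violation(w),
                 truncated_count = sum(at_bound), converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result:", if (x$converged) "converged" else
    "NOT converged", "in", x$iterations, "iteration(s); max relative",
    "violation", format(x$max_constraint_violation, digits = 3), ";",
    x$truncated_count, "weight(s) at bounds\n")
  invisible(x)
}

#' Per-cell benchmark error report
#'
#' Recomputes every benchmark cell's weighted total by direct summation and
#' reports the relative error, flagging cells above `tol`.
#'
#' @param records Survey records.
#' @param weights Weights aligned with `records`.
#' @param benchmarks A [benchmark_table()].
#' @param tol Flagging threshold on relative error.
#' @return data.frame: `margin`, `cell`, `target`, `achieved`,
#'   `relative_error`, `flagged`.
#' @export
check_benchmarks <- function(records, weights, benchmarks, tol = 1e-6) {
  if (length(weights) != nrow(records))
    stop("check_benchmarks: weights and records lengths differ")
  X <- cell_indicator_matrix(records, benchmarks)
  achieved <- as.vector(crossprod(X, weights))
  cells <- benchmarks$cells
  rel <- abs(achieved - cells$target) / cells$target
  data.frame(margin = cells$margin, cell = cells$cell,
             target = cells$target, achieved = achieved,
             relative_error = rel, flagged = rel > tol,
             stringsAsFactors = FALSE)
}
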