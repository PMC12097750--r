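#' Descriptive statistics table for a survey dataset
#'
#' Continuous variables (and the ordinal scales with published
#' mean/SD-style reporting) get n, mean and SD over non-missing values;
#' binary and categorical-style ordinal variables additionally get
#' per-level percentages. Rows follow the schema's reporting blocks
#' (outcomes, health-related, screening-related, sociodemographics).
#'
#' @param data Survey data frame.
#' @param schema Variable schema; see [default_schema()].
#' @return Data frame of class `pcq_descriptives` with columns `group`,
#'   `variable`, `level`, `n`, `percent`, `mean`, `sd`. Summary rows
#'   have `level = NA`; level rows have `percent` filled.
#' @export
describe_survey <- function(data, schema = default_schema()) {
  vars <- schema[schema$name %in% names(data), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    x <- data[[v$name]]
    obs <- x[!is.na(x)]
    rows[[length(rows) + 1]] <- data.frame(
      group = v$group, variable = v$name, level = NA_real_,
      n = length(obs), percent = NA_real_,
      mean = mean(obs), sd = stats::sd(obs), stringsAsFactors = FALSE)
    few_levels <- v$vtype %in% c("binary", "ordinal") && (v$hi - v$lo) <= 6
    if (few_levels && length(obs) > 0) {
      lv <- v$lo:v$hi
      cnt <- vapply(lv, function(l) sum(obs == l), 0)
      rows[[length(rows) + 1]] <- data.frame(
        group = v$group, variable = v$name, level = lv,
        n = cnt, percent = 100 * cnt / length(obs),
        mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pcq_descriptives", "data.frame")
  out
}

# Exact permutation distribution of the group-1 rank sum under ties:
# dynamic programming over doubled midranks (integers). Returns the
# two-sided p-value for the observed U.
exact_u_pvalue <- function(r2, n1, u_obs) {
  N <- length(r2)
  total_choose <- choose(N, n1)
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, n1 + 1, max_sum + 1)
  f[1, 1] <- 1
  for (item in r2) {
    kmax <- n1
    for (k in kmax:1) {
      shifted <- c(rep(0, item), f[k, seq_len(max_sum + 1 - item)])
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  counts <- f[n1 + 1, ]
  sums <- which(counts > 0) - 1          # doubled rank sums with mass
  u_vals <- sums / 2 - n1 * (n1 + 1) / 2 # corresponding U statistics
  mu <- n1 * (N - n1) / 2
  keep <- abs(u_vals - mu) >= abs(u_obs - mu) - 1e-9
  min(1, sum(counts[sums[keep] + 1]) / total_choose)
}

#' Mann-Whitney U comparison of an outcome between two groups
#'
#' U is computed from midranks, so each tied cross-group pair counts a
#' half win. The two-sided p-value uses the exact permutation
#' distribution of U (conditional on the observed ties) when
#' `n1 * n2 <= 400`, and otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x Outcome values in the first group (by convention the
#'   positively screened group, whose U is reported).
#' @param y Outcome values in the second group.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact
#'   computation; default `NULL` switches on `n1 * n2 <= 400`.
#' @return List of class `utest_result`: `u_statistic` (first group),
#'   `u_other`, `p_value`, `group_means`, `group_ns`, `tie_corrected`,
#'   `method`.
#' @examples
#' g <- mann_whitney_u(c(9, 12, 4), c(2, 0, 5, 7))
#' g$u_statistic
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(x, y))                      # midranks
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_y <- n1 * n2 - u_x
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- n1 * n2 <= 400
  if (exact) {
    p <- exact_u_pvalue(as.integer(round(2 * r)), n1, u_x)
    method <- "exact permutation"
  } else {
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z0 <- u_x - mu
      zstat <- (z0 - sign(z0) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(stats::pnorm(zstat),
                          stats::pnorm(zstat, lower.tail = FALSE)))
    }
    method <- "normal approximation (tie + continuity corrected)"
  }
  structure(list(u_statistic = u_x, u_other = u_y, p_value = p,
                 group_means = c(mean(x), mean(y)),
                 group_ns = c(n1, n2),
                 tie_corrected = has_ties, method = method),
            class = "utest_result")
}

#' @export
print.utest_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: U = %.1f (groups n = %d/%d), p = %.3g [%s]\n",
              x$u_statistic, x$group_ns[1], x$group_ns[2], x$p_value,
              x$method))
  cat(sprintf("  group means: %.2f vs %.2f\n",
              x$group_means[1], x$group_means[2]))
  invisible(x)
}

#' Compare the PCQ between the screening groups
#'
#' Convenience wrapper running [mann_whitney_u()] on one outcome split
#' by the binary screening-result column, positives first.
#'
#' @param data Survey data frame.
#' @param outcome Outcome column (default `"pcq_total"`).
#' @param group Binary grouping column (default `"screen_positive"`).
#' @return A `utest_result`.
#' @export
compare_screening_groups <- function(data, outcome = "pcq_total",
                                     group = "screen_positive") {
  stopifnot(outcome %in% names(data), group %in% names(data))
  g <- data[[group]]
  mann_whitney_u(data[[outcome]][!is.na(g) & g == 1],
                 data[[outcome]][!is.na(g) & g == 0])
}
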