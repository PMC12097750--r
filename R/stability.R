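# Child seeds for the B bootstrap replicates, derived once from the
# master seed so selection and refit stages see identical resamples.
derive_child_seeds <- function(master_seed, B) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Bootstrap stability selection for one outcome
#'
#' Draws `B` case-bootstrap resamples (size n, with replacement) of the
#' complete-case rows, runs the 10-fold cross-validated LASSO on each
#' (fold assignment re-randomized per bootstrap from a child seed), and
#' records, per bootstrap, the selected penalty and the coefficient
#' vector in original units. A predictor's selection frequency is the
#' fraction of bootstraps in which its coefficient at `lambda_min` is
#' nonzero. A resample whose outcome is constant is redrawn once; if
#' still degenerate that bootstrap is dropped with a warning and the
#' frequency denominator reduced.
#'
#' @param data Data frame of survey responses.
#' @param outcome Outcome column name.
#' @param predictors Candidate predictors; default: every column except
#'   the four PCQ scales.
#' @param B Number of bootstrap resamples (default 100).
#' @param k CV folds (default 10).
#' @param master_seed Integer master seed; the run is fully reproducible
#'   given it.
#' @param n_lambda,ratio Penalty grid parameters; see [lambda_path()].
#' @return List of class `selection_result`: `outcome`, `B` (effective),
#'   `frequency` (named, multiples of 1/B), `per_bootstrap` (list of
#'   records with `index`, `rows`, `lambda_min`, `beta_raw`,
#'   `intercept`), `n`, `predictors`, `seed`.
#' @export
bootstrap_selection <- function(data, outcome, predictors = NULL, B = 100,
                                k = 10, master_seed = 1,
                                n_lambda = 100, ratio = 1e-3) {
  if (is.null(predictors))
    predictors <- setdiff(names(data), c("pcq_total", "pcq_emotional",
                                         "pcq_physical", "pcq_social"))
  cols <- data[, c(outcome, predictors), drop = FALSE]
  cols <- cols[stats::complete.cases(cols), , drop = FALSE]
  n <- nrow(cols)
  if (n < 10 * k)
    warning("only ", n, " complete cases; fewer than 10 rows per fold")
  child <- derive_child_seeds(master_seed, B)
  records <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(child[b])
    rows <- sample.int(n, n, replace = TRUE)
    if (stats::var(cols[[outcome]][rows]) == 0) {
      rows <- sample.int(n, n, replace = TRUE)   # one redraw
      if (stats::var(cols[[outcome]][rows]) == 0) {
        warning("bootstrap ", b, ": zero-variance outcome after redraw; dropped")
        next
      }
    }
    cv <- cv_lasso(cols[rows, , drop = FALSE], outcome, predictors,
                   k = k, n_lambda = n_lambda, ratio = ratio,
                   seed = child[b])
    records[[b]] <- list(index = b, rows = rows, lambda_min = cv$lambda_min,
                         beta_raw = cv$beta_raw, intercept = cv$intercept)
  }
  records <- Filter(Negate(is.null), records)
  B_eff <- length(records)
  if (B_eff == 0) stop("all bootstrap resamples were degenerate")
  nz <- vapply(records, function(r) r$beta_raw != 0, logical(length(predictors)))
  freq <- rowMeans(nz)
  names(freq) <- predictors
  structure(list(outcome = outcome, B = B_eff, frequency = freq,
                 per_bootstrap = records, n = n, predictors = predictors,
                 seed = master_seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Bootstrap selection on '%s': B = %d, n = %d\n",
              x$outcome, x$B, x$n))
  top <- sort(x$frequency, decreasing = TRUE)
  top <- top[top > 0]
  cat("  top selection frequencies:\n")
  print(round(utils::head(top, 8), 2))
  invisible(x)
}

#' Apply the relevance threshold to selection frequencies
#'
#' A predictor is retained when it was selected in at least
#' `threshold` of the bootstraps (inclusive comparison). Retained
#' predictors are ordered by descending frequency, ties broken by the
#' candidate (schema) order.
#'
#' @param result A `selection_result` from [bootstrap_selection()].
#' @param threshold Relevance cut-off in `(0, 1]` (default 0.80).
#' @return List of class `selected_set`: `outcome`, `threshold`,
#'   `predictors` (character), `frequency` (named, for the retained
#'   predictors).
#' @export
select_predictors <- function(result, threshold = 0.80) {
  stopifnot(inherits(result, "selection_result"),
            threshold > 0, threshold <= 1)
  keep <- which(result$frequency >= threshold)
  ord <- keep[order(-result$frequency[keep], keep)]
  structure(list(outcome = result$outcome, threshold = threshold,
                 predictors = names(result$frequency)[ord],
                 frequency = result$frequency[ord]),
            class = "selected_set")
}

#' @export
print.selected_set <- function(x, ...) {
  cat(sprintf("Selected predictors for '%s' (threshold %.0f%%):\n",
              x$outcome, 100 * x$threshold))
  if (length(x$predictors) == 0) cat("  (none)\n")
  else for (p in x$predictors)
    cat(sprintf("  %-22s %.2f\n", p, x$frequency[[p]]))
  invisible(x)
}

#' Rank predictors by selection frequency across outcomes
#'
#' @param results A `selection_result` or a list of them (one per
#'   outcome).
#' @param threshold Threshold to annotate (default 0.80).
#' @return Data frame with columns `outcome`, `predictor`, `frequency`,
#'   `rank` (within outcome, descending frequency, ties by candidate
#'   order) and `selected` (frequency at or above the threshold).
#' @export
frequency_ranking <- function(results, threshold = 0.80) {
  if (inherits(results, "selection_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  out <- lapply(results, function(r) {
    ord <- order(-r$frequency, seq_along(r$frequency))
    data.frame(outcome = r$outcome,
               predictor = names(r$frequency)[ord],
               frequency = unname(r$frequency[ord]),
               rank = seq_along(ord),
               selected = unname(r$frequency[ord]) >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
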