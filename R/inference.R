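#' Root-mean-square and mean absolute prediction error
#'
#' @param y_obs,y_pred Equal-length numeric vectors.
#' @return Named numeric vector `c(rmse = , mae = )`.
#' @examples
#' fit_metrics(c(0, 0, 3), c(1, 0, 1))
#' @export
fit_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 1)
  e <- y_obs - y_pred
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Refit the cross-validated LASSO on the selected predictors per bootstrap
#'
#' Reuses the resampling scheme of [bootstrap_selection()] (same child
#' seeds from the same master seed, hence identical resamples) but
#' restricts the candidate set to the selected predictors. Each
#' bootstrap contributes its coefficient vector in original units and
#' its in-sample RMSE/MAE on that bootstrap's fitting sample.
#'
#' @param data Data frame of survey responses.
#' @param selected A `selected_set` from [select_predictors()]. An empty
#'   set yields intercept-only records with a warning.
#' @param B,k,master_seed,n_lambda,ratio As in [bootstrap_selection()].
#' @return List of class `coef_records`: `outcome`, `records` (one per
#'   effective bootstrap: `index`, `lambda_min`, `beta_raw`,
#'   `intercept`, `rmse`, `mae`), `predictors`, `n`, `seed`.
#' @export
refit_selected <- function(data, selected, B = 100, k = 10, master_seed = 1,
                           n_lambda = 100, ratio = 1e-3) {
  stopifnot(inherits(selected, "selected_set"))
  outcome <- selected$outcome
  preds <- selected$predictors
  intercept_only <- length(preds) == 0
  if (intercept_only)
    warning("empty selected set for '", outcome, "': intercept-only models")
  cols <- data[, c(outcome, preds), drop = FALSE]
  cols <- cols[stats::complete.cases(cols), , drop = FALSE]
  n <- nrow(cols)
  child <- derive_child_seeds(master_seed, B)
  records <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(child[b])
    rows <- sample.int(n, n, replace = TRUE)
    y <- cols[[outcome]][rows]
    if (stats::var(y) == 0) {
      rows <- sample.int(n, n, replace = TRUE)
      y <- cols[[outcome]][rows]
      if (stats::var(y) == 0) {
        warning("bootstrap ", b, ": zero-variance outcome after redraw; dropped")
        next
      }
    }
    if (intercept_only) {
      pred <- rep(mean(y), n)
      m <- fit_metrics(y, pred)
      records[[b]] <- list(index = b, lambda_min = NA_real_,
                           beta_raw = numeric(0), intercept = mean(y),
                           rmse = m[["rmse"]], mae = m[["mae"]])
      next
    }
    boot <- cols[rows, , drop = FALSE]
    cv <- cv_lasso(boot, outcome, preds, k = k, n_lambda = n_lambda,
                   ratio = ratio, seed = child[b])
    pred <- predict(cv, boot)
    m <- fit_metrics(y, pred)
    records[[b]] <- list(index = b, lambda_min = cv$lambda_min,
                         beta_raw = cv$beta_raw, intercept = cv$intercept,
                         rmse = m[["rmse"]], mae = m[["mae"]])
  }
  records <- Filter(Negate(is.null), records)
  structure(list(outcome = outcome, records = records, predictors = preds,
                 n = n, seed = master_seed),
            class = "coef_records")
}

#' Summarize bootstrap refits into a final model
#'
#' Averages the per-bootstrap coefficients (a predictor unselected
#' within a refit contributes its genuine zero), takes the bootstrap
#' standard deviation as the coefficient's standard error, and builds
#' normal-approximation confidence intervals `mean +/- z * se`
#' (`z = 1.96` for 95%). RMSE and MAE are averaged over bootstraps; the
#' outcome SD comes from the original, non-resampled complete cases,
#' and the model is flagged well fitted when average RMSE is below it.
#'
#' @param records A `coef_records` from [refit_selected()].
#' @param data The original survey data frame.
#' @param outcome Outcome name; default taken from `records`.
#' @param z Normal quantile for the interval (default 1.96).
#' @param conf_method `"normal"` (default) or `"percentile"` (empirical
#'   2.5/97.5 percentiles of the bootstrap coefficients).
#' @return List of class `final_model`: `outcome`, `predictors`,
#'   `coef_mean`, `coef_se`, `ci_low`, `ci_high`, `significant` (CI
#'   excluding 0, inclusive endpoints count as covering), `rmse`, `mae`,
#'   `outcome_sd`, `well_fitted`, `B`.
#' @export
summarize_final <- function(records, data, outcome = records$outcome,
                            z = 1.96,
                            conf_method = c("normal", "percentile")) {
  stopifnot(inherits(records, "coef_records"), length(records$records) >= 2)
  conf_method <- match.arg(conf_method)
  preds <- records$predictors
  Bmat <- do.call(rbind, lapply(records$records, function(r) {
    b <- stats::setNames(numeric(length(preds)), preds)
    if (length(r$beta_raw)) b[names(r$beta_raw)] <- r$beta_raw
    b
  }))
  coef_mean <- if (length(preds)) colMeans(Bmat) else numeric(0)
  coef_se <- if (length(preds)) apply(Bmat, 2, stats::sd) else numeric(0)
  if (conf_method == "normal") {
    ci_low <- coef_mean - z * coef_se
    ci_high <- coef_mean + z * coef_se
  } else {
    qs <- apply(Bmat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    ci_low <- qs[1, ]; ci_high <- qs[2, ]
    names(ci_low) <- names(ci_high) <- preds
  }
  rmse <- mean(vapply(records$records, `[[`, 0, "rmse"))
  mae <- mean(vapply(records$records, `[[`, 0, "mae"))
  y <- data[[outcome]]
  cc <- stats::complete.cases(data[, c(outcome, preds), drop = FALSE])
  outcome_sd <- stats::sd(y[cc])
  structure(list(outcome = outcome, predictors = preds,
                 coef_mean = coef_mean, coef_se = coef_se,
                 ci_low = ci_low, ci_high = ci_high,
                 significant = significance_from_ci(ci_low, ci_high),
                 rmse = rmse, mae = mae, outcome_sd = outcome_sd,
                 well_fitted = rmse < outcome_sd,
                 B = length(records$records)),
            class = "final_model")
}

significance_from_ci <- function(ci_low, ci_high) ci_low > 0 | ci_high < 0

#' Per-predictor significance flags from a final model
#'
#' A predictor is flagged significant when its confidence interval
#' excludes zero; an interval with an endpoint exactly at zero covers
#' zero and is not significant.
#'
#' @param model A `final_model` from [summarize_final()].
#' @return Named logical vector.
#' @export
significance_flags <- function(model) {
  stopifnot(inherits(model, "final_model"))
  significance_from_ci(model$ci_low, model$ci_high)
}

#' Format a final model as a report table
#'
#' Coefficients, confidence bounds, RMSE, MAE and the outcome SD are
#' rounded to 2 decimals and standard errors to 3, the print precision
#' of the study-style report.
#'
#' @param model A `final_model`.
#' @return Data frame with rows for each predictor plus footer rows
#'   `RMSE`, `SD of scale`, `MAE`.
#' @export
format_final_model <- function(model) {
  stopifnot(inherits(model, "final_model"))
  head_rows <- data.frame(
    term = model$predictors,
    coefficient = round(model$coef_mean, 2),
    se = round(model$coef_se, 3),
    ci = sprintf("[%.2f; %.2f]", model$ci_low, model$ci_high),
    significant = ifelse(model$significant, "yes", "no"),
    stringsAsFactors = FALSE)
  foot <- data.frame(
    term = c("RMSE", "SD of scale", "MAE"),
    coefficient = round(c(model$rmse, model$outcome_sd, model$mae), 2),
    se = NA_real_, ci = "", significant = "",
    stringsAsFactors = FALSE)
  rbind(head_rows, foot)
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("Final bootstrap-averaged model for '%s' (B = %d)\n",
              x$outcome, x$B))
  if (length(x$predictors) == 0) cat("  no predictors selected\n")
  else print.data.frame(format_final_model(x), row.names = FALSE)
  cat(sprintf("  %s fitted on average (RMSE %.2f vs outcome SD %.2f)\n",
              if (x$well_fitted) "well" else "NOT well", x$rmse, x$outcome_sd))
  invisible(x)
}
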