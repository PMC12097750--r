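#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the scalar kernel of coordinate
#' descent under an L1 penalty.
#'
#' @param z Numeric vector.
#' @param gamma Threshold, `gamma >= 0`.
#' @return Thresholded values, same length as `z`.
#' @examples
#' soft_threshold(c(3, -0.5, -3), 1)
#' @export
soft_threshold <- function(z, gamma) {
  stopifnot(gamma >= 0)
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Standardize a design matrix for penalized fitting
#'
#' Centers each column and scales it to unit population standard
#' deviation (the `1/n` variance convention, under which the smallest
#' all-zero penalty is `max_j |x_j' y| / n`), and centers the response.
#' Columns with zero variance are dropped and recorded; their
#' coefficients are reported as zero downstream.
#'
#' @param X Numeric matrix (or data frame) of predictors, n x p.
#' @param y Numeric response vector, length n.
#' @return List of class `std_design`: `X_std`, `y_centered`,
#'   `col_means`, `col_sds` (for retained columns), `y_mean`, `names`
#'   (retained), `dropped` (zero-variance names), `n`, `p`.
#' @export
standardize_design <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sds <- sqrt(colSums(Xc^2) / n)
  keep <- sds > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, sds[keep], "/")
  structure(list(
    X_std = Xs,
    y_centered = y - mean(y),
    col_means = mu[keep],
    col_sds = sds[keep],
    y_mean = mean(y),
    names = colnames(X)[keep],
    dropped = colnames(X)[!keep],
    n = n, p = sum(keep)), class = "std_design")
}

#' Penalty grid for a LASSO path
#'
#' `lambda_max = max_j |x_j' y| / n` on the standardized design (the
#' smallest penalty at which every coefficient is zero), then a
#' log-spaced decreasing grid down to `ratio * lambda_max`.
#'
#' @param design A `std_design` from [standardize_design()].
#' @param n_lambda Grid length (default 100).
#' @param ratio Ratio of smallest to largest penalty (default 1e-3).
#' @return Decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(design, n_lambda = 100, ratio = 1e-3) {
  stopifnot(inherits(design, "std_design"), n_lambda >= 2,
            ratio > 0, ratio < 1)
  lambda_max <- max(abs(crossprod(design$X_std, design$y_centered))) / design$n
  if (!is.finite(lambda_max) || lambda_max <= 0)
    stop("path error: degenerate response (lambda_max is zero)")
  exp(seq(log(lambda_max), log(ratio * lambda_max), length.out = n_lambda))
}

# Fit the whole path on Gram quantities; returns p_keep x L standardized
# coefficient matrix plus iteration/convergence info.
cd_path_fit <- function(design, lambda, tol = 1e-7, max_iter = 1e5) {
  G <- crossprod(design$X_std)
  cc <- drop(crossprod(design$X_std, design$y_centered))
  lasso_cd_path(G, cc, design$n, lambda, tol, as.integer(max_iter))
}

# Pure-R cyclic coordinate descent with an objective trace; used by
# fit_lasso(debug = TRUE) to assert sweep-wise monotonicity.
cd_fit_r <- function(design, lambda, tol = 1e-7, max_iter = 1e5) {
  X <- design$X_std; y <- design$y_centered; n <- design$n; p <- ncol(X)
  gjj <- colSums(X^2) / n
  b <- numeric(p)
  r <- y
  obj <- function(b) sum((y - X %*% b)^2) / (2 * n) + lambda * sum(abs(b))
  trace <- obj(b)
  it <- 0; ok <- FALSE
  while (it < max_iter) {
    it <- it + 1
    max_delta <- 0
    for (j in seq_len(p)) {
      if (gjj[j] <= 0) next
      z <- sum(X[, j] * r) / n + gjj[j] * b[j]
      bj <- soft_threshold(z, lambda) / gjj[j]
      d <- bj - b[j]
      if (d != 0) {
        r <- r - X[, j] * d
        b[j] <- bj
        max_delta <- max(max_delta, abs(d))
      }
    }
    trace <- c(trace, obj(b))
    if (max_delta < tol) { ok <- TRUE; break }
  }
  list(beta = b, n_iter = it, converged = ok, objective_trace = trace)
}

#' Fit the LASSO at a single penalty by cyclic coordinate descent
#'
#' Minimizes `(1/(2n)) ||y - X beta||^2 + lambda ||beta||_1` on the
#' standardized design and back-transforms to the original predictor
#' units: `beta_raw[j] = beta_std[j] / col_sds[j]` with the intercept
#' chosen so that predictions on the raw scale match predictions on the
#' standardized scale.
#'
#' @param design A `std_design` from [standardize_design()].
#' @param lambda Penalty, `lambda >= 0`.
#' @param tol Convergence tolerance: largest coefficient update in a
#'   full sweep (standardized scale), default 1e-7.
#' @param max_iter Sweep cap (default 1e5); non-convergence returns the
#'   current iterate with `converged = FALSE` and a warning.
#' @param debug If `TRUE`, use the reference R implementation, record
#'   the objective after every sweep and error if any sweep increases it.
#' @return List of class `lasso_fit`: `lambda`, `beta_std`, `beta_raw`,
#'   `intercept_raw`, `n_iter`, `converged` (and `objective_trace` when
#'   `debug = TRUE`). Coefficient vectors are named; zero-variance
#'   columns dropped during standardization appear with coefficient 0.
#' @export
fit_lasso <- function(design, lambda, tol = 1e-7, max_iter = 1e5,
                      debug = FALSE) {
  stopifnot(inherits(design, "std_design"), lambda >= 0)
  if (debug) {
    f <- cd_fit_r(design, lambda, tol, max_iter)
    dobj <- diff(f$objective_trace)
    if (any(dobj > 1e-10))
      stop("internal error: coordinate-descent objective increased")
    beta_std <- f$beta
    n_iter <- f$n_iter; converged <- f$converged
    trace <- f$objective_trace
  } else {
    f <- cd_path_fit(design, lambda, tol, max_iter)
    beta_std <- f$beta[, 1]
    n_iter <- f$n_iter[1]; converged <- f$converged[1]
    trace <- NULL
  }
  if (!converged)
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  names(beta_std) <- design$names
  beta_raw <- beta_std / design$col_sds
  intercept <- design$y_mean - sum(beta_raw * design$col_means)
  all_names <- c(design$names, design$dropped)
  full_std <- stats::setNames(numeric(length(all_names)), all_names)
  full_raw <- full_std
  full_std[design$names] <- beta_std
  full_raw[design$names] <- beta_raw
  out <- list(lambda = lambda, beta_std = full_std, beta_raw = full_raw,
              intercept_raw = intercept, n_iter = n_iter,
              converged = converged)
  if (!is.null(trace)) out$objective_trace <- trace
  class(out) <- "lasso_fit"
  out
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$beta_raw != 0)
  cat(sprintf("LASSO fit: lambda = %.5g, %d nonzero coefficient(s), %s\n",
              x$lambda, nz,
              if (x$converged) sprintf("converged in %d sweep(s)", x$n_iter)
              else "NOT converged"))
  invisible(x)
}

#' Cross-validated LASSO for one survey outcome
#'
#' Complete cases on the outcome and all candidate predictors are used.
#' The penalty grid is built from the full standardized design; rows are
#' shuffled into `k` folds of sizes differing by at most one (seeded);
#' for each fold the model is standardized and fitted on the training
#' split over the whole warm-started grid and validation mean squared
#' error is computed on the held-out raw rows. `lambda_min` is the grid
#' value minimizing mean validation MSE; among exact ties the largest
#' (sparsest) penalty is taken. The returned coefficients are the
#' full-data fit at `lambda_min`, in original predictor units.
#'
#' @param data Data frame of survey responses.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of candidate predictor columns;
#'   default: every column except the four PCQ scales.
#' @param k Number of folds (default 10).
#' @param n_lambda,ratio Penalty grid parameters; see [lambda_path()].
#' @param seed Integer seed for the fold shuffle.
#' @param tol,max_iter Coordinate-descent controls; see [fit_lasso()].
#' @return List of class `cv_lasso`: `lambda_grid`, `cv_mean`, `cv_se`,
#'   `lambda_min`, `fold_assignment`, `beta_raw` (named, at
#'   `lambda_min`), `intercept`, `n`, `outcome`, `predictors`.
#' @export
cv_lasso <- function(data, outcome, predictors = NULL, k = 10,
                     n_lambda = 100, ratio = 1e-3, seed = NULL,
                     tol = 1e-7, max_iter = 1e5) {
  if (is.null(predictors))
    predictors <- setdiff(names(data), c("pcq_total", "pcq_emotional",
                                         "pcq_physical", "pcq_social"))
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)),
            k >= 2)
  cols <- data[, c(outcome, predictors), drop = FALSE]
  cc <- stats::complete.cases(cols)
  cols <- cols[cc, , drop = FALSE]
  n <- nrow(cols)
  if (n < k) stop("fewer complete cases (", n, ") than folds (", k, ")")
  y <- cols[[outcome]]
  X <- as.matrix(cols[, predictors, drop = FALSE])
  design <- standardize_design(X, y)
  grid <- lambda_path(design, n_lambda, ratio)

  if (!is.null(seed)) set.seed(seed)
  foldid <- sample(rep(seq_len(k), length.out = n))
  mse <- matrix(NA_real_, k, length(grid))
  for (fold in seq_len(k)) {
    tr <- foldid != fold
    if (stats::var(y[tr]) == 0)
      warning("fold ", fold, ": zero-variance outcome in training split")
    d_tr <- standardize_design(X[tr, , drop = FALSE], y[tr])
    fit <- cd_path_fit(d_tr, grid, tol, max_iter)
    beta_raw <- fit$beta / d_tr$col_sds            # p_keep x L
    icept <- d_tr$y_mean - drop(crossprod(beta_raw, d_tr$col_means))
    Xval <- X[!tr, d_tr$names, drop = FALSE]
    pred <- sweep(Xval %*% beta_raw, 2, icept, "+")
    mse[fold, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_mean <- colMeans(mse)
  cv_se <- apply(mse, 2, stats::sd) / sqrt(k)
  i_min <- which(cv_mean <= min(cv_mean) + 1e-12)[1]  # grid decreasing: first = largest lambda
  lambda_min <- grid[i_min]

  full <- cd_path_fit(design, grid, tol, max_iter)
  beta_std <- stats::setNames(full$beta[, i_min], design$names)
  beta_raw <- beta_std / design$col_sds
  intercept <- design$y_mean - sum(beta_raw * design$col_means)
  all_beta <- stats::setNames(numeric(length(predictors)), predictors)
  all_beta[names(beta_raw)] <- beta_raw
  structure(list(lambda_grid = grid, cv_mean = cv_mean, cv_se = cv_se,
                 lambda_min = lambda_min, fold_assignment = foldid,
                 beta_raw = all_beta, intercept = intercept,
                 n = n, outcome = outcome, predictors = predictors,
                 dropped = design$dropped),
            class = "cv_lasso")
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat(sprintf("10-fold CV LASSO on '%s': n = %d, lambda_min = %.5g, %d active predictor(s)\n",
              x$outcome, x$n, x$lambda_min, sum(x$beta_raw != 0)))
  invisible(x)
}

#' Predict from a cross-validated LASSO fit
#'
#' @param object A `cv_lasso` fit.
#' @param newdata Data frame containing the fit's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions at `lambda_min`.
#' @export
predict.cv_lasso <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  drop(X %*% object$beta_raw) + object$intercept
}
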