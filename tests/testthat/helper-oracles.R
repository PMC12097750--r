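# Exact LASSO solution for small p by KKT sign-pattern enumeration:
# for each sign vector s in {-1,0,1}^p solve the stationarity system on
# the active set and keep solutions whose signs and subgradients check
# out. Independent of the coordinate-descent path.
lasso_kkt_oracle <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  G <- crossprod(X) / n
  cvec <- drop(crossprod(X, y)) / n
  obj <- function(b) sum((y - X %*% b)^2) / (2 * n) + lambda * sum(abs(b))
  best <- list(beta = numeric(p), value = obj(numeric(p)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (i in seq_len(nrow(signs))) {
    s <- signs[i, ]
    A <- which(s != 0)
    if (length(A) == 0) {
      if (all(abs(cvec) <= lambda + 1e-9)) {
        v <- obj(numeric(p))
        if (v < best$value) best <- list(beta = numeric(p), value = v)
      }
      next
    }
    GA <- G[A, A, drop = FALSE]
    if (abs(det(GA)) < 1e-12) next
    bA <- solve(GA, cvec[A] - lambda * s[A])
    if (any(sign(bA) != s[A])) next
    b <- numeric(p); b[A] <- bA
    notA <- setdiff(seq_len(p), A)
    if (length(notA) > 0 &&
        any(abs(cvec[notA] - G[notA, A, drop = FALSE] %*% bA) > lambda + 1e-9))
      next
    v <- obj(b)
    if (v < best$value) best <- list(beta = b, value = v)
  }
  best
}

lasso_objective <- function(design, beta_std, lambda) {
  sum((design$y_centered - design$X_std %*% beta_std)^2) / (2 * design$n) +
    lambda * sum(abs(beta_std))
}

# Mann-Whitney U by brute-force pair counting: wins + half ties.
u_pair_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Design with exactly mean-zero columns and (1/n) X'X = I.
orthonormal_design <- function(n, p) {
  X0 <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(X0)) * sqrt(n)
  colnames(Q) <- paste0("x", seq_len(p))
  Q
}

# coefficient records with an exact bootstrap mean and SD for one predictor
records_with_moments <- function(mean, sd, B = 100, predictor = "x") {
  z <- scale(seq_len(B))[, 1]          # mean 0, sd exactly 1
  vals <- mean + sd * z
  recs <- lapply(seq_len(B), function(b)
    list(index = b, lambda_min = 0.1,
         beta_raw = stats::setNames(vals[b], predictor),
         intercept = 0, rmse = 1, mae = 0.8))
  structure(list(outcome = "pcq_total", records = recs,
                 predictors = predictor, n = 487, seed = 1),
            class = "coef_records")
}

null_true_beta <- function() {
  list(pcq_emotional = numeric(0), pcq_social = numeric(0),
       pcq_physical = numeric(0))
}

# The six predictors of the published final models.
planted_predictors <- function() {
  c("komo_severity", "macarthur", "osss3", "age", "life_partner", "help_apply")
}
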