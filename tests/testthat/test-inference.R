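test_that("fit metrics match hand computation and the RMSE-MAE inequality", {
  expect_equal(fit_metrics(c(1, 2, 3), c(1, 2, 3)), c(rmse = 0, mae = 0))
  expect_equal(fit_metrics(c(1, 2), c(3, 4)), c(rmse = 2, mae = 2))
  m <- fit_metrics(c(0, 0, 3), c(1, 0, 1))
  expect_equal(m[["rmse"]], sqrt(5 / 3))
  expect_equal(m[["mae"]], 1)
  set.seed(41)
  for (i in 1:20) {
    m <- fit_metrics(rnorm(10), rnorm(10))
    expect_gte(m[["rmse"]], m[["mae"]])
  }
  expect_error(fit_metrics(numeric(0), numeric(0)))
})

test_that("normal-approximation intervals reproduce the reporting arithmetic", {
  d <- data.frame(pcq_total = rnorm(487), x = rnorm(487))
  cases <- list(c(2.72, 0.066, 2.59, 2.85),
                c(1.47, 0.032, 1.41, 1.53),
                c(0.94, 0.022, 0.90, 0.98))
  for (cs in cases) {
    fm <- summarize_final(records_with_moments(cs[1], cs[2]), d, "pcq_total")
    expect_equal(round(unname(fm$ci_low), 2), cs[3])
    expect_equal(round(unname(fm$ci_high), 2), cs[4])
    expect_true(fm$ci_low <= fm$coef_mean && fm$coef_mean <= fm$ci_high)
  }
  # zero spread collapses the interval
  fm0 <- summarize_final(records_with_moments(1.5, 0), d, "pcq_total")
  expect_equal(unname(fm0$ci_low), 1.5)
  expect_equal(unname(fm0$ci_high), 1.5)
})

test_that("significance requires the interval to exclude zero, endpoints inclusive", {
  d <- data.frame(pcq_total = rnorm(100), x = rnorm(100))
  sig <- summarize_final(records_with_moments(2.72, 0.066), d, "pcq_total")
  expect_true(significance_flags(sig)[["x"]])
  nsig <- summarize_final(records_with_moments(0, 0.05), d, "pcq_total")
  expect_false(significance_flags(nsig)[["x"]])
  # boundary: CI [0, 0.2] covers zero
  bound <- summarize_final(records_with_moments(0.1, 0.1 / 1.96), d, "pcq_total")
  expect_equal(unname(round(bound$ci_low, 10)), 0)
  expect_false(significance_flags(bound)[["x"]])
})

test_that("unselected-within-refit coefficients enter the average as zeros", {
  recs <- records_with_moments(2, 0.1, B = 10)
  recs$records[[1]]$beta_raw <- stats::setNames(numeric(0), character(0))
  d <- data.frame(pcq_total = rnorm(50), x = rnorm(50))
  fm <- summarize_final(recs, d, "pcq_total")
  manual <- c(0, 2 + 0.1 * scale(1:10)[2:10, 1])
  expect_equal(unname(fm$coef_mean), mean(manual))
  expect_equal(unname(fm$coef_se), sd(manual))
})

test_that("bootstrap refits recover a planted effect and track fit quality", {
  d <- simulate_survey(sim_config(n = 300, seed = 42))
  sel <- structure(list(outcome = "pcq_total", threshold = 0.8,
                        predictors = c("komo_severity", "macarthur"),
                        frequency = c(komo_severity = 1, macarthur = 0.9)),
                   class = "selected_set")
  recs <- refit_selected(d, sel, B = 40, k = 5, master_seed = 43, n_lambda = 40)
  expect_length(recs$records, 40)
  for (r in recs$records) expect_gte(r$rmse, r$mae)
  fm <- summarize_final(recs, d, "pcq_total")
  truth <- 1.47 + 0.44 + 0.94   # severity effect on the total score
  expect_lt(abs(fm$coef_mean[["komo_severity"]] - truth),
            3 * fm$coef_se[["komo_severity"]] + 0.3 * truth)
  expect_identical(fm$well_fitted, fm$rmse < fm$outcome_sd)
  expect_equal(fm$outcome_sd, sd(d$pcq_total))
})

test_that("noise-free linear data is fitted almost exactly", {
  noise <- default_outcome_noise()
  noise$intercept <- 2; noise$shared <- 0; noise$specific <- 0
  beta <- list(pcq_emotional = c(komo_severity = 1),
               pcq_physical = c(komo_severity = 0.8),
               pcq_social = c(komo_severity = 0.5))
  d <- simulate_survey(sim_config(n = 200, seed = 44, true_beta = beta,
                                  outcome_noise = noise))
  sel <- structure(list(outcome = "pcq_total", threshold = 0.8,
                        predictors = "komo_severity",
                        frequency = c(komo_severity = 1)),
                   class = "selected_set")
  recs <- refit_selected(d, sel, B = 10, k = 5, master_seed = 45, n_lambda = 40)
  for (r in recs$records) expect_lt(r$rmse, 0.5)
})

test_that("an empty selected set falls back to intercept-only models", {
  d <- simulate_survey(sim_config(n = 100, seed = 46))
  empty <- structure(list(outcome = "pcq_total", threshold = 0.8,
                          predictors = character(0),
                          frequency = numeric(0)),
                     class = "selected_set")
  expect_warning(recs <- refit_selected(d, empty, B = 5, k = 5,
                                        master_seed = 47),
                 "intercept-only")
  expect_length(recs$records, 5)
  expect_true(all(vapply(recs$records,
                         function(r) length(r$beta_raw) == 0, TRUE)))
})

test_that("report formatting rounds to the print precision", {
  d <- data.frame(pcq_total = rnorm(100), x = rnorm(100))
  fm <- summarize_final(records_with_moments(2.71828, 0.06612), d, "pcq_total")
  tb <- format_final_model(fm)
  expect_equal(tb$coefficient[1], 2.72)
  expect_equal(tb$se[1], 0.066)
  expect_equal(tb$term[(nrow(tb) - 2):nrow(tb)], c("RMSE", "SD of scale", "MAE"))
})
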