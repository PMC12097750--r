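test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n = 487, seed = 11, missing_rate = 0.05)
  d1 <- simulate_survey(cfg)
  d2 <- simulate_survey(cfg)
  expect_identical(d1, d2)
})

test_that("all generated values respect the schema ranges and types", {
  sch <- default_schema()
  d <- simulate_survey(sim_config(n = 25000, seed = 12))
  for (i in seq_len(nrow(sch))) {
    v <- sch[i, ]
    x <- d[[v$name]]
    expect_true(all(x >= v$lo & x <= v$hi), label = v$name)
    if (v$vtype %in% c("ordinal", "binary"))
      expect_true(all(x == round(x)), label = v$name)
  }
})

test_that("marginal moments of the predictors match their targets", {
  d <- generate_predictors(sim_config(n = 10000, seed = 13))
  expect_lt(abs(mean(d$age) - 62.37), 0.5)
  expect_lt(abs(sd(d$age) - 12.26), 0.5)
  expect_lt(abs(mean(d$macarthur) - 7.00), 0.25)
  # positive screen prevalence within 3 Monte-Carlo SEs of 4%
  se <- sqrt(0.04 * 0.96 / 10000)
  expect_lt(abs(mean(d$screen_positive) - 0.04), 3 * se)
  # shared latent factor induces mild positive predictor correlation
  expect_gt(cor(d$koko_critical, d$koko_active), 0.02)
})

test_that("zero effects, zero noise and zero intercepts give all-zero outcomes", {
  noise0 <- default_outcome_noise()
  noise0$intercept <- 0
  noise0$shared <- 0
  noise0$specific <- 0
  cfg <- sim_config(n = 50, seed = 14, true_beta = null_true_beta(),
                    outcome_noise = noise0)
  d <- simulate_survey(cfg)
  expect_true(all(d$pcq_total == 0))
  expect_true(all(d$pcq_emotional == 0))
})

test_that("PCQ outcomes are floor-heavy, right skewed, and satisfy the sum identity", {
  d <- simulate_survey(sim_config(n = 10000, seed = 15))
  expect_identical(d$pcq_total,
                   d$pcq_emotional + d$pcq_physical + d$pcq_social)
  skew <- mean((d$pcq_total - mean(d$pcq_total))^3) / sd(d$pcq_total)^3
  expect_gt(skew, 0)
  expect_gt(mean(d$pcq_total == 0), 0.15)  # visible floor mass
})

test_that("a planted total-score effect is recovered by an OLS oracle", {
  noise <- default_outcome_noise()
  noise$intercept <- 2
  noise$shared <- 0
  noise$specific <- 1
  beta <- list(pcq_emotional = c(komo_severity = 1.2),
               pcq_physical = c(komo_severity = 0.9),
               pcq_social = c(komo_severity = 0.6))
  d <- simulate_survey(sim_config(n = 5000, seed = 16, true_beta = beta,
                                  outcome_noise = noise))
  fit <- summary(lm(pcq_total ~ komo_severity, data = d))
  est <- fit$coefficients["komo_severity", ]
  expect_lt(abs(est[["Estimate"]] - 2.7), 3 * est[["Std. Error"]])
})

test_that("missingness injection is MCAR at the requested rate and seeded", {
  d <- simulate_survey(sim_config(n = 487, seed = 17))
  expect_identical(inject_missingness(d, 0), d)
  m1 <- inject_missingness(d, 0.1, seed = 18)
  m2 <- inject_missingness(d, 0.1, seed = 18)
  expect_identical(m1, m2)
  preds <- predictor_names(default_schema())
  cells <- 487 * length(preds)
  frac <- sum(is.na(m1[, preds])) / cells
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / cells))
  expect_false(anyNA(m1$pcq_total))  # outcomes never masked by default
  expect_error(inject_missingness(d, 1), "rate")
})

test_that("config validation catches unknown predictors and bad rates", {
  expect_error(sim_config(true_beta = list(pcq_emotional = c(nope = 1))),
               "unknown predictor")
  expect_error(sim_config(positive_rate = 1.5))
  expect_error(sim_config(missing_rate = 1))
})

test_that("survey CSV round-trips with its provenance sidecar", {
  d <- simulate_survey(sim_config(n = 60, seed = 19, missing_rate = 0.05))
  path <- file.path(tempdir(), "survey.csv")
  write_survey(d, path)
  expect_true(file.exists(sub("csv$", "json", path)))
  d2 <- read_survey(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)
})
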