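#' Default marginal distributions for the survey predictors
#'
#' One entry per predictor in [default_schema()], giving the mechanism
#' used by [generate_predictors()] and its parameters. Continuous
#' variables use a clipped normal with the published sample mean/SD;
#' ordinal variables with a published mean/SD use a rounded clipped
#' normal; ordinal variables for which only category percentages are
#' known use latent-normal thresholding at fixed category probabilities
#' (probabilities for categories only partially described in the source
#' table are completed with plausible mass, favouring the satisfied end
#' of satisfaction items as observed in screening samples); binaries are
#' Bernoulli via a latent-normal threshold.
#'
#' @param positive_rate Prevalence of the positive screening result
#'   (default 0.04, the screening program's positive rate).
#' @return Named list of marginal definitions.
#' @export
default_marginals <- function(positive_rate = 0.04) {
  m <- function(kind, ...) c(list(kind = kind), list(...))
  list(
    koko_critical   = m("normal", mean = 60.57, sd = 21.61),
    koko_active     = m("normal", mean = 58.33, sd = 24.30),
    help_apply      = m("normal", mean = 1.78, sd = 0.75),
    help_interact   = m("normal", mean = 1.82, sd = 0.87),
    komo_count      = m("rounded_normal", mean = 4.03, sd = 2.52),
    komo_severity   = m("normal", mean = 1.73, sd = 1.26),
    zap_trust_gp    = m("categorical", probs = c(0.620, 0.331, 0.035, 0.014)),
    zap_quality     = m("categorical", probs = c(0.580, 0.355, 0.045, 0.020)),
    zap_satisfaction = m("categorical", probs = c(0.630, 0.326, 0.030, 0.014)),
    osss3           = m("categorical", probs = c(0.314, 0.483, 0.203)),
    macarthur       = m("rounded_normal", mean = 7.00, sd = 1.70),
    screen_positive = m("bernoulli", p = positive_rate),
    info_screening  = m("categorical", probs = c(0.045, 0.073, 0.262, 0.380, 0.240)),
    info_risk       = m("categorical", probs = c(0.060, 0.097, 0.263, 0.350, 0.230)),
    good_hands_gp   = m("categorical", probs = c(0.025, 0.036, 0.280, 0.400, 0.259)),
    household_size  = m("rounded_normal", mean = 2.28, sd = 1.07),
    edu_school      = m("categorical", probs = c(0.005, 0.637, 0.200, 0.070, 0.088)),
    edu_professional = m("categorical", probs = c(0.060, 0.585, 0.165, 0.190)),
    employed        = m("bernoulli", p = 0.419),
    life_partner    = m("bernoulli", p = 0.775),
    received_result = m("bernoulli", p = 0.882),
    future_participation = m("bernoulli", p = 0.464),
    sex             = m("bernoulli", p = 0.508),
    age             = m("normal", mean = 62.37, sd = 12.26)
  )
}

#' Default sparse truth for the PCQ subscale models
#'
#' Effects (outcome units per predictor unit) for the six predictors
#' retained by the published final models, at their published averaged
#' magnitudes; all other predictors have effect zero. The total-score
#' truth is implied by the subscale sum identity. The partnership effect
#' on the emotional subscale is taken as negative (protective), as its
#' confidence interval and the accompanying interpretation indicate.
#'
#' @return Named list with one named effect vector per subscale outcome.
#' @export
default_true_beta <- function() {
  list(
    pcq_emotional = c(komo_severity = 1.47, macarthur = -0.30, osss3 = -0.33,
                      age = -0.03, life_partner = -1.08, help_apply = 0.48),
    pcq_social    = c(komo_severity = 0.44, macarthur = -0.24, osss3 = -0.24,
                      age = -0.03, life_partner = -0.48, help_apply = 0.33),
    pcq_physical  = c(komo_severity = 0.94, macarthur = -0.29, osss3 = -0.26,
                      life_partner = -0.59)
  )
}

#' Default noise model for the PCQ subscale outcomes
#'
#' Each subscale's latent score is `intercept + X beta + shared * u +
#' specific * e` with independent standard-normal `u` (one per
#' respondent, shared across subscales) and `e` (per subscale), then
#' rounded and clipped into the scale range. The shared component
#' induces the positive inter-subscale correlation a single instrument's
#' subscales exhibit; intercepts and the two noise scales are calibrated
#' by moment matching so the floor-clipped observed scores reproduce the
#' published sample means and SDs of the three subscales and the SD of
#' the total score (see the methods vignette).
#'
#' @return Data frame with one row per subscale: `intercept`, `shared`,
#'   `specific`.
#' @export
default_outcome_noise <- function() {
  data.frame(
    outcome   = c("pcq_emotional", "pcq_physical", "pcq_social"),
    intercept = c(2.439, 1.837, 2.243),
    shared    = c(6.836, 4.259, 3.345),
    specific  = c(3.270, 2.496, 2.061),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic survey generator
#'
#' @param n Respondent count (default 487, the analysed net sample size).
#' @param schema Variable schema; see [default_schema()].
#' @param true_beta Effects per subscale outcome; see [default_true_beta()].
#'   Use `NULL` effects vectors (or zeroes) for a global-null design.
#' @param outcome_noise Noise model; see [default_outcome_noise()].
#' @param marginals Predictor marginals; see [default_marginals()].
#' @param factor_loading Loading of every predictor's latent normal on a
#'   single shared factor (default 0.3), inducing mild positive
#'   collinearity among predictors.
#' @param positive_rate Prevalence of the positive screening result.
#' @param missing_rate MCAR per-cell missingness probability applied to
#'   predictors (default 0).
#' @param seed Integer seed; every generator call is deterministic given
#'   the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 487, schema = default_schema(),
                       true_beta = default_true_beta(),
                       outcome_noise = default_outcome_noise(),
                       marginals = default_marginals(positive_rate),
                       factor_loading = 0.3,
                       positive_rate = 0.04,
                       missing_rate = 0,
                       seed = NULL) {
  stopifnot(n >= 1, positive_rate >= 0, positive_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            abs(factor_loading) < 1)
  if (any(outcome_noise$shared < 0) || any(outcome_noise$specific < 0))
    stop("config error: noise scales must be >= 0")
  pred <- predictor_names(schema)
  miss_marg <- setdiff(pred, names(marginals))
  if (length(miss_marg) > 0)
    stop("config error: no marginal defined for predictor(s): ",
         paste(miss_marg, collapse = ", "))
  for (out in names(true_beta)) {
    if (!out %in% outcome_names(schema))
      stop("config error: true_beta names unknown outcome: ", out)
    unknown <- setdiff(names(true_beta[[out]]), pred)
    if (length(unknown) > 0)
      stop("config error: true_beta references unknown predictor(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(n = as.integer(n), schema = schema, true_beta = true_beta,
                 outcome_noise = outcome_noise, marginals = marginals,
                 factor_loading = factor_loading,
                 positive_rate = positive_rate,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' Generate the predictor block of a synthetic survey dataset
#'
#' Each predictor is driven by a latent standard normal
#' `z = loading * f + sqrt(1 - loading^2) * e` sharing a single factor
#' `f` across predictors, then transformed by its marginal mechanism
#' (see [default_marginals()]). All values fall inside the schema
#' ranges; ordinal and binary columns are integer-valued.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with `cfg$n` rows and one column per predictor.
#' @export
generate_predictors <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  pred <- predictor_names(cfg$schema)
  lam <- cfg$factor_loading
  f <- stats::rnorm(n)
  out <- vector("list", length(pred))
  names(out) <- pred
  for (v in pred) {
    spec <- cfg$schema[cfg$schema$name == v, ]
    marg <- cfg$marginals[[v]]
    z <- lam * f + sqrt(1 - lam^2) * stats::rnorm(n)
    x <- switch(marg$kind,
      normal = pmin(pmax(marg$mean + marg$sd * z, spec$lo), spec$hi),
      rounded_normal = pmin(pmax(round(marg$mean + marg$sd * z), spec$lo), spec$hi),
      categorical = {
        p <- marg$probs / sum(marg$probs)
        cuts <- stats::qnorm(cumsum(p)[-length(p)])
        spec$lo + findInterval(z, cuts)
      },
      bernoulli = as.numeric(z > stats::qnorm(1 - marg$p)),
      stop("config error: unknown marginal kind: ", marg$kind))
    out[[v]] <- x
  }
  as.data.frame(out)
}

#' Generate PCQ outcome scores from a predictor block
#'
#' Draws the three subscale scores from the latent linear model in
#' [default_outcome_noise()] (round-and-clip into the scale range, which
#' produces the floor-heavy right-skewed distributions the PCQ shows)
#' and sets the total to the subscale sum, so the scoring identity holds
#' by construction.
#'
#' @param predictors Predictor block from [generate_predictors()].
#' @param cfg The same [sim_config()].
#' @return Data frame with columns `pcq_total`, `pcq_emotional`,
#'   `pcq_physical`, `pcq_social`.
#' @export
generate_outcomes <- function(predictors, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed))
    set.seed((cfg$seed + 1000003L) %% .Machine$integer.max)
  n <- nrow(predictors)
  u <- stats::rnorm(n)
  out <- list()
  for (i in seq_len(nrow(cfg$outcome_noise))) {
    nm <- cfg$outcome_noise$outcome[i]
    spec <- cfg$schema[cfg$schema$name == nm, ]
    beta <- cfg$true_beta[[nm]]
    eta <- rep(cfg$outcome_noise$intercept[i], n)
    if (length(beta) > 0) {
      xb <- as.matrix(predictors[, names(beta), drop = FALSE]) %*% beta
      eta <- eta + drop(xb)
    }
    latent <- eta + cfg$outcome_noise$shared[i] * u +
      cfg$outcome_noise$specific[i] * stats::rnorm(n)
    out[[nm]] <- pmin(pmax(round(latent), spec$lo), spec$hi)
  }
  total_spec <- cfg$schema[cfg$schema$name == "pcq_total", ]
  out$pcq_total <- out$pcq_emotional + out$pcq_physical + out$pcq_social
  as.data.frame(out)[, c("pcq_total", "pcq_emotional", "pcq_physical", "pcq_social")]
}

#' Set predictor cells missing completely at random
#'
#' @param data Survey data frame.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @param columns Columns eligible for masking; defaults to every
#'   non-PCQ column (outcomes are never masked by default).
#' @return `data` with masked cells set to `NA`.
#' @export
inject_missingness <- function(data, rate, seed = NULL,
                               columns = setdiff(names(data),
                                 c("pcq_total", "pcq_emotional",
                                   "pcq_physical", "pcq_social"))) {
  if (rate < 0 || rate >= 1) stop("config error: rate must be in [0, 1)")
  if (rate == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  for (v in columns) {
    mask <- stats::runif(nrow(data)) < rate
    data[[v]][mask] <- NA
  }
  data
}

#' Simulate a complete synthetic survey dataset
#'
#' Convenience wrapper: [generate_predictors()], [generate_outcomes()],
#' then [inject_missingness()] at `cfg$missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with the four PCQ outcome columns followed by the
#'   24 predictor columns; attribute `"sim_config"` carries `cfg`.
#' @examples
#' d <- simulate_survey(sim_config(n = 200, seed = 1))
#' mean(d$pcq_total)
#' @export
simulate_survey <- function(cfg = sim_config()) {
  x <- generate_predictors(cfg)
  y <- generate_outcomes(x, cfg)
  d <- cbind(y, x)
  if (cfg$missing_rate > 0) {
    ms <- if (is.null(cfg$seed)) NULL else (cfg$seed + 2000003L) %% .Machine$integer.max
    d <- inject_missingness(d, cfg$missing_rate, seed = ms,
                            columns = predictor_names(cfg$schema))
  }
  attr(d, "sim_config") <- cfg
  d
}

#' Write a survey dataset as CSV with a JSON provenance sidecar
#'
#' @param data Survey data frame (typically from [simulate_survey()]).
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @param config Generator configuration to record; defaults to the
#'   dataset's `"sim_config"` attribute when present.
#' @return Invisibly, the CSV path.
#' @export
write_survey <- function(data, path, config = attr(data, "sim_config")) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    side <- sub("\\.csv$", ".json", path)
    if (identical(side, path)) side <- paste0(path, ".json")
    cfg_out <- config
    cfg_out$schema <- as.data.frame(unclass(config$schema))
    jsonlite::write_json(cfg_out, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Read a survey CSV written by [write_survey()] or prepared externally
#'
#' @param path CSV path with a header row of schema names; empty cells
#'   are read as missing.
#' @return Data frame of survey responses.
#' @export
read_survey <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
}
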