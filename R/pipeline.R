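#' Configuration for an end-to-end pipeline run
#'
#' @param input Path to a survey CSV, or a [sim_config()] to generate
#'   the data at run time.
#' @param outcomes Outcome columns to model (default: the four PCQ
#'   scales).
#' @param predictors Candidate predictors (default: the schema's 24).
#' @param B Bootstrap resamples per outcome (default 100).
#' @param k CV folds (default 10).
#' @param threshold Relevance cut-off on selection frequency (default
#'   0.80).
#' @param z Normal quantile for confidence intervals (default 1.96).
#' @param master_seed Master seed; per-outcome seeds are derived from it.
#' @param out_dir Output directory for report files, or `NULL` to skip
#'   writing.
#' @param schema Variable schema.
#' @param n_lambda,ratio Penalty grid parameters.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = sim_config(), outcomes = NULL,
                       predictors = NULL, B = 100, k = 10,
                       threshold = 0.80, z = 1.96, master_seed = 1,
                       out_dir = NULL, schema = default_schema(),
                       n_lambda = 100, ratio = 1e-3) {
  stopifnot(B >= 2, k >= 2, threshold > 0, threshold <= 1)
  if (is.null(outcomes)) outcomes <- outcome_names(schema)
  if (is.null(predictors)) predictors <- predictor_names(schema)
  structure(list(input = input, outcomes = outcomes, predictors = predictors,
                 B = B, k = k, threshold = threshold, z = z,
                 master_seed = as.integer(master_seed), out_dir = out_dir,
                 schema = schema, n_lambda = n_lambda, ratio = ratio),
            class = "run_config")
}

# one derived seed per outcome, independent of outcome subsetting
outcome_seed <- function(master_seed, outcome_index) {
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, 64L)
  s[outcome_index]
}

#' Run the full selection-and-inference pipeline
#'
#' Loads or generates the survey data, validates it against the schema,
#' and, per outcome: bootstrap stability selection, thresholding,
#' bootstrap refits on the selected set, and the final bootstrap-
#' averaged model. Also produces the descriptive table and the
#' frequency ranking. With an `out_dir`, writes all report files plus a
#' JSON manifest (configuration, seeds, package version, input hash)
#' from which the run can be reproduced exactly.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_run`: `data`, `validation`,
#'   `selection` (per outcome), `selected` (per outcome), `final` (per
#'   outcome), `ranking`, `descriptives`, `config`, `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  if (inherits(cfg$input, "sim_config")) {
    data <- simulate_survey(cfg$input)
    input_desc <- list(type = "simulated", n = cfg$input$n,
                       seed = cfg$input$seed)
  } else {
    data <- read_survey(cfg$input)
    input_desc <- list(type = "file", path = cfg$input,
                       md5 = unname(tools::md5sum(cfg$input)))
  }
  validation <- validate_dataset(data, cfg$schema)
  preds <- intersect(cfg$predictors, names(data))
  selection <- list(); selected <- list(); final <- list()
  for (i in seq_along(cfg$outcomes)) {
    out <- cfg$outcomes[i]
    seed_i <- outcome_seed(cfg$master_seed, match(out, outcome_names(cfg$schema)))
    sel <- bootstrap_selection(data, out, preds, B = cfg$B, k = cfg$k,
                               master_seed = seed_i,
                               n_lambda = cfg$n_lambda, ratio = cfg$ratio)
    set_i <- select_predictors(sel, cfg$threshold)
    rec <- refit_selected(data, set_i, B = cfg$B, k = cfg$k,
                          master_seed = seed_i,
                          n_lambda = cfg$n_lambda, ratio = cfg$ratio)
    fm <- summarize_final(rec, data, out, z = cfg$z)
    selection[[out]] <- sel
    selected[[out]] <- set_i
    final[[out]] <- fm
  }
  ranking <- frequency_ranking(selection, cfg$threshold)
  descriptives <- describe_survey(data, cfg$schema)
  manifest <- list(
    package = "pcqlasso",
    version = as.character(utils::packageVersion("pcqlasso")),
    master_seed = cfg$master_seed,
    outcome_seeds = stats::setNames(
      vapply(cfg$outcomes, function(o)
        outcome_seed(cfg$master_seed, match(o, outcome_names(cfg$schema))), 0L),
      cfg$outcomes),
    B = cfg$B, k = cfg$k, threshold = cfg$threshold, z = cfg$z,
    n_lambda = cfg$n_lambda, ratio = cfg$ratio,
    input = input_desc)
  run <- structure(list(data = data, validation = validation,
                        selection = selection, selected = selected,
                        final = final, ranking = ranking,
                        descriptives = descriptives, config = cfg,
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(cfg$out_dir)) render_reports(run, cfg$out_dir)
  run
}

#' Write pipeline reports to disk
#'
#' Emits `descriptives.csv` (sample characteristics),
#' `frequencies.csv` (per-outcome selection-frequency ranking with the
#' threshold marker), `final_models.csv` and `final_models.txt` (the
#' final-model table: coefficient, SE, 95% CI per selected predictor,
#' with RMSE / outcome-SD / MAE footer rows), and `manifest.json`.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(run, out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "descriptives.csv")
  utils::write.csv(run$descriptives, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  p <- file.path(out_dir, "frequencies.csv")
  utils::write.csv(run$ranking, p, row.names = FALSE)
  paths <- c(paths, p)
  tabs <- lapply(names(run$final), function(out) {
    tb <- format_final_model(run$final[[out]])
    if (length(run$final[[out]]$predictors) == 0)
      tb <- rbind(data.frame(term = "(no predictors selected)",
                             coefficient = NA_real_, se = NA_real_,
                             ci = "", significant = ""), tb)
    cbind(outcome = out, tb)
  })
  tab <- do.call(rbind, tabs)
  p <- file.path(out_dir, "final_models.csv")
  utils::write.csv(tab, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  p <- file.path(out_dir, "final_models.txt")
  txt <- utils::capture.output(for (out in names(run$final)) {
    print(run$final[[out]]); cat("\n")
  })
  writeLines(txt, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$data), "respondents,",
      length(x$final), "outcome model(s)\n")
  for (out in names(x$final)) {
    sel <- x$selected[[out]]
    cat(sprintf("  %-14s selected: %s\n", out,
                if (length(sel$predictors)) paste(sel$predictors, collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}
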