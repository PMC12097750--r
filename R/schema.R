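#' Variable schema for the screening survey
#'
#' A schema is a data frame with one row per variable and columns
#' `name`, `vtype` (`"continuous"`, `"ordinal"` or `"binary"`), `lo`, `hi`
#' (admissible range), `role` (`"outcome"` or `"predictor"`), `source`
#' (instrument label) and `group` (reporting block). [default_schema()]
#' ships the 28-variable schema of the liver-screening survey: the four
#' PCQ scales (total plus emotional, physical and social dysfunction)
#' and 24 candidate predictors covering communication competence (KoKo),
#' health literacy (HELP), comorbidity burden (KOMO), care satisfaction
#' (ZAP), social support (OSSS-3), subjective social status (MacArthur
#' ladder), the screening result and sociodemographics.
#'
#' @param source Either a file path to a schema config (Debian-control
#'   style text: one block per variable, fields `name`, `vtype`, `lo`,
#'   `hi`, `role` and optionally `source`, `group`) or a data frame with
#'   those columns.
#' @return A validated schema data frame of class `pcq_schema`.
#' @examples
#' sch <- default_schema()
#' table(sch$role)
#' @export
load_schema <- function(source) {
  if (is.character(source) && length(source) == 1) {
    blocks <- read.dcf(source,
      fields = c("name", "vtype", "lo", "hi", "role", "source", "group"))
    df <- as.data.frame(blocks, stringsAsFactors = FALSE)
    df$lo <- as.numeric(df$lo)
    df$hi <- as.numeric(df$hi)
  } else if (is.data.frame(source)) {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  } else {
    stop("`source` must be a file path or a data frame")
  }
  if (is.null(df$source)) df$source <- NA_character_
  if (is.null(df$group)) df$group <- NA_character_
  validate_schema(df)
}

validate_schema <- function(df) {
  required <- c("name", "vtype", "lo", "hi", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  if (anyNA(df$name) || any(!nzchar(df$name)))
    stop("schema error: empty variable name")
  dup <- df$name[duplicated(df$name)]
  if (length(dup) > 0)
    stop("schema error: duplicate variable name(s): ", paste(unique(dup), collapse = ", "))
  bad_type <- !df$vtype %in% c("continuous", "ordinal", "binary")
  if (any(bad_type))
    stop("schema error: unknown vtype for variable(s): ",
         paste(df$name[bad_type], collapse = ", "))
  bad_role <- !df$role %in% c("outcome", "predictor")
  if (any(bad_role))
    stop("schema error: unknown role for variable(s): ",
         paste(df$name[bad_role], collapse = ", "))
  bad_range <- !is.finite(df$lo) | !is.finite(df$hi) | df$lo >= df$hi
  if (any(bad_range))
    stop("schema error: lo >= hi (or non-finite bound) for variable(s): ",
         paste(df$name[bad_range], collapse = ", "))
  bad_bin <- df$vtype == "binary" & !(df$lo == 0 & df$hi == 1)
  if (any(bad_bin))
    stop("schema error: binary variable(s) must have range [0, 1]: ",
         paste(df$name[bad_bin], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("pcq_schema", "data.frame")
  df
}

#' @rdname load_schema
#' @export
default_schema <- function() {
  path <- system.file("extdata", "default_schema.dcf", package = "pcqlasso")
  if (!nzchar(path)) stop("bundled default schema not found")
  load_schema(path)
}

#' Names of outcome or predictor variables in a schema
#'
#' @param schema A schema from [load_schema()] or [default_schema()].
#' @return Character vector of variable names.
#' @export
outcome_names <- function(schema) schema$name[schema$role == "outcome"]

#' @rdname outcome_names
#' @export
predictor_names <- function(schema) schema$name[schema$role == "predictor"]

#' Validate a survey dataset against a schema
#'
#' Checks each dataset column that appears in the schema for values
#' outside the admissible range, counts missing values, and flags
#' constant (zero-variance) columns, which carry no information for
#' variable selection.
#'
#' @param data A data frame of survey responses (one row per respondent).
#' @param schema A schema data frame; see [load_schema()].
#' @param require_outcomes If `TRUE` (default), error when an outcome
#'   column declared in the schema is absent from the data.
#' @return A data frame of class `pcq_validation` with one row per
#'   checked variable: `name`, `n`, `n_missing`, `n_out_of_range`,
#'   `zero_variance`. Attribute `ok` is `TRUE` when no violations or
#'   zero-variance predictors were found.
#' @export
validate_dataset <- function(data, schema = default_schema(),
                             require_outcomes = TRUE) {
  stopifnot(is.data.frame(data))
  if (require_outcomes) {
    miss_out <- setdiff(outcome_names(schema), names(data))
    if (length(miss_out) > 0)
      stop("structural error: missing outcome column(s): ",
           paste(miss_out, collapse = ", "))
  }
  checked <- schema[schema$name %in% names(data), , drop = FALSE]
  rows <- lapply(seq_len(nrow(checked)), function(i) {
    v <- checked[i, ]
    x <- data[[v$name]]
    obs <- x[!is.na(x)]
    oor <- sum(obs < v$lo | obs > v$hi)
    if (v$vtype %in% c("ordinal", "binary"))
      oor <- oor + sum(obs >= v$lo & obs <= v$hi & obs != round(obs))
    data.frame(name = v$name,
               n = length(x),
               n_missing = sum(is.na(x)),
               n_out_of_range = oor,
               zero_variance = length(unique(obs)) <= 1,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  class(rep_df) <- c("pcq_validation", "data.frame")
  attr(rep_df, "ok") <- all(rep_df$n_out_of_range == 0) &&
    !any(rep_df$zero_variance & rep_df$name %in% predictor_names(schema))
  rep_df
}

#' @export
print.pcq_validation <- function(x, ...) {
  cat("Dataset validation report (", nrow(x), " variables checked)\n", sep = "")
  bad <- x[x$n_out_of_range > 0 | x$zero_variance, , drop = FALSE]
  if (nrow(bad) == 0) {
    cat("  no out-of-range values, no zero-variance columns\n")
  } else {
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}
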