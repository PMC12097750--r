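#' Score PCQ item responses into subscale and total scores
#'
#' The negative-consequence PCQ is scored as the plain sum of its items:
#' 5 emotional, 4 physical and 3 social items, each answered on a 0-3
#' scale, giving subscale ranges 0-15, 0-12 and 0-9 and a total range
#' 0-36. The total is defined as the sum of the three subscales, so the
#' identity `total = emotional + physical + social` holds whenever all
#' subscales are scorable. The 5/4/3 item split is the package's reading
#' of the published scale maxima; alternative item counts can be passed
#' via `n_items`.
#'
#' @param emotional,physical,social Item responses: numeric vectors (one
#'   respondent) or matrices with one row per respondent and one column
#'   per item. Values must be in `0:3` or `NA`.
#' @param missing_rule How to handle missing items within a subscale:
#'   `"omit"` (default) scores the subscale `NA` when any of its items
#'   is missing (no prorating); `"prorate"` substitutes the mean of the
#'   observed items for each missing item, provided at least half of the
#'   subscale's items were answered, and rounds the result to the
#'   nearest integer.
#' @param n_items Expected item counts per subscale
#'   (emotional, physical, social).
#' @return A data frame with columns `emotional`, `physical`, `social`
#'   and `total`. `total` is `NA` whenever any subscale is `NA`.
#' @examples
#' score_pcq(c(1, 0, 2, 0, 1), c(0, 0, 0, 1), c(3, 0, 0))
#' @export
score_pcq <- function(emotional, physical, social,
                      missing_rule = c("omit", "prorate"),
                      n_items = c(emotional = 5L, physical = 4L, social = 3L)) {
  missing_rule <- match.arg(missing_rule)
  blocks <- list(emotional = emotional, physical = physical, social = social)
  blocks <- lapply(blocks, function(b) {
    if (is.null(dim(b))) matrix(as.numeric(b), nrow = 1) else as.matrix(b)
  })
  n <- vapply(blocks, nrow, 0L)
  if (length(unique(n)) != 1)
    stop("subscale item blocks have differing respondent counts")
  for (s in names(blocks)) {
    if (ncol(blocks[[s]]) != n_items[[s]])
      stop(sprintf("expected %d %s items, got %d",
                   n_items[[s]], s, ncol(blocks[[s]])))
    bad <- which(!is.na(blocks[[s]]) &
                   (blocks[[s]] < 0 | blocks[[s]] > 3 |
                      blocks[[s]] != round(blocks[[s]])), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("value error: %s item %d of respondent %d is outside {0,1,2,3}",
                   s, bad[1, 2], bad[1, 1]))
  }
  score_block <- function(b) {
    obs <- rowSums(!is.na(b))
    total <- rowSums(b, na.rm = TRUE)
    if (missing_rule == "omit") {
      total[obs < ncol(b)] <- NA_real_
    } else {
      prorate <- obs < ncol(b) & obs >= ncol(b) / 2
      total[prorate] <- round(total[prorate] / obs[prorate] * ncol(b))
      total[obs < ncol(b) / 2] <- NA_real_
    }
    total
  }
  out <- data.frame(lapply(blocks, score_block))
  out$total <- out$emotional + out$physical + out$social
  out
}
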