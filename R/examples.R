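# Bundled worked examples: a 10-volunteer rate-point cohort covering all
# 42 queries, and the published 5-row-per-disorder score sheet with its
# Weight Scores and severity labels. Used in the README walk-through and
# as exact-match fixtures in the tests.

example_blocks <- function() {
  list(
    anxiety = matrix(c(
      3, 3, 1, 0, 1, 1, 0, 1, 0, 2, 3, 1, 0, 0,
      2, 3, 3, 1, 3, 2, 3, 3, 3, 3, 3, 1, 1, 2,
      3, 0, 0, 0, 0, 0, 1, 0, 2, 0, 1, 2, 0, 0,
      0, 2, 0, 0, 0, 0, 1, 0, 0, 0, 1, 1, 0, 1,
      1, 0, 2, 1, 0, 1, 2, 0, 1, 0, 0, 1, 2, 0,
      3, 0, 0, 0, 0, 0, 1, 0, 3, 0, 1, 2, 0, 0,
      0, 2, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 1,
      2, 0, 2, 1, 0, 1, 2, 0, 1, 0, 0, 1, 2, 0,
      3, 3, 1, 0, 1, 2, 0, 1, 0, 2, 3, 1, 0, 0,
      2, 2, 3, 1, 3, 1, 3, 2, 3, 3, 3, 1, 1, 2),
      nrow = 10, byrow = TRUE),
    stress = matrix(c(
      2, 1, 3, 2, 3, 3, 3, 3, 3, 2, 3, 3, 3, 2,
      3, 2, 2, 3, 3, 1, 1, 3, 0, 1, 1, 0, 1, 2,
      3, 2, 3, 0, 3, 3, 0, 2, 3, 1, 3, 3, 3, 2,
      2, 2, 0, 0, 1, 2, 0, 0, 0, 0, 1, 0, 0, 0,
      2, 0, 0, 2, 0, 0, 0, 2, 0, 3, 2, 3, 1, 1,
      2, 3, 0, 0, 1, 2, 0, 0, 0, 0, 1, 0, 0, 1,
      1, 0, 0, 2, 0, 0, 0, 2, 0, 3, 2, 3, 1, 1,
      3, 2, 3, 0, 3, 3, 0, 2, 3, 1, 3, 3, 3, 1,
      2, 1, 3, 2, 3, 3, 3, 3, 3, 2, 3, 3, 2, 2,
      3, 2, 2, 3, 3, 1, 1, 3, 0, 1, 1, 0, 1, 1),
      nrow = 10, byrow = TRUE),
    depression = matrix(c(
      3, 3, 3, 3, 2, 2, 1, 3, 1, 3, 3, 3, 0, 3,
      0, 1, 2, 1, 0, 2, 1, 1, 0, 0, 0, 2, 1, 0,
      1, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 1,
      1, 2, 1, 0, 0, 0, 3, 3, 1, 3, 0, 2, 3, 3,
      3, 1, 2, 0, 0, 1, 0, 1, 2, 2, 2, 1, 1, 2,
      1, 3, 1, 0, 0, 0, 3, 3, 1, 3, 0, 2, 3, 3,
      3, 1, 2, 0, 0, 1, 0, 1, 2, 1, 2, 1, 1, 2,
      1, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1,
      3, 3, 3, 3, 2, 2, 1, 3, 2, 3, 3, 3, 0, 3,
      0, 1, 2, 1, 0, 2, 1, 1, 0, 0, 0, 3, 1, 0),
      nrow = 10, byrow = TRUE)
  )
}

#' Worked-example volunteer cohort (10 respondents x 42 queries)
#'
#' A small rate-point matrix for ten volunteers (`V1` ... `V10`)
#' covering all 42 queries, used to demonstrate scoring and
#' Q-Prioritization end to end (with the default thresholds, `Q9` drops
#' from the anxiety set and `Q18` from the stress set).
#'
#' @return A `rate_points` data frame with `respondent_id` `V1..V10`.
#' @examples
#' m <- example_cohort()
#' colMeans(m[default_disorder_sets()$anxiety$queries])
#' @export
example_cohort <- function() {
  blocks <- example_blocks()
  sets <- default_disorder_sets()
  out <- data.frame(respondent_id = paste0("V", 1:10),
                    stringsAsFactors = FALSE)
  for (q in paste0("Q", 1:42)) out[[q]] <- 0L
  for (ds in names(sets)) {
    qs <- sets[[ds]]$queries
    for (j in seq_along(qs)) out[[qs[j]]] <- as.integer(blocks[[ds]][, j])
  }
  class(out) <- c("rate_points", "data.frame")
  out
}

example_published_labels <- function() {
  list(
    anxiety = data.frame(WS = c(16L, 33L, 9L, 6L, 11L),
                         Class = c("S", "ES", "M", "N", "MD")),
    stress = data.frame(WS = c(36L, 23L, 31L, 8L, 16L),
                        Class = c("ES", "MD", "S", "N", "M")),
    depression = data.frame(WS = c(33L, 11L, 4L, 22L, 18L),
                            Class = c("ES", "M", "N", "S", "MD"))
  )
}

#' Worked-example score sheet (5 rows per disorder)
#'
#' The first five cohort volunteers' rate points for one disorder,
#' together with the published Weight Score and severity label of each
#' row. Recomputing WS and Class from the rate points reproduces these
#' columns exactly, which the test suite asserts.
#'
#' @param disorder `"anxiety"`, `"stress"`, or `"depression"`; `NULL`
#'   (default) returns all three as a named list.
#' @return A data frame (or list of three) with 14 query columns plus
#'   `WS` and `Class`.
#' @export
example_score_sheet <- function(disorder = NULL) {
  sets <- default_disorder_sets()
  labs <- example_published_labels()
  build <- function(ds) {
    block <- example_blocks()[[ds]][1:5, , drop = FALSE]
    out <- data.frame(respondent_id = paste0("V", 1:5),
                      stringsAsFactors = FALSE)
    qs <- sets[[ds]]$queries
    for (j in seq_along(qs)) out[[qs[j]]] <- as.integer(block[, j])
    out$WS <- labs[[ds]]$WS
    out$Class <- factor(labs[[ds]]$Class, levels = SEVERITY_LEVELS)
    out
  }
  if (is.null(disorder))
    return(stats::setNames(lapply(names(sets), build), names(sets)))
  stopifnot(disorder %in% names(sets))
  build(disorder)
}
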