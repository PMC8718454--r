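# Segregate-Label phase: restrict the rate-point matrix to one disorder's
# 14 queries, sum them into a Weight Score, and band the score into the
# five severity levels.

#' Compute per-respondent Weight Scores for one disorder set
#'
#' The Weight Score (WS) of a respondent for a disorder is the sum of the
#' 14 rate points of that disorder's queries, so WS is an integer in
#' [0, 42].
#'
#' @param matrix A `rate_points` data frame containing at least the
#'   disorder's query columns.
#' @param set A [disorder_set].
#' @return A data frame of class `labeled_disorder` with `respondent_id`,
#'   the 14 query columns (in set order), and `WS`. The `Class` column is
#'   unset until [assign_severity()] is called.
#' @examples
#' m <- example_cohort()
#' head(compute_weight_scores(m, default_disorder_sets()$anxiety))
#' @export
compute_weight_scores <- function(matrix, set) {
  stopifnot(inherits(set, "disorder_set"))
  missing_q <- setdiff(set$queries, names(matrix))
  if (length(missing_q))
    stop("matrix lacks query column(s): ", paste(missing_q, collapse = ", "))
  out <- matrix[, c("respondent_id", set$queries), drop = FALSE]
  out$WS <- as.integer(rowSums(out[, set$queries, drop = FALSE]))
  attr(out, "disorder") <- set$name
  class(out) <- c("labeled_disorder", "data.frame")
  out
}

#' Band a Weight Score into a severity label
#'
#' Assigns each row the highest-severity band whose inclusive interval
#' contains its WS (precedence ES > S > MD > M > N wherever two bands
#' meet at a boundary, as the stress Severe/Extremely-Severe bands do
#' at WS 33).
#'
#' @param table Output of [compute_weight_scores()].
#' @param set The same [disorder_set].
#' @return The table with a `Class` factor column
#'   (levels `N, M, MD, S, ES`).
#' @export
assign_severity <- function(table, set) {
  stopifnot(inherits(set, "disorder_set"), "WS" %in% names(table))
  ws <- table$WS
  if (any(ws < 0 | ws > 42))
    stop("Weight Score outside [0, 42]; input is not a valid rate-point sum")
  table$Class <- factor(ws_to_label(ws, set$bands), levels = SEVERITY_LEVELS)
  table
}

ws_to_label <- function(ws, bands) {
  lab <- character(length(ws))
  # scan from most to least severe so overlapping boundaries resolve up
  for (i in rev(seq_len(nrow(bands)))) {
    hit <- lab == "" & ws >= bands$lo[i] & ws <= bands$hi[i]
    lab[hit] <- bands$label[i]
  }
  lab
}

#' Score and label the full matrix for all three disorders
#'
#' @param matrix A `rate_points` data frame with all 42 query columns.
#' @param sets Disorder sets, default [default_disorder_sets()].
#' @return Named list of three labeled tables (WS + Class per respondent).
#' @export
label_all_disorders <- function(matrix, sets = default_disorder_sets()) {
  lapply(sets, function(s) assign_severity(compute_weight_scores(matrix, s), s))
}
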