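# Q-Prioritization phase: rank queries by their mean rate point (priority
# relevance) and drop those at or below the disorder's relevance threshold.

#' Derive a relevance threshold from its defining ratio
#'
#' The threshold is `normal_max / (count_col * rate_max)`, where
#' `normal_max` is the largest Weight Score in the Normal band of the
#' disorder, `count_col` the number of query columns (14) and `rate_max`
#' the top of the rate-point scale. The published per-disorder constants
#' (0.5 / 1.0 / 0.2 for anxiety / stress / depression) are carried on
#' each [disorder_set] and can be overridden with `override`.
#'
#' @param normal_max Integer, largest Normal-band WS.
#' @param count_col Number of query columns, default 14.
#' @param rate_max Maximum rate point, default 3.
#' @param override If given, returned as the threshold unchanged.
#' @return A list of class `relevance_threshold` with fields `rth`,
#'   `normal_max`, `count_col`, `rate_max`, `derived`.
#' @export
compute_rth <- function(normal_max, count_col = 14, rate_max = 3,
                        override = NULL) {
  if (!is.null(override)) {
    rth <- as.numeric(override)
    derived <- FALSE
  } else {
    if (count_col <= 0 || rate_max <= 0)
      stop("count_col and rate_max must be positive")
    rth <- normal_max / (count_col * rate_max)
    derived <- TRUE
  }
  if (rth < 0) stop("relevance threshold must be non-negative")
  structure(list(rth = rth, normal_max = normal_max, count_col = count_col,
                 rate_max = rate_max, derived = derived),
            class = "relevance_threshold")
}

#' Mean rate point (priority relevance) of every query
#'
#' The priority relevance of a query is the arithmetic mean of its rate
#' points over all respondents.
#'
#' @param table A `labeled_disorder` table or `rate_points` matrix.
#' @param queries Query columns to score; defaults to every `Qn` column.
#' @return A data frame of class `priority_ranking` with columns `query`
#'   and `prel`, in the input column order. Kept/dropped flags and ranks
#'   are added by [prioritize()].
#' @export
compute_priority_relevance <- function(table, queries = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("cannot compute relevance of an empty table")
  if (is.null(queries)) queries <- grep("^Q[0-9]+$", names(table), value = TRUE)
  prel <- vapply(queries, function(q) mean(table[[q]]), numeric(1))
  out <- data.frame(query = queries, prel = unname(prel),
                    stringsAsFactors = FALSE)
  class(out) <- c("priority_ranking", "data.frame")
  out
}

#' Flag irrelevant queries and rank the survivors
#'
#' Queries whose priority relevance is less than or equal to the
#' threshold are flagged as dropped. Survivors are ranked by ascending
#' mean (lowest relevance first, mirroring the post-prioritized query
#' ordering); a descending rank is reported alongside. If the threshold
#' would eliminate every query, nothing is dropped and a warning is
#' raised.
#'
#' @param ranking Output of [compute_priority_relevance()].
#' @param threshold A `relevance_threshold`, a [disorder_set] (its `rth`
#'   is used), or a bare number.
#' @return The ranking with columns `kept`, `rank_asc`, `rank_desc`.
#' @export
prioritize <- function(ranking, threshold) {
  stopifnot(inherits(ranking, "priority_ranking"))
  rth <- if (inherits(threshold, "relevance_threshold")) threshold$rth
         else if (inherits(threshold, "disorder_set")) threshold$rth
         else as.numeric(threshold)
  kept <- ranking$prel > rth   # drop at equality
  if (!any(kept)) {
    warning("threshold ", rth, " would drop every query; keeping all")
    kept <- rep(TRUE, nrow(ranking))
  }
  ranking$kept <- kept
  ord <- order(ranking$prel, seq_len(nrow(ranking)))
  ranking$rank_asc <- match(seq_len(nrow(ranking)), ord)
  ranking$rank_desc <- nrow(ranking) + 1L - ranking$rank_asc
  attr(ranking, "rth") <- rth
  ranking
}

#' Remove dropped query columns from a rate-point matrix
#'
#' @param matrix A `rate_points` or `labeled_disorder` data frame.
#' @param ranking A prioritized [compute_priority_relevance()] result.
#' @return The matrix without the dropped columns; rows untouched.
#' @export
apply_prioritization <- function(matrix, ranking) {
  stopifnot(is.data.frame(matrix), "kept" %in% names(ranking))
  dropped <- ranking$query[!ranking$kept]
  missing_q <- setdiff(ranking$query, names(matrix))
  if (length(missing_q))
    stop("ranking refers to absent column(s): ",
         paste(missing_q, collapse = ", "))
  matrix[, setdiff(names(matrix), dropped), drop = FALSE]
}

#' Serialize a prioritization report to JSON
#'
#' @param ranking A prioritized ranking.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  obj <- list(rth = attr(ranking, "rth"),
              queries = ranking)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
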