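# Transform-Encode phase: read raw questionnaire CSVs, repair missing or
# out-of-range entries by column-mode imputation, and rescale the 1..4
# response codes to 0..3 rate points.

DASS_SCHEMA <- paste0("Q", 1:42)

#' Default DASS-42 column schema
#'
#' @return Character vector `Q1` ... `Q42`.
#' @export
dass_schema <- function() DASS_SCHEMA

id_column_aliases <- c("respondent_id", "id", "volunteer", "volunteer_id",
                       "name", "respondent")

#' Read raw questionnaire responses from a CSV file
#'
#' Expects an RFC-4180 CSV with a header row. Header tokens are matched
#' case-insensitively against the schema; extra columns are dropped with a
#' warning. A respondent-id column (any of `respondent_id`, `id`,
#' `volunteer`, `name`) is used when present, otherwise ids are synthesized
#' from the row index. Cells are left untouched: non-numeric or absent
#' entries become `NA` and are handled by [impute_missing()].
#'
#' @param path CSV file path.
#' @param schema Character vector of required query columns, in output
#'   order. Defaults to `Q1..Q42`.
#' @param col_map Optional named character vector remapping arbitrary
#'   headers to query ids, e.g. `c("How upset were you?" = "Q1")`.
#' @return A data frame of class `raw_responses` with a `respondent_id`
#'   column followed by the schema columns.
#' @export
read_responses <- function(path, schema = dass_schema(), col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse CSV ", path, ": ",
                             conditionMessage(e))
  )
  as_raw_responses(raw, schema = schema, col_map = col_map)
}

#' Coerce a data frame to a raw response table
#'
#' @param x Data frame with query columns (and optionally an id column).
#' @inheritParams read_responses
#' @return A `raw_responses` data frame.
#' @export
as_raw_responses <- function(x, schema = dass_schema(), col_map = NULL) {
  stopifnot(is.data.frame(x))
  nms <- names(x)
  if (!is.null(col_map)) {
    hit <- match(nms, names(col_map))
    nms[!is.na(hit)] <- unname(col_map[hit[!is.na(hit)]])
  }
  canon <- match(tolower(nms), tolower(schema))
  id_at <- which(tolower(nms) %in% id_column_aliases)[1]
  missing_cols <- setdiff(tolower(schema), tolower(nms))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(schema[tolower(schema) %in% missing_cols], collapse = ", "))
  extra <- nms[is.na(canon) & seq_along(nms) != ifelse(is.na(id_at), 0L, id_at)]
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  ids <- if (!is.na(id_at)) as.character(x[[id_at]])
         else as.character(seq_len(nrow(x)))
  out <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  for (q in schema) {
    v <- x[[which(canon == match(q, schema))[1]]]
    out[[q]] <- suppressWarnings(as.numeric(v))
  }
  class(out) <- c("raw_responses", "data.frame")
  out
}

query_cols <- function(table) setdiff(names(table), "respondent_id")

#' Impute missing and out-of-range response codes by the column mode
#'
#' Any cell that is absent, non-integer, or outside `valid_range` is
#' treated as missing and replaced by the most common in-range value of
#' its column. Modal ties break deterministically to the smallest value.
#' The number of replacements per column is attached as the
#' `"n_imputed"` attribute.
#'
#' @param table A `raw_responses` data frame.
#' @param valid_range Inclusive integer interval of valid codes,
#'   default `c(1, 4)`.
#' @return The table with every cell in `valid_range`.
#' @export
impute_missing <- function(table, valid_range = c(1, 4)) {
  stopifnot(is.data.frame(table), length(valid_range) == 2L)
  qs <- query_cols(table)
  n_imputed <- stats::setNames(integer(length(qs)), qs)
  for (q in qs) {
    v <- table[[q]]
    ok <- !is.na(v) & v == round(v) & v >= valid_range[1] & v <= valid_range[2]
    if (!any(ok))
      stop("column ", q, " has no in-range values; cannot impute")
    if (!all(ok)) {
      tab <- table(v[ok])
      mode_val <- as.numeric(names(tab)[tab == max(tab)])
      mode_val <- min(mode_val)  # tie-break: smallest modal value
      v[!ok] <- mode_val
      table[[q]] <- v
      n_imputed[q] <- sum(!ok)
    }
  }
  attr(table, "n_imputed") <- n_imputed
  table
}

#' Encode response codes onto the 0-3 rate-point scale
#'
#' Maps each 1..4 response code to a rate point by subtracting 1. Cells
#' must already be in range; run [impute_missing()] first.
#'
#' @param table A `raw_responses` data frame with all cells in 1..4.
#' @return A data frame of class `rate_points` with integer cells in 0..3.
#' @export
encode_rate_points <- function(table) {
  stopifnot(is.data.frame(table))
  qs <- query_cols(table)
  for (q in qs) {
    v <- table[[q]]
    if (anyNA(v) || any(v != round(v)) || any(v < 1) || any(v > 4))
      stop("column ", q,
           " has cells outside 1..4; run impute_missing() first")
    table[[q]] <- as.integer(v) - 1L
  }
  attr(table, "n_imputed") <- NULL
  class(table) <- c("rate_points", "data.frame")
  table
}

#' Write a rate-point matrix back to CSV
#'
#' @param matrix A `rate_points` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_points <- function(matrix, path) {
  utils::write.csv(matrix, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coerce a data frame of rate points (cells already 0..3)
#'
#' @param x Data frame with query columns holding 0..3 rate points and
#'   optionally a respondent-id column.
#' @param schema Query columns expected; default all `Qn` columns present.
#' @return A `rate_points` data frame.
#' @export
as_rate_points <- function(x, schema = NULL) {
  stopifnot(is.data.frame(x))
  nms <- names(x)
  if (is.null(schema)) schema <- nms[grepl("^Q[0-9]+$", nms)]
  id_at <- which(tolower(nms) %in% id_column_aliases)[1]
  ids <- if (!is.na(id_at)) as.character(x[[id_at]])
         else as.character(seq_len(nrow(x)))
  out <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  for (q in schema) {
    v <- as.integer(x[[q]])
    if (anyNA(v) || any(v < 0) || any(v > 3))
      stop("column ", q, " is not on the 0..3 rate-point scale")
    out[[q]] <- v
  }
  class(out) <- c("rate_points", "data.frame")
  out
}
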