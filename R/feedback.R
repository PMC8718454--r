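# Templated clinician feedback: turns a prediction plus its PP/PN sets
# and counterfactual deltas into short auditable prose.

fill_template <- function(template, values) {
  for (nm in names(values))
    template <- gsub(paste0("{", nm, "}"), values[[nm]], template,
                     fixed = TRUE)
  template
}

#' Load the feedback template set
#'
#' @param path YAML template file; defaults to the bundled templates.
#' @return List with `clauses` and `query_phrases`.
#' @export
load_feedback_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feedback_templates.yaml",
                        package = "dassxdt", mustWork = TRUE)
  yaml::read_yaml(path)
}

phrase_list <- function(queries, templates) {
  ph <- templates$query_phrases
  missing_q <- setdiff(queries, names(ph))
  if (length(missing_q))
    stop("no phrase template for query ", paste(missing_q, collapse = ", "))
  ps <- unlist(ph[queries])
  if (length(ps) <= 1L) return(paste(ps, collapse = ""))
  paste(paste(ps[-length(ps)], collapse = ", "), "and", ps[length(ps)])
}

#' Render a feedback report for one respondent and one disorder
#'
#' Builds "detected due to" prose from the pertinent positives, an
#' escalation/shift clause from the pertinent negatives, and per-query
#' advice lines from the counterfactual deltas (negative delta = reduce
#' that behaviour). Every query cited in the prose appears in PP, PN or
#' the deltas.
#'
#' @param respondent_id Respondent identifier string.
#' @param disorder Disorder name (`anxiety`, `stress`, `depression`).
#' @param level Predicted severity label (`N`/`M`/`MD`/`S`/`ES`).
#' @param pp A `contrastive_explanation` from [pertinent_positive()], or
#'   a character vector of query ids. Optional.
#' @param pn A `contrastive_explanation` from [pertinent_negative()].
#'   Optional; skipped when absent or not found.
#' @param cf A [counterfactual()] result. Optional.
#' @param templates Template set from [load_feedback_templates()].
#' @return List of class `feedback_report` with fields `respondent_id`,
#'   `disorder`, `level`, `pp`, `pn`, `advice` (character lines) and
#'   `text` (rendered prose).
#' @export
render_feedback <- function(respondent_id, disorder, level, pp = NULL,
                            pn = NULL, cf = NULL,
                            templates = load_feedback_templates()) {
  stopifnot(level %in% SEVERITY_LEVELS)
  pp_ids <- if (inherits(pp, "contrastive_explanation")) pp$pp else pp
  pn_ids <- character(0)
  flipped <- NA_character_
  if (inherits(pn, "contrastive_explanation") && isTRUE(pn$found)) {
    pn_ids <- pn$pn
    flipped <- pn$flipped_to
  }
  cl <- templates$clauses
  parts <- character(0)
  if (length(pp_ids)) {
    parts <- fill_template(cl$detected, list(
      id = respondent_id, level = SEVERITY_LONG[[level]],
      disorder = disorder, pp = phrase_list(pp_ids, templates)))
  } else {
    parts <- fill_template(cl$no_risk,
                           list(id = respondent_id, disorder = disorder))
  }
  if (length(pn_ids)) {
    parts <- c(parts, fill_template(cl$escalation, list(
      pn = phrase_list(pn_ids, templates),
      level2 = SEVERITY_LONG[[flipped]])))
  }
  advice <- character(0)
  if (inherits(cf, "counterfactual")) {
    nz <- cf$deltas[abs(cf$deltas) > 1e-9]
    for (q in names(nz)) {
      tpl <- if (nz[[q]] < 0) cl$advice_reduce else cl$advice_increase
      advice <- c(advice, fill_template(tpl, list(
        phrase = phrase_list(q, templates),
        amount = format(abs(round(nz[[q]], 5))))))
    }
  }
  text <- paste(c(paste(parts, collapse = " "), advice), collapse = "\n")
  structure(list(respondent_id = respondent_id, disorder = disorder,
                 level = level, pp = pp_ids, pn = pn_ids,
                 flipped_to = flipped, advice = advice, text = text),
            class = "feedback_report")
}

#' @export
print.feedback_report <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}
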