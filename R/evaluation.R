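# Validate phase: confusion matrix, accuracy, one-vs-rest precision /
# recall / F-score with macro averaging, MSE on the integer severity
# coding, and a model-comparison harness.

#' Confusion matrix over the five severity levels
#'
#' @param truth,predicted Vectors of severity labels (`N/M/MD/S/ES`),
#'   equal length.
#' @param levels Class order; defaults to the five severity levels.
#' @return Integer matrix (true label x predicted label) of class
#'   `confusion_matrix`.
#' @export
confusion <- function(truth, predicted, levels = severity_levels()) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels), factor(predicted, levels))
  cm <- unclass(cm)
  dimnames(cm) <- list(truth = levels, predicted = levels)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

severity_to_int <- function(labels, levels = severity_levels()) {
  match(as.character(labels), levels) - 1L
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Precision, recall and F-score
#' are computed one-vs-rest per class and macro-averaged (unweighted
#' mean); a zero denominator yields 0 with a warning. MSE is the mean
#' squared difference of the labels on the integer severity coding
#' N=0, M=1, MD=2, S=3, ES=4.
#'
#' @param cm A [confusion()] matrix.
#' @return List of class `metrics_report`: `accuracy`, `per_class` (data
#'   frame with precision/recall/f_score per class), `macro_precision`,
#'   `macro_recall`, `macro_f`, `mse`, `n`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  levels <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0))
      warning(what, " undefined for class(es) ",
              paste(levels[den == 0], collapse = ", "), "; reported as 0")
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  codes <- seq_along(levels) - 1L
  err2 <- outer(codes, codes, function(a, b) (a - b)^2)
  mse <- sum(cm * err2) / total
  structure(list(
    accuracy = sum(tp) / total,
    per_class = data.frame(class = levels, precision = unname(precision),
                           recall = unname(recall), f_score = unname(f)),
    macro_precision = mean(precision), macro_recall = mean(recall),
    macro_f = mean(f), mse = mse, n = total
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F %.4f | MSE %.4f (n=%d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f,
              x$mse, x$n))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Evaluate a model on labeled data
#'
#' @param model A fitted model with a `predict` method.
#' @param data Labeled data frame.
#' @param label_col Label column, default `"Class"`.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, data, label_col = "Class") {
  pred <- as.character(predict(model, data))
  classification_metrics(confusion(data[[label_col]], pred))
}

# built-in model specs for the comparison harness -----------------------

#' Built-in model specifications for [compare_models()]
#'
#' `model_spec_balanced()` trains the oversampling-loop tree;
#' `model_spec_plain()` grows a single tree on the training split with no
#' oversampling (same stratified holdout). A model spec is simply a
#' `function(train, seed, attributes)` returning an object with a
#' `predict` method, so external learners can be plugged in.
#'
#' @param rate_step,valid_frac Passed to [train_balanced()].
#' @return A model-spec function.
#' @export
model_spec_balanced <- function(rate_step = 0.1, valid_frac = 0.2) {
  function(train, seed, attributes)
    train_balanced(train, seed = seed, rate_step = rate_step,
                   valid_frac = valid_frac, attributes = attributes)
}

#' @rdname model_spec_balanced
#' @export
model_spec_plain <- function() {
  function(train, seed, attributes)
    grow_tree(train, attributes = attributes)
}

#' Compare model specs with and without Q-Prioritization
#'
#' For every model x condition x seed cell: stratified holdout, optional
#' query elimination on the training split's priority relevance, fit,
#' and test-set metrics. A failing fit is recorded (`failed = TRUE`) and
#' the run continues.
#'
#' @param data Labeled disorder table (14 query columns + `Class`).
#' @param models Named list of model-spec functions.
#' @param rth Relevance threshold used for the "with prioritization"
#'   condition.
#' @param prioritization Conditions to run, subset of `c(TRUE, FALSE)`.
#' @param seeds Integer vector of seeds.
#' @param test_frac Held-out test fraction, default 0.25.
#' @param label_col Label column, default `"Class"`.
#' @return Data frame: one row per model x condition x seed with
#'   accuracy, macro P/R/F, MSE, `n_queries`, `failed`.
#' @export
compare_models <- function(data, models, rth,
                           prioritization = c(TRUE, FALSE), seeds = 1:5,
                           test_frac = 0.25, label_col = "Class") {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  rows <- list()
  for (seed in seeds) {
    split <- stratified_split(data[[label_col]], test_frac, seed)
    train <- data[split$train, , drop = FALSE]
    test <- data[split$valid, , drop = FALSE]
    for (prio in prioritization) {
      attrs <- grep("^Q[0-9]+$", names(train), value = TRUE)
      if (prio) {
        ranking <- prioritize(
          compute_priority_relevance(train, queries = attrs), rth)
        attrs <- ranking$query[ranking$kept]
      }
      for (mn in names(models)) {
        res <- tryCatch({
          fit <- models[[mn]](train, seed, attrs)
          m <- evaluate_model(fit, test, label_col = label_col)
          data.frame(model = mn, prioritized = prio, seed = seed,
                     accuracy = m$accuracy,
                     macro_precision = m$macro_precision,
                     macro_recall = m$macro_recall, macro_f = m$macro_f,
                     mse = m$mse, n_queries = length(attrs),
                     failed = FALSE)
        }, error = function(e) {
          data.frame(model = mn, prioritized = prio, seed = seed,
                     accuracy = NA_real_, macro_precision = NA_real_,
                     macro_recall = NA_real_, macro_f = NA_real_,
                     mse = NA_real_, n_queries = length(attrs),
                     failed = TRUE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  do.call(rbind, rows)
}
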