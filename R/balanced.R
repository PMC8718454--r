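# Balanced decision tree: the information-gain tree retrained under
# escalating minority-class random oversampling. Each round replicates
# minority rows (with replacement) until every class reaches the round's
# sampling rate times the majority count, grows a tree, and scores it on
# an untouched stratified validation split; the loop keeps the best round
# and stops at the first round whose accuracy falls below the best so far
# or once the rate reaches 1.0.

# evaluate code under a temporary RNG seeded with `seed` (NULL = current RNG)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly oversample minority classes to a target ratio
#'
#' Every class whose count is below `rate` times the majority-class count
#' is augmented by drawing its own rows with replacement until it reaches
#' `ceiling(rate * majority count)`. The majority class (and any class
#' already at or above the target) is untouched, and no row is ever
#' removed.
#'
#' @param data Labeled data frame.
#' @param rate Target minority:majority count ratio in (0, 1].
#' @param seed Optional integer; fixing it makes the draw reproducible.
#' @param label_col Label column, default `"Class"`.
#' @return The augmented data frame (original rows first).
#' @export
oversample <- function(data, rate, seed = NULL, label_col = "Class") {
  stopifnot(is.data.frame(data), rate > 0, rate <= 1)
  y <- as.character(data[[label_col]])
  cnt <- table(y)
  if (length(cnt) < 2L) {
    warning("single-class data; oversampling is a no-op")
    return(data)
  }
  maj <- max(cnt)
  target <- ceiling(rate * maj)
  extra <- with_seed(seed, {
    unlist(lapply(names(cnt)[cnt < target], function(cl) {
      idx <- which(y == cl)
      sample(idx, target - length(idx), replace = TRUE)
    }))
  })
  if (!length(extra)) return(data)
  out <- rbind(data, data[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# stratified train/validation split; errors if a training class cannot be
# represented in validation
stratified_split <- function(y, valid_frac, seed) {
  y <- as.character(y)
  with_seed(seed, {
    val <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < 2L)
        stop("class ", cl, " has fewer than 2 rows; ",
             "validation split would miss a training class")
      n_val <- max(1L, round(valid_frac * length(idx)))
      if (n_val >= length(idx)) n_val <- length(idx) - 1L
      val <- c(val, sample(idx, n_val))
    }
    list(train = setdiff(seq_along(y), val), valid = sort(val))
  })
}

#' Train a balanced decision tree by repeated oversampling
#'
#' Splits the data into a stratified train/validation holdout, then
#' iterates the sampling rate over `rate_step, 2*rate_step, ..., 1`:
#' oversample the training split at the current rate, grow an
#' information-gain tree, and measure accuracy on the untouched
#' validation split. The best round is kept; starting from a reference
#' accuracy of zero, the loop stops at the first round whose accuracy
#' falls strictly below the best seen so far, or when the rate reaches 1.
#' Oversampling happens strictly after the split, so validation rows are
#' never replicated into training.
#'
#' @param data Labeled data frame with query columns and `label_col`.
#' @param seed Integer seed driving the split and every round's draw.
#' @param rate_step Sampling-rate increment, default 0.1.
#' @param valid_frac Validation fraction of the stratified holdout,
#'   default 0.2.
#' @param attributes Candidate split columns (default: all `Qn` columns).
#' @param label_col Label column, default `"Class"`.
#' @param min_leaf Passed to [grow_tree()].
#' @return An object of class `balanced_tree`: fields `tree` (best
#'   round's `dass_tree`), `trace` (one row per round: `round`, `rate`,
#'   `accuracy`, post-sampling class counts), `best_round`,
#'   `best_accuracy`, `seed`, `attributes`, `valid_idx`.
#' @examples
#' \donttest{
#' gen <- generate_responses(300, mixture = c(.5, .2, .15, .1, .05), seed = 1)
#' tab <- assign_severity(compute_weight_scores(
#'   gen$rate_points, default_disorder_sets()$anxiety),
#'   default_disorder_sets()$anxiety)
#' fit <- train_balanced(tab, seed = 1)
#' fit$trace
#' }
#' @export
train_balanced <- function(data, seed = 1L, rate_step = 0.1,
                           valid_frac = 0.2, attributes = NULL,
                           label_col = "Class", min_leaf = 1L) {
  stopifnot(is.data.frame(data), rate_step > 0, rate_step <= 1)
  if (is.null(attributes))
    attributes <- grep("^Q[0-9]+$", names(data), value = TRUE)
  y <- as.character(data[[label_col]])
  if (length(unique(y)) < 2L)
    stop("training data must contain at least 2 classes")
  split <- stratified_split(y, valid_frac, seed)
  train <- data[split$train, , drop = FALSE]
  valid <- data[split$valid, , drop = FALSE]

  rates <- seq(rate_step, 1, by = rate_step)
  classes <- sort(unique(y))
  trace <- data.frame(round = integer(), rate = numeric(),
                      accuracy = numeric())
  counts <- list()
  best_acc <- 0       # reference accuracy before the first round
  best_tree <- NULL
  best_round <- NA_integer_
  for (r in seq_along(rates)) {
    boosted <- oversample(train, rates[r], seed = seed * 1000L + r,
                          label_col = label_col)
    tree <- grow_tree(boosted, attributes = attributes,
                      label_col = label_col, min_leaf = min_leaf)
    acc <- mean(as.character(predict(tree, valid)) == valid[[label_col]])
    trace <- rbind(trace, data.frame(round = r, rate = rates[r],
                                     accuracy = acc))
    counts[[r]] <- table(factor(boosted[[label_col]], levels = classes))
    if (acc > best_acc) {
      best_acc <- acc
      best_tree <- tree
      best_round <- r
    } else if (acc < best_acc) {
      break  # first drop below the best so far
    }
  }
  if (is.null(best_tree)) {  # every round scored exactly 0
    best_tree <- grow_tree(oversample(train, rates[1],
                                      seed = seed * 1000L + 1L,
                                      label_col = label_col),
                           attributes = attributes, label_col = label_col,
                           min_leaf = min_leaf)
    best_round <- 1L
    best_acc <- trace$accuracy[1]
  }
  for (cl in classes)
    trace[[paste0("n_", cl)]] <-
      vapply(counts[seq_len(nrow(trace))], function(ct) as.integer(ct[[cl]]), 0L)
  structure(list(tree = best_tree, trace = trace, best_round = best_round,
                 best_accuracy = best_acc, seed = seed,
                 rate_step = rate_step, attributes = attributes,
                 classes = best_tree$classes, label_col = label_col,
                 valid_idx = split$valid),
            class = "balanced_tree")
}

#' @rdname train_balanced
#' @param object A `balanced_tree`.
#' @param newdata Data frame with the model's query columns.
#' @param ... Unused.
#' @export
predict.balanced_tree <- function(object, newdata, ...) {
  predict(object$tree, newdata)
}

#' @export
print.balanced_tree <- function(x, ...) {
  cat(sprintf(
    "<balanced_tree> best round %d (rate %.1f), validation accuracy %.3f\n",
    x$best_round, x$trace$rate[x$best_round], x$best_accuracy))
  print(x$tree)
  invisible(x)
}

# ---- JSON (de)serialization -------------------------------------------

node_to_list <- function(node) {
  out <- list(type = node$type, label = node$label,
              counts = as.integer(node$counts))
  if (node$type == "split") {
    out$attribute <- node$attribute
    out$children <- lapply(node$children, node_to_list)
  }
  out
}

list_to_node <- function(l) {
  node <- list(counts = as.integer(unlist(l$counts)), label = l$label,
               type = l$type)
  if (l$type == "split") {
    node$attribute <- l$attribute
    node$children <- lapply(l$children, list_to_node)
  }
  node
}

#' Save or load a balanced-tree model as JSON
#'
#' Models are stored as plain JSON (tree nodes, oversampling trace,
#' schema, seed) so runs are auditable and reloadable without binary
#' artifacts.
#'
#' @param model A `balanced_tree`.
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   returns the restored `balanced_tree`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "balanced_tree"))
  obj <- list(
    tree = node_to_list(model$tree$root),
    tree_meta = list(attributes = model$tree$attributes,
                     classes = model$tree$classes,
                     label_col = model$tree$label_col,
                     min_leaf = model$tree$min_leaf),
    trace = model$trace, best_round = model$best_round,
    best_accuracy = model$best_accuracy, seed = model$seed,
    rate_step = model$rate_step, attributes = model$attributes,
    classes = model$classes, label_col = model$label_col,
    valid_idx = model$valid_idx
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  # read tree nodes without vector simplification (children keys matter)
  raw <- jsonlite::read_json(path)
  tree <- structure(
    list(root = list_to_node(raw$tree),
         attributes = unlist(obj$tree_meta$attributes),
         classes = unlist(obj$tree_meta$classes),
         label_col = obj$tree_meta$label_col,
         min_leaf = obj$tree_meta$min_leaf),
    class = "dass_tree")
  structure(list(tree = tree, trace = as.data.frame(obj$trace),
                 best_round = obj$best_round,
                 best_accuracy = obj$best_accuracy, seed = obj$seed,
                 rate_step = obj$rate_step,
                 attributes = unlist(obj$attributes),
                 classes = unlist(obj$classes), label_col = obj$label_col,
                 valid_idx = unlist(obj$valid_idx)),
            class = "balanced_tree")
}
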