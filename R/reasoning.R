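# Reasoning engine: permutation feature importance, contrastive
# pertinent-positive / pertinent-negative query sets, and prototype-guided
# counterfactual search over the rate-point grid.

model_attributes <- function(model) {
  if (inherits(model, "balanced_tree")) model$tree$attributes
  else if (inherits(model, "dass_tree")) model$attributes
  else stop("unsupported model type")
}

model_tree <- function(model) {
  if (inherits(model, "balanced_tree")) model$tree else model
}

as_instance <- function(instance, attrs) {
  if (is.data.frame(instance)) {
    stopifnot(nrow(instance) == 1L)
    v <- as.numeric(instance[1, attrs])
    names(v) <- attrs
  } else {
    stopifnot(all(attrs %in% names(instance)))
    v <- as.numeric(instance[attrs])
    names(v) <- attrs
  }
  v
}

predict_one <- function(model, inst) {
  as.character(predict(model, as.data.frame(as.list(inst))))
}

#' Permutation feature importance (P-score)
#'
#' For each query, its column is independently shuffled `repeats` times;
#' the importance is the base accuracy minus the mean accuracy under
#' shuffling. Constant columns get an exact zero. Queries are ranked by
#' descending score.
#'
#' @param model A `balanced_tree` or `dass_tree`.
#' @param data Labeled data frame (2 or more rows) matching the model
#'   schema.
#' @param repeats Number of shuffles per query, default 10.
#' @param seed Integer seed for the shuffles.
#' @param label_col Label column, default `"Class"`.
#' @return A data frame of class `importance_ranking` with columns
#'   `query`, `importance`, `rank`, ordered by rank; attributes
#'   `base_accuracy`, `repeats`, `seed`.
#' @export
permuted_importance <- function(model, data, repeats = 10L, seed = 1L,
                                label_col = "Class") {
  stopifnot(is.data.frame(data), repeats >= 1L)
  if (nrow(data) < 2L)
    stop("importance is degenerate on fewer than 2 rows")
  attrs <- model_attributes(model)
  y <- as.character(data[[label_col]])
  base <- mean(as.character(predict(model, data)) == y)
  imp <- with_seed(seed, vapply(attrs, function(q) {
    col <- data[[q]]
    if (length(unique(col)) == 1L) return(0)  # identity under permutation
    accs <- vapply(seq_len(repeats), function(r) {
      d <- data
      d[[q]] <- sample(col)
      mean(as.character(predict(model, d)) == y)
    }, numeric(1))
    base - mean(accs)
  }, numeric(1)))
  out <- data.frame(query = attrs, importance = unname(imp),
                    stringsAsFactors = FALSE)
  ord <- order(-out$importance, seq_len(nrow(out)))
  out$rank <- match(seq_len(nrow(out)), ord)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "base_accuracy") <- base
  attr(out, "repeats") <- repeats
  attr(out, "seed") <- seed
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Pertinent positives: minimal query set preserving the prediction
#'
#' Finds a locally minimal set of queries `PP` such that masking every
#' query outside `PP` to the baseline value still yields the original
#' predicted label. Backward greedy elimination (queries closest to
#' baseline tried first) followed by a leave-one-out verification pass:
#' removing any single member of the returned set changes the
#' prediction.
#'
#' @param model A fitted model.
#' @param instance One respondent's rate points (1-row data frame or
#'   named vector).
#' @param baseline Neutral masking value per query, default 0 (the
#'   "never applied to me" response).
#' @return List of class `contrastive_explanation` with `pp` (query
#'   ids), `label`, `baseline`, `non_minimal` flag.
#' @export
pertinent_positive <- function(model, instance, baseline = 0) {
  attrs <- model_attributes(model)
  inst <- as_instance(instance, attrs)
  base_vals <- if (length(baseline) == 1L)
    stats::setNames(rep(baseline, length(attrs)), attrs)
  else as_instance(baseline, attrs)
  orig <- predict_one(model, inst)
  mask_outside <- function(keep) {
    v <- base_vals
    v[keep] <- inst[keep]
    v
  }
  keep <- attrs
  # try least-deviating queries first so strong symptoms stay in PP
  order_try <- attrs[order(abs(inst - base_vals))]
  repeat {
    removed <- FALSE
    for (q in intersect(order_try, keep)) {
      cand <- setdiff(keep, q)
      if (predict_one(model, mask_outside(cand)) == orig) {
        keep <- cand
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  non_minimal <- length(keep) == length(attrs) &&
    predict_one(model, mask_outside(keep)) != orig
  structure(list(pp = keep, label = orig, baseline = base_vals,
                 non_minimal = non_minimal),
            class = "contrastive_explanation")
}

#' Pertinent negatives: smallest value change that flips the prediction
#'
#' Searches value substitutions on the 0..3 grid, by increasing number of
#' changed queries up to `budget`, for the first substitution set that
#' changes the predicted label. Returns an explicit not-found result when
#' no flip exists within budget.
#'
#' @inheritParams pertinent_positive
#' @param budget Maximum number of queries that may change, default 3.
#' @return List of class `contrastive_explanation` with `found`, `pn`
#'   (query ids), `values` (their flipping values), `label` (original),
#'   `flipped_to`.
#' @export
pertinent_negative <- function(model, instance, budget = 3L) {
  attrs <- model_attributes(model)
  inst <- as_instance(instance, attrs)
  orig <- predict_one(model, inst)
  not_found <- structure(list(found = FALSE, pn = character(0),
                              values = numeric(0), label = orig,
                              flipped_to = NA_character_),
                         class = "contrastive_explanation")
  if (budget < 1L) return(not_found)
  for (size in seq_len(min(budget, length(attrs)))) {
    sets <- utils::combn(attrs, size, simplify = FALSE)
    for (qs in sets) {
      # all value assignments differing from the instance in every query
      grids <- lapply(qs, function(q) setdiff(0:3, inst[[q]]))
      combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
      cand <- matrix(rep(inst, nrow(combos)), nrow = nrow(combos),
                     byrow = TRUE, dimnames = list(NULL, attrs))
      for (j in seq_along(qs)) cand[, qs[j]] <- combos[[j]]
      pred <- as.character(predict(model, as.data.frame(cand)))
      hit <- which(pred != orig)
      if (length(hit)) {
        i <- hit[1]
        return(structure(list(found = TRUE, pn = qs,
                              values = stats::setNames(as.numeric(combos[i, ]), qs),
                              label = orig, flipped_to = pred[i]),
                         class = "contrastive_explanation"))
      }
    }
  }
  not_found
}

#' Prototype-guided counterfactual search
#'
#' Finds a sparse perturbation `delta` of an instance so that the model
#' assigns the perturbed instance `s0 + delta` to a chosen target label,
#' by coordinate descent on the loss
#' `x_weight * L_pred + beta_reg * sum(|delta|) + sum(delta^2)`,
#' where `L_pred` is a hinge on the margin between the target class and
#' the best other class at the reached leaf. The search starts at the
#' target-class prototype (the per-query mean of reference rows carrying
#' the target label) and pulls coordinates back toward the instance,
#' visiting them in order of prototype distance; candidate values lie on
#' a fine grid in [0, 3], so deltas may be fractional. When the
#' regularizers dominate the hinge (so the unconstrained minimum would
#' abandon the flip), the prediction weight is doubled, up to 13 times,
#' until the target label holds; `x_used` records the final weight. The
#' accepted-move loss sequence within the reported search is
#' non-increasing by construction.
#'
#' @inheritParams pertinent_positive
#' @param target Target severity label.
#' @param reference Labeled reference data (e.g. the training table) from
#'   which class prototypes are computed.
#' @param x_weight Weight of the prediction-loss term, default 1.
#' @param beta_reg L1 sparsity weight, default 0.1.
#' @param max_iter Maximum coordinate-descent sweeps, default 50.
#' @param grid_step Candidate-value grid spacing, default 0.25.
#' @param label_col Label column of `reference`.
#' @return List of class `counterfactual`: `s0`, `sxy`, `deltas`
#'   (negative values mean "reduce this metric"), `target`, `converged`,
#'   `iterations`, `loss`, `loss_terms`, `loss_trace`, `x_used`.
#' @export
counterfactual <- function(model, instance, target, reference,
                           x_weight = 1, beta_reg = 0.1, max_iter = 50L,
                           grid_step = 0.25, label_col = "Class") {
  attrs <- model_attributes(model)
  inst <- as_instance(instance, attrs)
  tree <- model_tree(model)
  if (!target %in% tree$classes)
    stop("target label ", target, " is not predicted by this model")
  ref_rows <- reference[as.character(reference[[label_col]]) == target, ,
                        drop = FALSE]
  if (!nrow(ref_rows))
    stop("no reference rows with target label ", target)
  proto <- vapply(attrs, function(q) mean(ref_rows[[q]]), numeric(1))

  loss_terms <- function(s, x) {
    p <- .leaf_probs(tree, s)
    other <- p[names(p) != target]
    l_pred <- if (length(other)) max(0, max(other) - p[[target]]) else 0
    d <- s - inst
    c(pred = x * l_pred, l1 = beta_reg * sum(abs(d)), l2 = sum(d^2))
  }

  if (predict_one(model, inst) == target) {
    lt <- c(pred = 0, l1 = 0, l2 = 0)
    return(structure(list(s0 = inst, sxy = inst,
                          deltas = stats::setNames(rep(0, length(attrs)), attrs),
                          target = target, converged = TRUE, iterations = 0L,
                          loss = 0, loss_terms = lt, loss_trace = 0,
                          x_used = x_weight),
                     class = "counterfactual"))
  }

  visit <- attrs[order(-abs(proto - inst))]  # prototype-guided order
  grid <- seq(0, 3, by = grid_step)
  descend <- function(x) {
    total <- function(s) sum(loss_terms(s, x))
    s <- proto  # initialize at the target-class prototype
    cur <- total(s)
    trace <- cur
    it <- 0L
    repeat {
      it <- it + 1L
      improved <- FALSE
      for (q in visit) {
        cands <- unique(c(s[[q]], inst[[q]], proto[[q]], grid))
        best_v <- s[[q]]
        best_l <- cur
        for (v in cands) {
          s2 <- s
          s2[[q]] <- v
          l <- total(s2)
          if (l < best_l - 1e-12) {
            best_l <- l
            best_v <- v
          }
        }
        if (best_v != s[[q]]) {
          s[[q]] <- best_v
          cur <- best_l
          trace <- c(trace, cur)
          improved <- TRUE
        }
      }
      if (!improved || it >= max_iter) break
    }
    list(s = s, loss = cur, trace = trace, it = it)
  }

  # if the regularizers overwhelm the hinge the unconstrained minimum is
  # "do not flip"; escalate the prediction weight until the target holds
  res <- NULL
  x <- x_weight
  for (try in 1:13) {
    res <- descend(x)
    if (predict_one(model, res$s) == target) break
    x <- x * 2
  }
  converged <- predict_one(model, res$s) == target
  if (!converged)
    warning("counterfactual search did not reach target label ", target,
            "; returning best effort")
  structure(list(s0 = inst, sxy = res$s, deltas = res$s - inst,
                 target = target, converged = converged,
                 iterations = res$it, loss = res$loss,
                 loss_terms = loss_terms(res$s, x), loss_trace = res$trace,
                 x_used = x),
            class = "counterfactual")
}
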