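# Decision-tree core: Shannon entropy, information gain, and a multiway
# categorical tree over the 0..3 rate-point grid. Attributes are split on
# their observed values (no binary thresholding); each root-to-leaf path
# tests an attribute at most once; leaves carry the majority severity
# label of their training rows.

#' Shannon entropy of a class-count vector, in bits
#'
#' @param class_counts Non-negative counts per class.
#' @return `-sum(p * log2(p))` over classes with positive count.
#' @examples
#' entropy_bits(c(1, 1))    # 1 bit
#' entropy_bits(c(2, 1, 1)) # 1.5 bits
#' @export
entropy_bits <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be non-negative")
  tot <- sum(class_counts)
  if (tot == 0) stop("entropy undefined for all-zero counts")
  p <- class_counts[class_counts > 0] / tot
  -sum(p * log2(p))
}

#' Information gain of splitting labeled rows on one attribute
#'
#' Parent entropy minus the size-weighted entropies of the subsets
#' induced by each observed value of the attribute.
#'
#' @param data Data frame of labeled rows.
#' @param attribute Column name to split on.
#' @param label_col Name of the label column, default `"Class"`.
#' @return Gain in bits (0 when the attribute is constant or the labels
#'   are pure).
#' @export
information_gain <- function(data, attribute, label_col = "Class") {
  stopifnot(is.data.frame(data), nrow(data) >= 1L,
            attribute %in% names(data), label_col %in% names(data))
  y <- factor(data[[label_col]])
  a <- factor(data[[attribute]])
  parent <- entropy_bits(tabulate(y, nlevels(y)))
  n <- length(y)
  child <- 0
  for (v in levels(a)) {
    sel <- a == v
    if (!any(sel)) next
    child <- child + sum(sel) / n * entropy_bits(tabulate(y[sel], nlevels(y)))
  }
  parent - child
}

# entropy from a count vector without validation (hot path)
.ent <- function(cnt) {
  tot <- sum(cnt)
  p <- cnt[cnt > 0L] / tot
  -sum(p * log2(p))
}

# gains for all candidate attributes at once; x integer matrix with values
# in 0..(nv-1), y integer labels 1..k
.gains <- function(x, y, attrs, k, nv = 4L) {
  n <- length(y)
  parent <- .ent(tabulate(y, k))
  vapply(attrs, function(j) {
    a <- x[, j]
    cnt <- tabulate(a * k + y, nv * k)
    child <- 0
    for (v in seq_len(nv)) {
      cv <- cnt[((v - 1L) * k + 1L):(v * k)]
      nv_rows <- sum(cv)
      if (nv_rows > 0L) child <- child + nv_rows / n * .ent(cv)
    }
    parent - child
  }, numeric(1))
}

#' Grow a multiway information-gain decision tree
#'
#' Recursively splits on the attribute of maximal information gain
#' (ties broken toward the lowest-indexed query; value branches ordered
#' 0..3), stopping at pure nodes, exhausted attributes, node size at or
#' below `min_leaf`, or zero best gain. Attribute values are treated as
#' categories on the 0..3 rate-point grid.
#'
#' @param data Data frame with query columns and a label column.
#' @param attributes Candidate split columns; defaults to every `Qn`
#'   column present.
#' @param label_col Label column name, default `"Class"`.
#' @param min_leaf Minimum node size eligible for splitting minus one;
#'   nodes with `min_leaf` rows or fewer become leaves. Default 1.
#' @return An object of class `dass_tree`.
#' @export
grow_tree <- function(data, attributes = NULL, label_col = "Class",
                      min_leaf = 1L) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  if (is.null(attributes))
    attributes <- grep("^Q[0-9]+$", names(data), value = TRUE)
  if (!length(attributes)) stop("no candidate attributes")
  y_fac <- factor(data[[label_col]],
                  levels = if (all(data[[label_col]] %in% SEVERITY_LEVELS))
                    SEVERITY_LEVELS else sort(unique(as.character(data[[label_col]]))))
  y_fac <- droplevels(y_fac)
  classes <- levels(y_fac)
  y <- as.integer(y_fac)
  x <- as.matrix(data[, attributes, drop = FALSE])
  storage.mode(x) <- "integer"
  if (any(x < 0L | x > 3L))
    stop("attribute values must be rate points in 0..3")
  k <- length(classes)

  build <- function(rows, avail) {
    cnt <- tabulate(y[rows], k)
    maj <- which.max(cnt)  # ties -> first class in level order
    node <- list(counts = cnt, label = classes[maj])
    pure <- cnt[maj] == length(rows)
    if (pure || !length(avail) || length(rows) <= min_leaf) {
      node$type <- "leaf"
      return(node)
    }
    g <- .gains(x[rows, , drop = FALSE], y[rows], avail, k)
    best <- avail[which.max(g)]   # which.max: lowest index on ties
    if (max(g) <= 1e-12) {
      node$type <- "leaf"
      return(node)
    }
    a <- x[rows, best]
    kids <- list()
    for (v in 0:3) {
      sel <- a == v
      if (!any(sel)) next
      kids[[as.character(v)]] <- build(rows[sel], setdiff(avail, best))
    }
    if (length(kids) < 2L) {  # attribute constant in this node
      node$type <- "leaf"
      return(node)
    }
    node$type <- "split"
    node$attribute <- attributes[best]
    node$children <- kids
    node
  }

  structure(list(root = build(seq_along(y), seq_along(attributes)),
                 attributes = attributes, classes = classes,
                 label_col = label_col, min_leaf = min_leaf),
            class = "dass_tree")
}

# descend to the leaf (or fallback node) for one row; returns the node
.descend <- function(node, row) {
  while (node$type == "split") {
    v <- as.character(.snap_rate(row[[node$attribute]]))
    child <- node$children[[v]]
    if (is.null(child)) return(node)  # unseen value: node majority
    node <- child
  }
  node
}

# snap a possibly fractional rate point onto the 0..3 grid
.snap_rate <- function(v) max(0L, min(3L, as.integer(round(v))))

#' Predict severity labels with a decision tree
#'
#' Rows descend the tree by their attribute values; a value with no
#' branch at a node falls back to that node's majority label. Fractional
#' values (as produced by counterfactual search) are rounded onto the
#' 0..3 grid before descent.
#'
#' @param object A `dass_tree`.
#' @param newdata Data frame providing every schema attribute.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.dass_tree <- function(object, newdata, ...) {
  missing_q <- setdiff(object$attributes, names(newdata))
  if (length(missing_q))
    stop("newdata lacks attribute(s): ", paste(missing_q, collapse = ", "))
  m <- as.matrix(newdata[, object$attributes, drop = FALSE])
  out <- character(nrow(m))
  for (i in seq_len(nrow(m)))
    out[i] <- .descend(object$root, m[i, ])$label
  factor(out, levels = object$classes)
}

# class-probability vector (training proportions) at the reached node
.leaf_probs <- function(tree, row) {
  node <- .descend(tree$root, row)
  p <- node$counts / sum(node$counts)
  names(p) <- tree$classes
  p
}

#' @export
print.dass_tree <- function(x, ...) {
  depth <- function(n) if (n$type == "leaf") 0L else
    1L + max(vapply(n$children, depth, 0L))
  n_leaves <- function(n) if (n$type == "leaf") 1L else
    sum(vapply(n$children, n_leaves, 0L))
  cat(sprintf("<dass_tree> %d attributes, %d classes, depth %d, %d leaves\n",
              length(x$attributes), length(x$classes), depth(x$root),
              n_leaves(x$root)))
  invisible(x)
}
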