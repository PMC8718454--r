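# Synthetic DASS-42-style response generator: per-disorder severity
# mixtures, band-conditioned rate points drawn exactly uniformly over
# the tuples whose sum falls in the band (composition-count sampling),
# designated class-independent (irrelevant) queries, and symmetric +/-1
# response noise. Ground-truth labels are re-derived from the final
# rate points, so they stay consistent with the scoring rules even
# under noise.

normalize_mixture <- function(mixture) {
  if (is.null(names(mixture))) {
    stopifnot(length(mixture) == 5L)
    names(mixture) <- SEVERITY_LEVELS
  }
  stopifnot(setequal(names(mixture), SEVERITY_LEVELS))
  mixture <- mixture[SEVERITY_LEVELS]
  if (abs(sum(mixture) - 1) > 1e-6)
    stop("mixture proportions must sum to 1")
  if (any(mixture < 0)) stop("mixture proportions must be non-negative")
  mixture
}

# composition_counts[j + 1, s + 1] = number of j-tuples over {0..3}
# summing to s; doubles are exact here (max count 4^14 << 2^53)
composition_counts <- function(n_items = 14L, v_max = 3L) {
  cnt <- matrix(0, n_items + 1L, n_items * v_max + 1L)
  cnt[1L, 1L] <- 1
  for (j in seq_len(n_items))
    for (s in 0:(j * v_max))
      cnt[j + 1L, s + 1L] <-
        sum(cnt[j, pmax(s - v_max, 0):s + 1L])
  cnt
}

# k rows of n_items rate points whose sum lies in [lo, hi], exactly
# uniform over all such tuples: the row sum is drawn with weight equal
# to its composition count, then cells are filled sequentially with
# probabilities proportional to the remaining-composition counts
sample_band_rows <- function(k, lo, hi, n_items = 14L) {
  if (k == 0L) return(matrix(integer(0), 0L, n_items))
  cnt <- composition_counts(n_items)
  sums <- lo:hi
  w <- cnt[n_items + 1L, sums + 1L]
  if (all(w == 0))
    stop("band [", lo, ", ", hi, "] admits no rate-point tuples")
  s <- sums[sample.int(length(sums), k, replace = TRUE, prob = w)]
  out <- matrix(0L, k, n_items)
  rem <- s
  for (j in seq_len(n_items)) {
    left <- n_items - j          # items still to fill after this one
    # P(v | rem) proportional to count of (left)-tuples summing to rem - v
    pv <- vapply(0:3, function(v) {
      ok <- rem - v >= 0 & rem - v <= left * 3L
      p <- numeric(k)
      p[ok] <- cnt[left + 1L, rem[ok] - v + 1L]
      p
    }, numeric(k))
    cum <- pv %*% upper.tri(diag(4), diag = TRUE)
    u <- stats::runif(k) * cum[, 4L]
    v <- 4L - as.integer(rowSums(u <= cum))
    out[, j] <- v
    rem <- rem - v
  }
  stopifnot(all(rem == 0L))
  out
}

#' Generate synthetic DASS-42 responses with known severity structure
#'
#' For each respondent and each disorder a target severity band is drawn
#' from the mixture, and the disorder's 14 rate points are sampled
#' uniformly from all value tuples whose Weight Score falls in that
#' band's interval (exact composition-count sampling, so even extreme
#' bands are drawn without rejection). Queries listed in `irrelevant`
#' are then overwritten with draws from a fixed low-mean distribution
#' (P(0,1,2,3) = .7/.2/.08/.02) independent of class, and each cell is
#' perturbed by +/-1 (clipped to [0, 3]) with probability `noise`.
#' Ground-truth labels are re-derived from the final rate points, so
#' they remain exactly consistent with [assign_severity()]. The three
#' disorders are generated independently.
#'
#' @param n Number of respondents.
#' @param mixture Severity mixture over `N/M/MD/S/ES`: a probability
#'   vector applied to all three disorders, or a named list with one
#'   vector per disorder. Default `c(.3, .2, .2, .2, .1)`.
#' @param noise Per-cell perturbation probability in [0, 1], default
#'   0.05.
#' @param irrelevant Query ids generated independently of class.
#' @param sets Disorder sets, default [default_disorder_sets()].
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return List: `responses` (raw 1..4 codes, class `raw_responses`),
#'   `rate_points` (0..3, class `rate_points`), `truth` (data frame of
#'   per-disorder labels), `config`.
#' @examples
#' gen <- generate_responses(50, noise = 0, seed = 7)
#' table(gen$truth$anxiety)
#' @export
generate_responses <- function(n,
                               mixture = c(N = 0.3, M = 0.2, MD = 0.2,
                                           S = 0.2, ES = 0.1),
                               noise = 0.05, irrelevant = character(),
                               sets = default_disorder_sets(), seed = 1L) {
  stopifnot(n >= 1L, noise >= 0, noise <= 1)
  mixtures <- if (is.list(mixture)) {
    stopifnot(setequal(names(mixture), names(sets)))
    lapply(mixture, normalize_mixture)
  } else {
    m <- normalize_mixture(mixture)
    stats::setNames(rep(list(m), length(sets)), names(sets))
  }
  bad_q <- setdiff(irrelevant, unlist(lapply(sets, `[[`, "queries")))
  if (length(bad_q))
    stop("irrelevant queries not in any disorder set: ",
         paste(bad_q, collapse = ", "))

  with_seed(seed, {
    all_q <- unlist(lapply(sets, `[[`, "queries"), use.names = FALSE)
    rp <- matrix(0L, n, length(all_q), dimnames = list(NULL, all_q))
    for (ds in names(sets)) {
      set <- sets[[ds]]
      mix <- mixtures[[ds]]
      band_draw <- sample(SEVERITY_LEVELS, n, replace = TRUE, prob = mix)
      block <- matrix(0L, n, 14L)
      for (lv in SEVERITY_LEVELS) {
        idx <- which(band_draw == lv)
        if (!length(idx)) next
        b <- set$bands[set$bands$label == lv, ]
        block[idx, ] <- sample_band_rows(length(idx), b$lo, b$hi)
      }
      rp[, set$queries] <- block
    }
    if (length(irrelevant)) {
      low <- c(0.70, 0.20, 0.08, 0.02)
      for (q in irrelevant)
        rp[, q] <- sample(0:3, n, replace = TRUE, prob = low)
    }
    if (noise > 0) {
      flip <- matrix(stats::runif(length(rp)) < noise, nrow = n)
      dir <- matrix(sample(c(-1L, 1L), length(rp), replace = TRUE), nrow = n)
      rp[flip] <- pmin(3L, pmax(0L, rp[flip] + dir[flip]))
    }
    ord <- paste0("Q", 1:42)
    rp <- rp[, ord, drop = FALSE]
    mat <- data.frame(respondent_id = as.character(seq_len(n)),
                      stringsAsFactors = FALSE)
    for (q in ord) mat[[q]] <- rp[, q]
    class(mat) <- c("rate_points", "data.frame")
    truth <- data.frame(respondent_id = mat$respondent_id,
                        stringsAsFactors = FALSE)
    for (ds in names(sets)) {
      lab <- assign_severity(compute_weight_scores(mat, sets[[ds]]),
                             sets[[ds]])
      truth[[ds]] <- as.character(lab$Class)
    }
    raw <- mat
    for (q in ord) raw[[q]] <- raw[[q]] + 1L
    class(raw) <- c("raw_responses", "data.frame")
    list(responses = raw, rate_points = mat, truth = truth,
         config = list(n = n, mixture = mixtures, noise = noise,
                       irrelevant = irrelevant, seed = seed))
  })
}

#' Labeled table for one disorder from a generator draw
#'
#' Convenience wrapper used throughout the examples and tests: restrict
#' a generated rate-point matrix to one disorder and attach WS + Class.
#'
#' @param gen Result of [generate_responses()].
#' @param disorder Disorder name.
#' @param sets Disorder sets used at generation time.
#' @return A labeled disorder table.
#' @export
labeled_table <- function(gen, disorder, sets = default_disorder_sets()) {
  set <- sets[[disorder]]
  assign_severity(compute_weight_scores(gen$rate_points, set), set)
}
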