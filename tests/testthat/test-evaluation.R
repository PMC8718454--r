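test_that("confusion counts are exact with fixed class order", {
  cm <- confusion(c("N", "S"), c("N", "S"))
  expect_equal(diag(unclass(cm)), c(N = 1, M = 0, MD = 0, S = 1, ES = 0))
  cm2 <- confusion(c("N", "S"), c("S", "N"))
  expect_equal(cm2["N", "S"], 1L, ignore_attr = TRUE)
  expect_equal(cm2["S", "N"], 1L, ignore_attr = TRUE)
  expect_equal(sum(cm2), 2L)
  set.seed(1)
  t <- sample(severity_levels(), 50, replace = TRUE)
  p <- sample(severity_levels(), 50, replace = TRUE)
  expect_equal(sum(confusion(t, p)), 50L)
  expect_error(confusion(c("N", "xx"), c("N", "N")), "unknown")
  expect_error(confusion(c("N"), c("N", "M")), "equal length")
})

test_that("perfect predictions give unit metrics and zero MSE", {
  t <- rep(severity_levels(), 4)
  m <- classification_metrics(confusion(t, t))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_f, 1)
  expect_equal(m$mse, 0)
})

test_that("metrics match hand arithmetic on a two-class block", {
  truth <- rep(c("N", "M"), c(10, 10))
  pred <- c(rep("N", 8), "M", "M", "N", rep("M", 9))
  m <- suppressWarnings(classification_metrics(confusion(truth, pred)))
  expect_equal(m$accuracy, 17 / 20)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == "N"], 8 / 9)
  expect_equal(pc$recall[pc$class == "N"], 8 / 10)
  expect_equal(pc$f_score[pc$class == "N"],
               2 * (8 / 9) * (8 / 10) / (8 / 9 + 8 / 10))
  # MSE: three mistakes, each one severity step apart
  expect_equal(m$mse, 3 / 20)
})

test_that("absent predicted classes yield zero precision with a warning", {
  truth <- c("N", "N", "M")
  pred <- c("N", "N", "N")
  w <- capture_warnings(m <- classification_metrics(confusion(truth, pred)))
  expect_true(any(grepl("precision", w)))
  expect_equal(m$per_class$precision[m$per_class$class == "M"], 0)
})

test_that("micro accuracy equals the matching fraction (oracle)", {
  set.seed(2)
  for (rep in 1:5) {
    t <- sample(severity_levels(), 30, replace = TRUE)
    p <- sample(severity_levels(), 30, replace = TRUE)
    m <- suppressWarnings(classification_metrics(confusion(t, p)))
    expect_equal(m$accuracy, mean(t == p))
    expect_equal(m$mse,
                 mean((match(t, severity_levels()) -
                         match(p, severity_levels()))^2))
  }
})

test_that("macro F is invariant to relabeling permutations", {
  set.seed(3)
  t <- sample(severity_levels(), 60, replace = TRUE)
  p <- sample(severity_levels(), 60, replace = TRUE)
  m1 <- suppressWarnings(classification_metrics(confusion(t, p)))
  perm <- c(N = "ES", M = "S", MD = "MD", S = "M", ES = "N")
  m2 <- suppressWarnings(classification_metrics(confusion(perm[t], perm[p])))
  expect_equal(m1$macro_f, m2$macro_f)
  expect_equal(m1$macro_precision, m2$macro_precision)
})

test_that("compare_models produces one bookkept row per cell", {
  gen <- generate_responses(250, mixture = c(.5, .2, .15, .1, .05),
                            noise = .05, seed = 31)
  tab <- labeled_table(gen, "anxiety")
  res <- compare_models(tab, list(plain = model_spec_plain()), rth = 0.5,
                        prioritization = TRUE, seeds = 1)
  expect_equal(nrow(res), 1L)
  res2 <- compare_models(
    tab, list(balanced = model_spec_balanced(), plain = model_spec_plain()),
    rth = 0.5, seeds = 1:2)
  expect_equal(nrow(res2), 2 * 2 * 2)  # models x conditions x seeds
  expect_true(all(!res2$failed))
  expect_true(all(res2$n_queries[res2$prioritized] <= 14))
})

test_that("a failing model spec is recorded, not fatal", {
  gen <- generate_responses(120, noise = 0, seed = 37)
  tab <- labeled_table(gen, "stress")
  broken <- function(train, seed, attributes) stop("boom")
  res <- compare_models(tab, list(bad = broken, plain = model_spec_plain()),
                        rth = 1.0, prioritization = FALSE, seeds = 1)
  expect_true(res$failed[res$model == "bad"])
  expect_false(res$failed[res$model == "plain"])
})
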