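test_that("entropy matches closed forms", {
  expect_equal(entropy_bits(c(5, 0, 0, 0, 0)), 0)
  expect_equal(entropy_bits(c(1, 1)), 1)
  expect_equal(entropy_bits(c(2, 1, 1)), 1.5)
  expect_error(entropy_bits(c(0, 0)), "all-zero")
  expect_error(entropy_bits(c(-1, 2)), "non-negative")
})

test_that("information gain hits its structural extremes", {
  d <- data.frame(Q1 = c(0L, 0L, 1L, 1L), Q2 = c(2L, 2L, 2L, 2L),
                  Class = c("N", "N", "S", "S"))
  # attribute identical to the label: gain equals parent entropy
  expect_equal(information_gain(d, "Q1"), entropy_bits(c(2, 2)))
  # constant attribute: no information
  expect_equal(information_gain(d, "Q2"), 0)
  # pure labels: zero gain, not an error
  d$Class <- "N"
  expect_equal(information_gain(d, "Q1"), 0)
})

test_that("entropy and gain agree with a brute-force oracle on small tables", {
  set.seed(11)
  for (case in 1:80) {
    d <- random_small_table()
    expect_equal(entropy_bits(table(d$Class)), oracle_entropy(d$Class),
                 tolerance = 1e-12)
    for (q in setdiff(names(d), "Class"))
      expect_equal(information_gain(d, q), oracle_gain(d$Class, d[[q]]),
                   tolerance = 1e-12)
  }
})

test_that("grow_tree learns a one-query rule with a depth-1 split", {
  d <- depth1_data()
  tree <- grow_tree(d)
  expect_equal(tree$root$attribute, "Q2")
  expect_equal(as.character(predict(tree, d)), d$Class)
})

test_that("single-class data yields a single leaf", {
  d <- depth1_data()
  d$Class <- "MD"
  tree <- grow_tree(d)
  expect_equal(tree$root$type, "leaf")
  expect_equal(tree$root$label, "MD")
})

test_that("tied gains break toward the lowest-indexed query", {
  d <- data.frame(Q1 = c(0L, 0L, 3L, 3L), Q2 = c(0L, 0L, 3L, 3L),
                  Class = c("N", "N", "S", "S"))
  expect_equal(grow_tree(d)$root$attribute, "Q1")
})

test_that("prediction falls back to node majority on unseen values", {
  d <- depth1_data()
  d <- d[d$Q2 != 3, ]  # withhold value 3 at the root
  tree <- grow_tree(d)
  maj <- names(which.max(table(d$Class)))
  row <- d[1, ]
  row$Q2 <- 3L
  expect_equal(as.character(predict(tree, row)), maj)
  expect_error(predict(tree, row[, "Q4", drop = FALSE]), "lacks")
})

test_that("oversample tops minority classes up to the target ratio", {
  d <- data.frame(Q1 = 0L, Class = rep(c("N", "S"), c(100, 10)))
  out <- oversample(d, 0.5, seed = 9)
  expect_equal(as.vector(table(out$Class)[c("N", "S")]), c(100L, 50L))
  # balanced data at rate 1 is untouched
  bal <- data.frame(Q1 = 0L, Class = rep(c("N", "S"), each = 20))
  expect_equal(oversample(bal, 1, seed = 1), bal)
  # determinism under a fixed seed
  expect_equal(oversample(d, 0.7, seed = 4), oversample(d, 0.7, seed = 4))
  expect_warning(oversample(data.frame(Q1 = 0L, Class = "N"), 0.5), "single")
})

test_that("oversample never deletes rows nor touches the majority class", {
  set.seed(5)
  for (rep in 1:10) {
    cnts <- sample(3:40, 3)
    d <- data.frame(Q1 = sample(0:3, sum(cnts), replace = TRUE),
                    Class = rep(c("N", "MD", "ES"), cnts))
    rate <- sample(seq(0.1, 1, 0.1), 1)
    out <- oversample(d, rate, seed = rep)
    tab_in <- table(d$Class)
    tab_out <- table(out$Class)
    expect_equal(as.data.frame(out[seq_len(nrow(d)), ]), d) # originals intact
    expect_equal(tab_out[[names(which.max(tab_in))]], max(tab_in))
    expect_true(all(tab_out / max(tab_out) >= rate - 1e-9))
    expect_true(all(tab_out >= tab_in))
  }
})

test_that("train_balanced escalates the rate and stops on the first drop", {
  gen <- generate_responses(400, mixture = c(.5, .2, .15, .1, .05),
                            noise = .05, seed = 21)
  tab <- labeled_table(gen, "stress")
  fit <- train_balanced(tab, seed = 2)
  tr <- fit$trace
  expect_equal(tr$rate, seq(0.1, by = 0.1, length.out = nrow(tr)))
  expect_equal(fit$best_accuracy, max(tr$accuracy))
  if (nrow(tr) < 10L) {  # stopped early: last round fell below the best
    expect_lt(tr$accuracy[nrow(tr)], max(tr$accuracy[-nrow(tr)]))
  }
  # rerun is identical under the same seed
  fit2 <- train_balanced(tab, seed = 2)
  expect_equal(fit2$trace, fit$trace)
})

test_that("validation rows are split off before any oversampling", {
  gen <- generate_responses(300, noise = 0, seed = 8)
  tab <- labeled_table(gen, "anxiety")
  fit <- train_balanced(tab, seed = 5)
  expect_length(intersect(fit$valid_idx,
                          setdiff(seq_len(nrow(tab)), fit$valid_idx)), 0L)
  expect_lte(abs(length(fit$valid_idx) - 0.2 * nrow(tab)), 5)
})

test_that("a one-round loop equals a plain tree on once-oversampled data", {
  gen <- generate_responses(300, mixture = c(.6, .1, .1, .1, .1),
                            noise = 0, seed = 13)
  tab <- labeled_table(gen, "depression")
  fit <- train_balanced(tab, seed = 4, rate_step = 1)
  expect_equal(nrow(fit$trace), 1L)
  split <- dassxdt:::stratified_split(as.character(tab$Class), 0.2, 4)
  once <- oversample(tab[split$train, ], 1, seed = 4L * 1000L + 1L)
  ref <- grow_tree(once)
  va <- tab[split$valid, ]
  expect_equal(as.character(predict(fit, va)),
               as.character(predict(ref, va)))
})

test_that("training refuses degenerate class structure", {
  d <- depth1_data()
  d$Class <- "N"
  expect_error(train_balanced(d, seed = 1), "2 classes")
  d2 <- depth1_data(n = 30)
  d2$Class[1] <- "ES"  # singleton class cannot be stratified
  d2$Class[-1] <- "N"
  expect_error(train_balanced(d2, seed = 1), "fewer than 2")
})

test_that("models survive a JSON round trip", {
  gen <- generate_responses(200, noise = 0, seed = 3)
  tab <- labeled_table(gen, "anxiety")
  fit <- train_balanced(tab, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(as.character(predict(back, tab)),
               as.character(predict(fit, tab)))
  expect_equal(back$trace$accuracy, fit$trace$accuracy)
  expect_equal(back$best_round, fit$best_round)
})
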