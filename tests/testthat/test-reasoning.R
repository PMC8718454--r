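test_that("permuted importance ranks a planted label-determining query first", {
  d <- depth1_data(n = 60)
  tree <- grow_tree(d)
  imp <- permuted_importance(tree, d, repeats = 10, seed = 1)
  expect_equal(imp$query[imp$rank == 1], "Q2")
  expect_gt(imp$importance[imp$rank == 1], 0)
  expect_setequal(imp$rank, seq_len(nrow(imp)))
})

test_that("constant columns get importance exactly zero", {
  d <- depth1_data(n = 40)
  d$Q4 <- 2L
  tree <- grow_tree(d)
  imp <- permuted_importance(tree, d, repeats = 5, seed = 2)
  expect_identical(imp$importance[imp$query == "Q4"], 0)
  expect_error(permuted_importance(tree, d[1, ], seed = 1), "2 rows")
})

test_that("importance ranking of the top feature is stable across seeds", {
  d <- depth1_data(n = 80)
  tree <- grow_tree(d)
  top <- vapply(c(101, 202), function(s) {
    imp <- permuted_importance(tree, d, repeats = 50, seed = s)
    imp$query[imp$rank == 1]
  }, character(1))
  expect_equal(top[1], top[2])
})

test_that("pertinent positives isolate the deciding query of a depth-1 tree", {
  tree <- depth1_model()
  inst <- c(Q2 = 3, Q4 = 1, Q7 = 2)  # predicted S because Q2 >= 2
  pp <- pertinent_positive(tree, inst)
  expect_equal(pp$pp, "Q2")
  expect_equal(pp$label, "S")
  expect_false(pp$non_minimal)
})

test_that("an instance at baseline has an empty pertinent-positive set", {
  tree <- depth1_model()
  inst <- c(Q2 = 0, Q4 = 0, Q7 = 0)
  pp <- pertinent_positive(tree, inst)
  expect_length(pp$pp, 0L)
})

test_that("returned PP sets are leave-one-out minimal", {
  gen <- generate_responses(300, noise = 0, seed = 17)
  tab <- labeled_table(gen, "anxiety")
  tree <- grow_tree(tab)
  attrs <- tree$attributes
  base <- stats::setNames(rep(0, length(attrs)), attrs)
  for (i in c(1, 5, 9)) {
    inst <- stats::setNames(as.numeric(tab[i, attrs]), attrs)
    pp <- pertinent_positive(tree, inst)
    orig <- as.character(predict(tree, as.data.frame(as.list(inst))))
    masked <- function(keep) {
      v <- base; v[keep] <- inst[keep]
      as.data.frame(as.list(v))
    }
    expect_equal(as.character(predict(tree, masked(pp$pp))), orig)
    for (q in pp$pp)
      expect_false(as.character(predict(tree,
                                        masked(setdiff(pp$pp, q)))) == orig)
  }
})

test_that("pertinent negatives flip a depth-1 tree at the split", {
  tree <- depth1_model()
  pn <- pertinent_negative(tree, c(Q2 = 3, Q4 = 1, Q7 = 2))
  expect_true(pn$found)
  expect_equal(pn$pn, "Q2")
  expect_lte(pn$values[["Q2"]], 1)  # any value on the N branch
  expect_equal(pn$flipped_to, "N")
})

test_that("pertinent negatives report not-found honestly", {
  d <- depth1_data()
  d$Class <- "N"
  const <- grow_tree(d)
  pn <- pertinent_negative(const, c(Q2 = 3, Q4 = 1, Q7 = 2))
  expect_false(pn$found)
  pn0 <- pertinent_negative(depth1_model(), c(Q2 = 3, Q4 = 1, Q7 = 2),
                            budget = 0)
  expect_false(pn0$found)
})

test_that("applying a PN's values always reproduces the reported flip", {
  gen <- generate_responses(200, noise = 0, seed = 23)
  tab <- labeled_table(gen, "stress")
  tree <- grow_tree(tab)
  attrs <- tree$attributes
  for (i in c(2, 7, 11, 20)) {
    inst <- stats::setNames(as.numeric(tab[i, attrs]), attrs)
    pn <- pertinent_negative(tree, inst, budget = 2)
    if (pn$found) {
      mod <- inst
      mod[pn$pn] <- pn$values
      expect_equal(as.character(predict(tree, as.data.frame(as.list(mod)))),
                   pn$flipped_to)
    }
  }
})

test_that("counterfactual of an already-target instance is the identity", {
  tree <- depth1_model()
  d <- depth1_data()
  cf <- counterfactual(tree, c(Q2 = 3, Q4 = 0, Q7 = 0), target = "S",
                       reference = d)
  expect_true(cf$converged)
  expect_true(all(cf$deltas == 0))
  expect_equal(cf$loss, 0)
})

test_that("counterfactuals cross a depth-1 split with one sparse delta", {
  tree <- depth1_model()
  d <- depth1_data()
  cf <- counterfactual(tree, c(Q2 = 3, Q4 = 1, Q7 = 2), target = "N",
                       reference = d)
  expect_true(cf$converged)
  nz <- cf$deltas[abs(cf$deltas) > 1e-9]
  expect_length(nz, 1L)
  expect_equal(names(nz), "Q2")
  expect_lt(nz[[1]], 0)  # reduce the symptom
  # re-prediction contract
  expect_equal(as.character(predict(tree, as.data.frame(as.list(cf$sxy)))),
               "N")
  # never worse than the best exhaustive single-query integer change
  best <- Inf
  for (v in 0:3) {
    s <- c(Q2 = 3, Q4 = 1, Q7 = 2); s["Q2"] <- v
    if (as.character(predict(tree, as.data.frame(as.list(s)))) == "N") {
      delta <- abs(v - 3)
      best <- min(best, 0.1 * delta + delta^2)  # L_pred = 0 at a pure leaf
    }
  }
  expect_lte(cf$loss, best + 1e-9)
})

test_that("accepted counterfactual iterations never increase the loss", {
  gen <- generate_responses(200, noise = 0, seed = 29)
  tab <- labeled_table(gen, "depression")
  tree <- grow_tree(tab)
  attrs <- tree$attributes
  row <- tab[which(tab$Class == "S")[1], ]
  cf <- counterfactual(tree, row, target = "MD", reference = tab)
  expect_true(all(diff(cf$loss_trace) <= 1e-12))
})

test_that("raising the sparsity weight never adds nonzero deltas", {
  tree <- depth1_model()
  d <- depth1_data()
  inst <- c(Q2 = 2, Q4 = 3, Q7 = 1)
  nnz <- vapply(c(0.01, 0.1, 0.5, 2), function(b) {
    cf <- counterfactual(tree, inst, target = "N", reference = d,
                         beta_reg = b)
    sum(abs(cf$deltas) > 1e-9)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("feedback prose cites the explaining queries", {
  fb <- render_feedback("V5", "anxiety", "MD", pp = c("Q7", "Q20"))
  expect_match(fb$text, "shakiness")
  expect_match(fb$text, "scared")
  expect_match(fb$text, "Moderate")
  expect_match(fb$text, "V5")
  # empty PN -> no escalation clause
  expect_no_match(fb$text, "shift")
  # counterfactual advice line with the stress wording for Q1
  tree <- depth1_model()
  d <- depth1_data()
  cf <- counterfactual(tree, c(Q2 = 2, Q4 = 0, Q7 = 0), target = "N",
                       reference = d)
  names(cf$deltas) <- sub("^Q2$", "Q1", names(cf$deltas))
  fb2 <- render_feedback("V5", "stress", "M", pp = "Q1", cf = cf)
  expect_match(fb2$text, "reduce: getting upset by trivial things")
  expect_error(render_feedback("V5", "anxiety", "MD", pp = "Q99"), "Q99")
})

test_that("a found PN adds the shift clause with the flipped level", {
  tree <- depth1_model()
  pn <- pertinent_negative(tree, c(Q2 = 3, Q4 = 1, Q7 = 2))
  fb <- render_feedback("r1", "anxiety", "S", pp = "Q2", pn = pn)
  expect_match(fb$text, "shift")
  expect_match(fb$text, "Normal")
})
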