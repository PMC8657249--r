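test_that("random search selects the best candidate and is deterministic", {
  ch <- counted_cohort(180, 120, seed = 4)
  enc <- encode_features(ch)
  cfg <- tuning_config(m = 4, k = 3, repeats = 1, seed = 9)
  t1 <- random_search_tune(get_learner("cart"), enc$x, ch$labels, cfg)
  t2 <- random_search_tune(get_learner("cart"), enc$x, ch$labels, cfg)
  # determinism: identical chosen params and OOF vector
  expect_identical(t1$chosen_params, t2$chosen_params)
  expect_identical(t1$oof_probs, t2$oof_probs)
  # selection optimality against the recorded candidate table
  expect_equal(t1$cv_auc, max(t1$candidate_table$score, na.rm = TRUE))
  # m = 1: the single candidate is chosen regardless of score
  t3 <- random_search_tune(get_learner("cart"), enc$x, ch$labels,
                           tuning_config(m = 1, k = 3, repeats = 1, seed = 9))
  expect_equal(nrow(t3$candidate_table), 1L)
  expect_false(is.null(t3$chosen_params))
})

test_that("perfectly separable data yields near-perfect logistic CV AUC", {
  ch <- separable_cohort(n = 200, gap = 8)
  enc <- encode_features(ch)
  t <- random_search_tune(get_learner("lgr"), enc$x, ch$labels,
                          tuning_config(m = 1, k = 5, repeats = 1, seed = 2))
  expect_gte(t$cv_auc, 0.99)
})

test_that("out-of-fold predictions are honest", {
  # permuting the training labels destroys the OOF signal
  ch <- separable_cohort(n = 300, gap = 4, seed = 6)
  enc <- encode_features(ch)
  cfg <- tuning_config(m = 1, k = 5, repeats = 1, seed = 3)
  t_real <- random_search_tune(get_learner("lgr"), enc$x, ch$labels, cfg)
  expect_gte(roc_auc(t_real$oof_probs, ch$labels)$auc, 0.95)
  y_perm <- withr::with_seed(11, sample(ch$labels))
  t_perm <- random_search_tune(get_learner("lgr"), enc$x, y_perm, cfg)
  expect_lt(abs(roc_auc(t_perm$oof_probs, y_perm)$auc - 0.5), 0.1)
})

test_that("fold assignments are stratified partitions", {
  y <- rep(c(0L, 1L), c(200, 50))
  folds <- make_cv_folds(y, k = 5, repeats = 2, seed = 7)
  for (r in 1:2) {
    f <- folds$assignments[[r]]
    expect_setequal(unique(f), 1:5)
    for (i in 1:5) {
      expect_equal(sum(f == i & y == 1L), 10L) # minority evenly spread
    }
  }
  expect_error(make_cv_folds(rep(c(0L, 1L), c(50, 3)), k = 5), "minority")
})

test_that("collect_oof_predictions aligns columns and checks folds", {
  f <- list(assignments = list(rep(1:2, 5)))
  t1 <- fake_tuned("a", runif(10), folds = f)
  t2 <- fake_tuned("b", runif(10), folds = f)
  m <- collect_oof_predictions(list(a = t1, b = t2))
  expect_equal(dim(m), c(10L, 2L))
  expect_identical(colnames(m), c("a", "b"))
  # a learner with missing cells propagates them
  t3 <- fake_tuned("c", c(NA, runif(9)), folds = f)
  expect_true(anyNA(collect_oof_predictions(list(a = t1, c = t3))[, "c"]))
  # misaligned fold assignments error
  t4 <- fake_tuned("d", runif(10), folds = list(assignments = list(rep(2:1, 5))))
  expect_error(collect_oof_predictions(list(a = t1, d = t4)), "misaligned")
})

test_that("learners with missing OOF cells are ejected before correlation", {
  f <- list(assignments = list(rep(1:2, 5)))
  good <- lapply(paste0("g", 1:9), function(nm) fake_tuned(nm, runif(10), folds = f))
  names(good) <- paste0("g", 1:9)
  bad <- fake_tuned("svm_like", replace(runif(10), c(2, 5, 9), NA), folds = f)
  ej <- eject_invalid_learners(c(good, list(svm_like = bad)))
  # 10 learners, 1 invalid -> 9 survive; log records the 3 missing cells
  expect_length(ej$tuned, 9L)
  expect_identical(ej$log$name, "svm_like")
  expect_equal(ej$log$n_missing, 3L)
  # no missing values anywhere -> identity
  ej2 <- eject_invalid_learners(good)
  expect_identical(names(ej2$tuned), names(good))
  expect_equal(nrow(ej2$log), 0L)
  # all invalid -> fatal
  expect_error(eject_invalid_learners(list(svm_like = bad)), "all learners")
})

test_that("every registered learner fits, predicts in [0,1], and is usable", {
  ch <- separable_cohort(n = 240, gap = 2, seed = 9)
  enc <- encode_features(ch)
  cfg <- tuning_config(m = 1, k = 3, repeats = 1, seed = 5)
  for (nm in registered_learners()) {
    t <- random_search_tune(get_learner(nm), enc$x, ch$labels, cfg)
    expect_false(t$failed, info = nm)
    p <- t$spec$predict_prob(t$fitted, enc$x)
    expect_true(all(p >= 0 & p <= 1), info = nm)
    # an informative single feature should separate at least weakly
    expect_gt(roc_auc(p, ch$labels)$auc, 0.6)
  }
})

test_that("the Gini tree recovers a planted threshold split", {
  withr::local_seed(21)
  x <- cbind(signal = runif(400), noise = runif(400))
  y <- as.integer(x[, "signal"] > 0.62)
  tree <- get_learner("cart")$fit(x, y, list(maxdepth = 2L, minbucket = 5L))
  root <- tree$nodes[[1L]]
  expect_identical(colnames(x)[root$feat], "signal")
  expect_lt(abs(root$thr - 0.62), 0.03)
  expect_gt(tree$importance[1L], tree$importance[2L])
})
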