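test_that("per-learner importance separates planted from null features", {
  sch <- feature_schema(c("signal", "null"), rep("continuous", 2), "y")
  withr::local_seed(6)
  x1 <- rnorm(5000); x0 <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(1.2 * x1 - 1))
  ch <- cohort_table(data.frame(signal = x1, null = x0, y = y), sch)
  tb <- tune_bank(default_learner_bank("lgr"), ch,
                  tuning_config(m = 1, k = 3, repeats = 1, seed = 1))
  imp <- per_learner_importance(tb$tuned$lgr, tb$x, tb$y, tb$encoder)
  expect_gt(imp[["signal"]], imp[["null"]])
  expect_true(all(imp >= 0))
})

test_that("one-hot columns fold back into a single parent entry", {
  sch <- feature_schema(c("site", "age"), c("categorical", "continuous"), "y")
  withr::local_seed(7)
  df <- data.frame(site = sample(c("a", "b", "c", "d"), 400, TRUE),
                   age = rnorm(400))
  df$y <- rbinom(400, 1, plogis(df$age))
  ch <- cohort_table(df, sch)
  tb <- tune_bank(default_learner_bank("lgr"), ch,
                  tuning_config(m = 1, k = 3, repeats = 1, seed = 1))
  imp <- per_learner_importance(tb$tuned$lgr, tb$x, tb$y, tb$encoder)
  # 4-level categorical encoded as 3 columns -> one entry for the parent
  expect_identical(names(imp), c("site", "age"))
})

test_that("aggregate_ranks follows the weighted-sum rank rule", {
  # single learner: final order is its own importance order
  m1 <- matrix(c(3, 1, 2), ncol = 1, dimnames = list(c("A", "B", "C"), "l1"))
  a1 <- aggregate_ranks(m1, c(l1 = 2))
  expect_identical(a1$order, c("A", "C", "B"))

  # two equally weighted learners with opposed rankings: scores tie at the
  # mean rank 1.5, broken alphabetically (oracle: hand computation)
  m2 <- matrix(c(5, 1, 1, 5), ncol = 2,
               dimnames = list(c("A", "B"), c("l1", "l2")))
  a2 <- aggregate_ranks(m2, c(l1 = 0.5, l2 = -0.5))
  expect_equal(unname(a2$score), c(1.5, 1.5))
  expect_identical(a2$order, c("A", "B"))
  expect_setequal(a2$ties, c("A", "B"))

  # zero-weight learner has no effect on the final order
  m3 <- cbind(m2, l3 = c(9, 1))
  a3 <- aggregate_ranks(m3, c(l1 = 0.5, l2 = -0.5, l3 = 0))
  expect_identical(a3$order, a2$order)
  expect_equal(unname(a3$share), c(0.5, 0.5, 0))

  # rank columns are permutations and scores live in [1, p]
  withr::local_seed(8)
  m4 <- matrix(runif(14 * 3), 14, 3,
               dimnames = list(paste0("f", 1:14), paste0("l", 1:3)))
  a4 <- aggregate_ranks(m4, c(l1 = 1, l2 = -2, l3 = 0.5))
  for (j in 1:3) expect_setequal(a4$ranks[, j], 1:14)
  expect_true(all(a4$score >= 1 & a4$score <= 14))
})

test_that("knee_point equals the exhaustive two-line search", {
  # exact two-line sequence with the regime change after position 6 (the
  # second line does not pass through the sixth point, so the zero-residual
  # split is unique)
  y <- c(seq(1, 6, by = 1), seq(20, 48, by = 4))
  expect_equal(as.integer(knee_point(y)), 6L)

  # perfectly linear: smallest candidate split, flagged as no clear knee
  k <- knee_point(seq_len(14))
  expect_equal(as.integer(k), 2L)
  expect_true(attr(k, "no_clear_knee"))

  # random sequences, p = 14: match brute force over 100 seeds
  for (s in 1:100) {
    scores <- withr::with_seed(s, sort(runif(14, 1, 14)))
    expect_equal(as.integer(knee_point(scores)), brute_force_knee(scores),
                 info = paste("seed", s))
  }

  expect_warning(k4 <- knee_point(c(1, 2, 3)), "fewer than 4")
  expect_equal(as.integer(k4), 3L)
  expect_error(knee_point(c(3, 1, 2, 5)), "ascending")
})

test_that("direction labels recover planted signs", {
  # planted positive continuous and negative binary effects at n = 10000
  sch <- feature_schema(c("pos_cont", "neg_bin", "multi"),
                        c("continuous", "categorical", "categorical"), "y")
  gens <- list(
    pos_cont = list(kind = "continuous", mean = 0, sd = 1),
    neg_bin = list(kind = "categorical", levels = c("n", "y"), probs = c(0.6, 0.4)),
    multi = list(kind = "categorical", levels = c("a", "b", "c", "d"),
                 probs = rep(0.25, 4))
  )
  cfg <- synthetic_config(n = 10000L, prevalence = 0.3, schema = sch,
                          linear_coefs = c(pos_cont = 0.8, neg_bin = -0.7),
                          nonlinear_terms = list(), interaction_terms = list(),
                          generators = gens, seed = 31)
  g <- generate_cohort(cfg)
  tb <- tune_bank(default_learner_bank("lgr"), g$cohort,
                  tuning_config(m = 1, k = 3, repeats = 1, seed = 1))
  dir <- assign_directions(tb$tuned$lgr, tb$encoder)
  expect_identical(unname(dir["pos_cont"]), "positive")
  expect_identical(unname(dir["neg_bin"]), "negative")
  expect_identical(unname(dir["multi"]), "categorical/unsigned")
  # no logistic learner available -> unsigned with a warning
  expect_warning(d0 <- assign_directions(NULL, tb$encoder), "unsigned")
  expect_true(all(d0 == "categorical/unsigned"))
})

test_that("build_importance_table assembles a coherent report", {
  ch <- separable_cohort(n = 400, gap = 2, seed = 15)
  tb <- tune_bank(default_learner_bank(c("lgr", "cart", "nb")), ch,
                  tuning_config(m = 1, k = 3, repeats = 1, seed = 3))
  ens <- build_ensemble(tb$tuned, tb$y, tb$encoder)
  # p = 2 < 4: the knee warns and falls back to p
  expect_warning(
    imp <- build_importance_table(ens, tb$x, tb$y, lgr_tuned = tb$tuned$lgr),
    "fewer than 4")
  expect_s3_class(imp, "importance_table")
  expect_equal(nrow(imp$table), 2L)
  expect_identical(imp$table$feature[1L], "age") # the planted signal leads
  expect_equal(sum(imp$meta_weight_share), 1)
  expect_true(imp$knee_index >= 1 && imp$knee_index <= 2)
})
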