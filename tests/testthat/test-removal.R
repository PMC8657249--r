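test_that("prediction correlation matrix is exact on constructed columns", {
  withr::local_seed(1)
  a <- runif(50, 0.1, 0.9)
  # identical columns correlate at 1; the reflection about 0.5 at -1
  m <- cbind(a = a, b = a, c = 1 - a)
  cm <- prediction_correlation_matrix(m)
  expect_equal(cm$values["a", "b"], 1)
  expect_equal(cm$values["a", "c"], -1)
  expect_identical(cm$values, t(cm$values))
  # i.i.d. noise columns at n = 5000: off-diagonals within +/- 0.05 of 0
  z <- matrix(runif(15000), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  cz <- prediction_correlation_matrix(z)$values
  expect_lt(max(abs(cz[upper.tri(cz)])), 0.05)
  # constant column names the learner
  expect_error(prediction_correlation_matrix(cbind(a = a, k = rep(0.5, 50))),
               "k")
  expect_error(prediction_correlation_matrix(cbind(a = a, b = replace(a, 1, NA))),
               "missing")
})

test_that("find_max_pair picks the upper-triangular argmax with ties logged", {
  v <- diag(3)
  v[1, 2] <- v[2, 1] <- 0.85
  v[1, 3] <- v[3, 1] <- 0.3
  v[2, 3] <- v[3, 2] <- 0.1
  mp <- find_max_pair(corr_matrix(v, c("A", "B", "C")))
  expect_identical(mp$pair, c("A", "B"))
  expect_equal(mp$value, 0.85)
  expect_false(mp$tie)
  # all equal -> lexicographically first pair, tie flagged
  ve <- matrix(0.4, 3, 3); diag(ve) <- 1
  mpe <- find_max_pair(corr_matrix(ve, c("A", "B", "C")))
  expect_identical(mpe$pair, c("A", "B"))
  expect_true(mpe$tie)
  # l = 2 degenerate
  v2 <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  expect_identical(find_max_pair(corr_matrix(v2, c("A", "B")))$pair, c("A", "B"))
})

test_that("removal_iteration removes the higher-average member", {
  # (A,B) at 0.85; avg_A = (0.85 + 0.35)/2 = 0.60 > avg_B = (0.85 - 0.05)/2
  v <- diag(3)
  v[1, 2] <- v[2, 1] <- 0.85
  v[1, 3] <- v[3, 1] <- 0.35
  v[2, 3] <- v[3, 2] <- -0.05
  step <- removal_iteration(corr_matrix(v, c("A", "B", "C")), removal_config())
  expect_identical(step$removed, "A")
  expect_equal(step$record$avg_a, 0.60)
  expect_equal(step$record$avg_b, 0.40)

  # below threshold -> nothing removed
  v2 <- diag(2); v2[1, 2] <- v2[2, 1] <- 0.70
  expect_null(removal_iteration(corr_matrix(v2, c("A", "B")),
                                removal_config())$removed)

  # exact average tie -> lower CV AUC removed
  v3 <- diag(2); v3[1, 2] <- v3[2, 1] <- 0.9
  step3 <- removal_iteration(corr_matrix(v3, c("A", "B")), removal_config(),
                             cv_aucs = c(A = 0.70, B = 0.72))
  expect_identical(step3$removed, "A")
  expect_true(step3$record$tie_avg)
})

test_that("run_removal terminates with survivors below the threshold", {
  # identity structure: nothing above threshold, all survive
  idm <- corr_matrix(diag(4), paste0("L", 1:4))
  tr <- run_removal(idm, removal_config())
  expect_equal(nrow(tr$iterations), 0L)
  expect_length(tr$survivors, 4L)

  # all pairwise 0.9: exactly one survivor after l - 1 iterations
  v <- matrix(0.9, 5, 5); diag(v) <- 1
  colnames(v) <- rownames(v) <- paste0("L", 1:5)
  aucs <- setNames(seq(0.6, 0.8, length.out = 5), paste0("L", 1:5))
  tr2 <- run_removal(corr_matrix(v), removal_config(), aucs)
  expect_length(tr2$survivors, 1L)
  expect_equal(nrow(tr2$iterations), 4L)
  expect_true(all(tr2$iterations$max_corr > 0.75))
})

test_that("run_removal matches the brute-force reference on random matrices", {
  aucs5 <- setNames(seq(0.55, 0.8, length.out = 5), paste0("L", 1:5))
  for (s in 1:150) {
    l <- if (s %% 2) 4L else 5L
    v <- random_grid_corr(l, seed = 1000 + s)
    got <- run_removal(corr_matrix(v), removal_config(), aucs5[1:l])
    ref <- brute_force_removal(v, 0.75, aucs5[1:l])
    expect_identical(sort(got$survivors), sort(ref$survivors),
                     info = paste("seed", s))
    # post-condition: survivor submatrix has no entry above the threshold
    sub <- v[got$survivors, got$survivors, drop = FALSE]
    diag(sub) <- 0
    expect_lte(max(sub), 0.75)
  }
})

test_that("raising the threshold never shrinks the survivor set", {
  for (s in 1:40) {
    v <- random_grid_corr(5L, seed = 2000 + s)
    aucs <- setNames(seq(0.55, 0.8, length.out = 5), paste0("L", 1:5))
    n_low <- length(run_removal(corr_matrix(v), removal_config(0.6), aucs)$survivors)
    n_high <- length(run_removal(corr_matrix(v), removal_config(0.85), aucs)$survivors)
    expect_gte(n_high, n_low)
  }
})

test_that("removal trace serializes to JSON", {
  v <- matrix(0.9, 3, 3); diag(v) <- 1
  colnames(v) <- rownames(v) <- c("A", "B", "C")
  tr <- run_removal(corr_matrix(v), removal_config(),
                    c(A = 0.6, B = 0.7, C = 0.8))
  path <- withr::local_tempfile(fileext = ".json")
  write_removal_trace(tr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$threshold, 0.75)
  expect_identical(back$survivors, tr$survivors)
})
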