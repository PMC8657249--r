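# Shared fixture builders. Everything is generated in code at test time; no
# stored data files.

# Minimal two-feature schema.
toy_schema <- function() {
  feature_schema(c("age", "grade"), c("continuous", "categorical"), "event")
}

# Cohort with a single strongly informative continuous feature.
separable_cohort <- function(n = 200, gap = 6, seed = 1) {
  withr::local_seed(seed)
  y <- rep(0:1, length.out = n)
  x <- rnorm(n) + gap * y
  cohort_table(data.frame(age = x, grade = sample(c("lo", "hi"), n, TRUE),
                          event = y),
               toy_schema())
}

# Cohort with given class counts and an uninformative feature.
counted_cohort <- function(n0, n1, seed = 1) {
  withr::local_seed(seed)
  y <- c(rep(0L, n0), rep(1L, n1))
  cohort_table(data.frame(age = rnorm(n0 + n1), grade = "lo", event = y),
               toy_schema())
}

# A fake tuned_learner carrying an arbitrary OOF vector (for ejection and
# removal plumbing tests).
fake_tuned <- function(name, oof, cv_auc = 0.7, folds = list(assignments = list(1L))) {
  structure(list(name = name, spec = get_learner("lgr"), chosen_params = list(),
                 cv_auc = cv_auc, candidate_table = data.frame(),
                 oof_probs = oof, fitted = NULL, folds = folds, failed = FALSE),
            class = "tuned_learner")
}

# Independent brute-force reference for the removal scheme, written as plain
# loops straight from the procedure's description (kept free of any package
# internals beyond the matrix itself).
brute_force_removal <- function(values, threshold, cv_aucs = NULL) {
  names <- colnames(values)
  remaining <- names
  removed <- character(0)
  repeat {
    if (length(remaining) < 2L) break
    v <- values[remaining, remaining, drop = FALSE]
    best <- -Inf; bi <- NA; bj <- NA
    for (i in seq_along(remaining)) {
      for (j in seq_along(remaining)) {
        if (j > i && v[i, j] > best + 1e-12) {
          best <- v[i, j]; bi <- i; bj <- j
        }
      }
    }
    if (best <= threshold) break
    a <- remaining[bi]; b <- remaining[bj]
    avg_a <- mean(v[a, setdiff(remaining, a)])
    avg_b <- mean(v[b, setdiff(remaining, b)])
    out <- if (abs(avg_a - avg_b) <= 1e-12) {
      if (cv_aucs[[a]] <= cv_aucs[[b]]) a else b
    } else if (avg_a > avg_b) a else b
    removed <- c(removed, out)
    remaining <- setdiff(remaining, out)
  }
  list(survivors = remaining, removed = removed)
}

# Random symmetric "correlation" matrix on a 0.05 grid (values need not be a
# realisable correlation structure; the algorithm only reads the entries).
random_grid_corr <- function(l, seed) {
  withr::local_seed(seed)
  v <- diag(l)
  for (i in seq_len(l - 1)) {
    for (j in (i + 1):l) {
      v[i, j] <- v[j, i] <- sample(seq(-0.95, 0.95, by = 0.05), 1)
    }
  }
  colnames(v) <- rownames(v) <- paste0("L", seq_len(l))
  v
}

# Independent exhaustive knee search (straight two-segment RSS scan).
brute_force_knee <- function(scores) {
  p <- length(scores)
  rss_line <- function(y) {
    t <- seq_along(y)
    f <- lm(y ~ t)
    sum(resid(f)^2)
  }
  best <- Inf; knee <- NA
  for (s in 2:(p - 2)) {
    r <- rss_line(scores[1:s]) + rss_line(scores[(s + 1):p])
    if (r < best - 1e-12) { best <- r; knee <- s }
  }
  knee
}
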