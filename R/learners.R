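# Base-learner registry and tuning. Each learner is a small record: a
# hyper-parameter space with sampling rules, a fit function on an encoded
# design matrix, a positive-class probability predictor, and (where the
# learner family defines one) a native per-column importance. The pruning /
# stacking / importance machinery downstream is agnostic to which learners
# are registered.
#
# The classical registry for this kind of registry-cohort work is R-package
# specific (rpart, randomForest, nnet, earth, kernlab ...). This package
# ships role-equivalents built on what a lean scientific stack provides:
#   lgr  - logistic regression (stats::glm.fit)
#   enet - elastic-net logistic regression (glmnet)
#   gam  - spline GAM, the smooth-nonlinear role a MARS model plays (mgcv)
#   lda  - linear discriminant analysis (MASS)
#   rda  - shrinkage quadratic discriminant (hand-rolled; captures
#          covariance/interaction structure linear learners miss)
#   knn  - k-nearest neighbours on standardised features (FNN)
#   nb   - Gaussian naive Bayes (hand-rolled)
#   cart - greedy Gini decision tree (hand-rolled, CART role)
#   bag  - bagged Gini trees with feature subsampling (random-forest role)

.registry <- new.env(parent = emptyenv())

#' Register a base learner
#'
#' @param name short identifier.
#' @param fit `function(x, y, params, ctx)` returning an opaque model; `x` is
#'   a numeric design matrix, `y` integer 0/1 labels, `ctx` optional encoding
#'   context (`col_kind`, `encoder`).
#' @param predict_prob `function(model, x)` returning positive-class
#'   probabilities in `[0, 1]`.
#' @param hyper_space named list of sampling rules, each one of
#'   `list(type = "uniform", min=, max=)`, `list(type = "loguniform", min=,
#'   max=)`, `list(type = "int", min=, max=)` or `list(type = "choice",
#'   values=)`.
#' @param importance optional `function(model, x)` returning a nonnegative
#'   native importance per design-matrix column; learners without one fall
#'   back to permutation importance.
#' @param label human-readable role description.
#' @param produces_probabilities flag; learners exposing only scores must
#'   map them through a sigmoid themselves and set this `FALSE` to be flagged.
#' @return the learner spec, invisibly.
#' @export
register_learner <- function(name, fit, predict_prob, hyper_space = list(),
                             importance = NULL, label = name,
                             produces_probabilities = TRUE) {
  spec <- structure(
    list(name = name, label = label, fit = fit, predict_prob = predict_prob,
         hyper_space = hyper_space, importance = importance,
         produces_probabilities = produces_probabilities),
    class = "learner_spec"
  )
  assign(name, spec, envir = .registry)
  invisible(spec)
}

#' Fetch a registered learner spec
#' @param name learner identifier.
#' @return a `learner_spec`.
#' @export
get_learner <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE)) {
    stop("unknown learner: ", name, "; registered: ",
         paste(ls(.registry), collapse = ", "), call. = FALSE)
  }
  get(name, envir = .registry, inherits = FALSE)
}

#' Names of all registered learners
#' @return character vector.
#' @export
registered_learners <- function() sort(ls(.registry))

#' A default bank of learner specs
#'
#' @param names learner identifiers; the default is the full nine-member
#'   registry. `fast = TRUE` restricts to the seven members that fit in
#'   seconds (drops the hand-rolled tree learners), the bank the package's
#'   larger simulations use.
#' @param fast use the seven-member fast bank?
#' @return named list of `learner_spec`s.
#' @export
default_learner_bank <- function(names = NULL, fast = FALSE) {
  if (is.null(names)) {
    names <- if (fast) {
      c("lgr", "lda", "gam", "rda", "nb", "cart", "knn")
    } else {
      c("lgr", "enet", "gam", "lda", "rda", "knn", "nb", "cart", "bag")
    }
  }
  stats::setNames(lapply(names, get_learner), names)
}

# ---- hyper-parameter sampling ------------------------------------------------

sample_params <- function(hyper_space) {
  out <- list()
  for (nm in names(hyper_space)) {
    rule <- hyper_space[[nm]]
    out[[nm]] <- switch(rule$type,
      uniform = stats::runif(1, rule$min, rule$max),
      loguniform = exp(stats::runif(1, log(rule$min), log(rule$max))),
      int = sample(seq.int(rule$min, rule$max), 1L),
      choice = rule$values[[sample.int(length(rule$values), 1L)]],
      stop("unknown sampling rule type: ", rule$type, call. = FALSE)
    )
  }
  out
}

# ---- built-in learners -------------------------------------------------------

fit_lgr <- function(x, y, params, ctx = NULL) {
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(xm, y, family = stats::binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(coefs = coefs), class = "sp_lgr")
}

predict_lgr <- function(model, x) {
  as.numeric(stats::plogis(cbind(1, x) %*% model$coefs))
}

importance_lgr <- function(model, x) {
  abs(model$coefs[-1L]) * apply(x, 2, stats::sd)
}

fit_enet <- function(x, y, params, ctx = NULL) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = params$alpha,
                        standardize = TRUE)
  structure(list(fit = fit, lambda = params$lambda), class = "sp_enet")
}

predict_enet <- function(model, x) {
  as.numeric(stats::predict(model$fit, newx = x, s = model$lambda,
                            type = "response"))
}

importance_enet <- function(model, x) {
  beta <- as.numeric(stats::coef(model$fit, s = model$lambda))[-1L]
  abs(beta) * apply(x, 2, stats::sd)
}

fit_gam <- function(x, y, params, ctx = NULL) {
  dd <- as.data.frame(x)
  names(dd) <- paste0("V", seq_len(ncol(x)))
  kinds <- if (!is.null(ctx$col_kind)) ctx$col_kind else rep("continuous", ncol(x))
  smooth_ok <- kinds == "continuous" &
    vapply(dd, function(v) length(unique(v)) >= 10L, logical(1))
  k <- params$k %||% 5
  terms <- ifelse(smooth_ok,
                  sprintf("s(%s, k = %d)", names(dd), as.integer(k)),
                  names(dd))
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  dd$y <- y
  fit <- if (nrow(dd) >= 3000) {
    mgcv::bam(form, family = stats::binomial(), data = dd,
              discrete = TRUE, gamma = params$gamma %||% 1)
  } else {
    mgcv::gam(form, family = stats::binomial(), data = dd,
              gamma = params$gamma %||% 1)
  }
  structure(list(fit = fit, ncol = ncol(x)), class = "sp_gam")
}

predict_gam <- function(model, x) {
  dd <- as.data.frame(x)
  names(dd) <- paste0("V", seq_len(ncol(x)))
  as.numeric(stats::predict(model$fit, newdata = dd, type = "response"))
}

fit_lda <- function(x, y, params, ctx = NULL) {
  keep <- apply(x, 2, stats::sd) > 0
  fit <- suppressWarnings(MASS::lda(x[, keep, drop = FALSE], grouping = factor(y)))
  structure(list(fit = fit, keep = keep), class = "sp_lda")
}

predict_lda <- function(model, x) {
  post <- stats::predict(model$fit, x[, model$keep, drop = FALSE])$posterior
  as.numeric(post[, "1"])
}

importance_lda <- function(model, x) {
  imp <- numeric(ncol(x))
  imp[model$keep] <- abs(model$fit$scaling[, 1L]) *
    apply(x[, model$keep, drop = FALSE], 2, stats::sd)
  imp
}

# Shrinkage quadratic discriminant: per-class covariances mixed toward the
# pooled covariance (lambda) and toward a spherical target (gamma), so it
# stays well-posed with one-hot columns where plain QDA is singular.
fit_rda <- function(x, y, params, ctx = NULL) {
  lambda <- params$lambda %||% 0.5
  gamma <- params$gamma %||% 0.1
  # standardise so the spherical shrinkage target is scale-free
  mu0 <- colMeans(x)
  sd0 <- apply(x, 2, stats::sd)
  sd0[sd0 == 0] <- 1
  x <- sweep(sweep(x, 2, mu0), 2, sd0, "/")
  classes <- c(0L, 1L)
  n <- nrow(x)
  pooled <- stats::cov(x)
  per <- lapply(classes, function(cls) {
    xi <- x[y == cls, , drop = FALSE]
    s <- if (nrow(xi) > 1) stats::cov(xi) else pooled
    s <- (1 - lambda) * s + lambda * pooled
    s <- (1 - gamma) * s + gamma * mean(diag(s)) * diag(ncol(x))
    ch <- tryCatch(chol(s), error = function(e) chol(s + 1e-6 * diag(ncol(x))))
    list(mean = colMeans(xi), chol = ch,
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(xi) / n))
  })
  structure(list(per = per, mu0 = mu0, sd0 = sd0), class = "sp_rda")
}

predict_rda <- function(model, x) {
  x <- sweep(sweep(x, 2, model$mu0), 2, model$sd0, "/")
  scores <- vapply(model$per, function(cl) {
    d <- sweep(x, 2, cl$mean)
    z <- backsolve(cl$chol, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$logprior
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  as.numeric(1 / (1 + exp(scores[, 1L] - scores[, 2L])))
}

fit_knn <- function(x, y, params, ctx = NULL) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  structure(list(train = sweep(sweep(x, 2, mu), 2, sdv, "/"),
                 y = y, mu = mu, sd = sdv,
                 k = max(1L, as.integer(params$k %||% 25L))),
            class = "sp_knn")
}

predict_knn <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  idx <- FNN::knnx.index(model$train, xs, k = model$k)
  votes <- matrix(model$y[idx], nrow = nrow(xs))
  rowMeans(votes)
}

fit_nb <- function(x, y, params, ctx = NULL) {
  # per-column relative smoothing: columns live on very different scales
  eps <- (params$smooth %||% 1e-6) * pmax(apply(x, 2, stats::var), 1e-12)
  per <- lapply(c(0L, 1L), function(cls) {
    xi <- x[y == cls, , drop = FALSE]
    list(mean = colMeans(xi),
         var = apply(xi, 2, stats::var) + eps,
         logprior = log(nrow(xi) / nrow(x)))
  })
  structure(list(per = per), class = "sp_nb")
}

predict_nb <- function(model, x) {
  ll <- vapply(model$per, function(cl) {
    d <- sweep(x, 2, cl$mean)
    rowSums(-0.5 * sweep(d^2, 2, cl$var, "/") -
              matrix(0.5 * log(2 * pi * cl$var), nrow(x), ncol(x), byrow = TRUE)) +
      cl$logprior
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  as.numeric(1 / (1 + exp(ll[, 1L] - ll[, 2L])))
}

# ---- hand-rolled Gini trees --------------------------------------------------

# Best single split of one node by Gini impurity decrease; vectorised scan
# over sorted values of each candidate column.
best_gini_split <- function(x, y, cols, minbucket) {
  n <- length(y)
  tot1 <- sum(y)
  parent <- 2 * (tot1 / n) * (1 - tot1 / n)
  best <- list(gain = 0, feat = NA_integer_, thr = NA_real_)
  for (j in cols) {
    o <- order(x[, j])
    xo <- x[o, j]
    cum1 <- cumsum(y[o])
    i <- seq_len(n - 1L)
    valid <- (xo[i] < xo[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
    if (!any(valid)) next
    p1l <- cum1[i] / i
    p1r <- (tot1 - cum1[i]) / (n - i)
    child <- (i / n) * 2 * p1l * (1 - p1l) + ((n - i) / n) * 2 * p1r * (1 - p1r)
    gain <- ifelse(valid, parent - child, -Inf)
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      best <- list(gain = gain[b], feat = j, thr = (xo[b] + xo[b + 1L]) / 2)
    }
  }
  best
}

fit_gini_tree <- function(x, y, maxdepth = 5L, minsplit = 20L, minbucket = 7L,
                          mtry = ncol(x)) {
  nodes <- list()
  importance <- numeric(ncol(x))
  n_total <- length(y)
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(leaf = TRUE, pred = NA_real_) # reserve slot
    yb <- y[rows]
    pred <- mean(yb)
    leaf <- list(leaf = TRUE, pred = pred)
    if (depth >= maxdepth || length(rows) < minsplit ||
        pred == 0 || pred == 1) {
      nodes[[id]] <<- leaf
      return(id)
    }
    cols <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else seq_len(ncol(x))
    sp <- best_gini_split(x[rows, , drop = FALSE], yb, cols, minbucket)
    if (is.na(sp$feat) || sp$gain <= 0) {
      nodes[[id]] <<- leaf
      return(id)
    }
    importance[sp$feat] <<- importance[sp$feat] + sp$gain * length(rows) / n_total
    left_rows <- rows[x[rows, sp$feat] <= sp$thr]
    right_rows <- rows[x[rows, sp$feat] > sp$thr]
    left <- grow(left_rows, depth + 1L)
    right <- grow(right_rows, depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, pred = pred, feat = sp$feat,
                         thr = sp$thr, left = left, right = right)
    id
  }
  grow(seq_along(y), 0L)
  list(nodes = nodes, importance = importance)
}

predict_gini_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  recurse <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[rows] <<- nd$pred
      return(invisible(NULL))
    }
    go_left <- x[rows, nd$feat] <= nd$thr
    if (any(go_left)) recurse(nd$left, rows[go_left])
    if (any(!go_left)) recurse(nd$right, rows[!go_left])
  }
  if (nrow(x)) recurse(1L, seq_len(nrow(x)))
  out
}

fit_cart <- function(x, y, params, ctx = NULL) {
  tree <- fit_gini_tree(x, y,
                        maxdepth = as.integer(params$maxdepth %||% 5L),
                        minsplit = 20L,
                        minbucket = as.integer(params$minbucket %||% 7L))
  structure(tree, class = "sp_cart")
}

predict_cart <- function(model, x) predict_gini_tree(model, x)

importance_cart <- function(model, x) model$importance

fit_bag <- function(x, y, params, ctx = NULL) {
  ntree <- as.integer(params$ntree %||% 20L)
  mtry <- max(1L, as.integer(ceiling((params$mtry_frac %||% 0.6) * ncol(x))))
  trees <- vector("list", ntree)
  importance <- numeric(ncol(x))
  for (b in seq_len(ntree)) {
    rows <- sample.int(nrow(x), replace = TRUE)
    trees[[b]] <- fit_gini_tree(x[rows, , drop = FALSE], y[rows],
                                maxdepth = as.integer(params$maxdepth %||% 4L),
                                minsplit = 20L, minbucket = 7L, mtry = mtry)
    importance <- importance + trees[[b]]$importance
  }
  structure(list(trees = trees, importance = importance / ntree),
            class = "sp_bag")
}

predict_bag <- function(model, x) {
  rowMeans(vapply(model$trees, predict_gini_tree, numeric(nrow(x)), x = x))
}

importance_bag <- function(model, x) model$importance

register_builtin_learners <- function() {
  register_learner("lgr", fit_lgr, predict_lgr, hyper_space = list(),
                   importance = importance_lgr, label = "logistic regression")
  register_learner("enet", fit_enet, predict_enet,
                   hyper_space = list(
                     alpha = list(type = "uniform", min = 0, max = 1),
                     lambda = list(type = "loguniform", min = 1e-4, max = 0.5)),
                   importance = importance_enet,
                   label = "elastic-net logistic regression")
  register_learner("gam", fit_gam, predict_gam,
                   hyper_space = list(
                     k = list(type = "choice", values = c(4L, 5L, 6L)),
                     gamma = list(type = "uniform", min = 1, max = 2.5)),
                   label = "spline generalized additive model")
  register_learner("lda", fit_lda, predict_lda, hyper_space = list(),
                   importance = importance_lda,
                   label = "linear discriminant analysis")
  register_learner("rda", fit_rda, predict_rda,
                   hyper_space = list(
                     lambda = list(type = "uniform", min = 0, max = 1),
                     gamma = list(type = "loguniform", min = 0.01, max = 0.5)),
                   label = "shrinkage quadratic discriminant")
  register_learner("knn", fit_knn, predict_knn,
                   hyper_space = list(
                     k = list(type = "choice", values = c(11L, 25L, 51L))),
                   label = "k-nearest neighbours")
  register_learner("nb", fit_nb, predict_nb,
                   hyper_space = list(
                     smooth = list(type = "loguniform", min = 1e-9, max = 1e-1)),
                   label = "Gaussian naive Bayes")
  register_learner("cart", fit_cart, predict_cart,
                   hyper_space = list(
                     maxdepth = list(type = "int", min = 2L, max = 7L),
                     minbucket = list(type = "choice", values = c(5L, 10L, 20L))),
                   importance = importance_cart,
                   label = "Gini decision tree")
  register_learner("bag", fit_bag, predict_bag,
                   hyper_space = list(
                     ntree = list(type = "choice", values = c(15L, 25L)),
                     maxdepth = list(type = "choice", values = c(3L, 4L, 5L)),
                     mtry_frac = list(type = "uniform", min = 0.4, max = 0.9)),
                   importance = importance_bag,
                   label = "bagged Gini trees")
}

.onLoad <- function(libname, pkgname) {
  register_builtin_learners()
}

# ---- cross-validation machinery ---------------------------------------------

#' Tuning configuration
#'
#' Defaults match the scheme's stated protocol: 30 uniformly sampled
#' hyper-parameter candidates per learner, each scored by 3-repeat 10-fold
#' cross-validation, selecting the candidate with the highest mean CV AUC.
#'
#' @param m number of random hyper-parameter candidates.
#' @param k number of CV folds.
#' @param repeats number of CV repetitions.
#' @param metric selection metric (only `"auc"` is implemented).
#' @param seed integer seed governing candidate sampling, fold assignment and
#'   in-fold upsampling.
#' @return object of class `tuning_config`.
#' @export
tuning_config <- function(m = 30L, k = 10L, repeats = 3L, metric = "auc",
                          seed = 1L) {
  stopifnot(m >= 1L, k >= 2L, repeats >= 1L, identical(metric, "auc"))
  structure(list(m = as.integer(m), k = as.integer(k),
                 repeats = as.integer(repeats), metric = metric,
                 seed = as.integer(seed)),
            class = "tuning_config")
}

#' Stratified cross-validation fold assignments
#'
#' One shared assignment must be used by every learner in a bank so their
#' out-of-fold predictions align case by case (the stacking prerequisite).
#'
#' @param labels integer 0/1 outcome vector.
#' @param k folds. @param repeats repetitions. @param seed integer seed.
#' @return object of class `cv_folds`: list `assignments` (one integer vector
#'   of fold ids per repeat), plus `k`, `repeats`, `seed`.
#' @export
make_cv_folds <- function(labels, k = 10L, repeats = 3L, seed = 1L) {
  n <- length(labels)
  if (min(table(labels)) < k) {
    stop("fewer minority cases than folds; reduce k", call. = FALSE)
  }
  assignments <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      for (cls in unique(labels)) {
        rows <- which(labels == cls)
        fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
      }
      fold
    })
  })
  structure(list(assignments = assignments, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_folds")
}

# AUC used for fold scoring; NA when undefined.
safe_auc <- function(probs, labels) {
  if (anyNA(probs) || length(unique(labels)) < 2L) return(NA_real_)
  roc_auc(probs, labels)$auc
}

#' Tune one learner by random hyper-parameter search
#'
#' Samples `cfg$m` candidate hyper-parameter sets from the learner's sampling
#' rules, scores each by repeated stratified k-fold cross-validation (minority
#' upsampling applied inside each training fold only, never to the held-out
#' fold), selects the candidate with the highest mean fold AUC, and refits it
#' on the full (upsampled) training data. The chosen candidate's out-of-fold
#' probabilities (averaged over repeats) are retained for stacking.
#'
#' @param spec a `learner_spec` (see [get_learner()]).
#' @param x numeric design matrix of the training partition.
#' @param y integer 0/1 labels.
#' @param cfg a [tuning_config()].
#' @param folds optional shared [make_cv_folds()] assignment; built from `cfg`
#'   if omitted. Banks being stacked must pass the same object.
#' @param ctx optional encoding context passed to the learner's fit function.
#' @return object of class `tuned_learner`: `chosen_params`, `cv_auc`,
#'   `candidate_table`, `oof_probs`, `fitted`, `folds`, `failed`.
#' @export
random_search_tune <- function(spec, x, y, cfg = tuning_config(),
                               folds = NULL, ctx = NULL) {
  stopifnot(inherits(spec, "learner_spec"))
  if (length(unique(y)) < 2L) stop("training labels contain one class", call. = FALSE)
  if (is.null(folds)) folds <- make_cv_folds(y, cfg$k, cfg$repeats, cfg$seed)
  n <- length(y)
  seed_base <- child_seed(cfg$seed, sum(utf8ToInt(spec$name)))
  n_cand <- if (length(spec$hyper_space)) cfg$m else 1L
  candidates <- with_seed(seed_base, {
    lapply(seq_len(n_cand), function(i) sample_params(spec$hyper_space))
  })
  scores <- rep(NA_real_, n_cand)
  oof_store <- vector("list", n_cand)
  for (ci in seq_len(n_cand)) {
    params <- candidates[[ci]]
    oof <- matrix(NA_real_, n, folds$repeats)
    fold_aucs <- c()
    broken <- FALSE
    for (r in seq_len(folds$repeats)) {
      fold_id <- folds$assignments[[r]]
      for (f in seq_len(folds$k)) {
        te <- which(fold_id == f)
        tr <- which(fold_id != f)
        up <- upsample_indices(y[tr],
                               seed = child_seed(seed_base, ci * 1000L + r * 50L + f))
        tr_up <- tr[up]
        model <- tryCatch(
          with_seed(child_seed(seed_base, ci * 7919L + r * 50L + f),
                    spec$fit(x[tr_up, , drop = FALSE], y[tr_up], params, ctx)),
          error = function(e) NULL)
        if (is.null(model)) { broken <- TRUE; break }
        p <- tryCatch(spec$predict_prob(model, x[te, , drop = FALSE]),
                      error = function(e) NULL)
        if (is.null(p)) { broken <- TRUE; break }
        oof[te, r] <- p
        fold_aucs <- c(fold_aucs, safe_auc(p, y[te]))
      }
      if (broken) break
    }
    if (!broken) {
      scores[ci] <- mean(fold_aucs, na.rm = TRUE)
      oof_store[[ci]] <- rowMeans(oof) # NA if any repeat left a cell missing
    }
  }
  candidate_table <- data.frame(
    candidate = seq_len(n_cand),
    score = scores,
    params = vapply(candidates, function(p) {
      if (!length(p)) "(none)" else paste(names(p), signif(unlist(p), 4),
                                          sep = "=", collapse = ", ")
    }, character(1))
  )
  if (all(is.na(scores))) {
    return(structure(list(name = spec$name, spec = spec, chosen_params = NULL,
                          cv_auc = NA_real_, candidate_table = candidate_table,
                          oof_probs = rep(NA_real_, n), fitted = NULL,
                          folds = folds, failed = TRUE),
                     class = "tuned_learner"))
  }
  best <- which.max(scores)
  up <- upsample_indices(y, seed = child_seed(seed_base, 999983L))
  fitted <- tryCatch(
    with_seed(child_seed(seed_base, 424243L),
              spec$fit(x[up, , drop = FALSE], y[up], candidates[[best]], ctx)),
    error = function(e) NULL)
  structure(
    list(name = spec$name, spec = spec, chosen_params = candidates[[best]],
         cv_auc = scores[best], candidate_table = candidate_table,
         oof_probs = oof_store[[best]], fitted = fitted, folds = folds,
         failed = is.null(fitted)),
    class = "tuned_learner"
  )
}

#' @export
print.tuned_learner <- function(x, ...) {
  cat(sprintf("<tuned_learner> %s  cv_auc = %.3f%s\n", x$name,
              x$cv_auc, if (x$failed) "  [FAILED]" else ""))
  invisible(x)
}

#' Tune a whole learner bank on a training cohort
#'
#' Encodes the cohort once, builds one shared fold assignment, and tunes each
#' learner with [random_search_tune()].
#'
#' @param bank named list of `learner_spec`s (see [default_learner_bank()]).
#' @param train a [cohort_table()] training partition.
#' @param cfg a [tuning_config()].
#' @return list with `tuned` (named list of `tuned_learner`), `encoder`, `x`,
#'   `y`, `folds`, `ctx`.
#' @export
tune_bank <- function(bank, train, cfg = tuning_config()) {
  stopifnot(inherits(train, "cohort_table"))
  encd <- encode_features(train)
  y <- train$labels
  folds <- make_cv_folds(y, cfg$k, cfg$repeats, cfg$seed)
  col_kind <- train$schema$feature_kinds[encd$encoder$col_feature]
  names(col_kind) <- colnames(encd$x)
  ctx <- list(encoder = encd$encoder, col_kind = col_kind,
              schema = train$schema)
  tuned <- lapply(bank, function(spec) {
    random_search_tune(spec, encd$x, y, cfg, folds = folds, ctx = ctx)
  })
  names(tuned) <- names(bank)
  list(tuned = tuned, encoder = encd$encoder, x = encd$x, y = y,
       folds = folds, ctx = ctx)
}

#' Collect aligned out-of-fold predictions from a tuned bank
#'
#' @param tuned named list of `tuned_learner`s sharing one fold assignment.
#' @return numeric matrix, one row per training case, one column per learner.
#'   Cells a learner could not predict are `NA`.
#' @export
collect_oof_predictions <- function(tuned) {
  stopifnot(length(tuned) >= 1L)
  ref <- tuned[[1L]]$folds$assignments
  for (t in tuned) {
    if (!identical(t$folds$assignments, ref)) {
      stop("misaligned fold assignments across learners; tune with a shared `folds`",
           call. = FALSE)
    }
  }
  m <- vapply(tuned, function(t) t$oof_probs, numeric(length(tuned[[1L]]$oof_probs)))
  colnames(m) <- names(tuned)
  m
}

#' Eject learners with invalid out-of-fold predictions
#'
#' A learner that failed tuning outright, or whose out-of-fold vector contains
#' any missing value, cannot enter the correlation analysis and is removed up
#' front (the role the SVM ejection plays in the scheme's worked example).
#'
#' @param tuned named list of `tuned_learner`s.
#' @return list with `tuned` (survivors) and `log` (data.frame: name,
#'   n_missing, reason).
#' @export
eject_invalid_learners <- function(tuned) {
  n_missing <- vapply(tuned, function(t) sum(!is.finite(t$oof_probs)), integer(1))
  failed <- vapply(tuned, function(t) isTRUE(t$failed), logical(1))
  drop <- failed | n_missing > 0L
  log <- data.frame(name = names(tuned)[drop],
                    n_missing = n_missing[drop],
                    reason = ifelse(failed[drop], "tuning failed",
                                    "missing out-of-fold predictions"),
                    row.names = NULL)
  if (all(drop)) stop("all learners ejected; nothing left to ensemble", call. = FALSE)
  list(tuned = tuned[!drop], log = log)
}
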