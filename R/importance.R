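# Ensemble feature importance: per-learner importances (native measures where
# the learner family defines one, permutation importance otherwise), combined
# across surviving learners by a weighted-sum rank aggregation using the
# normalised absolute meta-coefficients as weights, then truncated at a
# two-line knee point. Direction labels come from the tuned logistic
# regression's coefficient signs.

#' Per-feature importance of one tuned learner
#'
#' Uses the learner's native importance when registered (absolute
#' standardised coefficients for linear learners, accumulated impurity
#' decrease for trees) and AUC-drop permutation importance otherwise.
#' One-hot indicator columns are summed back to their parent feature, so the
#' result has one nonnegative entry per schema feature.
#'
#' @param tuned a `tuned_learner` with a fitted model.
#' @param x encoded training design matrix.
#' @param y integer 0/1 labels (needed for permutation importance).
#' @param encoder the [fit_encoder()] map that produced `x`.
#' @param n_perm permutation repeats (permutation fallback only).
#' @param seed integer seed for the permutations.
#' @param max_rows permutation importance is evaluated on at most this many
#'   (seeded) subsampled rows; importance contrasts stabilise long before the
#'   full cohort is needed and instance-based learners predict in quadratic
#'   time.
#' @return named nonnegative numeric vector over the schema's features.
#' @export
per_learner_importance <- function(tuned, x, y, encoder, n_perm = 3L, seed = 1L,
                                   max_rows = 2000L) {
  stopifnot(inherits(tuned, "tuned_learner"), !is.null(tuned$fitted))
  col_imp <- if (!is.null(tuned$spec$importance)) {
    tuned$spec$importance(tuned$fitted, x)
  } else {
    if (nrow(x) > max_rows) {
      rows <- with_seed(child_seed(seed, 77L), sample.int(nrow(x), max_rows))
      x <- x[rows, , drop = FALSE]
      y <- y[rows]
    }
    permutation_importance(tuned, x, y, n_perm = n_perm, seed = seed)
  }
  col_imp <- pmax(as.numeric(col_imp), 0)
  names(col_imp) <- colnames(x)
  feats <- encoder$schema$feature_names
  out <- stats::setNames(numeric(length(feats)), feats)
  parent <- encoder$col_feature[colnames(x)]
  for (f in feats) out[f] <- sum(col_imp[parent == f])
  out
}

# AUC drop when one column is permuted, averaged over n_perm shuffles.
permutation_importance <- function(tuned, x, y, n_perm = 3L, seed = 1L) {
  base_auc <- safe_auc(tuned$spec$predict_prob(tuned$fitted, x), y)
  with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_perm), function(r) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        base_auc - safe_auc(tuned$spec$predict_prob(tuned$fitted, xp), y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
}

#' Weighted-sum rank aggregation of per-learner importances
#'
#' Within each learner, features are ranked 1 (most important) to p (average
#' ranks on ties). Each learner's rank vector is weighted by its share of the
#' meta-classifier weight — `|meta coefficient|` normalised to sum 1 — and the
#' shares-weighted rank sum is the aggregated score: consistently top-ranked
#' features get the smallest scores.
#'
#' @param importances p x l matrix (features x learners) of nonnegative
#'   importances, dimnames set.
#' @param meta_weights named numeric vector of meta-classifier coefficients,
#'   one per learner column.
#' @return list with `score` (named, aggregated), `order` (feature names,
#'   best first; score ties broken alphabetically), `ranks` (p x l within-
#'   learner ranks), `share` (normalised weights), `ties` (tied feature
#'   names, if any).
#' @export
aggregate_ranks <- function(importances, meta_weights) {
  importances <- as.matrix(importances)
  l <- ncol(importances)
  stopifnot(l >= 1L, length(meta_weights) == l)
  meta_weights <- meta_weights[colnames(importances)]
  share <- abs(meta_weights)
  if (sum(share) == 0) {
    share <- rep(1 / l, l) # degenerate meta: fall back to equal shares
  } else {
    share <- share / sum(share)
  }
  ranks <- apply(importances, 2, function(v) rank(-v, ties.method = "average"))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = l,
                                           dimnames = dimnames(importances))
  score <- as.numeric(ranks %*% share)
  names(score) <- rownames(importances)
  ord <- order(score, names(score)) # ties alphabetical
  dup <- duplicated(score) | duplicated(score, fromLast = TRUE)
  list(score = score, order = names(score)[ord], ranks = ranks,
       share = stats::setNames(as.numeric(share), colnames(importances)),
       ties = names(score)[dup])
}

#' Knee point of an ascending score sequence by two-line regression
#'
#' For every candidate split s in 2..p-2, fits one least-squares line to the
#' first s scores (against their positions) and one to the rest, and returns
#' the s minimising the total residual sum of squares; ties go to the
#' smallest s. Features at positions 1..s are the "important" set.
#'
#' @param sorted_scores aggregated scores sorted ascending (best feature
#'   first).
#' @return integer knee index with attributes `rss` (per-candidate totals)
#'   and `no_clear_knee` (TRUE when every split fits equally well, e.g. a
#'   perfectly linear sequence).
#' @export
knee_point <- function(sorted_scores) {
  p <- length(sorted_scores)
  if (p < 4L) {
    warning("fewer than 4 scores; no two-line split possible, knee = p",
            call. = FALSE)
    return(structure(p, no_clear_knee = TRUE, rss = numeric(0)))
  }
  if (is.unsorted(sorted_scores)) {
    stop("scores must be sorted ascending", call. = FALSE)
  }
  seg_rss <- function(y) {
    m <- length(y)
    t <- seq_len(m)
    f <- stats::lm.fit(cbind(1, t), y)
    sum(f$residuals^2)
  }
  cand <- 2:(p - 2L)
  rss <- vapply(cand, function(s) {
    seg_rss(sorted_scores[1:s]) + seg_rss(sorted_scores[(s + 1L):p])
  }, numeric(1))
  # near-ties (e.g. an exactly linear sequence, where every split has RSS 0
  # up to float noise) resolve to the smallest candidate split
  tol <- 1e-8 * max(1, sum(sorted_scores^2))
  knee <- cand[which(rss <= min(rss) + tol)[1L]]
  no_clear <- (max(rss) - min(rss)) <= tol
  structure(as.integer(knee), rss = rss, no_clear_knee = no_clear)
}

#' Direction labels from logistic-regression coefficient signs
#'
#' Continuous, ordinal and binary (two-level categorical) features are
#' labelled `"positive"` or `"negative"` by the sign of the tuned logistic
#' regression's coefficient; categorical features with more than two levels
#' get `"categorical/unsigned"` (one sign per level would be meaningless for
#' a single bar).
#'
#' @param lgr_tuned the bank's tuned logistic-regression learner (it may have
#'   been pruned from the ensemble; direction labelling still uses it).
#' @param encoder the [fit_encoder()] map.
#' @return named character vector over schema features.
#' @export
assign_directions <- function(lgr_tuned, encoder) {
  schema <- encoder$schema
  out <- stats::setNames(rep("categorical/unsigned", schema$p),
                         schema$feature_names)
  if (is.null(lgr_tuned) || is.null(lgr_tuned$fitted) ||
      !inherits(lgr_tuned$fitted, "sp_lgr")) {
    warning("no fitted logistic-regression learner in the bank; directions unsigned",
            call. = FALSE)
    return(out)
  }
  coefs <- lgr_tuned$fitted$coefs[-1L] # drop intercept
  for (f in schema$feature_names) {
    kind <- schema$feature_kinds[[f]]
    cols <- names(encoder$col_feature)[encoder$col_feature == f]
    if (kind == "categorical" && length(encoder$levels_map[[f]]) > 2L) {
      next # stays unsigned
    }
    if (!length(cols)) next
    s <- sum(coefs[cols])
    out[f] <- if (s >= 0) "positive" else "negative"
  }
  out
}

#' Build the full ensemble importance table
#'
#' Computes per-learner importances for the ensemble's surviving base
#' learners, aggregates them with the meta-weight shares, finds the knee
#' point, and attaches direction labels.
#'
#' @param model an [build_ensemble()] result.
#' @param x encoded training design matrix.
#' @param y integer 0/1 training labels.
#' @param lgr_tuned optional tuned logistic-regression learner for direction
#'   signs (defaults to the model's own `lgr` survivor if present).
#' @param seed seed for permutation importances.
#' @param n_perm,max_rows forwarded to [per_learner_importance()].
#' @return object of class `importance_table`: data.frame `table` (feature,
#'   aggregated_score, rank, direction, important), `knee_index`,
#'   `per_learner_ranks`, `meta_weight_share`.
#' @export
build_importance_table <- function(model, x, y, lgr_tuned = NULL, seed = 1L,
                                   n_perm = 2L, max_rows = 1500L) {
  stopifnot(inherits(model, "ensemble_model"))
  encoder <- model$encoder
  imps <- vapply(model$base_models, per_learner_importance,
                 numeric(encoder$schema$p),
                 x = x, y = y, encoder = encoder, seed = seed,
                 n_perm = n_perm, max_rows = max_rows)
  if (is.null(dim(imps))) {
    imps <- matrix(imps, ncol = length(model$base_models),
                   dimnames = list(encoder$schema$feature_names,
                                   names(model$base_models)))
  }
  agg <- aggregate_ranks(imps, model$meta$weights)
  sorted <- agg$score[agg$order]
  knee <- knee_point(as.numeric(sorted))
  if (is.null(lgr_tuned)) lgr_tuned <- model$base_models[["lgr"]]
  directions <- if (!is.null(lgr_tuned)) {
    assign_directions(lgr_tuned, encoder)
  } else {
    suppressWarnings(assign_directions(NULL, encoder))
  }
  tab <- data.frame(
    feature = agg$order,
    aggregated_score = as.numeric(sorted),
    rank = seq_along(agg$order),
    direction = directions[agg$order],
    important = seq_along(agg$order) <= as.integer(knee),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, knee_index = as.integer(knee),
         no_clear_knee = isTRUE(attr(knee, "no_clear_knee")),
         per_learner_ranks = agg$ranks[agg$order, , drop = FALSE],
         meta_weight_share = agg$share, importances = imps),
    class = "importance_table"
  )
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("<importance_table> knee at %d of %d features\n",
              x$knee_index, nrow(x$table)))
  print(x$table, digits = 3)
  invisible(x)
}

#' Horizontal bar chart of aggregated feature importance
#'
#' Most important feature on top; bars coloured by direction (positive blue,
#' negative red, unsigned grey); features past the knee drawn paler.
#'
#' @param imp an [build_importance_table()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_importance <- function(imp, ...) {
  tab <- imp$table[rev(seq_len(nrow(imp$table))), ]
  cols <- ifelse(tab$direction == "positive", "#3B6FB6",
                 ifelse(tab$direction == "negative", "#C0392B", "#8C8C8C"))
  cols[!tab$important] <- grDevices::adjustcolor(cols[!tab$important], 0.35)
  # lower aggregated score = more important; plot inverted score as bar length
  len <- max(tab$aggregated_score) + 1 - tab$aggregated_score
  graphics::barplot(len, names.arg = tab$feature, horiz = TRUE, las = 1,
                    col = cols, border = NA,
                    xlab = "ensemble importance (inverted weighted rank)", ...)
  invisible(imp)
}
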