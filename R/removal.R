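# Iterative correlation-based classifier removal. Redundant base classifiers
# add little to a stack; the scheme repeatedly finds the most-correlated pair
# of out-of-fold prediction vectors and, while that correlation exceeds a
# threshold (default 0.75), drops the pair member whose average correlation
# to the other remaining classifiers is higher. Averages are recomputed on
# the shrunken matrix each round.

#' Removal configuration
#' @param threshold correlation cutoff, usually in (0, 1); default 0.75, the
#'   usual boundary of a "strong" positive linear relationship. Values of 1
#'   or more disable pruning (no correlation can exceed them).
#' @return object of class `removal_config`.
#' @export
removal_config <- function(threshold = 0.75) {
  if (!(threshold > 0)) {
    stop("threshold must be positive", call. = FALSE)
  }
  structure(list(threshold = threshold), class = "removal_config")
}

#' Inter-classifier correlation matrix of out-of-fold predictions
#'
#' @param oof_matrix n x l matrix of out-of-fold positive-class probabilities
#'   with learner names as column names; no missing cells (eject first).
#' @return object of class `corr_matrix`: `learner_names` and `values`
#'   (l x l Pearson correlations, exactly symmetric, unit diagonal).
#' @export
prediction_correlation_matrix <- function(oof_matrix) {
  oof_matrix <- as.matrix(oof_matrix)
  if (ncol(oof_matrix) < 2L) stop("need at least two learners", call. = FALSE)
  if (anyNA(oof_matrix)) {
    stop("missing cells in out-of-fold matrix; run eject_invalid_learners() first",
         call. = FALSE)
  }
  sds <- apply(oof_matrix, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant prediction column(s): ",
         paste(colnames(oof_matrix)[sds == 0], collapse = ", "),
         "; correlation undefined", call. = FALSE)
  }
  v <- stats::cor(oof_matrix)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  corr_matrix(v, colnames(oof_matrix))
}

#' Construct a correlation-matrix object directly
#'
#' @param values l x l symmetric matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @param learner_names optional names (defaults to the matrix dimnames or
#'   `L1..Ll`).
#' @return object of class `corr_matrix`.
#' @export
corr_matrix <- function(values, learner_names = NULL) {
  values <- as.matrix(values)
  l <- nrow(values)
  if (ncol(values) != l) stop("correlation matrix must be square", call. = FALSE)
  if (is.null(learner_names)) {
    learner_names <- colnames(values) %||% paste0("L", seq_len(l))
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(values) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (any(values < -1 - 1e-8 | values > 1 + 1e-8)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  dimnames(values) <- list(learner_names, learner_names)
  structure(list(learner_names = learner_names, values = values),
            class = "corr_matrix")
}

#' Find the maximal upper-triangular correlation pair
#'
#' Ties are broken by lexicographic pair order over the matrix's learner
#' ordering, i.e. (1,2), (1,3), ..., (2,3), ...; a tie is flagged.
#'
#' @param corr a `corr_matrix`.
#' @return list with `pair` (two learner names), `value`, and `tie` flag.
#' @export
find_max_pair <- function(corr) {
  stopifnot(inherits(corr, "corr_matrix"))
  v <- corr$values
  l <- nrow(v)
  if (l < 2L) stop("need at least two learners", call. = FALSE)
  best <- -Inf
  best_pair <- c(NA_integer_, NA_integer_)
  tie <- FALSE
  for (i in seq_len(l - 1L)) {
    for (j in (i + 1L):l) {
      if (v[i, j] > best + 1e-12) {
        best <- v[i, j]
        best_pair <- c(i, j)
        tie <- FALSE
      } else if (abs(v[i, j] - best) <= 1e-12) {
        tie <- TRUE
      }
    }
  }
  list(pair = corr$learner_names[best_pair], value = best, tie = tie)
}

#' One step of the removal scheme
#'
#' If the largest pairwise correlation does not exceed the threshold, nothing
#' is removed. Otherwise each member of the maximal pair gets its mean
#' correlation to all other remaining learners (self excluded) and the member
#' with the larger mean is removed; an exact tie removes the member with the
#' lower cross-validated AUC.
#'
#' @param corr a `corr_matrix` over the currently remaining learners.
#' @param cfg a [removal_config()].
#' @param cv_aucs named numeric vector of each learner's tuning CV AUC (used
#'   only for average ties).
#' @return list with `removed` (name or `NULL`) and `record` (one-row
#'   data.frame of the decision).
#' @export
removal_iteration <- function(corr, cfg = removal_config(), cv_aucs = NULL) {
  stopifnot(inherits(corr, "corr_matrix"))
  mp <- find_max_pair(corr)
  if (mp$value <= cfg$threshold) {
    return(list(removed = NULL, record = NULL))
  }
  v <- corr$values
  avg_of <- function(name) {
    others <- setdiff(corr$learner_names, name)
    mean(v[name, others])
  }
  a <- mp$pair[1L]; b <- mp$pair[2L]
  avg_a <- avg_of(a); avg_b <- avg_of(b)
  tie_avg <- abs(avg_a - avg_b) <= 1e-12
  removed <- if (tie_avg) {
    if (is.null(cv_aucs)) {
      stop("average-correlation tie requires cv_aucs for the tie-break", call. = FALSE)
    }
    if (cv_aucs[[a]] <= cv_aucs[[b]]) a else b
  } else if (avg_a > avg_b) a else b
  record <- data.frame(
    learner_a = a, learner_b = b, max_corr = mp$value,
    avg_a = avg_a, avg_b = avg_b, removed = removed,
    tie_max_pair = mp$tie, tie_avg = tie_avg,
    stringsAsFactors = FALSE
  )
  list(removed = removed, record = record)
}

#' Run the full iterative removal scheme
#'
#' Repeats [removal_iteration()] on the matrix restricted to the remaining
#' learners until the largest pairwise correlation is at or below the
#' threshold, or a single learner remains. Terminates after at most l - 1
#' iterations.
#'
#' @param x either an n x l out-of-fold probability matrix (named columns) or
#'   a `corr_matrix`.
#' @param cfg a [removal_config()].
#' @param cv_aucs named CV AUC vector (tie-breaks only).
#' @return object of class `removal_trace`: `iterations` (data.frame, one row
#'   per removal) and `survivors` (ordered names).
#' @export
run_removal <- function(x, cfg = removal_config(), cv_aucs = NULL) {
  corr <- if (inherits(x, "corr_matrix")) x else prediction_correlation_matrix(x)
  remaining <- corr$learner_names
  records <- list()
  while (length(remaining) >= 2L) {
    sub <- corr_matrix(corr$values[remaining, remaining, drop = FALSE], remaining)
    step <- removal_iteration(sub, cfg, cv_aucs)
    if (is.null(step$removed)) break
    records[[length(records) + 1L]] <- step$record
    remaining <- setdiff(remaining, step$removed)
  }
  iterations <- if (length(records)) do.call(rbind, records) else
    data.frame(learner_a = character(0), learner_b = character(0),
               max_corr = numeric(0), avg_a = numeric(0), avg_b = numeric(0),
               removed = character(0), tie_max_pair = logical(0),
               tie_avg = logical(0))
  structure(list(iterations = iterations, survivors = remaining,
                 threshold = cfg$threshold),
            class = "removal_trace")
}

#' @export
print.removal_trace <- function(x, ...) {
  cat(sprintf("<removal_trace> %d removal(s), threshold %.2f\n",
              nrow(x$iterations), x$threshold))
  if (nrow(x$iterations)) {
    for (i in seq_len(nrow(x$iterations))) {
      r <- x$iterations[i, ]
      cat(sprintf("  %d. max pair (%s, %s) r=%.3f; avg %.3f vs %.3f -> removed %s\n",
                  i, r$learner_a, r$learner_b, r$max_corr, r$avg_a, r$avg_b,
                  r$removed))
    }
  }
  cat("  survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a removal trace to JSON
#' @param trace a `removal_trace`. @param path output path.
#' @export
write_removal_trace <- function(trace, path) {
  jsonlite::write_json(
    list(threshold = trace$threshold,
         iterations = trace$iterations,
         survivors = trace$survivors),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
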