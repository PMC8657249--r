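# Stacked meta-classifier. The survivors of the removal scheme feed a
# second-level logistic regression trained on their out-of-fold
# probabilities (never on refit-on-train predictions, which would let the
# meta-model reward base-learner overfitting). At predict time each base
# model scores the new data and the meta-model maps the l-vector of
# probabilities to one ensemble probability.

#' Fit the meta-classifier on out-of-fold predictions
#'
#' @param oof_matrix n x l matrix of survivors' out-of-fold probabilities
#'   (named columns).
#' @param labels integer 0/1 training labels.
#' @param meta_kind only `"lgr"` (logistic regression) is implemented.
#' @return list with `intercept`, `weights` (one per column), `meta_kind`,
#'   and `penalized` flag (TRUE when a ridge fallback was used).
#' @export
fit_meta <- function(oof_matrix, labels, meta_kind = "lgr") {
  oof_matrix <- as.matrix(oof_matrix)
  stopifnot(identical(meta_kind, "lgr"), ncol(oof_matrix) >= 1L)
  if (anyNA(oof_matrix)) stop("missing cells in meta inputs", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, oof_matrix), labels, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  coefs <- fit$coefficients
  if (separated || any(abs(coefs[!is.na(coefs)]) > 50)) {
    warning("perfect separation in meta inputs; falling back to ridge-penalized fit",
            call. = FALSE)
    # glmnet needs >= 2 columns; duplicate and split the weight if needed
    xm <- if (ncol(oof_matrix) == 1L) cbind(oof_matrix, oof_matrix) else oof_matrix
    rfit <- glmnet::glmnet(xm, labels, family = "binomial", alpha = 0,
                           lambda = 1e-2)
    beta <- as.numeric(rfit$beta)
    if (ncol(oof_matrix) == 1L) beta <- sum(beta)
    coefs <- c(rfit$a0, beta)
    names(coefs) <- c("(Intercept)", colnames(oof_matrix))
    return(list(intercept = coefs[[1L]],
                weights = stats::setNames(coefs[-1L], colnames(oof_matrix)),
                meta_kind = meta_kind, penalized = TRUE))
  }
  coefs[is.na(coefs)] <- 0 # aliased (e.g. duplicated survivor columns)
  list(intercept = coefs[[1L]],
       weights = stats::setNames(coefs[-1L], colnames(oof_matrix)),
       meta_kind = meta_kind, penalized = FALSE)
}

#' Build an ensemble model from a tuned bank
#'
#' Runs the full post-tuning path: eject learners with invalid out-of-fold
#' predictions, optionally run the correlation-based removal scheme, and fit
#' the meta-classifier on the survivors' out-of-fold probabilities.
#'
#' @param tuned named list of `tuned_learner`s (shared fold assignment).
#' @param labels integer 0/1 training labels.
#' @param encoder the frozen [fit_encoder()] map used at tuning time.
#' @param removal a [removal_config()], or `NULL` to skip the removal scheme
#'   (the "without removal" ensemble).
#' @param meta_kind meta-classifier kind (default `"lgr"`).
#' @param meta_seed seed for the minority upsampling applied to the
#'   meta-classifier's training rows. Base learners are trained on balanced
#'   folds, so their probabilities are calibrated to ~0.5 prevalence; the
#'   meta-fit sees the same balance so the 0.5 decision threshold stays
#'   meaningful for the ensemble.
#' @return object of class `ensemble_model`: `survivors`, `meta`,
#'   `base_models` (the surviving `tuned_learner`s), `encoder`,
#'   `removal_trace`, `ejection_log`.
#' @export
build_ensemble <- function(tuned, labels, encoder,
                           removal = removal_config(), meta_kind = "lgr",
                           meta_seed = 1L) {
  ej <- eject_invalid_learners(tuned)
  oof <- collect_oof_predictions(ej$tuned)
  cv_aucs <- vapply(ej$tuned, function(t) t$cv_auc, numeric(1))
  trace <- if (!is.null(removal) && ncol(oof) >= 2L) {
    run_removal(oof, removal, cv_aucs)
  } else {
    structure(list(iterations = data.frame(), survivors = colnames(oof),
                   threshold = NA_real_), class = "removal_trace")
  }
  survivors <- trace$survivors
  up <- upsample_indices(labels, seed = meta_seed)
  meta <- fit_meta(oof[up, survivors, drop = FALSE], labels[up], meta_kind)
  structure(
    list(survivors = survivors, meta = meta,
         base_models = ej$tuned[survivors], encoder = encoder,
         removal_trace = trace, ejection_log = ej$log),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d survivor(s): %s\n", length(x$survivors),
              paste(x$survivors, collapse = ", ")))
  cat("  meta weights:",
      paste(sprintf("%s=%.3f", names(x$meta$weights), x$meta$weights),
            collapse = ", "), "\n")
  invisible(x)
}

# Base-model probability matrix on new encoded data; errors name the learner.
base_predictions <- function(model, x) {
  out <- matrix(NA_real_, nrow(x), length(model$survivors),
                dimnames = list(NULL, model$survivors))
  for (nm in model$survivors) {
    t <- model$base_models[[nm]]
    p <- tryCatch(t$spec$predict_prob(t$fitted, x),
                  error = function(e) {
                    stop(sprintf("base model '%s' failed at predict time: %s",
                                 nm, conditionMessage(e)), call. = FALSE)
                  })
    out[, nm] <- p
  }
  out
}

#' Predict ensemble probabilities
#'
#' @param model an [build_ensemble()] result.
#' @param newdata a [cohort_table()] (encoded with the model's frozen
#'   encoder) or an already-encoded numeric matrix.
#' @return positive-class probability per row, in `[0, 1]`.
#' @export
predict_ensemble <- function(model, newdata) {
  stopifnot(inherits(model, "ensemble_model"))
  x <- if (inherits(newdata, "cohort_table")) {
    apply_encoder(model$encoder, newdata)
  } else {
    as.matrix(newdata)
  }
  bp <- base_predictions(model, x)
  eta <- model$meta$intercept + as.numeric(bp %*% model$meta$weights)
  stats::plogis(eta)
}
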