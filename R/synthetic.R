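# Synthetic registry-shaped cohorts with planted, fully known signal. Stands
# in for the access-restricted hospital registry: same shape (n in the tens of
# thousands, ~12% event prevalence, 14 mixed-type predictors), not the same
# joint distribution. Signal is split across a linear part, a threshold
# nonlinearity and one interaction so that linear, smooth and
# partition/instance learner families genuinely capture different aspects.

#' Default 14-feature registry schema
#'
#' Mirrors the variable list of a head-and-neck cancer registry cohort (age,
#' sex, primary site, staging variables, surgical margins, lymph-node size,
#' treatment sequencing, radiotherapy dose, nodal levels, BMI). The names and
#' kinds are cosmetic fidelity so importance reports read like a registry
#' analysis; the generated values are synthetic.
#'
#' @param outcome_name outcome column name (default `"spc"`, second primary
#'   cancer yes/no).
#' @return A [feature_schema()] with 14 features.
#' @export
default_registry_schema <- function(outcome_name = "spc") {
  feature_schema(
    feature_names = c(
      "age_at_diagnosis", "sex", "primary_site", "clinical_stage",
      "pathologic_stage", "combined_stage", "surgical_margins",
      "lymph_node_size", "surgery_interval_days", "rt_surgery_sequence",
      "therapy_sequence", "ctv_l_dose", "ln_level_i_iii", "bmi"
    ),
    feature_kinds = c(
      "continuous", "categorical", "categorical", "ordinal",
      "ordinal", "ordinal", "categorical",
      "continuous", "continuous", "categorical",
      "categorical", "continuous", "categorical", "continuous"
    ),
    outcome_name = outcome_name
  )
}

# Per-feature marginal generators for the default schema. Continuous entries
# carry (mean, sd) so signal encodings can be standardised analytically;
# ordinal entries carry level probabilities over codes 1..4; categorical
# entries carry level labels and probabilities (2-level entries behave as
# binary indicators of the second level).
default_registry_generators <- function() {
  list(
    age_at_diagnosis      = list(kind = "continuous", mean = 57, sd = 11),
    sex                   = list(kind = "categorical", levels = c("female", "male"), probs = c(0.12, 0.88)),
    primary_site          = list(kind = "categorical",
                                 levels = c("oral_cavity", "oropharynx", "hypopharynx", "larynx"),
                                 probs = c(0.52, 0.2, 0.15, 0.13)),
    clinical_stage        = list(kind = "ordinal", probs = c(0.22, 0.2, 0.2, 0.38)),
    pathologic_stage      = list(kind = "ordinal", probs = c(0.25, 0.22, 0.2, 0.33)),
    combined_stage        = list(kind = "ordinal", probs = c(0.22, 0.2, 0.2, 0.38)),
    surgical_margins      = list(kind = "categorical",
                                 levels = c("negative", "close", "involved"), probs = c(0.74, 0.14, 0.12)),
    lymph_node_size       = list(kind = "continuous", mean = 2, sd = 1.1),
    surgery_interval_days = list(kind = "continuous", mean = 30, sd = 14),
    rt_surgery_sequence   = list(kind = "categorical",
                                 levels = c("no_rt", "rt_after_surgery", "rt_only"), probs = c(0.35, 0.45, 0.2)),
    therapy_sequence      = list(kind = "categorical",
                                 levels = c("local_only", "local_then_systemic", "concurrent"),
                                 probs = c(0.45, 0.3, 0.25)),
    ctv_l_dose            = list(kind = "continuous", mean = 5000, sd = 650),
    ln_level_i_iii        = list(kind = "categorical", levels = c("no", "yes"), probs = c(0.62, 0.38)),
    bmi                   = list(kind = "continuous", mean = 23.5, sd = 4)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults are the package's stated world: n = 27455 with prevalence
#' 3365/27455 (the shape of the registry cohort the package emulates), six
#' informative features among fourteen, and signal split across linear,
#' threshold-nonlinear and interaction components on the logit scale.
#'
#' @param n cohort size.
#' @param prevalence target event fraction in (0, 1).
#' @param schema a [feature_schema()]; defaults to [default_registry_schema()].
#' @param linear_coefs named numeric vector of logit-scale weights on
#'   standardised signal encodings (continuous: z-score; ordinal: centred
#'   code; 2-level categorical: centred indicator of the second level).
#' @param nonlinear_terms list of `list(feature=, type="threshold", cut=,
#'   weight=)` entries; the term is `weight * centred 1(x > cut)`.
#' @param interaction_terms list of `list(features=c(a, b), weight=)` entries;
#'   the term is `weight *` product of the two standardised encodings.
#' @param noise_sd logit-scale Gaussian noise standard deviation.
#' @param generators per-feature marginal generators (see
#'   `default_registry_generators`); required entries for every schema feature.
#' @param seed integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 27455L,
                             prevalence = 3365 / 27455,
                             schema = default_registry_schema(),
                             linear_coefs = c(bmi = -0.3, sex = 0.35,
                                              clinical_stage = 0.25,
                                              ln_level_i_iii = 0.4),
                             nonlinear_terms = list(
                               list(feature = "lymph_node_size",
                                    type = "threshold", cut = 3, weight = 1.3)
                             ),
                             interaction_terms = list(
                               list(features = c("clinical_stage", "ctv_l_dose"),
                                    weight = 0.8)
                             ),
                             noise_sd = 0.5,
                             generators = NULL,
                             seed = 1L) {
  stopifnot(inherits(schema, "feature_schema"))
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must be in (0, 1)", call. = FALSE)
  }
  if (is.null(generators)) {
    generators <- default_registry_generators()
  }
  missing_gen <- setdiff(schema$feature_names, names(generators))
  if (length(missing_gen)) {
    stop("no generator for feature(s): ", paste(missing_gen, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(linear_coefs), schema$feature_names)
  if (length(unknown)) {
    stop("linear_coefs name unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence, schema = schema,
         linear_coefs = linear_coefs, nonlinear_terms = nonlinear_terms,
         interaction_terms = interaction_terms, noise_sd = noise_sd,
         generators = generators[schema$feature_names], seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Standardised signal encoding of one feature: mean ~0, sd ~1 analytically,
# so planted weights are comparable across kinds.
signal_encoding <- function(values, gen) {
  switch(gen$kind,
    continuous = (values - gen$mean) / gen$sd,
    ordinal = {
      codes <- seq_along(gen$probs)
      mu <- sum(codes * gen$probs)
      sdv <- sqrt(sum((codes - mu)^2 * gen$probs))
      (as.numeric(values) - mu) / sdv
    },
    categorical = {
      # indicator of the LAST level, centred and scaled by its Bernoulli sd;
      # for 2-level features this is the usual coded binary covariate.
      pr <- gen$probs[length(gen$probs)]
      ind <- as.numeric(as.character(values) == gen$levels[length(gen$levels)])
      (ind - pr) / sqrt(pr * (1 - pr))
    }
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws features from the configured marginals, composes a logit-scale
#' linear + nonlinear + interaction signal plus Gaussian noise, calibrates the
#' intercept by root finding so the expected event rate equals the target
#' prevalence, and draws Bernoulli labels.
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` (a [cohort_table()]) and `truth`: informative
#'   feature names, per-feature planted direction (`"positive"`, `"negative"`,
#'   or `NA` for interaction-only features), the calibrated intercept, and the
#'   per-row linear predictor.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  schema <- config$schema
  n <- config$n
  with_seed(config$seed, {
    feats <- list()
    for (f in schema$feature_names) {
      gen <- config$generators[[f]]
      feats[[f]] <- switch(gen$kind,
        continuous = stats::rnorm(n, gen$mean, gen$sd),
        ordinal = sample(seq_along(gen$probs), n, replace = TRUE, prob = gen$probs),
        categorical = sample(gen$levels, n, replace = TRUE, prob = gen$probs)
      )
    }
    eta <- numeric(n)
    for (f in names(config$linear_coefs)) {
      eta <- eta + config$linear_coefs[[f]] *
        signal_encoding(feats[[f]], config$generators[[f]])
    }
    for (term in config$nonlinear_terms) {
      if (term$type != "threshold") {
        stop("unknown nonlinear term type: ", term$type, call. = FALSE)
      }
      x <- feats[[term$feature]]
      ind <- as.numeric(as.numeric(x) > term$cut)
      eta <- eta + term$weight * (ind - mean(ind))
    }
    for (term in config$interaction_terms) {
      a <- signal_encoding(feats[[term$features[1L]]], config$generators[[term$features[1L]]])
      b <- signal_encoding(feats[[term$features[2L]]], config$generators[[term$features[2L]]])
      eta <- eta + term$weight * a * b
    }
    if (config$noise_sd > 0) {
      eta <- eta + stats::rnorm(n, 0, config$noise_sd)
    }
    f_rate <- function(b0) mean(stats::plogis(b0 + eta)) - config$prevalence
    if (f_rate(-30) > 0 || f_rate(30) < 0) {
      stop("calibration error: target prevalence unreachable within intercept bounds",
           call. = FALSE)
    }
    b0 <- stats::uniroot(f_rate, c(-30, 30), tol = 1e-10)$root
    labels <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))

    informative <- unique(c(
      names(config$linear_coefs)[config$linear_coefs != 0],
      vapply(config$nonlinear_terms, function(t) if (t$weight != 0) t$feature else NA_character_, ""),
      unlist(lapply(config$interaction_terms,
                    function(t) if (t$weight != 0) t$features else NULL))
    ))
    informative <- informative[!is.na(informative)]
    direction <- rep(NA_character_, schema$p)
    names(direction) <- schema$feature_names
    for (f in names(config$linear_coefs)) {
      if (config$linear_coefs[[f]] != 0) {
        direction[f] <- if (config$linear_coefs[[f]] > 0) "positive" else "negative"
      }
    }
    for (term in config$nonlinear_terms) {
      if (is.na(direction[term$feature]) && term$weight != 0) {
        direction[term$feature] <- if (term$weight > 0) "positive" else "negative"
      }
    }
    df <- as.data.frame(feats, stringsAsFactors = FALSE)
    df[[schema$outcome_name]] <- labels
    list(
      cohort = cohort_table(df, schema),
      truth = list(informative = informative, direction = direction,
                   intercept = b0, eta = eta)
    )
  })
}

#' Generate a bank of pseudo-learner prediction vectors
#'
#' Builds `l` probability vectors whose pairwise Pearson correlations match a
#' target matrix (Gaussian copula: correlated standard normals mapped through
#' the logistic function), plus labels drawn from the consensus latent score.
#' Used to exercise the correlation-based removal scheme with a controlled
#' correlation structure.
#'
#' @param l number of pseudo-learners.
#' @param n number of cases.
#' @param target_corr `l` x `l` symmetric positive semidefinite correlation
#'   matrix with unit diagonal.
#' @param seed integer seed.
#' @param names optional learner names (default `L1..Ll`).
#' @return list with `probs` (n x l matrix), `labels` (0/1), and `target_corr`.
#' @export
generate_prediction_bank <- function(l, n, target_corr = diag(l), seed = 1L,
                                     names = NULL) {
  l <- as.integer(l)
  target_corr <- as.matrix(target_corr)
  if (!isTRUE(all.equal(target_corr, t(target_corr), tolerance = 1e-8))) {
    stop("target_corr must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(target_corr) - 1) > 1e-8)) {
    stop("target_corr must have unit diagonal", call. = FALSE)
  }
  eig <- eigen(target_corr, symmetric = TRUE)
  if (any(eig$values < -1e-8)) {
    bad <- min(eig$values)
    stop(sprintf("target_corr is not positive semidefinite (eigenvalue %.6f)", bad),
         call. = FALSE)
  }
  root <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), l) %*% t(eig$vectors)
  if (is.null(names)) names <- paste0("L", seq_len(l))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * l), nrow = n) %*% root
    probs <- stats::plogis(z)
    colnames(probs) <- names
    consensus <- rowMeans(z)
    labels <- stats::rbinom(n, 1L, stats::plogis(consensus))
    list(probs = probs, labels = as.integer(labels), target_corr = target_corr)
  })
}
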