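# Cohort I/O: schema, loading/validation, train/test splitting, minority
# upsampling, and feature encoding for a tabular registry cohort with a
# binary outcome.

#' Define a feature schema for a cohort
#'
#' A schema names the feature columns, declares each one categorical, ordinal
#' or continuous, and names the binary outcome column. Every other operation
#' in the package is typed against a schema.
#'
#' @param feature_names character vector of unique feature column names.
#' @param feature_kinds character vector, one of `"categorical"`, `"ordinal"`,
#'   `"continuous"` per feature.
#' @param outcome_name name of the binary outcome column (1 = event,
#'   0 = no event); must not collide with a feature name.
#' @return An object of class `feature_schema` with fields `feature_names`,
#'   `feature_kinds`, `outcome_name` and `p` (the feature count).
#' @export
#' @examples
#' feature_schema(c("age", "sex"), c("continuous", "categorical"), "event")
feature_schema <- function(feature_names, feature_kinds, outcome_name) {
  feature_names <- as.character(feature_names)
  feature_kinds <- as.character(feature_kinds)
  if (length(feature_names) != length(feature_kinds)) {
    stop("feature_names and feature_kinds must have equal length", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(feature_kinds), c("categorical", "ordinal", "continuous"))
  if (length(bad)) {
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (outcome_name %in% feature_names) {
    stop("outcome_name must not be a feature name", call. = FALSE)
  }
  structure(
    list(
      feature_names = feature_names,
      feature_kinds = stats::setNames(feature_kinds, feature_names),
      outcome_name = as.character(outcome_name),
      p = length(feature_names)
    ),
    class = "feature_schema"
  )
}

#' Construct a validated cohort table
#'
#' @param data data.frame holding the schema's feature columns and outcome
#'   column (extra columns are dropped).
#' @param schema a [feature_schema()].
#' @return Object of class `cohort_table`: `features` (typed data.frame),
#'   `labels` (integer 0/1), `schema`, `n`.
#' @export
cohort_table <- function(data, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  missing_cols <- setdiff(c(schema$feature_names, schema$outcome_name), names(data))
  if (length(missing_cols)) {
    stop("schema error: column(s) missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw_labels <- data[[schema$outcome_name]]
  lab_num <- suppressWarnings(as.numeric(as.character(raw_labels)))
  bad <- which(is.na(lab_num) | !(lab_num %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf(
      "validation error: outcome '%s' must be 0 or 1; first offending row: %d (value '%s')",
      schema$outcome_name, bad[1L], as.character(raw_labels[bad[1L]])
    ), call. = FALSE)
  }
  features <- data[schema$feature_names]
  for (f in schema$feature_names) {
    features[[f]] <- switch(
      schema$feature_kinds[[f]],
      categorical = if (is.factor(features[[f]])) features[[f]] else factor(features[[f]]),
      ordinal = {
        v <- suppressWarnings(as.numeric(features[[f]]))
        if (anyNA(v)) stop(sprintf("ordinal feature '%s' has non-numeric values", f), call. = FALSE)
        v
      },
      continuous = {
        v <- suppressWarnings(as.numeric(features[[f]]))
        if (anyNA(v)) stop(sprintf("continuous feature '%s' has non-numeric values", f), call. = FALSE)
        v
      }
    )
  }
  structure(
    list(features = features, labels = as.integer(lab_num),
         schema = schema, n = nrow(features)),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> n = %d, p = %d, events = %d (%.1f%%)\n",
              x$n, x$schema$p, sum(x$labels), 100 * mean(x$labels)))
  invisible(x)
}

#' Load a cohort from a CSV file
#'
#' Reads a comma-delimited UTF-8 file with a header row, checks it against the
#' schema, and validates the outcome column. Row order is preserved.
#'
#' @inheritParams cohort_table
#' @param path path to the CSV file.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cohort_table(data, schema)
}

#' Subset a cohort by row index
#'
#' @param cohort a [cohort_table()].
#' @param idx integer row indices (1-based; duplicates allowed, so this also
#'   realises resampling).
#' @return A [cohort_table()] with the selected rows.
#' @export
cohort_subset <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cohort_table"))
  structure(
    list(features = cohort$features[idx, , drop = FALSE],
         labels = cohort$labels[idx],
         schema = cohort$schema, n = length(idx)),
    class = "cohort_table"
  )
}

#' Split a cohort into training and testing sets
#'
#' Random 60/40 split by default. With `stratify = TRUE` the split is drawn
#' within each outcome class so the class proportion is preserved to within
#' one case per class; with `stratify = FALSE` it is a plain random split.
#'
#' @param cohort a [cohort_table()].
#' @param train_frac fraction of rows assigned to training (default 0.6).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratify preserve the class ratio across the two partitions?
#' @return Object of class `split_indices`: `train_idx`, `test_idx`, `seed`.
#' @export
split_cohort <- function(cohort, train_frac = 0.6, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  if (cohort$n < 2L) stop("need at least two rows to split", call. = FALSE)
  stopifnot_flag(stratify, "stratify")
  n <- cohort$n
  train_idx <- with_seed(seed, {
    if (stratify) {
      idx <- integer(0)
      for (cls in sort(unique(cohort$labels))) {
        rows <- which(cohort$labels == cls)
        idx <- c(idx, sample(rows, round(train_frac * length(rows))))
      }
      sort(idx)
    } else {
      sort(sample.int(n, round(train_frac * n)))
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  if (!stratify && length(unique(cohort$labels[train_idx])) < 2L) {
    warning("training partition contains a single outcome class", call. = FALSE)
  }
  structure(list(train_idx = train_idx, test_idx = test_idx,
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' Write split indices to CSV
#'
#' Persists a split as a two-column CSV (`row_index`, `partition`) with
#' 1-based row indices.
#'
#' @param split a [split_cohort()] result.
#' @param path output file path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_indices"))
  df <- data.frame(
    row_index = c(split$train_idx, split$test_idx),
    partition = rep(c("train", "test"),
                    c(length(split$train_idx), length(split$test_idx)))
  )
  df <- df[order(df$row_index), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Upsample the minority class to exact balance
#'
#' Minority-class rows are resampled with replacement until the two class
#' counts are equal; every original row (both classes) is kept. The result
#' has prevalence exactly 0.5.
#'
#' @param cohort a [cohort_table()] with both classes present.
#' @param seed integer seed for the resampling.
#' @return A balanced [cohort_table()].
#' @export
upsample_minority <- function(cohort, seed = 1L) {
  idx <- upsample_indices(cohort$labels, seed)
  cohort_subset(cohort, idx)
}

# Index-level form used inside CV folds (avoids materialising data frames).
upsample_indices <- function(labels, seed = 1L) {
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0L)) {
    stop("upsampling requires both outcome classes present", call. = FALSE)
  }
  minority <- as.integer(names(counts)[which.min(counts)])
  deficit <- abs(counts[[1L]] - counts[[2L]])
  if (deficit == 0L) return(seq_along(labels))
  min_rows <- which(labels == minority)
  # index into min_rows explicitly: sample(x, ...) on a length-1 x would
  # sample from 1:x instead
  extra <- with_seed(seed,
                     min_rows[sample.int(length(min_rows), deficit, replace = TRUE)])
  c(seq_along(labels), extra)
}

#' Fit a feature encoder on training data
#'
#' Builds an invertible encoding map: categorical features become one-hot
#' indicator columns (reference level dropped), ordinal features become their
#' numeric codes, continuous features pass through. The map is frozen on the
#' training cohort and must be reused verbatim on test data so no test-set
#' levels leak into level discovery.
#'
#' @param cohort training [cohort_table()].
#' @return Object of class `feature_encoder` with the level tables and a
#'   column-to-parent-feature map.
#' @export
fit_encoder <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- cohort$schema
  levels_map <- list()
  col_names <- character(0)
  col_feature <- character(0)
  for (f in schema$feature_names) {
    kind <- schema$feature_kinds[[f]]
    if (kind == "categorical") {
      levs <- levels(droplevels(cohort$features[[f]]))
      if (length(levs) < 1L) stop(sprintf("feature '%s' has no observed levels", f), call. = FALSE)
      levels_map[[f]] <- levs
      keep <- levs[-1L] # first observed level is the reference
      if (length(keep)) {
        nm <- paste(f, keep, sep = "..")
        col_names <- c(col_names, nm)
        col_feature <- c(col_feature, rep(f, length(nm)))
      }
    } else {
      col_names <- c(col_names, f)
      col_feature <- c(col_feature, f)
    }
  }
  structure(
    list(schema = schema, levels_map = levels_map,
         col_names = col_names,
         col_feature = stats::setNames(col_feature, col_names)),
    class = "feature_encoder"
  )
}

#' Apply a fitted encoder to a cohort
#'
#' @param encoder a [fit_encoder()] result.
#' @param cohort a [cohort_table()] sharing the encoder's schema.
#' @return Numeric matrix with one row per cohort row and the encoder's
#'   columns. Categorical values unseen at fit time map to the all-zero
#'   reference row with a warning.
#' @export
apply_encoder <- function(encoder, cohort) {
  stopifnot(inherits(encoder, "feature_encoder"), inherits(cohort, "cohort_table"))
  schema <- encoder$schema
  n <- cohort$n
  x <- matrix(0, nrow = n, ncol = length(encoder$col_names),
              dimnames = list(NULL, encoder$col_names))
  for (f in schema$feature_names) {
    kind <- schema$feature_kinds[[f]]
    if (kind == "categorical") {
      vals <- as.character(cohort$features[[f]])
      levs <- encoder$levels_map[[f]]
      unseen <- !(vals %in% levs)
      if (any(unseen)) {
        warning(sprintf("feature '%s': %d value(s) unseen at encoding time mapped to reference level",
                        f, sum(unseen)), call. = FALSE)
      }
      for (lev in levs[-1L]) {
        x[, paste(f, lev, sep = "..")] <- as.numeric(!unseen & vals == lev)
      }
    } else {
      x[, f] <- as.numeric(cohort$features[[f]])
    }
  }
  x
}

#' Encode a cohort's features
#'
#' Convenience wrapper: fits the encoder on `cohort` and applies it.
#'
#' @param cohort a [cohort_table()].
#' @return list with `x` (design matrix) and `encoder` (the frozen map).
#' @export
encode_features <- function(cohort) {
  enc <- fit_encoder(cohort)
  list(x = apply_encoder(enc, cohort), encoder = enc)
}
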