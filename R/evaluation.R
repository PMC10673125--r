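# Binary classification metrics with invalid-fold bookkeeping, weighted
# aggregation across pathway categories, relative feature importance, and
# feature presence odds ratios.

#' Binary classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall, F1, Matthews correlation
#' coefficient (MCC) and unit-normalized MCC. Metrics whose denominator is
#' zero are flagged invalid (value `NA`) rather than propagating `NaN`;
#' accuracy and MCC are always valid — when any factor of the MCC
#' denominator is zero the MCC is defined as 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (sum > 0).
#' @return data.frame with columns `metric`, `value`, `valid`.
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("confusion counts sum to zero")

  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else 0
  data.frame(
    metric = c("accuracy", "precision", "recall", "f1", "mcc",
               "normalized_mcc"),
    value = c(accuracy, precision, recall, f1, mcc, (mcc + 1) / 2),
    valid = c(TRUE, !is.na(precision), !is.na(recall), !is.na(f1), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Unit-normalize an MCC value
#'
#' Rescales the Matthews correlation coefficient from \[-1, 1\] to \[0, 1\]
#' via (MCC + 1) / 2, making it comparable to the other metrics.
#'
#' @param mcc value in \[-1, 1\].
#' @return value in \[0, 1\].
#' @export
normalized_mcc <- function(mcc) {
  if (any(mcc < -1 | mcc > 1)) stop("MCC must lie in [-1, 1]")
  (mcc + 1) / 2
}

#' Weighted aggregation of per-category, per-fold scores
#'
#' Each (category, fold) score carries its category's dataset proportion as
#' weight; invalid scores are excluded before aggregation. The weighted
#' standard deviation uses the frequency-weighted population form
#' sqrt(sum(w (x - xw)^2) / sum(w)). Categories with zero valid scores are
#' reported in `n_valid` and excluded.
#'
#' @param scores data.frame with columns `category`, `value`, `valid`.
#' @param weights named non-negative numeric vector (category -> proportion),
#'   not all zero.
#' @return list with `weighted_mean`, `weighted_sd`, `unweighted_mean`,
#'   `unweighted_sd` (population form), `median`, `maximum`, `n_valid`
#'   (named per category).
#' @export
weighted_aggregate <- function(scores, weights) {
  stopifnot(all(c("category", "value", "valid") %in% names(scores)))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  n_valid <- vapply(split(scores$valid, scores$category), sum, 0L)
  ok <- scores$valid & !is.na(scores$value)
  sc <- scores[ok, , drop = FALSE]
  if (nrow(sc) == 0L) stop("no valid scores to aggregate")
  missing_w <- setdiff(unique(sc$category), names(weights))
  if (length(missing_w)) {
    stop("no weight given for categories: ", paste(missing_w, collapse = ", "))
  }
  w <- weights[sc$category]
  x <- sc$value
  wm <- sum(w * x) / sum(w)
  wsd <- sqrt(sum(w * (x - wm)^2) / sum(w))
  m <- mean(x)
  list(weighted_mean = wm,
       weighted_sd = wsd,
       unweighted_mean = m,
       unweighted_sd = sqrt(mean((x - m)^2)),
       median = stats::median(x),
       maximum = max(x),
       n_valid = n_valid)
}

#' Relative feature importance across folds
#'
#' Each fold's raw importance scores are divided by that fold's maximum, so
#' the most important feature of a fold scores 1.0. Features absent from a
#' fold's model score 0 in that fold. Per feature, the median across folds
#' is reported (importance distributions are skewed, so the median is the
#' stabler summary).
#'
#' @param per_fold_raw list (one element per fold) of named numeric vectors
#'   of raw importance scores.
#' @return data.frame with columns `feature`, `median_relative_importance`,
#'   sorted by decreasing median then feature name, plus attribute
#'   `relative` (feature x fold matrix).
#' @export
relative_importance <- function(per_fold_raw) {
  if (length(per_fold_raw) == 0L) stop("no folds supplied")
  features <- sort(unique(unlist(lapply(per_fold_raw, names))))
  rel <- matrix(0, nrow = length(features), ncol = length(per_fold_raw),
                dimnames = list(features, NULL))
  for (j in seq_along(per_fold_raw)) {
    v <- per_fold_raw[[j]]
    mx <- if (length(v)) max(v) else 0
    if (mx <= 0) stop("fold ", j, " has no feature with positive importance")
    rel[names(v), j] <- v / mx
  }
  med <- apply(rel, 1L, stats::median)
  out <- data.frame(feature = features,
                    median_relative_importance = as.numeric(med),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_relative_importance, out$feature), ]
  rownames(out) <- NULL
  attr(out, "relative") <- rel
  out
}

#' Odds ratio from positive and negative odds
#'
#' @param positive_odds,negative_odds non-negative odds values.
#' @return their quotient; `Inf` when the negative odds are 0 and the
#'   positive odds are positive; `NA` when both are 0.
#' @export
odds_ratio <- function(positive_odds, negative_odds) {
  if (any(positive_odds < 0) || any(negative_odds < 0)) {
    stop("odds must be non-negative")
  }
  ifelse(negative_odds > 0, positive_odds / negative_odds,
         ifelse(positive_odds > 0, Inf, NA_real_))
}

#' Feature presence odds for one pathway category
#'
#' An entry "has" a feature when the atom color appears at least once in
#' the compound. The positive odds are (positives with the feature) /
#' (positives without it); the negative odds likewise among negatives. The
#' odds ratio is their quotient (`Inf` when no negative entry has the
#' feature but some positive does): values well above 1 mark features
#' associated with pathway involvement, values near 0 with exclusion.
#'
#' @param presence logical vector: entry has the feature.
#' @param labels logical vector: entry is positive for the category.
#' @param category category name for error messages.
#' @param feature feature name carried into the output.
#' @return one-row data.frame with columns `category`, `feature`,
#'   `positive_odds`, `negative_odds`, `odds_ratio`.
#' @export
feature_odds <- function(presence, labels, category = "", feature = "") {
  stopifnot(length(presence) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L) stop("category '", category, "' has no positive entries")
  if (n_neg == 0L) stop("category '", category, "' has no negative entries")
  pos_with <- sum(presence & labels)
  neg_with <- sum(presence & !labels)
  pos_odds <- if (n_pos - pos_with > 0) pos_with / (n_pos - pos_with) else Inf
  neg_odds <- if (n_neg - neg_with > 0) neg_with / (n_neg - neg_with) else Inf
  data.frame(category = category, feature = feature,
             positive_odds = pos_odds, negative_odds = neg_odds,
             odds_ratio = odds_ratio(pos_odds, neg_odds),
             stringsAsFactors = FALSE)
}

#' Odds table for a set of features
#'
#' Runs [feature_odds()] for every requested feature column of a dataset's
#' feature matrix against one category's labels.
#'
#' @param ds a `benchmark_dataset` with features.
#' @param category category name (column of the label matrix).
#' @param features feature column names (default: all).
#' @return data.frame, one row per feature.
#' @export
dataset_feature_odds <- function(ds, category, features = NULL) {
  stopifnot(inherits(ds, "benchmark_dataset"), !is.null(ds$features))
  if (is.null(features)) features <- colnames(ds$features)
  labels <- ds$labels[, category]
  out <- lapply(features, function(f) {
    feature_odds(ds$features[, f] >= 1L, labels, category, f)
  })
  do.call(rbind, out)
}

#' Write / read a CV results table
#'
#' Tab-separated results store with one row per (task, fold, partition,
#' metric): columns `family`, `category`, `training_dataset`, `fold`,
#' `partition`, `metric`, `value`, `valid`. Infinite values serialize as
#' the literal string `inf`.
#'
#' @param results results data.frame.
#' @param path file path.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  if ("value" %in% names(out)) {
    v <- out$value
    out$value <- ifelse(is.finite(v) | is.na(v), as.character(v),
                        ifelse(v > 0, "inf", "-inf"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("value" %in% names(df) && is.character(df$value)) {
    v <- suppressWarnings(as.numeric(df$value))
    v[df$value == "inf"] <- Inf
    v[df$value == "-inf"] <- -Inf
    df$value <- v
  }
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  df
}

#' Aggregate a CV results table
#'
#' Applies [weighted_aggregate()] per (family, training_dataset, partition,
#' metric) group of a results store, using the given category proportions
#' as weights.
#'
#' @param results results data.frame (see [write_results_tsv()] schema).
#' @param weights named vector of category proportions.
#' @return data.frame of aggregate rows.
#' @export
aggregate_results <- function(results, weights) {
  keys <- interaction(results$family, results$training_dataset,
                      results$partition, results$metric, drop = TRUE)
  parts <- split(results, keys)
  rows <- lapply(parts, function(p) {
    agg <- weighted_aggregate(
      data.frame(category = p$category, value = p$value, valid = p$valid),
      weights)
    data.frame(family = p$family[1], training_dataset = p$training_dataset[1],
               partition = p$partition[1], metric = p$metric[1],
               weighted_mean = agg$weighted_mean, weighted_sd = agg$weighted_sd,
               unweighted_mean = agg$unweighted_mean,
               unweighted_sd = agg$unweighted_sd,
               median = agg$median, maximum = agg$maximum,
               n_valid = sum(agg$n_valid), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family, out$training_dataset, out$partition, out$metric), ]
}

#' Write report tables
#'
#' Emits the per-task aggregate table and, when supplied, importance and
#' odds tables as TSV files with a stable column order. Re-running on the
#' same inputs produces byte-identical output.
#'
#' @param results CV results data.frame.
#' @param weights named category-proportion vector.
#' @param out_dir output directory.
#' @param importance optional data.frame from [relative_importance()].
#' @param odds optional data.frame from [dataset_feature_odds()].
#' @return invisibly, the paths written.
#' @export
report_tables <- function(results, weights, out_dir, importance = NULL,
                          odds = NULL) {
  if (nrow(results) == 0L) stop("results store is empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(out_dir, "aggregates.tsv")
  utils::write.table(aggregate_results(results, weights), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(importance)) {
    p <- file.path(out_dir, "importance.tsv")
    utils::write.table(importance, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(odds)) {
    p <- file.path(out_dir, "odds.tsv")
    odds_out <- odds
    odds_out$odds_ratio <- ifelse(is.finite(odds_out$odds_ratio),
                                  as.character(odds_out$odds_ratio), "inf")
    utils::write.table(odds_out, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
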