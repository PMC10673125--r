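# Information-content filtering: per-compound misclassification rates under
# stochastic retraining, sliding-window averaging against non-hydrogen atom
# count, and selection of the first-local-minimum threshold.

#' Per-compound misclassification rates
#'
#' For each pathway category a binary random-forest classifier is retrained
#' `n_reps` times on the dataset and every compound's out-of-bag prediction
#' is scored, so each compound's rate for a category is the fraction of the
#' `n_reps` stochastic retrainings that misclassify it (`rule = "oob"`, the
#' default). With `rule = "holdout"` a stratified split is drawn per repeat
#' instead and only held-out compounds accrue an outcome — unbiased for any
#' model family, but each compound is observed in only a `test_frac`
#' fraction of the repeats. Categories without both classes are marked
#' undefined and excluded from the per-compound mean.
#'
#' @param ds a `benchmark_dataset` with features.
#' @param n_reps number of train/evaluate repetitions (>= 1).
#' @param seed RNG seed.
#' @param rule prediction rule: `"oob"` (out-of-bag, random forest only) or
#'   `"holdout"`.
#' @param test_frac held-out fraction per repeat (holdout rule).
#' @param spec classifier spec; default random forest. The OOB rule
#'   requires the random-forest family.
#' @return data.frame with columns `compound_id`, `non_h_count`,
#'   `overall_rate` plus attribute `per_category` (compound x category rate
#'   matrix, `NaN` where a compound was never evaluated for a category).
#' @export
per_compound_misclassification <- function(ds, n_reps = 1000L, seed = 1L,
                                           rule = c("oob", "holdout"),
                                           test_frac = 0.05,
                                           spec = model_spec(
                                             "random_forest",
                                             list(num_trees = 100L))) {
  stopifnot(inherits(ds, "benchmark_dataset"), !is.null(ds$features),
            n_reps >= 1L)
  rule <- match.arg(rule)
  if (rule == "oob" && spec$family != "random_forest") {
    stop("the out-of-bag rule requires the random_forest family")
  }
  X <- unclass(ds$features)
  n <- length(ds$ids)
  categories <- colnames(ds$labels)
  wrong <- matrix(0, n, length(categories),
                  dimnames = list(ds$ids, categories))
  seen <- wrong

  for (cat_i in seq_along(categories)) {
    y <- ds$labels[, cat_i]
    if (all(y) || !any(y)) next  # single-class: rate stays undefined
    for (rep in seq_len(n_reps)) {
      rep_seed <- seed + 7919L * (cat_i - 1L) + rep
      sp <- spec
      sp$seed <- rep_seed
      if (rule == "oob") {
        hp <- sp$hyperparameters
        fit <- ranger::ranger(
          x = as.matrix(X), y = factor(y, levels = c(FALSE, TRUE)),
          num.trees = hp$num_trees,
          mtry = max(1L, floor(hp$mtry_frac * ncol(X))),
          min.node.size = hp$min_node_size, splitrule = hp$splitrule,
          seed = rep_seed, num.threads = 1L)
        pred <- fit$predictions == "TRUE"
        ok <- !is.na(pred)
        wrong[ok, cat_i] <- wrong[ok, cat_i] + (pred[ok] != y[ok])
        seen[ok, cat_i] <- seen[ok, cat_i] + 1L
      } else {
        test <- with_seed(rep_seed, .stratified_test_idx(y, test_frac))
        train <- setdiff(seq_len(n), test)
        model <- fit_model(sp, X[train, , drop = FALSE], y[train])
        pred <- stats::predict(model, X[test, , drop = FALSE])
        wrong[test, cat_i] <- wrong[test, cat_i] + (pred != y[test])
        seen[test, cat_i] <- seen[test, cat_i] + 1L
      }
    }
  }

  rates <- wrong / seen  # NaN where never seen or category undefined
  overall <- apply(rates, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0L) NA_real_ else mean(r)
  })
  out <- data.frame(compound_id = ds$ids,
                    non_h_count = as.integer(ds$non_h_count),
                    overall_rate = as.numeric(overall),
                    stringsAsFactors = FALSE)
  attr(out, "per_category") <- rates
  # smallest nonzero difference two overall rates can represent
  attr(out, "rate_resolution") <- 1 / (length(categories) * n_reps)
  out
}

#' Sliding-window mean misclassification rates
#'
#' The window starting at non-hydrogen atom count `s` averages the overall
#' misclassification rate of compounds with counts in
#' `[s, s + window_size - 1]` (both ends inclusive). Window starts run from
#' 0 to the maximum observed count in steps of 1; windows containing no
#' compounds are flagged with `n_compounds = 0` and `mean_rate = NA`, never
#' fabricated.
#'
#' @param records data.frame with columns `non_h_count`, `overall_rate`
#'   (from [per_compound_misclassification()]).
#' @param window_size window width in atom counts (>= 1, default 5).
#' @return data.frame of class `window_series` with columns `start`,
#'   `mean_rate`, `n_compounds`.
#' @export
sliding_window_rates <- function(records, window_size = 5L) {
  stopifnot(all(c("non_h_count", "overall_rate") %in% names(records)),
            window_size >= 1L)
  records <- records[!is.na(records$overall_rate), , drop = FALSE]
  if (nrow(records) == 0L) stop("no compounds with defined rates")
  starts <- 0:max(records$non_h_count)
  rows <- lapply(starts, function(s) {
    inside <- records$non_h_count >= s &
      records$non_h_count <= s + window_size - 1L
    data.frame(start = s,
               mean_rate = if (any(inside))
                 mean(records$overall_rate[inside]) else NA_real_,
               n_compounds = sum(inside))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_series", class(out))
  attr(out, "window_size") <- window_size
  attr(out, "rate_resolution") <- attr(records, "rate_resolution")
  out
}

#' Select the atom-count threshold at the first local minimum
#'
#' Scans the non-empty window means in order of window start and returns
#' the start count of the first local minimum: a point strictly below its
#' predecessor and not above its successor. A series that never decreases
#' returns 0; a series still strictly decreasing at its end returns the
#' last start with a warning (boundary minimum).
#'
#' Window means are estimates whose finest meaningful difference is the
#' per-compound rate quantization (1 / (categories x repeats)); `tol`
#' treats differences up to half that resolution as ties, so a decrease
#' must exceed `tol` to count and a successor within `tol` still ends the
#' drop. `tol = 0` gives the exact comparison rule.
#'
#' @param series a `window_series` from [sliding_window_rates()] (>= 3
#'   non-empty points).
#' @param tol tie tolerance on rate comparisons; defaults to half the
#'   series' recorded rate resolution, or 0 when none is recorded.
#' @return integer window start — the selected minimum non-hydrogen atom
#'   count.
#' @export
select_threshold <- function(series, tol = NULL) {
  if (is.null(tol)) {
    res <- attr(series, "rate_resolution")
    tol <- if (is.null(res)) 0 else res / 2
  }
  pts <- series[series$n_compounds > 0L, , drop = FALSE]
  if (nrow(pts) == 0L) stop("all windows are empty")
  if (nrow(pts) < 3L) stop("need at least 3 non-empty windows")
  r <- pts$mean_rate
  for (i in 2:(nrow(pts) - 1L)) {
    if (r[i] < r[i - 1L] - tol && r[i] <= r[i + 1L] + tol) {
      return(pts$start[i])
    }
  }
  last <- nrow(pts)
  if (r[last] < r[last - 1L] - tol) {
    warning("series is still decreasing at its end; ",
            "returning the boundary minimum")
    return(pts$start[last])
  }
  0L
}

#' Write the misclassification records and window series
#'
#' @param records data.frame from [per_compound_misclassification()].
#' @param series data.frame from [sliding_window_rates()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_info_filter_tsv <- function(records, series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rates <- attr(records, "per_category")
  rec_out <- cbind(records, as.data.frame(rates))
  p1 <- file.path(dir, "misclassification.tsv")
  utils::write.table(rec_out, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, "window_series.tsv")
  utils::write.table(as.data.frame(series), p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
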