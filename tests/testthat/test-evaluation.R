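# Metrics, aggregation, importance and odds-ratio bookkeeping.

test_that("binary metrics match their definitions and validity rules", {
  perfect <- binary_metrics(5, 5, 0, 0)
  expect_equal(perfect$value[perfect$metric %in%
                               c("accuracy", "precision", "recall", "f1",
                                 "mcc")],
               rep(1, 5))
  expect_true(all(perfect$valid))

  coin <- binary_metrics(1, 1, 1, 1)
  expect_equal(coin$value[coin$metric == "mcc"], 0)
  expect_equal(coin$value[coin$metric == "accuracy"], 0.5)

  # no positive predictions: precision undefined, MCC still valid (= 0)
  nopos <- binary_metrics(0, 8, 0, 2)
  expect_false(nopos$valid[nopos$metric == "precision"])
  expect_true(nopos$valid[nopos$metric == "mcc"])
  expect_equal(nopos$value[nopos$metric == "mcc"], 0)
  expect_true(nopos$valid[nopos$metric == "accuracy"])

  # direct formula spot check
  m <- binary_metrics(3, 4, 2, 1)
  mcc_direct <- (3 * 4 - 2 * 1) / sqrt((3 + 2) * (3 + 1) * (4 + 2) * (4 + 1))
  expect_equal(m$value[m$metric == "mcc"], mcc_direct)
  expect_equal(m$value[m$metric == "f1"],
               2 * (3 / 5) * (3 / 4) / (3 / 5 + 3 / 4))

  expect_error(binary_metrics(-1, 1, 1, 1), "non-negative")
  expect_error(binary_metrics(0, 0, 0, 0), "sum to zero")
})

test_that("MCC is symmetric under class swap; normalization is affine", {
  set.seed(17)
  for (rep in 1:20) {
    cts <- sample(0:10, 4, replace = TRUE)
    if (sum(cts) == 0) next
    a <- binary_metrics(cts[1], cts[2], cts[3], cts[4])
    b <- binary_metrics(cts[2], cts[1], cts[4], cts[3])
    expect_equal(a$value[a$metric == "mcc"], b$value[b$metric == "mcc"])
  }
  expect_equal(normalized_mcc(-1), 0)
  expect_equal(normalized_mcc(1), 1)
  expect_equal(normalized_mcc(0), 0.5)
  expect_error(normalized_mcc(1.2), "\\[-1, 1\\]")
})

test_that("weighted aggregation follows the weighted population formulas", {
  two <- data.frame(category = rep(c("A", "B"), each = 3),
                    value = rep(c(0.8, 0.4), each = 3),
                    valid = TRUE)
  agg <- weighted_aggregate(two, c(A = 0.75, B = 0.25))
  expect_equal(agg$weighted_mean, 0.75 * 0.8 + 0.25 * 0.4)
  # constant within category: weighted variance from the two levels only
  expect_equal(agg$weighted_sd,
               sqrt(0.75 * (0.8 - 0.7)^2 + 0.25 * (0.4 - 0.7)^2))

  # equal weights reduce to the plain mean / population SD
  set.seed(3)
  sc <- data.frame(category = rep(c("A", "B"), 10),
                   value = runif(20), valid = TRUE)
  eq <- weighted_aggregate(sc, c(A = 0.5, B = 0.5))
  expect_equal(eq$weighted_mean, mean(sc$value))
  expect_equal(eq$weighted_sd, sqrt(mean((sc$value - mean(sc$value))^2)))
  expect_equal(eq$weighted_mean, eq$unweighted_mean)
  expect_equal(eq$weighted_sd, eq$unweighted_sd)

  # zero weight removes a category's influence
  z <- weighted_aggregate(two, c(A = 1, B = 0))
  expect_equal(z$weighted_mean, 0.8)

  # one category reduces to that category's plain aggregates
  one <- data.frame(category = "A", value = c(0.2, 0.6, 0.7), valid = TRUE)
  agg1 <- weighted_aggregate(one, c(A = 0.3))
  expect_equal(agg1$weighted_mean, mean(one$value))
  expect_equal(agg1$median, 0.6)

  # invalid scores are excluded before aggregation
  mixed <- data.frame(category = "A", value = c(0.5, NA, 0.9),
                      valid = c(TRUE, FALSE, TRUE))
  expect_equal(weighted_aggregate(mixed, c(A = 1))$weighted_mean, 0.7)
  expect_equal(unname(weighted_aggregate(mixed, c(A = 1))$n_valid), 2L)

  expect_error(weighted_aggregate(two, c(A = -1, B = 2)), "non-negative")
})

test_that("relative importance normalizes per fold and takes the median", {
  one_fold <- relative_importance(list(c(a = 2, b = 1)))
  expect_equal(one_fold$median_relative_importance[one_fold$feature == "a"],
               1.0)
  expect_equal(one_fold$median_relative_importance[one_fold$feature == "b"],
               0.5)

  # feature absent in half of an even number of folds, top in the rest
  folds <- list(c(x = 3, y = 1), c(x = 3, y = 1),
                c(x = 3), c(x = 3))
  ri <- relative_importance(folds)
  expect_equal(ri$median_relative_importance[ri$feature == "y"],
               median(c(1 / 3, 1 / 3, 0, 0)))
  expect_equal(ri$median_relative_importance[ri$feature == "x"], 1.0)
  # per-fold maxima are exactly 1
  rel <- attr(ri, "relative")
  expect_equal(unname(apply(rel, 2, max)), rep(1, 4))
  expect_true(all(rel >= 0))

  expect_error(relative_importance(list(c(a = 0, b = 0))), "positive")
})

test_that("odds ratios reproduce the published arithmetic", {
  # printed positive/negative odds pairs and their printed ratios
  # the published ratios were computed before the odds were rounded for
  # printing, so the quotient of the printed odds matches them to ~1e-6
  # relative, the precision the printed inputs support
  expect_equal(odds_ratio(0.160809368, 0.007166948), 22.437637329,
               tolerance = 1e-6)
  expect_equal(odds_ratio(0.055646483, 0.007492113), 7.427340984,
               tolerance = 1e-6)
  expect_equal(odds_ratio(0.271787286, 0.003995206), 68.028358459,
               tolerance = 1e-6)
  # division by zero negative odds gives infinity
  expect_equal(odds_ratio(0.088626295, 0), Inf)
  expect_true(is.na(odds_ratio(0, 0)))
  expect_error(odds_ratio(-0.1, 0.2), "non-negative")
})

test_that("feature odds count presence among positives and negatives", {
  presence <- c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 4), rep(FALSE, 6))
  labels <- c(rep(TRUE, 10), rep(FALSE, 10))
  rec <- feature_odds(presence, labels, "CatA", "k0|Cl0")
  expect_equal(rec$positive_odds, 4 / 6)
  expect_equal(rec$negative_odds, 4 / 6)
  expect_equal(rec$odds_ratio, 1)

  # no negative has the feature -> infinite ratio
  rec2 <- feature_odds(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE), "CatA", "f")
  expect_equal(rec2$odds_ratio, Inf)

  expect_error(feature_odds(presence, rep(TRUE, 20), "CatA"), "no negative")
  expect_error(feature_odds(presence, rep(FALSE, 20), "CatA"), "no positive")

  # swapping the labels inverts every finite ratio
  set.seed(23)
  for (rep in 1:10) {
    pres <- runif(30) < 0.5
    labs <- runif(30) < 0.5
    if (all(labs) || !any(labs)) next
    r1 <- feature_odds(pres, labs)$odds_ratio
    r2 <- feature_odds(pres, !labs)$odds_ratio
    if (is.finite(r1) && r1 > 0 && is.finite(r2)) {
      expect_equal(r2, 1 / r1)
    }
  }
})

test_that("dataset odds use presence = count >= 1", {
  ds <- separable_dataset(n = 40L, n_categories = 2L, seed = 5L)
  cat1 <- colnames(ds$labels)[1]
  odds <- dataset_feature_odds(ds, cat1)
  expect_equal(nrow(odds), ncol(ds$features))
  # the planted motif color (chlorine) should be positively associated
  cl_rows <- odds[grepl("Cl", odds$feature), ]
  expect_true(any(cl_rows$odds_ratio > 1 | is.infinite(cl_rows$odds_ratio)))
})

test_that("results tables round-trip, including infinities", {
  res <- data.frame(family = "gradient_boosted_trees", category = "CatA",
                    training_dataset = "full", fold = 1:3,
                    partition = "full", metric = "mcc",
                    value = c(0.5, Inf, NA), valid = c(TRUE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(res, path)
  back <- read_results_tsv(path)
  expect_equal(back$value, c(0.5, Inf, NA))
  expect_equal(back$valid, res$valid)

  expect_error(report_tables(res[0, ], c(CatA = 1), tempdir()), "empty")
})
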