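# Evaluation machinery: confusion metrics, AUC, PAM, CV folds, method
# comparison and the moisture ratio.

test_that("confusion metrics match hand computation and printed table values", {
  # perfect classifier
  b <- basic_metrics(confusion_counts(tp = 40, tn = 60, fp = 0, fn = 0))
  expect_equal(unname(unlist(unclass(b))), rep(1, 6))

  # F1 from the printed precision/recall pair at 999 superpixels
  p <- 0.9344
  r <- 0.9661
  f1 <- 2 * r * p / (r + p)
  expect_equal(round(f1, 4), 0.9500)

  # same arithmetic through confusion counts
  cc <- confusion_counts(tp = 9661, tn = 9000, fp = 678, fn = 339)
  b <- basic_metrics(cc)
  expect_equal(b$recall, 9661 / (9661 + 339))
  expect_equal(b$precision, 9661 / (9661 + 678))
  expect_equal(b$f1, 2 * b$recall * b$precision / (b$recall + b$precision))
  expect_equal(b$jaccard, b$f1 / (2 - b$f1))
})

test_that("metric identities hold over a brute-force grid of counts", {
  grid <- expand.grid(tp = c(0L, 1L, 7L, 20L), tn = c(0L, 3L, 15L),
                      fp = c(0L, 2L, 9L), fn = c(0L, 4L, 11L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (sum(unlist(g)) == 0) next
    b <- basic_metrics(confusion_counts(tp = g$tp, tn = g$tn,
                                        fp = g$fp, fn = g$fn))
    if (!is.na(b$f1) && !is.na(b$jaccard)) {
      expect_equal(b$jaccard, b$f1 / (2 - b$f1), tolerance = 1e-12)
    }
    if (!is.na(b$precision) && !is.na(b$recall) && b$precision + b$recall > 0) {
      expect_equal(b$f1,
                   2 * b$precision * b$recall / (b$precision + b$recall),
                   tolerance = 1e-12)
    }
    vals <- unlist(unclass(b))
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  }
})

test_that("zero denominators are flagged undefined, never silently zero", {
  b <- basic_metrics(confusion_counts(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(b$recall))
  expect_true("recall" %in% attr(b, "undefined"))
  expect_true("precision" %in% attr(b, "undefined"))
  expect_equal(b$accuracy, 1)
})

test_that("AUC: perfect ranking, chance level, and Mann-Whitney equivalence", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.9), c(1, 1, 0)), 0)

  with_seed(99, {
    n <- 1e4
    sc <- runif(n)
    lab <- rbinom(n, 1, 0.5)
    expect_equal(auc_score(sc, lab), 0.5, tolerance = 0.05)
  })

  # small fixed set with ties: compare to the rank-statistic (Mann-Whitney)
  sc <- c(0.3, 0.5, 0.5, 0.7, 0.2, 0.9)
  lab <- c(0, 0, 1, 1, 0, 1)
  rk <- rank(sc)
  n1 <- sum(lab == 1)
  n0 <- sum(lab == 0)
  u <- sum(rk[lab == 1]) - n1 * (n1 + 1) / 2
  expect_equal(auc_score(sc, lab), u / (n1 * n0))

  expect_error(auc_score(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("PAM: unit hexagon, truncated normalizer, shoelace oracle, monotonicity", {
  full <- pam_score(rep(1, 6))
  expect_equal(full$PA, 3 * sqrt(3) / 2)
  expect_equal(full$PAM, 1)
  expect_equal(trunc(full$PA * 1e5) / 1e5, 2.59807)
  expect_equal(pam_score(rep(0, 6))$PAM, 0)

  shoelace <- function(r) {
    ang <- (seq_along(r) - 1) * 2 * pi / length(r)
    x <- r * cos(ang)
    y <- r * sin(ang)
    j <- c(seq_along(r)[-1], 1)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }
  with_seed(7, {
    for (i in 1:200) {
      r <- runif(6)
      expect_equal(pam_score(r)$PA, shoelace(r), tolerance = 1e-12)
    }
    # monotone non-decreasing in each radius
    for (i in 1:50) {
      r <- runif(6)
      j <- sample(6, 1)
      r2 <- r
      r2[j] <- min(1, r[j] + runif(1, 0, 1 - r[j]))
      expect_gte(pam_score(r2)$PAM, pam_score(r)$PAM)
    }
  })
  expect_error(pam_score(c(1, 1, 1, 1, 1, 1.2)), "\\[0, 1\\]")
})

test_that("k-fold assignment is a seeded near-equal partition", {
  f <- kfold_indices(10, k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(f, kfold_indices(10, k = 5, seed = 3))
  expect_false(identical(f, kfold_indices(10, k = 5, seed = 4)))
  for (n in c(7, 23, 40)) {
    f <- kfold_indices(n, k = 5, seed = 1)
    expect_equal(length(f), n)
    expect_true(max(table(f)) - min(table(f)) <= 1)
  }
  expect_error(kfold_indices(10, k = 1), "k must be")
})

test_that("kfold_cv validates each record exactly once and returns metrics", {
  with_seed(11, {
    x <- matrix(rnorm(60 * 3), 60)
    y <- as.integer(x[, 1] + 0.2 * rnorm(60) > 0)
  })
  cv <- kfold_cv(x, y,
                 train_fn = function(xt, yt) {
                   suppressWarnings(
                     stats::glm.fit(cbind(1, xt), yt,
                                    family = stats::binomial())$coefficients)
                 },
                 predict_fn = function(m, xt) {
                   1 / (1 + exp(-(cbind(1, xt) %*% m)[, 1]))
                 },
                 k = 5, seed = 2)
  expect_length(cv$folds, 60)
  expect_length(cv$per_fold, 5)
  expect_true(cv$mean$accuracy > 0.7)
  expect_true(all(vapply(cv$per_fold, function(b) {
    v <- unlist(unclass(b))
    all(is.na(v) | (v >= 0 & v <= 1))
  }, logical(1))))
})

test_that("method comparison reproduces the printed deltas", {
  ours <- list(recall = 0.9661, precision = 0.9344, f1 = 0.9500,
               accuracy = 0.9591)
  yolo8 <- list(recall = 0.7788, precision = 0.7606, f1 = 0.7696,
                accuracy = 0.7795)
  psr <- list(recall = 0.9412, precision = 0.9412, f1 = 0.9412,
              accuracy = 0.9500)
  cmp <- compare_methods(ours, yolo8)
  expect_equal(cmp$delta[cmp$metric == "recall"], 0.1873)
  expect_equal(cmp$delta[cmp$metric == "precision"], 0.1738)
  expect_equal(cmp$delta[cmp$metric == "f1"], 0.1804)
  expect_equal(cmp$delta[cmp$metric == "accuracy"], 0.1796)
  expect_equal(cmp$relative_pct[cmp$metric == "recall"], 24.05)
  cmp2 <- compare_methods(ours, psr)
  expect_equal(cmp2$delta[cmp2$metric == "recall"], 0.0249)
  same <- compare_methods(ours, ours)
  expect_true(all(same$delta == 0))
  expect_true(all(same$relative_pct == 0))
  zero <- compare_methods(list(recall = 0.5), list(recall = 0))
  expect_true(is.na(zero$relative_pct))
})

test_that("moisture ratio is the normalized drying residual", {
  expect_equal(moisture_ratio(Mt = 300, Mo = 300, Me = 20), 1)
  expect_equal(moisture_ratio(Mt = 20, Mo = 300, Me = 20), 0)
  expect_equal(moisture_ratio(Mt = 160, Mo = 300, Me = 20), 0.5)
  expect_equal(moisture_ratio(c(300, 160, 20), 300, 20), c(1, 0.5, 0))
  expect_error(moisture_ratio(1, 5, 5), "must differ")
})
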