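# Evaluation machinery: confusion metrics, ROC AUC, the Polygon Area Metric,
# k-fold cross-validation, method-comparison deltas and the moisture-ratio
# drying utility.

#' Confusion counts
#'
#' @param pred,truth Binary vectors (1 = positive), or supply the four counts
#'   directly.
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(pred = NULL, truth = NULL,
                             tp = NULL, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.null(pred)) {
    pred <- as.integer(pred)
    truth <- as.integer(truth)
    assert_that(length(pred) == length(truth),
                "pred and truth must have equal length")
    tp <- sum(pred == 1L & truth == 1L)
    tn <- sum(pred == 0L & truth == 0L)
    fp <- sum(pred == 1L & truth == 0L)
    fn <- sum(pred == 0L & truth == 1L)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  assert_that(all(counts >= 0), "counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' Recall (sensitivity), precision, F-score, accuracy, specificity and
#' Jaccard index from the four confusion counts. A metric with a zero
#' denominator is returned as `NA` and listed in the `undefined` attribute —
#' never silently zero.
#'
#' @param counts A [confusion_counts()] object.
#' @return A `metrics_bundle` (named list); `attr(, "undefined")` names any
#'   undefined metrics.
#' @export
basic_metrics <- function(counts) {
  assert_that(inherits(counts, "confusion_counts"),
              "counts must be confusion_counts")
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    recall = safe(tp, tp + fn),
    precision = safe(tp, tp + fp),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    specificity = safe(tn, tn + fp),
    jaccard = safe(tp, tp + fp + fn))
  undefined <- names(out)[vapply(out, is.na, logical(1))]
  structure(out, undefined = undefined, counts = counts,
            class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  vals <- unlist(x)
  cat("<metrics_bundle>\n")
  for (nm in names(vals)) cat(sprintf("  %-12s %.4f\n", nm, vals[nm]))
  und <- attr(x, "undefined")
  if (length(und)) cat("  undefined:", paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC obtained by sweeping the score threshold;
#' tied scores contribute half credit (equivalent to the Mann-Whitney
#' statistic).
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(length(scores) == length(labels),
              "scores and labels must have equal length")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  assert_that(np > 0 && nn > 0, "AUC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # threshold sweep over distinct score values
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(l == 1L)
  fp_cum <- cumsum(l == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp_cum[last] / np)
  fpr <- c(0, fp_cum[last] / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Polygon Area Metric
#'
#' Six metric values are placed as radii on rays 60 degrees apart (default
#' order: sensitivity, specificity, Jaccard, accuracy, F1, AUC); `PA` is the
#' shoelace area of the polygon and `PAM = PA / (3 sqrt(3) / 2)` normalizes by
#' the unit hexagon (2.59807... to five truncated decimals).
#'
#' @param values Numeric radii in `[0, 1]`; a `metrics_bundle` plus `auc` is
#'   also accepted.
#' @param auc AUC value when `values` is a `metrics_bundle`.
#' @param vertex_order Metric names, used when `values` is a bundle.
#' @return List with `PA` and `PAM`.
#' @export
pam_score <- function(values, auc = NULL,
                      vertex_order = c("recall", "specificity", "jaccard",
                                       "accuracy", "f1", "auc")) {
  if (inherits(values, "metrics_bundle")) {
    pool <- c(unclass(values), list(auc = auc))
    values <- vapply(vertex_order, function(nm) {
      v <- pool[[nm]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
  }
  values <- as.numeric(values)
  n <- length(values)
  assert_that(n >= 3L, "polygon needs at least 3 radii")
  assert_that(!anyNA(values) && all(values >= 0 & values <= 1),
              "all radii must lie in [0, 1]")
  ang <- (seq_len(n) - 1L) * 2 * pi / n
  px <- values * cos(ang)
  py <- values * sin(ang)
  j <- c(seq_len(n)[-1L], 1L)
  pa <- abs(sum(px * py[j] - px[j] * py)) / 2
  list(PA = pa, PAM = pa / (n * sin(2 * pi / n) / 2))
}

#' Hexagon PAM plot
#'
#' Draws the unit hexagon and the shaded metric polygon.
#'
#' @param values Six radii (or a `metrics_bundle` with `auc`).
#' @param auc,vertex_order See [pam_score()].
#' @param labels Vertex labels.
#' @param main Plot title.
#' @return The [pam_score()] of the drawn polygon, invisibly.
#' @export
plot_pam <- function(values, auc = NULL,
                     vertex_order = c("recall", "specificity", "jaccard",
                                      "accuracy", "f1", "auc"),
                     labels = toupper(vertex_order), main = "PAM") {
  if (inherits(values, "metrics_bundle")) {
    pool <- c(unclass(values), list(auc = auc))
    values <- vapply(vertex_order, function(nm) pool[[nm]], numeric(1))
  }
  n <- length(values)
  ang <- (seq_len(n) - 1L) * 2 * pi / n
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(cos(ang), sin(ang), border = "grey40")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
  graphics::polygon(values * cos(ang), values * sin(ang),
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    border = "steelblue")
  graphics::text(1.15 * cos(ang), 1.15 * sin(ang), labels, cex = 0.8)
  invisible(pam_score(values))
}

#' Seeded k-fold assignment
#'
#' @param n Number of records.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, a near-equal partition.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  assert_that(k >= 2L, "k must be >= 2")
  assert_that(n >= k, "need at least k records")
  with_seed(seed, {
    folds <- rep(seq_len(k), length.out = n)
    sample(folds)
  })
}

#' k-fold cross-validation of a binary classifier
#'
#' Splits the records into `k` seeded folds, trains on `k - 1` and validates
#' on the held-out fold, so each record is validated exactly once.
#'
#' @param x Feature matrix (rows = records).
#' @param y Binary labels.
#' @param train_fn `function(x_train, y_train)` returning a fitted model.
#' @param predict_fn `function(model, x_test)` returning scores in `[0, 1]`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param threshold Decision threshold on the score.
#' @return List with `folds` (assignment), `per_fold` (list of
#'   `metrics_bundle` + auc), and `mean` (averaged metrics).
#' @export
kfold_cv <- function(x, y, train_fn, predict_fn, k = 5L, seed = 1L,
                     threshold = 0.5) {
  x <- as_plain_matrix(x)
  y <- as.integer(y)
  folds <- kfold_indices(nrow(x), k, seed)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_fn(x[tr, , drop = FALSE], y[tr])
    sc <- predict_fn(model, x[!tr, , drop = FALSE])
    b <- basic_metrics(confusion_counts(as.integer(sc >= threshold), y[!tr]))
    b$auc <- if (length(unique(y[!tr])) == 2L) auc_score(sc, y[!tr]) else NA_real_
    per_fold[[f]] <- b
  }
  nms <- c("recall", "precision", "f1", "accuracy", "specificity", "jaccard",
           "auc")
  means <- vapply(nms, function(nm) {
    mean(vapply(per_fold, function(b) b[[nm]], numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(folds = folds, per_fold = per_fold, mean = as.list(means))
}

#' Compare two metric bundles
#'
#' Absolute deltas `a - b` (4 decimals) and relative percentage improvements
#' `100 * (a / b - 1)` (2 decimals) per shared metric; a relative improvement
#' against a zero baseline is flagged undefined (`NA`).
#'
#' @param bundle_a,bundle_b Named lists / `metrics_bundle`s of metric values.
#' @return Data frame with `metric`, `a`, `b`, `delta`, `relative_pct`.
#' @export
compare_methods <- function(bundle_a, bundle_b) {
  a <- unlist(unclass(bundle_a))
  b <- unlist(unclass(bundle_b))
  shared <- intersect(names(a), names(b))
  assert_that(length(shared) >= 1L, "bundles share no metrics")
  delta <- round(a[shared] - b[shared], 4)
  rel <- ifelse(b[shared] == 0, NA_real_,
                round(100 * (a[shared] / b[shared] - 1), 2))
  data.frame(metric = shared, a = a[shared], b = b[shared],
             delta = as.numeric(delta), relative_pct = as.numeric(rel),
             row.names = NULL)
}

#' Moisture ratio during leaf drying
#'
#' `MR = (Mt - Me) / (Mo - Me)` with `Mt` the moisture at time t, `Mo` the
#' initial and `Me` the equilibrium moisture: 1 at the start of drying, 0 at
#' equilibrium.
#'
#' @param Mt Moisture at time t (same units as `Mo`, `Me`).
#' @param Mo Initial moisture.
#' @param Me Equilibrium moisture (must differ from `Mo`).
#' @return The moisture ratio (vectorized over `Mt`).
#' @export
moisture_ratio <- function(Mt, Mo, Me) {
  assert_that(all(Mo != Me), "Mo and Me must differ")
  (Mt - Me) / (Mo - Me)
}

#' Write a metrics report as CSV and/or JSON
#'
#' @param bundle A `metrics_bundle` (extra named values allowed).
#' @param csv,json Optional output paths.
#' @return The bundle as a one-row data frame, invisibly.
#' @export
write_metrics_report <- function(bundle, csv = NULL, json = NULL) {
  df <- as.data.frame(as.list(unlist(unclass(bundle))))
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(as.list(df), json, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
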