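# Stress classification: a fixed-length 15-value feature vector built from
# leaf centroids feeds a 15-128-64-32-64-128-2 feed-forward network with
# sigmoid outputs (unit 1 = stressed, unit 2 = without stress is the
# complement; reported score is the stressed-class sigmoid).

STRESS_LAYER_SIZES <- c(15L, 128L, 64L, 32L, 64L, 128L, 2L)

#' Build the 15-value centroid feature vector
#'
#' Leaves are ordered by pixel-projection count `w` descending (ties broken by
#' centroid X then Y ascending). `"heights"` mode takes the centroid Z of the
#' first 15 leaves; `"full_centroids"` concatenates `(X, Y, Z)` of the first
#' 5. Overflow is truncated; shortfall padded with `pad_value`.
#'
#' @param leaves List of `leaf3d` objects (may be empty).
#' @param mode `"heights"` or `"full_centroids"`.
#' @param pad_value Filler for empty slots; must lie outside plausible leaf
#'   heights (default 0).
#' @return A length-15 numeric of class `feature_vector` with attributes
#'   `mode` and `n_leaves`.
#' @export
build_feature_vector <- function(leaves, mode = c("heights", "full_centroids"),
                                 pad_value = 0) {
  mode <- match.arg(mode)
  out <- rep(pad_value, 15L)
  if (length(leaves)) {
    w <- vapply(leaves, function(l) l$w, numeric(1))
    cx <- vapply(leaves, function(l) l$centroid[["X"]], numeric(1))
    cy <- vapply(leaves, function(l) l$centroid[["Y"]], numeric(1))
    cz <- vapply(leaves, function(l) l$centroid[["Z"]], numeric(1))
    ord <- order(-w, cx, cy)
    if (mode == "heights") {
      take <- utils::head(ord, 15L)
      out[seq_along(take)] <- cz[take]
    } else {
      take <- utils::head(ord, 5L)
      vals <- as.vector(t(cbind(cx, cy, cz)[take, , drop = FALSE]))
      out[seq_along(vals)] <- vals
    }
  }
  structure(out, mode = mode, n_leaves = length(leaves),
            class = "feature_vector")
}

#' Train the stress-detection DNN
#'
#' Fixed architecture 15-128-64-32-64-128-2 (five ReLU hidden layers, two
#' sigmoid outputs) trained with Adam and cross-entropy.
#'
#' @param features N x 15 matrix of feature vectors.
#' @param labels Binary labels (1 = stressed, 0 = without stress).
#' @param hyper Training settings: `epochs`, `batch`, `lr`.
#' @param seed Integer seed.
#' @return A `stress_model` with a training log.
#' @export
train_stress_dnn <- function(features, labels, hyper = list(), seed = 1L) {
  features <- as_plain_matrix(features)
  assert_that(ncol(features) == 15L, "features must have exactly 15 columns")
  labels <- as.integer(labels)
  if (!all(c(0L, 1L) %in% labels)) {
    missing <- if (all(labels == 1L)) "without-stress (0)" else "stressed (1)"
    stop("training set lacks the ", missing, " class", call. = FALSE)
  }
  h <- utils::modifyList(list(epochs = 150L, batch = 32L, lr = 1e-3), hyper)
  sizes <- STRESS_LAYER_SIZES
  layers <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    layers <- c(layers, list(nn_dense(sizes[i], sizes[i + 1L])))
    if (i < length(sizes) - 1L) layers <- c(layers, list(nn_relu()))
  }
  Y <- cbind(stressed = labels, without = 1L - labels)
  fit <- nn_fit(layers, features, Y, loss = "bce", epochs = h$epochs,
                batch = h$batch, lr = h$lr, seed = seed)
  structure(list(layers = layers, params = fit$params, state = fit$state,
                 history = fit$history, sizes = sizes,
                 meta = list(seed = seed, hyper = h)),
            class = c("stress_model", "canopy3d_model"))
}

#' Layer sizes of a stress model
#'
#' @param model A `stress_model`.
#' @return Integer vector of layer sizes (input, hidden..., output).
#' @export
stress_architecture <- function(model) model$sizes

#' Classify plant stress from a feature vector
#'
#' The sigmoid output for the stressed class is the score; the label is the
#' class with the larger output, equivalent to thresholding the score at 0.5.
#'
#' @param model A [train_stress_dnn()] model.
#' @param feature Length-15 numeric (a [build_feature_vector()]) or an
#'   N x 15 matrix.
#' @return For a single vector, list with `label` (1 = stressed) and `score`
#'   in `(0, 1)`; for a matrix, a data frame of labels and scores.
#' @export
classify_stress <- function(model, feature) {
  assert_that(inherits(model, "stress_model"), "model must be a stress_model")
  single <- is.null(dim(feature))
  X <- if (single) matrix(as.numeric(feature), 1L) else as_plain_matrix(feature)
  assert_that(ncol(X) == 15L, "feature vector must have length 15")
  s <- nn_predict(model$layers, model$params, model$state, X)
  label <- as.integer(s[, 1] >= s[, 2])
  if (single) list(label = label, score = s[1, 1])
  else data.frame(label = label, score = s[, 1])
}
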