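# Patch-based plant/no-plant semantic segmentation: a CNN classifies 32x32 RGB
# sections and a sliding window paints the central pixel of every window with
# the predicted label (plant = 1, "painted green"; no-plant = 0, black).

# Top-left coordinates of every full patch window along one axis.
patch_starts <- function(extent, patch, stride) {
  assert_that(extent >= patch, "image is smaller than the patch size")
  seq(1L, extent - patch + 1L, by = as.integer(stride))
}

#' Number of patch windows tiling an image
#'
#' Exhaustive window enumeration: `floor((H - patch)/stride + 1) *
#' floor((W - patch)/stride + 1)`.
#'
#' @param height,width Image size in pixels.
#' @param patch Patch size (default 32).
#' @param stride Window stride in pixels.
#' @return Integer window count.
#' @export
count_patches <- function(height, width, patch = 32L, stride = 1L) {
  length(patch_starts(height, patch, stride)) *
    length(patch_starts(width, patch, stride))
}

# Gather a batch of windows from one image via linear indexing.
# tl: n x 2 matrix of (row, col) top-left corners. Returns p x p x C x n.
gather_windows <- function(image, tl, patch) {
  d <- dim(image)
  H <- d[1]
  C <- if (length(d) == 3L) d[3] else 1L
  HW <- d[1] * d[2]
  off <- as.vector(outer(seq_len(patch) - 1L,
                         (seq_len(patch) - 1L) * H, "+"))
  off <- as.vector(outer(off, (seq_len(C) - 1L) * HW, "+"))
  origins <- tl[, 1] + (tl[, 2] - 1L) * H
  idx <- outer(off, origins, "+")
  array(image[idx], c(patch, patch, C, nrow(tl)))
}

# Central pixel of a patch whose top-left is (r0, c0): offset patch/2 - 1.
patch_center_offset <- function(patch) as.integer(patch %/% 2L - 1L)

#' Extract labelled training patches from masked images
#'
#' Tiles each image with `patch`-sized windows at the given stride and labels
#' every patch with the ground-truth class of its central pixel (or the
#' majority class over the window).
#'
#' @param images A single H x W x 3 array or a list of them.
#' @param masks Matching 0/1 plant mask matrix or list of them (1 = plant).
#' @param patch Patch size in pixels.
#' @param stride Tiling stride in pixels.
#' @param label_rule `"center"` (default) or `"majority"`.
#' @return List with `patches` (patch x patch x 3 x N array), `labels`
#'   (integer, 1 = plant, 0 = no-plant) and `centers` (N x 2 matrix).
#' @export
extract_training_patches <- function(images, masks, patch = 32L, stride = patch,
                                     label_rule = c("center", "majority")) {
  label_rule <- match.arg(label_rule)
  if (!is.list(images)) {
    images <- list(images)
    masks <- list(masks)
  }
  assert_that(length(images) == length(masks),
              "images and masks must have equal length")
  all_p <- list()
  all_l <- list()
  all_c <- list()
  co <- patch_center_offset(patch)
  for (i in seq_along(images)) {
    img <- images[[i]]
    msk <- masks[[i]]
    assert_that(all(dim(img)[1:2] == dim(msk)[1:2]),
                "image and mask disagree on size")
    tlr <- patch_starts(dim(img)[1], patch, stride)
    tlc <- patch_starts(dim(img)[2], patch, stride)
    tl <- cbind(rep(tlr, times = length(tlc)), rep(tlc, each = length(tlr)))
    all_p[[i]] <- gather_windows(img, tl, patch)
    centers <- cbind(tl[, 1] + co, tl[, 2] + co)
    if (label_rule == "center") {
      all_l[[i]] <- as.integer(msk[centers])
    } else {
      wins <- gather_windows(msk, tl, patch)
      all_l[[i]] <- as.integer(apply(wins, 4L, mean) >= 0.5)
    }
    all_c[[i]] <- centers
  }
  n <- sum(vapply(all_p, function(a) dim(a)[4], integer(1)))
  patches <- array(0, c(patch, patch, 3L, n))
  at <- 0L
  for (a in all_p) {
    nn <- dim(a)[4]
    patches[, , , at + seq_len(nn)] <- a
    at <- at + nn
  }
  list(patches = patches, labels = unlist(all_l), centers = do.call(rbind, all_c))
}

# Encoder architectures shared by the segmentation and depth networks.
# "reduced": 3 conv blocks, single early pool — keeps the window's central
#   pixel localizable, which per-pixel *classification* needs.
# "reduced_pooled": 3 conv/pool blocks — aggressive spatial aggregation,
#   better suited to *regressing* the window-mean depth code.
# "vgg16": 13 conv + 13 batch-norm + 5 max-pool layers.
encoder_layers <- function(variant = c("reduced", "reduced_pooled", "vgg16"),
                           patch = 32L) {
  variant <- match.arg(variant)
  if (variant == "reduced_pooled") {
    layers <- list(
      nn_conv(3L, 8L), nn_bnorm(8L), nn_relu(), nn_pool(2L),
      nn_conv(8L, 16L), nn_bnorm(16L), nn_relu(), nn_pool(2L),
      nn_conv(16L, 16L), nn_bnorm(16L), nn_relu(), nn_pool(2L))
    feat <- 2L * 2L * 16L
  } else if (variant == "reduced") {
    # single early pool: the center-pixel painting rule stays spatially
    # representable (deep pooling stacks cannot localize the central pixel)
    layers <- list(
      nn_conv(3L, 8L), nn_bnorm(8L), nn_relu(), nn_pool(2L),
      nn_conv(8L, 12L), nn_bnorm(12L), nn_relu(),
      nn_conv(12L, 12L), nn_bnorm(12L), nn_relu())
    feat <- 11L * 11L * 12L
  } else {
    widths <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                512L, 512L, 512L, 512L, 512L, 512L)
    pool_after <- c(2L, 4L, 7L, 10L, 13L)
    layers <- list()
    in_ch <- 3L
    for (i in seq_along(widths)) {
      layers <- c(layers, list(nn_conv(in_ch, widths[i], pad = 1L),
                               nn_bnorm(widths[i]), nn_relu()))
      if (i %in% pool_after) layers <- c(layers, list(nn_pool(2L)))
      in_ch <- widths[i]
    }
    feat <- 512L
  }
  list(layers = layers, features = feat, variant = variant)
}

classifier_head <- function(features, hidden = 32L, out = 2L) {
  list(nn_flatten(), nn_dense(features, hidden), nn_bnorm(hidden), nn_relu(),
       nn_dense(hidden, out))
}

#' Train the patch classifier for plant segmentation
#'
#' Fits a CNN (VGG16-style encoder or the reduced 3-block test encoder) on
#' labelled 32x32 patches with Adam and binary cross-entropy on two sigmoid
#' outputs (plant, no-plant).
#'
#' @param patches `patch x patch x 3 x N` array (or the list returned by
#'   [extract_training_patches()]).
#' @param labels Integer labels, 1 = plant, 0 = no-plant (ignored when
#'   `patches` carries its own).
#' @param hyper List of training settings: `encoder` (`"reduced"` or
#'   `"vgg16"`), `epochs`, `batch`, `lr`, `hidden`.
#' @param seed Integer seed; training is bit-reproducible for a fixed seed.
#' @return A `seg_model` with weights, batch-norm state and a training log
#'   (`$history`: epoch, loss, accuracy).
#' @export
train_segmenter <- function(patches, labels = NULL, hyper = list(), seed = 1L) {
  if (is.list(patches) && !is.null(patches$patches)) {
    labels <- patches$labels
    patches <- patches$patches
  }
  assert_that(length(dim(patches)) == 4L, "patches must be a 4-d array")
  labels <- as.integer(labels)
  if (!all(c(0L, 1L) %in% labels)) {
    missing <- if (all(labels == 1L)) "no-plant (v2)" else "plant (v1)"
    stop("training set lacks the ", missing, " class", call. = FALSE)
  }
  h <- utils::modifyList(list(encoder = "reduced", epochs = 6L, batch = 64L,
                              lr = 1e-3, hidden = 32L), hyper)
  enc <- encoder_layers(h$encoder, dim(patches)[1])
  layers <- c(enc$layers, classifier_head(enc$features, h$hidden, 2L))
  Y <- cbind(plant = labels, noplant = 1L - labels)
  fit <- nn_fit(layers, patches, Y, loss = "bce", epochs = h$epochs,
                batch = h$batch, lr = h$lr, seed = seed)
  structure(list(layers = layers, params = fit$params, state = fit$state,
                 history = fit$history, patch = dim(patches)[1],
                 meta = list(seed = seed, hyper = h, encoder = enc$variant,
                             classes = c(plant = 1L, noplant = 0L))),
            class = c("seg_model", "canopy3d_model"))
}

# Forward a batch of patches through a patch model; returns sigmoid outputs.
predict_patches <- function(model, patches, chunk = 256L) {
  nn_predict(model$layers, model$params, model$state, patches, chunk = chunk)
}

# Edge-replication padding: after padding, every original pixel is the center
# of one full window.
pad_image_edge <- function(image, before, after) {
  d <- dim(image)
  ri <- clamp(seq_len(d[1] + before + after) - before, 1L, d[1])
  ci <- clamp(seq_len(d[2] + before + after) - before, 1L, d[2])
  image[ri, ci, , drop = FALSE]
}

# Shared sliding-window driver: evaluates the model on a stride-spaced grid of
# window centers. border = "pad" replicates edge pixels so that every pixel
# (including those within half a patch of an edge) is classified on a full
# window; border = "nearest" evaluates only fully interior windows and copies
# the nearest evaluated center outward. Pixels skipped by a stride > 1 take
# the nearest evaluated center either way.
slide_windows <- function(model, image, stride, border = c("pad", "nearest"),
                          chunk = 256L) {
  border <- match.arg(border)
  p <- model$patch
  d <- dim(image)
  assert_that(d[1] >= p && d[2] >= p,
              sprintf("image must be at least %d x %d", p, p))
  co <- patch_center_offset(p)
  if (border == "pad") {
    img <- pad_image_edge(image, co, p - 1L - co)
    center_rows <- seq(1L, d[1], by = as.integer(stride))
    center_cols <- seq(1L, d[2], by = as.integer(stride))
    tlr <- center_rows # top-left in padded coords = center in original coords
    tlc <- center_cols
  } else {
    img <- image
    tlr <- patch_starts(d[1], p, stride)
    tlc <- patch_starts(d[2], p, stride)
    center_rows <- tlr + co
    center_cols <- tlc + co
  }
  tl <- cbind(rep(tlr, times = length(tlc)), rep(tlc, each = length(tlr)))
  n <- nrow(tl)
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    batch <- gather_windows(img, tl[idx, , drop = FALSE], p)
    piece <- predict_patches(model, batch, chunk = chunk)
    out <- if (is.null(out)) piece else rbind(out, piece)
  }
  list(scores = out, n_windows = n,
       center_rows = center_rows, center_cols = center_cols,
       nr = length(tlr), nc = length(tlc))
}

# Expand per-window values (one per grid node) to a full H x W matrix.
fill_full_map <- function(values, sw, H, W) {
  grid <- matrix(values, sw$nr, sw$nc)
  ri <- nearest_grid_index(seq_len(H), sw$center_rows)
  ci <- nearest_grid_index(seq_len(W), sw$center_cols)
  grid[ri, ci, drop = FALSE]
}

#' Segment an image with the sliding-window patch classifier
#'
#' Every evaluated window paints its central pixel with the predicted label;
#' pixels skipped by a stride > 1 take the label of the nearest evaluated
#' window center, and the image border is handled per the `border` rule.
#'
#' @param model A [train_segmenter()] model.
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param stride Sliding-window sweep in pixels (1 = dense).
#' @param border `"pad"` (default; edge-replication padding gives every pixel
#'   a full window) or `"nearest"` (border pixels copy the nearest fully
#'   interior window center).
#' @return A `segmentation_mask`: list with `labels` (H x W, 1 = plant),
#'   `scores` (plant-class sigmoid in `[0, 1]`), `n_windows`, `stride`.
#' @export
segment_image <- function(model, image, stride = 1L,
                          border = c("pad", "nearest")) {
  assert_that(inherits(model, "seg_model"), "model must be a seg_model")
  sw <- slide_windows(model, image, stride, border)
  lab <- as.integer(sw$scores[, 1] >= sw$scores[, 2])
  H <- dim(image)[1]
  W <- dim(image)[2]
  structure(list(labels = fill_full_map(lab, sw, H, W),
                 scores = fill_full_map(sw$scores[, 1], sw, H, W),
                 n_windows = sw$n_windows, stride = as.integer(stride),
                 patch = model$patch),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d, %.1f%% plant, %d windows (stride %d)\n",
              nrow(x$labels), ncol(x$labels), 100 * mean(x$labels),
              x$n_windows, x$stride))
  invisible(x)
}

#' Render a segmentation mask as an RGB image
#'
#' Plant pixels are painted green, no-plant pixels black.
#'
#' @param mask A `segmentation_mask` or a 0/1 matrix.
#' @return H x W x 3 array.
#' @export
mask_to_rgb <- function(mask) {
  lab <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  out <- array(0, c(dim(lab), 3L))
  out[, , 2] <- lab * 0.8
  out
}
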