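# Monocular depth inference: a patch CNN regresses the mean 8-bit depth code
# under each 32x32 RGB section, then runs as a sliding window to produce a
# dense depth-code map from a single RGB image.

#' Depth-code map container
#'
#' @param codes H x W matrix of depth codes in `[0, 255]` (real-valued when
#'   inferred, integer when loaded from file).
#' @param convention `"eq4"` (code grows with distance, `Z = k * z / 255`) or
#'   `"inverted"` (near-bright).
#' @return An object of class `depth_map`.
#' @export
depth_map <- function(codes, convention = c("eq4", "inverted")) {
  convention <- match.arg(convention)
  codes <- as.matrix(codes)
  assert_that(all(codes >= 0 & codes <= 255),
              "depth codes must lie in [0, 255]")
  structure(list(codes = codes, convention = convention), class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d, codes %.1f-%.1f (%s)\n",
              nrow(x$codes), ncol(x$codes), min(x$codes), max(x$codes),
              x$convention))
  invisible(x)
}

#' Build (patch, mean depth code) training pairs
#'
#' Each RGB section is paired with the arithmetic mean of the depth codes
#' under it.
#'
#' @param rgb H x W x 3 RGB array.
#' @param depth `depth_map` or plain code matrix of the same size.
#' @param patch Patch size in pixels.
#' @param stride Tiling stride in pixels.
#' @return List with `patches` (4-d array), `targets` (mean codes in
#'   `[0, 255]`) and `centers`.
#' @export
build_depth_pairs <- function(rgb, depth, patch = 32L, stride = patch) {
  codes <- if (inherits(depth, "depth_map")) depth$codes else as.matrix(depth)
  assert_that(all(dim(rgb)[1:2] == dim(codes)),
              "rgb and depth disagree on size")
  tlr <- patch_starts(dim(rgb)[1], patch, stride)
  tlc <- patch_starts(dim(rgb)[2], patch, stride)
  tl <- cbind(rep(tlr, times = length(tlc)), rep(tlc, each = length(tlr)))
  patches <- gather_windows(rgb, tl, patch)
  wins <- gather_windows(codes, tl, patch)
  targets <- colMeans(matrix(wins, patch * patch, nrow(tl)))
  co <- patch_center_offset(patch)
  list(patches = patches, targets = targets,
       centers = cbind(tl[, 1] + co, tl[, 2] + co))
}

#' Train the patch depth-regression network
#'
#' Shares the segmentation encoder architecture; a scalar sigmoid head is
#' regressed with squared error against mean depth codes scaled to `[0, 1]`.
#'
#' @param pairs List from [build_depth_pairs()] (or a 4-d patch array).
#' @param targets Mean depth codes in `[0, 255]` (when `pairs` is an array).
#' @param hyper Training settings: `encoder`, `epochs`, `batch`, `lr`,
#'   `hidden`.
#' @param seed Integer seed.
#' @return A `depth_model`.
#' @export
train_depth_net <- function(pairs, targets = NULL, hyper = list(), seed = 1L) {
  if (is.list(pairs) && !is.null(pairs$patches)) {
    targets <- pairs$targets
    pairs <- pairs$patches
  }
  assert_that(length(dim(pairs)) == 4L && dim(pairs)[4] >= 1L,
              "no training pairs supplied")
  assert_that(length(unique(round(targets, 6))) >= 2L,
              "depth training needs at least two distinct targets")
  assert_that(all(targets >= 0 & targets <= 255),
              "targets must be mean depth codes in [0, 255]")
  h <- utils::modifyList(list(encoder = "reduced_pooled", epochs = 6L,
                              batch = 64L, lr = 1e-3, hidden = 32L), hyper)
  enc <- encoder_layers(h$encoder, dim(pairs)[1])
  layers <- c(enc$layers,
              list(nn_flatten(), nn_dense(enc$features, h$hidden),
                   nn_bnorm(h$hidden), nn_relu(), nn_dense(h$hidden, 1L)))
  # map the observed code range onto the sigmoid's working band [0.1, 0.9]:
  # raw codes/255 occupy a sliver of the unit interval, which flattens the
  # fused-sigmoid MSE gradient and makes convergence seed-sensitive
  lo <- min(targets)
  hi <- max(targets)
  span <- max(hi - lo, 1e-6)
  Y <- matrix(0.1 + 0.8 * (targets - lo) / span, ncol = 1L)
  fit <- nn_fit(layers, pairs, Y, loss = "mse", epochs = h$epochs,
                batch = h$batch, lr = h$lr, seed = seed)
  structure(list(layers = layers, params = fit$params, state = fit$state,
                 history = fit$history, patch = dim(pairs)[1],
                 code_range = c(lo = lo, hi = hi),
                 meta = list(seed = seed, hyper = h, encoder = enc$variant)),
            class = c("depth_model", "canopy3d_model"))
}

#' Predict mean depth codes for a batch of patches
#'
#' @param model A [train_depth_net()] model.
#' @param patches 4-d patch array.
#' @return Numeric vector of codes in `[0, 255]`.
#' @export
predict_depth_codes <- function(model, patches) {
  s <- predict_patches(model, patches)[, 1]
  depth_unscale(model, s)
}

depth_unscale <- function(model, s) {
  lo <- model$code_range[["lo"]]
  hi <- model$code_range[["hi"]]
  clamp(lo + (s - 0.1) / 0.8 * (hi - lo), 0, 255)
}

#' Infer a dense depth-code map from a single RGB image
#'
#' The regression network is slid over the image; each pixel receives the
#' output of the window centered there (borders and stride gaps take the
#' nearest evaluated center, as in [segment_image()]).
#'
#' @param model A `depth_model`.
#' @param image H x W x 3 RGB array.
#' @param stride Sliding-window sweep in pixels.
#' @param border Border rule, as in [segment_image()].
#' @return A [depth_map()] with real-valued codes.
#' @export
infer_depth <- function(model, image, stride = 1L,
                        border = c("pad", "nearest")) {
  assert_that(inherits(model, "depth_model"), "model must be a depth_model")
  sw <- slide_windows(model, image, stride, border)
  codes <- depth_unscale(model, sw$scores[, 1])
  dm <- depth_map(fill_full_map(codes, sw, dim(image)[1], dim(image)[2]))
  dm$stride <- as.integer(stride)
  dm$n_windows <- sw$n_windows
  dm
}

#' Write a depth map as an 8-bit PNG (plus optional lossless sidecar)
#'
#' @param dm A [depth_map()].
#' @param path PNG output path.
#' @param invert Export with the near-bright convention (`255 - z`).
#' @param sidecar Optional path for a lossless CSV of the real-valued codes.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(dm, path, invert = FALSE, sidecar = NULL) {
  codes <- round(dm$codes)
  if (invert) codes <- 255 - codes
  png::writePNG(codes / 255, path)
  if (!is.null(sidecar)) {
    utils::write.table(dm$codes, sidecar, row.names = FALSE,
                       col.names = FALSE, sep = ",")
  }
  invisible(path)
}
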