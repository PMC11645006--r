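# Shared fixtures: small scene configurations and lazily trained toy models.
# Everything is generated in code under fixed seeds; nothing is read from
# disk.

small_scene_config <- function(width = 96L, height = 96L, ...) {
  scene_config(width = width, height = height,
               leaves_per_plant = c(4L, 7L), noise_sd = 2, ...)
}

test_camera <- function(width = 96L, height = 96L) {
  camera_model(f = 300, k = 4, width = width, height = height)
}

# Two-color separable toy world: pure green leaves (plant) on pure black soil.
# Patches from it are linearly separable, so the patch CNN must reach
# held-out accuracy 1 and near-perfect interior segmentation.
toy_two_color_image <- function(H = 64L, W = 64L, seed = 1L) {
  with_seed(seed, {
    mask <- matrix(0L, H, W)
    # a few random axis-aligned rectangles of "plant"
    for (i in 1:3) {
      r0 <- sample.int(H - 20L, 1)
      c0 <- sample.int(W - 20L, 1)
      mask[r0:(r0 + sample(8:18, 1)), c0:(c0 + sample(8:18, 1))] <- 1L
    }
  })
  img <- array(0, c(H, W, 3))
  img[, , 2] <- mask * 0.8
  list(rgb = img, mask = mask)
}

toy_patch_set <- function(n_images = 6L, stride = 8L, seed = 2L) {
  toys <- lapply(seq_len(n_images), function(i) {
    toy_two_color_image(seed = seed + i)
  })
  extract_training_patches(lapply(toys, `[[`, "rgb"),
                           lapply(toys, `[[`, "mask"), stride = stride)
}

# Pure-color patch set: every patch is uniformly green (plant) or black
# (soil) -- the linearly separable family.
pure_color_patches <- function(n_per_class = 110L, seed = 21L) {
  n <- 2L * n_per_class
  patches <- array(0, c(32, 32, 3, n))
  labels <- rep(c(1L, 0L), each = n_per_class)
  with_seed(seed, {
    for (i in seq_len(n)) {
      if (labels[i] == 1L) patches[, , 2, i] <- runif(1, 0.7, 0.9)
    }
  })
  list(patches = patches, labels = labels)
}

# Session-cached toy segmenters (trained once per test run).
.fixture_cache <- new.env(parent = emptyenv())

# quick variant: enough for determinism/equivalence contracts
toy_segmenter <- function() {
  if (is.null(.fixture_cache$seg)) {
    ps <- toy_patch_set()
    .fixture_cache$seg <- train_segmenter(
      ps, hyper = list(epochs = 2L, batch = 64L, lr = 2e-3), seed = 42L)
  }
  .fixture_cache$seg
}

# strong variant: the ~2000-patch training prescribed for interior-F1 checks
strong_toy_segmenter <- function() {
  if (is.null(.fixture_cache$seg_strong)) {
    toys <- lapply(1:25, function(i) toy_two_color_image(seed = 600 + i))
    ps <- extract_training_patches(lapply(toys, `[[`, "rgb"),
                                   lapply(toys, `[[`, "mask"), stride = 4)
    stopifnot(length(ps$labels) >= 2000)
    .fixture_cache$seg_strong <- train_segmenter(
      ps, hyper = list(epochs = 6L, batch = 64L, lr = 2e-3), seed = 61L)
  }
  .fixture_cache$seg_strong
}

# A model stub that always predicts the no-plant class, for constant-output
# contracts. Built from a real (untrained) architecture by forcing the final
# bias.
constant_noplant_model <- function() {
  ps <- toy_patch_set(n_images = 1L)
  m <- train_segmenter(ps, hyper = list(epochs = 1L, batch = 64L), seed = 1L)
  last <- length(m$layers)
  m$params[[last]]$W[] <- 0
  m$params[[last]]$b <- c(-10, 10) # (plant, noplant) logits
  m
}

# Random leaf3d stand-in with given w and centroid.
fake_leaf <- function(w, X = 0, Y = 0, Z = 0.7) {
  structure(list(points = matrix(rep(c(X, Y, Z), each = w), ncol = 3),
                 w = w, id = NA_integer_,
                 centroid = c(X = X, Y = Y, Z = Z)),
            class = "leaf3d")
}
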