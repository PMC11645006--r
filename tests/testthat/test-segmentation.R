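# Patch extraction, the patch classifier, and sliding-window segmentation.

test_that("patch tiling follows exhaustive window enumeration", {
  # 64 x 64 at stride 32 -> 2 x 2
  expect_equal(count_patches(64, 64, patch = 32, stride = 32), 4)
  # full-HD frame at non-overlapping stride: 33 x 60 windows
  expect_equal(count_patches(1080, 1920, patch = 32, stride = 32), 1980)
  # dense sweep on a 116 x 116 image: (116 - 32 + 1)^2
  expect_equal(count_patches(116, 116, patch = 32, stride = 1), 85^2)
  # brute-force enumeration oracle across assorted shapes
  for (d in list(c(32, 32, 1), c(50, 40, 4), c(96, 64, 8), c(33, 65, 16))) {
    brute <- 0
    for (r in seq_len(d[1])) {
      for (cc in seq_len(d[2])) {
        if (r + 31 <= d[1] && cc + 31 <= d[2] &&
            (r - 1) %% d[3] == 0 && (cc - 1) %% d[3] == 0) {
          brute <- brute + 1
        }
      }
    }
    expect_equal(count_patches(d[1], d[2], patch = 32, stride = d[3]), brute)
  }
  expect_error(count_patches(20, 64, patch = 32, stride = 1), "smaller")
})

test_that("extracted patches carry the center-pixel label", {
  toy <- toy_two_color_image(seed = 3)
  ps <- extract_training_patches(toy$rgb, toy$mask, stride = 8)
  expect_equal(dim(ps$patches), c(32, 32, 3, count_patches(64, 64, 32, 8)))
  expect_equal(ps$labels, unname(toy$mask[ps$centers]))
  # all-plant mask -> every patch labelled plant
  ones <- matrix(1L, 64, 64)
  ps1 <- extract_training_patches(toy$rgb, ones, stride = 16)
  expect_true(all(ps1$labels == 1L))
  # the patch content is the actual window
  tl <- ps$centers[5, ] - (32 %/% 2 - 1)
  expect_equal(ps$patches[, , , 5],
               toy$rgb[tl[1]:(tl[1] + 31), tl[2]:(tl[2] + 31), ])
})

test_that("the patch classifier separates the two-color toy world perfectly", {
  ps <- pure_color_patches() # 220 pure green / pure black patches
  expect_gte(length(ps$labels), 200)
  with_seed(30, idx <- sample(length(ps$labels)))
  tr <- idx[1:floor(0.75 * length(idx))]
  te <- setdiff(idx, tr)
  m <- train_segmenter(ps$patches[, , , tr, drop = FALSE], ps$labels[tr],
                       hyper = list(epochs = 2, batch = 64, lr = 2e-3),
                       seed = 11)
  sc <- predict_patches(m, ps$patches[, , , te, drop = FALSE])
  pred <- as.integer(sc[, 1] >= sc[, 2])
  expect_equal(mean(pred == ps$labels[te]), 1) # linearly separable
  # seeded determinism of training
  m2 <- train_segmenter(ps$patches[, , , tr, drop = FALSE], ps$labels[tr],
                        hyper = list(epochs = 2, batch = 64, lr = 2e-3),
                        seed = 11)
  expect_identical(m$params, m2$params)
})

test_that("single-class training sets are rejected naming the missing class", {
  ps <- toy_patch_set(n_images = 2L)
  keep <- ps$labels == 1L
  expect_error(train_segmenter(ps$patches[, , , keep, drop = FALSE],
                               ps$labels[keep]), "no-plant")
  expect_error(train_segmenter(ps$patches[, , , !keep, drop = FALSE],
                               ps$labels[!keep]), "plant")
})

test_that("a constant no-plant classifier paints an all-black mask", {
  m <- constant_noplant_model()
  toy <- toy_two_color_image(seed = 4)
  mask <- segment_image(m, toy$rgb, stride = 4)
  expect_true(all(mask$labels == 0L))
  expect_true(all(mask$scores >= 0 & mask$scores <= 1))
  expect_equal(dim(mask$labels), c(64, 64))
})

test_that("batched sliding window equals naive per-window evaluation", {
  m <- toy_segmenter()
  toy <- toy_two_color_image(seed = 9)
  got <- segment_image(m, toy$rgb, stride = 1, border = "nearest")
  expect_equal(got$n_windows, count_patches(64, 64, 32, 1))
  # the padded border rule evaluates one window per pixel instead
  expect_equal(segment_image(m, toy$rgb, stride = 8)$n_windows, 8 * 8)
  # naive oracle: forward one window at a time at a sample of centers
  co <- 32 %/% 2 - 1
  with_seed(17, {
    centers <- cbind(sample(16:48, 12, TRUE), sample(16:48, 12, TRUE))
  })
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1]
    cc <- centers[i, 2]
    win <- toy$rgb[(r - co):(r - co + 31), (cc - co):(cc - co + 31), ,
                   drop = FALSE]
    dim(win) <- c(32, 32, 3, 1)
    sc <- predict_patches(m, win)
    expect_equal(got$scores[r, cc], sc[1, 1], tolerance = 1e-12)
    expect_equal(got$labels[r, cc], as.integer(sc[1, 1] >= sc[1, 2]))
  }
})

test_that("toy segmentation recovers the color rule on window interiors", {
  m <- strong_toy_segmenter()
  interior <- matrix(FALSE, 64, 64)
  interior[16:48, 16:48] <- TRUE
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (s in 11:13) {
    toy <- toy_two_color_image(seed = s)
    mask <- segment_image(m, toy$rgb, stride = 1)
    # color-threshold oracle: plant iff green channel is high
    oracle <- (toy$rgb[, , 2] > 0.4) * 1L
    counts <- counts + c(
      tp = sum(mask$labels[interior] == 1 & oracle[interior] == 1),
      tn = sum(mask$labels[interior] == 0 & oracle[interior] == 0),
      fp = sum(mask$labels[interior] == 1 & oracle[interior] == 0),
      fn = sum(mask$labels[interior] == 0 & oracle[interior] == 1))
  }
  b <- basic_metrics(confusion_counts(tp = counts["tp"], tn = counts["tn"],
                                      fp = counts["fp"], fn = counts["fn"]))
  expect_gte(b$f1, 0.99)
  # identical inputs give identical masks
  toy <- toy_two_color_image(seed = 12)
  expect_identical(segment_image(m, toy$rgb, stride = 2)$labels,
                   segment_image(m, toy$rgb, stride = 2)$labels)
})

test_that("the full VGG16-style encoder has the specified architecture", {
  enc <- encoder_layers("vgg16")
  kinds <- vapply(enc$layers, `[[`, "", "kind")
  expect_equal(sum(kinds == "conv"), 13)
  expect_equal(sum(kinds == "bnorm"), 13)
  expect_equal(sum(kinds == "pool"), 5)
  expect_equal(enc$features, 512)
  # forward shape check on a tiny batch (untrained weights)
  layers <- c(enc$layers, classifier_head(enc$features, 64L, 2L))
  with_seed(1, {
    params <- nn_init_params(layers)
    state <- nn_init_state(layers)
    X <- array(runif(32 * 32 * 3 * 2), c(32, 32, 2, 3)) # internal layout
  })
  out <- nn_forward(layers, params, state, X, train = FALSE)$out
  expect_equal(dim(out), c(2L, 2L))
})
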