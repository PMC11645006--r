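# Pinhole conversion, back-projection, moments/centroids and RMS error.

test_that("depth-code conversion matches the worked example and endpoints", {
  expect_equal(round(code_to_depth(128, k = 4)), 2) # ~2 m
  expect_equal(code_to_depth(128, k = 4), 4 * 128 / 255)
  expect_equal(code_to_depth(0, k = 4), 0)
  expect_equal(code_to_depth(255, k = 4), 4)
  z <- 0:255
  expect_true(all(diff(code_to_depth(z, k = 2.5)) > 0))
  expect_error(code_to_depth(300, k = 4), "\\[0, 255\\]")
  # round trip with the encoder
  expect_equal(depth_to_code(code_to_depth(0:255, k = 4), k = 4), 0:255)
})

test_that("back-projection follows X = xZ/f and round-trips the forward map", {
  cam <- camera_model(f = 100, k = 4, width = 64, height = 64)
  expect_equal(unname(back_project(0, 0, 1.7, cam)), cbind(0, 0, 1.7),
               ignore_attr = TRUE)
  expect_equal(unname(back_project(100, 0, 2, cam)[1, "X"]), 2)
  with_seed(5, {
    for (i in 1:20) {
      P <- c(runif(2, -1, 1), runif(1, 0.5, 4))
      p <- project_point(P[1], P[2], P[3], cam)
      back <- back_project(p[1, "x"], p[1, "y"], P[3], cam)
      expect_equal(unname(back[1, ]), P, tolerance = 1e-12)
    }
  })
  expect_error(camera_model(f = -1), "f must be")
})

test_that("leaf reconstruction composes conversion and projection per pixel", {
  cam <- camera_model(f = 100, k = 4, width = 9, height = 9,
                      principal = c(5, 5))
  depth <- matrix(255L, 9, 9)
  lf <- reconstruct_leaf(cbind(5, 5), depth, cam)
  expect_equal(unname(lf$points[1, ]), c(0, 0, 4))
  expect_equal(lf$w, 1)

  with_seed(8, {
    for (i in 1:5) {
      n <- sample(3:30, 1)
      reg <- unique(cbind(sample.int(9, n, TRUE), sample.int(9, n, TRUE)))
      lf <- reconstruct_leaf(reg, depth, cam)
      expect_equal(lf$w, nrow(reg))
      # constant depth => coplanar, constant Z
      expect_equal(unname(lf$points[, 3]), rep(4, nrow(reg)))
      # plane fit residual is exactly zero
      expect_equal(stats::sd(lf$points[, 3]), 0)
    }
  })
  expect_error(reconstruct_leaf(matrix(numeric(), 0, 2), depth, cam),
               "at least one pixel")
})

test_that("moments and centroid equal the brute-force summation oracle", {
  pts <- rbind(c(1, 2, 3), c(3, 4, 5))
  expect_equal(leaf_moments(pts, 1, 0, 0), 4)
  expect_equal(leaf_moments(pts, 0, 1, 0), 6)
  expect_equal(leaf_moments(pts, 0, 0, 1), 8)
  expect_equal(unname(leaf_centroid(pts)), c(2, 3, 4))

  cloud7 <- matrix(rnorm(21), 7, 3)
  expect_equal(leaf_moments(cloud7, 0, 0, 0), 7)

  with_seed(13, {
    for (i in 1:10) {
      pts <- matrix(rnorm(3 * sample(1:40, 1)), ncol = 3)
      for (ord in list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                       c(1, 1, 0), c(1, 1, 1))) {
        brute <- sum(apply(pts, 1, function(p) {
          p[1]^ord[1] * p[2]^ord[2] * p[3]^ord[3]
        }))
        expect_equal(leaf_moments(pts, ord[1], ord[2], ord[3]), brute)
      }
      expect_equal(unname(leaf_centroid(pts)), unname(colMeans(pts)))
      # translation equivariance
      t3 <- rnorm(3)
      shifted <- sweep(pts, 2, t3, "+")
      expect_equal(unname(leaf_centroid(shifted)),
                   unname(leaf_centroid(pts)) + t3)
      expect_equal(leaf_moments(shifted, 1, 0, 0),
                   leaf_moments(pts, 1, 0, 0) + nrow(pts) * t3[1])
    }
  })
  expect_error(leaf_moments(pts, 2, 0, 0), "0 or 1")
  expect_error(leaf_centroid(matrix(numeric(), 0, 3)), "empty")
})

test_that("RMS error matches its closed forms and the printed table row", {
  gt <- matrix(rnorm(15), 5, 3)
  z <- rms_error(gt, gt)
  expect_equal(unname(z$per_axis), c(0, 0, 0))
  expect_equal(z$average, 0)

  one <- rms_error(rbind(c(0.3, 0, 0.4)), rbind(c(0, 0, 0)))
  expect_equal(unname(one$per_axis), c(0.3, 0, 0.4))

  # printed per-axis values average to the printed overall value
  per_axis <- c(0.009217, 0.008913, 0.069241)
  expect_equal(round(mean(per_axis), 6), 0.029124)

  # invariance to pair ordering
  with_seed(21, {
    pred <- gt + matrix(rnorm(15, sd = 0.01), 5, 3)
    perm <- sample(5)
    a <- rms_error(pred, gt)
    b <- rms_error(pred[perm, ], gt[perm, ])
    expect_equal(a$per_axis, b$per_axis)
    expect_true(all(a$per_axis >= 0))
  })

  # nearest-neighbour matching recovers a shuffled correspondence
  shuffled <- gt[c(3, 1, 5, 2, 4), ]
  nn <- rms_error(shuffled, gt, matching = "nearest")
  expect_equal(unname(nn$per_axis), c(0, 0, 0))
  expect_equal(nn$n_matched, 5)
  expect_error(rms_error(gt[1:2, ], gt, matching = "paired"), "equally many")
})

test_that("PLY export writes a readable ASCII point cloud", {
  cam <- test_camera()
  depth <- matrix(128L, 96, 96)
  lf <- reconstruct_leaf(cbind(40:44, 50), depth, cam, id = 3L)
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(lf, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  expect_equal(sum(grepl("^element vertex", lines)), 1)
  n_declared <- as.integer(sub("element vertex ", "",
                               lines[grepl("^element vertex", lines)]))
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  expect_equal(length(body), n_declared)
  expect_equal(n_declared, lf$w)
})
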