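# Metric 3D recovery: depth-code conversion, pinhole back-projection,
# per-leaf moments/centroids and centroid RMS error.

#' Pinhole camera model
#'
#' @param f Focal length in pixels (must be positive).
#' @param k Maximum sensor depth in meters; the 8-bit depth code 255 maps to
#'   `k`.
#' @param width,height Image size in pixels.
#' @param principal Principal point as `c(row, col)` in 1-based pixel
#'   coordinates; defaults to the image center.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(f = 525, k = 4, width = 640L, height = 480L,
                         principal = NULL) {
  assert_that(is.numeric(f) && f > 0, "focal length f must be > 0")
  assert_that(is.numeric(k) && k > 0, "maximum depth k must be > 0")
  if (is.null(principal)) principal <- c((height + 1) / 2, (width + 1) / 2)
  assert_that(principal[1] >= 1 && principal[1] <= height &&
                principal[2] >= 1 && principal[2] <= width,
              "principal point must lie inside the image")
  structure(list(f = f, k = k, width = as.integer(width),
                 height = as.integer(height), principal = principal),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> f = %g px, k = %g m, %d x %d, principal (%g, %g)\n",
              x$f, x$k, x$width, x$height, x$principal[1], x$principal[2]))
  invisible(x)
}

#' Convert an 8-bit depth code to metric depth
#'
#' `Z = k * z / 255`: code 0 is the camera plane, code 255 the maximum sensor
#' depth `k`.
#'
#' @param z Depth code(s) in `[0, 255]`.
#' @param k Maximum depth in meters (or a `camera_model`).
#' @return Depth in meters, same shape as `z`.
#' @export
code_to_depth <- function(z, k = 4) {
  if (inherits(k, "camera_model")) k <- k$k
  assert_that(k > 0, "maximum depth k must be > 0")
  if (any(z < 0 | z > 255, na.rm = TRUE)) {
    stop("depth codes must lie in [0, 255]", call. = FALSE)
  }
  k * z / 255
}

#' Encode metric depth as an 8-bit code
#'
#' Inverse of [code_to_depth()] up to rounding; values are clipped to
#' `[0, 255]`.
#' @inheritParams code_to_depth
#' @param Z Depth in meters.
#' @export
depth_to_code <- function(Z, k = 4) {
  if (inherits(k, "camera_model")) k <- k$k
  clamp(round(255 * Z / k), 0, 255)
}

#' Back-project image-plane coordinates to 3D
#'
#' `X = x * Z / f`, `Y = y * Z / f` with `x`, `y` measured in pixels relative
#' to the principal point (x rightward along columns, y downward along rows).
#'
#' @param x,y Image-plane coordinates relative to the principal point, pixels.
#' @param Z Metric depth (meters), non-negative.
#' @param cam A `camera_model` (or a bare focal length).
#' @return A matrix with columns `X`, `Y`, `Z` (meters).
#' @export
back_project <- function(x, y, Z, cam) {
  f <- if (inherits(cam, "camera_model")) cam$f else cam
  assert_that(is.numeric(f) && f > 0, "focal length f must be > 0")
  assert_that(all(Z >= 0), "depth Z must be non-negative")
  cbind(X = x * Z / f, Y = y * Z / f, Z = Z)
}

#' Project a 3D point onto the image plane
#'
#' The forward pinhole map `P(X, Y, Z) -> p(fX/Z, fY/Z)`.
#' @inheritParams back_project
#' @param X,Y 3D coordinates in meters.
#' @return Matrix with columns `x`, `y` (pixels relative to the principal
#'   point).
#' @export
project_point <- function(X, Y, Z, cam) {
  f <- if (inherits(cam, "camera_model")) cam$f else cam
  assert_that(all(Z > 0), "projection requires Z > 0")
  cbind(x = f * X / Z, y = f * Y / Z)
}

#' Reconstruct one leaf region as a metric point cloud
#'
#' Every pixel of the region is converted to depth via [code_to_depth()] and
#' back-projected through the pinhole model; moments of order 0/1 and the
#' centroid are attached.
#'
#' @param region Two-column matrix of `(row, col)` pixel coordinates
#'   (1-based).
#' @param depth A `depth_map` or a plain matrix of depth codes in `[0, 255]`.
#' @param cam A [camera_model()].
#' @param id Optional leaf/superpixel id tag.
#' @return An object of class `leaf3d` with fields `points` (w x 3 matrix),
#'   `w`, `id`, `moments` and `centroid`.
#' @export
reconstruct_leaf <- function(region, depth, cam, id = NA_integer_) {
  region <- as.matrix(region)
  assert_that(nrow(region) >= 1, "leaf region must contain at least one pixel")
  codes <- if (inherits(depth, "depth_map")) depth$codes else depth
  assert_that(all(region[, 1] >= 1 & region[, 1] <= nrow(codes) &
                    region[, 2] >= 1 & region[, 2] <= ncol(codes)),
              "region lies outside the depth map")
  z <- codes[region]
  Z <- code_to_depth(z, cam)
  x <- region[, 2] - cam$principal[2]
  y <- region[, 1] - cam$principal[1]
  pts <- back_project(x, y, Z, cam)
  moments <- list(m000 = nrow(pts),
                  m100 = sum(pts[, 1]), m010 = sum(pts[, 2]),
                  m001 = sum(pts[, 3]))
  structure(list(points = pts, w = nrow(pts), id = id, moments = moments,
                 centroid = c(X = moments$m100, Y = moments$m010,
                              Z = moments$m001) / moments$m000),
            class = "leaf3d")
}

#' @export
print.leaf3d <- function(x, ...) {
  cat(sprintf("<leaf3d> id %s, w = %d points, centroid (%.4f, %.4f, %.4f) m\n",
              as.character(x$id), x$w,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Geometric moments of a 3D point cloud
#'
#' `m[p,q,g] = sum over the w points of X^p * Y^q * Z^g`; only orders 0 and 1
#' are supported (all that the centroid needs).
#'
#' @param points A w x 3 matrix of `(X, Y, Z)` or a `leaf3d`.
#' @param p,q,g Moment orders, each 0 or 1.
#' @return The scalar moment.
#' @export
leaf_moments <- function(points, p = 0L, q = 0L, g = 0L) {
  if (inherits(points, "leaf3d")) points <- points$points
  points <- as.matrix(points)
  assert_that(nrow(points) >= 1, "point cloud is empty")
  if (!all(c(p, q, g) %in% c(0L, 1L))) {
    stop("moment orders p, q, g must each be 0 or 1", call. = FALSE)
  }
  sum(points[, 1]^p * points[, 2]^q * points[, 3]^g)
}

#' Centroid of a 3D leaf
#'
#' Component-wise ratio of first- to zeroth-order moments, i.e. the coordinate
#' mean of the point cloud.
#'
#' @param leaf A `leaf3d` or a w x 3 point matrix.
#' @return Named numeric `c(X, Y, Z)` in meters.
#' @export
leaf_centroid <- function(leaf) {
  pts <- if (inherits(leaf, "leaf3d")) leaf$points else as.matrix(leaf)
  assert_that(nrow(pts) >= 1, "cannot take the centroid of an empty leaf")
  m0 <- leaf_moments(pts, 0L, 0L, 0L)
  c(X = leaf_moments(pts, 1L, 0L, 0L) / m0,
    Y = leaf_moments(pts, 0L, 1L, 0L) / m0,
    Z = leaf_moments(pts, 0L, 0L, 1L) / m0)
}

#' Per-axis RMS error between predicted and ground-truth centroids
#'
#' Root of the mean squared matched-pair difference, reported per axis plus
#' their arithmetic mean. Pairs are matched positionally (`"paired"`) or by
#' greedy nearest-neighbour in the `(X, Y)` plane (`"nearest"`) with an
#' optional gating radius; unmatched centroids are excluded and counted.
#'
#' @param pred,gt Matrices (or lists of `leaf3d`) of centroids, columns
#'   `(X, Y, Z)`.
#' @param matching `"paired"` (row i vs row i) or `"nearest"`.
#' @param gate Maximum `(X, Y)` distance for a nearest-neighbour match.
#' @return List with `per_axis` (named `X`, `Y`, `Z`), `average`, `n_matched`,
#'   `n_unmatched`.
#' @export
rms_error <- function(pred, gt, matching = c("paired", "nearest"), gate = Inf) {
  matching <- match.arg(matching)
  to_mat <- function(v) {
    if (is.list(v) && !is.data.frame(v)) {
      v <- do.call(rbind, lapply(v, function(l) {
        if (inherits(l, "leaf3d")) l$centroid else as.numeric(l)
      }))
    }
    as_plain_matrix(v)
  }
  pred <- to_mat(pred)
  gt <- to_mat(gt)
  if (matching == "paired") {
    assert_that(nrow(pred) == nrow(gt) && nrow(pred) >= 1,
                "paired matching needs equally many predictions and ground truths")
    pairs <- cbind(seq_len(nrow(pred)), seq_len(nrow(gt)))
  } else {
    d <- outer(seq_len(nrow(pred)), seq_len(nrow(gt)), function(i, j) {
      sqrt((pred[i, 1] - gt[j, 1])^2 + (pred[i, 2] - gt[j, 2])^2)
    })
    pairs <- matrix(integer(), 0, 2)
    while (length(d) && any(is.finite(d)) && min(d, na.rm = TRUE) <= gate) {
      ij <- arrayInd(which.min(d), dim(d))
      pairs <- rbind(pairs, ij)
      d[ij[1], ] <- Inf
      d[, ij[2]] <- Inf
    }
    assert_that(nrow(pairs) >= 1, "no centroid pairs matched within the gate")
  }
  diff <- pred[pairs[, 1], , drop = FALSE] - gt[pairs[, 2], , drop = FALSE]
  per_axis <- sqrt(colMeans(diff^2))
  names(per_axis) <- c("X", "Y", "Z")
  list(per_axis = per_axis, average = mean(per_axis),
       n_matched = nrow(pairs),
       n_unmatched = (nrow(pred) - nrow(pairs)) + (nrow(gt) - nrow(pairs)))
}

#' Write leaves as an ASCII PLY point cloud
#'
#' Vertices carry `x`, `y`, `z` in meters plus an integer `leaf` id property.
#'
#' @param leaves A `leaf3d`, a list of them, or a points matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(leaves, path) {
  if (inherits(leaves, "leaf3d")) leaves <- list(leaves)
  if (is.matrix(leaves)) {
    leaves <- list(structure(list(points = leaves, id = 1L), class = "leaf3d"))
  }
  pts <- do.call(rbind, lapply(leaves, function(l) {
    cbind(l$points, leaf = rep(if (is.na(l$id)) 0L else as.integer(l$id),
                               nrow(l$points)))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z",
               "property int leaf", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %d",
                     pts[, 1], pts[, 2], pts[, 3], as.integer(pts[, 4])), con)
  invisible(path)
}
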