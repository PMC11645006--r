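# SLIC superpixels and purity-gated leaf detection.
#
# Superpixels are clustered in CIELAB + (x, y) with the standard SLIC distance
# d^2 = d_lab^2 + (m/S)^2 d_xy^2, searched over 2S x 2S windows. Connectivity
# is enforced afterwards by connected-component relabelling; fragments smaller
# than a quarter of the expected superpixel size are merged into the adjacent
# component sharing the longest border.

rgb_to_lab <- function(image) {
  d <- dim(image)
  m <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

#' Compute SLIC superpixels
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param n_desired Desired number of superpixels (the achieved count may
#'   differ and is recorded in the result).
#' @param iterations Number of pixel-level assignment iterations.
#' @param smoothing Shape smoothing (compactness) term `m`.
#' @return A `superpixel_map`: list with `assignment` (H x W integer ids
#'   forming a partition of 4-connected regions), `n`, `sizes` (pixel count
#'   per superpixel) and `params`.
#' @export
compute_superpixels <- function(image, n_desired = 999L, iterations = 9L,
                                smoothing = 5) {
  assert_that(length(dim(image)) == 3L && all(dim(image)[1:2] > 0L),
              "image must be a non-empty H x W x 3 array")
  assert_that(n_desired >= 1L, "n_desired must be >= 1")
  H <- dim(image)[1]
  W <- dim(image)[2]
  npix <- H * W
  lab <- rgb_to_lab(image)
  xv <- rep(seq_len(W), each = H)
  yv <- rep(seq_len(H), W)
  S <- sqrt(npix / n_desired)
  cy <- seq(S / 2, H, by = S)
  cx <- seq(S / 2, W, by = S)
  centers_xy <- cbind(x = rep(cx, times = length(cy)),
                      y = rep(cy, each = length(cx)))
  ncen <- nrow(centers_xy)
  # seed center features from the nearest pixel
  pix <- cbind(clamp(round(centers_xy[, "y"]), 1, H),
               clamp(round(centers_xy[, "x"]), 1, W))
  cen <- cbind(lab[pix[, 1] + (pix[, 2] - 1L) * H, , drop = FALSE],
               centers_xy)
  wxy <- (smoothing / S)^2
  labm <- integer(npix)
  distm <- rep(Inf, npix)
  for (it in seq_len(as.integer(iterations))) {
    distm[] <- Inf
    labm[] <- 0L
    for (ci in seq_len(ncen)) {
      r1 <- max(1L, floor(cen[ci, 5] - S))
      r2 <- min(H, ceiling(cen[ci, 5] + S))
      c1 <- max(1L, floor(cen[ci, 4] - S))
      c2 <- min(W, ceiling(cen[ci, 4] + S))
      idx <- as.vector(outer(r1:r2, (c1:c2 - 1L) * H, "+"))
      dl <- (lab[idx, 1] - cen[ci, 1])^2 + (lab[idx, 2] - cen[ci, 2])^2 +
        (lab[idx, 3] - cen[ci, 3])^2
      dxy <- (xv[idx] - cen[ci, 4])^2 + (yv[idx] - cen[ci, 5])^2
      dd <- dl + wxy * dxy
      upd <- dd < distm[idx]
      ii <- idx[upd]
      distm[ii] <- dd[upd]
      labm[ii] <- ci
    }
    # stragglers outside every search window: nearest center spatially
    miss <- which(labm == 0L)
    if (length(miss)) {
      for (i in miss) {
        labm[i] <- which.min((cen[, 4] - xv[i])^2 + (cen[, 5] - yv[i])^2)
      }
    }
    sums <- rowsum(cbind(lab, xv, yv), labm, reorder = TRUE)
    cnt <- as.vector(table(factor(labm, levels = sort(unique(labm)))))
    keep <- sort(unique(labm))
    cen[keep, ] <- sums / cnt
  }
  assignment <- enforce_connectivity(matrix(labm, H, W),
                                     min_size = max(1L, floor(0.25 * npix /
                                                                ncen)))
  n <- max(assignment)
  structure(list(assignment = assignment, n = n,
                 sizes = tabulate(assignment, nbins = n),
                 params = list(n_desired = as.integer(n_desired),
                               iterations = as.integer(iterations),
                               smoothing = smoothing)),
            class = "superpixel_map")
}

# Relabel so every superpixel is one 4-connected component; merge small
# fragments into the adjacent component with the longest shared border.
enforce_connectivity <- function(assignment, min_size = 1L) {
  H <- nrow(assignment)
  W <- ncol(assignment)
  npix <- H * W
  id <- as.vector(assignment)
  # edges between 4-neighbours sharing a label
  vert_a <- as.vector(outer(seq_len(H - 1L), (seq_len(W) - 1L) * H, "+"))
  vert_b <- vert_a + 1L
  horiz_a <- seq_len(npix - H)
  horiz_b <- horiz_a + H
  keep_v <- id[vert_a] == id[vert_b]
  keep_h <- id[horiz_a] == id[horiz_b]
  g <- igraph::graph_from_edgelist(
    cbind(c(vert_a[keep_v], horiz_a[keep_h]),
          c(vert_b[keep_v], horiz_b[keep_h])), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, npix - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(npix)]
  csize <- tabulate(comp)
  if (any(csize < min_size)) {
    small <- order(csize)[csize[order(csize)] < min_size]
    for (s in small) {
      px <- which(comp == s)
      nb <- integer(0)
      r <- ((px - 1L) %% H) + 1L
      cl <- ((px - 1L) %/% H) + 1L
      for (shift in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + shift[1]
        cc <- cl + shift[2]
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        nb <- c(nb, comp[rr[ok] + (cc[ok] - 1L) * H])
      }
      nb <- nb[nb != s]
      if (!length(nb)) next
      target <- as.integer(names(which.max(table(nb))))
      comp[px] <- target
      csize[target] <- csize[target] + length(px)
      csize[s] <- 0L
    }
  }
  matrix(match(comp, sort(unique(comp))), H, W)
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d x %d, %d superpixels (desired %d, %d iters, m = %g)\n",
              nrow(x$assignment), ncol(x$assignment), x$n,
              x$params$n_desired, x$params$iterations, x$params$smoothing))
  invisible(x)
}
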