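# Leaf detection: keep exactly those superpixels made entirely of plant
# pixels. With phi_i the pixel count of superpixel i and gamma_i its count of
# plant-labelled pixels, the gate is the strict purity rule
# S(theta_i) = 1 iff phi_i = gamma_i; impure superpixels are discarded.

#' Gate superpixels on segmentation purity
#'
#' @param spmap A [compute_superpixels()] map.
#' @param mask A `segmentation_mask` or 0/1 plant-mask matrix of the same
#'   size.
#' @return A `leaf_region_set`: list with `phi` (pixels per superpixel),
#'   `gamma` (plant pixels per superpixel), `theta` (0/1 keep decisions),
#'   `kept_ids`, and the `assignment` matrix.
#' @export
classify_superpixels <- function(spmap, mask) {
  assert_that(inherits(spmap, "superpixel_map"),
              "spmap must be a superpixel_map")
  lab <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  assert_that(all(dim(spmap$assignment) == dim(lab)),
              "superpixel map and mask disagree on size")
  n <- spmap$n
  phi <- tabulate(spmap$assignment, nbins = n)
  gamma <- tabulate(spmap$assignment[lab == 1L], nbins = n)
  theta <- as.integer(phi == gamma & phi > 0L)
  structure(list(phi = phi, gamma = gamma, theta = theta,
                 kept_ids = which(theta == 1L),
                 assignment = spmap$assignment),
            class = "leaf_region_set")
}

#' @export
print.leaf_region_set <- function(x, ...) {
  cat(sprintf("<leaf_region_set> %d/%d superpixels kept (%d leaf pixels)\n",
              length(x$kept_ids), length(x$phi),
              sum(x$phi[x$kept_ids])))
  invisible(x)
}

#' Pixel coordinates of one region
#'
#' @param x A `leaf_region_set` or `superpixel_map`.
#' @param id Superpixel id.
#' @return Two-column `(row, col)` matrix.
#' @export
region_pixels <- function(x, id) {
  which(x$assignment == id, arr.ind = TRUE)
}

# 0/1 mask of all kept leaf pixels.
kept_pixel_mask <- function(lrs) {
  matrix(as.integer(lrs$assignment %in% lrs$kept_ids),
         nrow(lrs$assignment), ncol(lrs$assignment))
}

#' Merge adjacent kept superpixels into connected leaf regions
#'
#' Kept superpixels are leaf *sections*; touching sections (4-connectivity)
#' belong to the same leaf, so merging the kept set's connected components
#' yields one region per (possibly partially occluded) leaf. Discarded
#' superpixels are unaffected.
#'
#' @param lrs A [classify_superpixels()] result.
#' @return A `leaf_region_set` whose kept regions are connected components of
#'   the kept pixel set (ids renumbered; `phi = gamma` by construction).
#' @export
merge_leaf_regions <- function(lrs) {
  assert_that(inherits(lrs, "leaf_region_set"), "lrs must be a leaf_region_set")
  keep <- matrix(lrs$assignment %in% lrs$kept_ids,
                 nrow(lrs$assignment), ncol(lrs$assignment))
  if (!any(keep)) {
    out <- lrs
    out$assignment <- matrix(0L, nrow(keep), ncol(keep))
    out$phi <- out$gamma <- integer(0)
    out$theta <- integer(0)
    out$kept_ids <- integer(0)
    return(out)
  }
  H <- nrow(keep)
  W <- ncol(keep)
  kv <- as.vector(keep)
  va <- as.vector(outer(seq_len(H - 1L), (seq_len(W) - 1L) * H, "+"))
  ha <- seq_len(H * W - H)
  ev <- va[kv[va] & kv[va + 1L]]
  eh <- ha[kv[ha] & kv[ha + H]]
  g <- igraph::graph_from_edgelist(cbind(c(ev, eh), c(ev + 1L, eh + H)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, H * W - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(H * W)]
  memb[!kv] <- 0L
  ids <- sort(unique(memb[memb > 0L]))
  comp <- matrix(ifelse(memb > 0L, match(memb, ids), 0L), H, W)
  n <- length(ids)
  phi <- tabulate(comp[comp > 0L], nbins = n)
  structure(list(phi = phi, gamma = phi, theta = rep(1L, n),
                 kept_ids = seq_len(n), assignment = comp),
            class = "leaf_region_set")
}

#' Export kept leaf regions as run-length-encoded JSON
#'
#' Column-major runs (`start`, `length`) per kept superpixel.
#'
#' @param lrs A `leaf_region_set`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
leaf_regions_to_json <- function(lrs, path = NULL) {
  H <- nrow(lrs$assignment)
  regions <- lapply(lrs$kept_ids, function(id) {
    lin <- sort(which(lrs$assignment == id))
    breaks <- c(0L, which(diff(lin) != 1L), length(lin))
    runs <- cbind(start = lin[breaks[-length(breaks)] + 1L],
                  length = diff(breaks))
    list(id = id, pixels = sum(runs[, "length"]), runs = runs)
  })
  js <- jsonlite::toJSON(list(height = H, width = ncol(lrs$assignment),
                              order = "column-major", regions = regions),
                         auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' End-to-end metric sweep over the desired superpixel count
#'
#' Runs segmentation + superpixel gating for each candidate count on a set of
#' scenes and tabulates pixel-level precision, recall, F1 and accuracy of the
#' kept leaf pixels against the ground-truth plant masks.
#'
#' @param scenes List of [generate_scene()] scenes (or lists with `rgb` and
#'   `plant_mask`).
#' @param seg_model A trained [train_segmenter()] model.
#' @param counts Candidate desired superpixel counts.
#' @param stride Sliding-window stride for segmentation.
#' @param iterations,smoothing SLIC parameters.
#' @return Data frame with one row per count.
#' @export
sweep_superpixel_count <- function(scenes, seg_model,
                                   counts = c(800L, 900L, 999L, 1100L, 1200L),
                                   stride = 2L, iterations = 9L,
                                   smoothing = 5) {
  assert_that(length(counts) >= 1L, "counts must be non-empty")
  if (inherits(scenes, "scene")) scenes <- list(scenes)
  masks <- lapply(scenes, function(sc) segment_image(seg_model, sc$rgb, stride))
  rows <- lapply(counts, function(k) {
    tp <- tn <- fp <- fn <- 0
    for (i in seq_along(scenes)) {
      sp <- compute_superpixels(scenes[[i]]$rgb, n_desired = k,
                                iterations = iterations,
                                smoothing = smoothing)
      lrs <- classify_superpixels(sp, masks[[i]])
      pred <- kept_pixel_mask(lrs)
      truth <- scenes[[i]]$plant_mask
      tp <- tp + sum(pred == 1L & truth == 1L)
      tn <- tn + sum(pred == 0L & truth == 0L)
      fp <- fp + sum(pred == 1L & truth == 0L)
      fn <- fn + sum(pred == 0L & truth == 1L)
    }
    b <- basic_metrics(confusion_counts(tp = tp, tn = tn, fp = fp, fn = fn))
    data.frame(n_superpixels = k, precision = b$precision, recall = b$recall,
               f1 = b$f1, accuracy = b$accuracy)
  })
  do.call(rbind, rows)
}
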