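# SLIC superpixels and the purity gate.

test_that("SLIC produces a conserving partition of 4-connected superpixels", {
  cfg <- small_scene_config(width = 64L, height = 64L)
  sc <- generate_scene(cfg, default_groups()$C, seed = 2)
  sp <- compute_superpixels(sc$rgb, n_desired = 60)
  expect_s3_class(sp, "superpixel_map")
  expect_equal(sum(sp$sizes), 64 * 64)
  expect_equal(sort(unique(as.vector(sp$assignment))), seq_len(sp$n))
  expect_equal(sp$params, list(n_desired = 60L, iterations = 9L,
                               smoothing = 5))
  # 4-connectivity of every superpixel, via graph components
  H <- nrow(sp$assignment)
  W <- ncol(sp$assignment)
  id <- as.vector(sp$assignment)
  va <- as.vector(outer(seq_len(H - 1L), (seq_len(W) - 1L) * H, "+"))
  ha <- seq_len(H * W - H)
  edges <- rbind(cbind(va, va + 1L), cbind(ha, ha + H))
  edges <- edges[id[edges[, 1]] == id[edges[, 2]], ]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, H * W - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # each superpixel id must map to exactly one component
  expect_true(all(tapply(comp, id, function(v) length(unique(v))) == 1))
})

test_that("default parameters are recorded and degenerate cases behave", {
  uni <- array(0.5, c(40, 40, 3))
  sp1 <- compute_superpixels(uni, n_desired = 1)
  expect_equal(sp1$n, 1)
  expect_true(all(sp1$assignment == 1L))
  spd <- compute_superpixels(uni)
  expect_equal(spd$params$n_desired, 999L)
  expect_equal(spd$params$iterations, 9L)
  expect_equal(spd$params$smoothing, 5)
  expect_error(compute_superpixels(uni, n_desired = 0), "n_desired")
})

test_that("purity gating equals the brute-force per-superpixel scan", {
  cfg <- small_scene_config(width = 64L, height = 64L)
  sc <- generate_scene(cfg, default_groups()$D, seed = 4)
  sp <- compute_superpixels(sc$rgb, n_desired = 80)
  with_seed(6, {
    for (rep in 1:3) {
      mask <- matrix(rbinom(64 * 64, 1, 0.8), 64, 64)
      lrs <- classify_superpixels(sp, mask)
      brute_keep <- vapply(seq_len(sp$n), function(i) {
        all(mask[sp$assignment == i] == 1L)
      }, logical(1))
      expect_identical(lrs$kept_ids, which(brute_keep))
      expect_identical(lrs$theta, as.integer(brute_keep))
      # kept-region pixel union equals the brute-force union
      expect_identical(kept_pixel_mask(lrs) == 1L,
                       matrix(sp$assignment %in% which(brute_keep), 64, 64))
      # phi/gamma bookkeeping
      expect_equal(sum(lrs$phi), 64 * 64)
      expect_equal(sum(lrs$gamma), sum(mask))
      # strict equality gate: an almost-pure superpixel is dropped
      big <- which.max(lrs$phi)
      m2 <- mask
      m2[sp$assignment == big] <- 1L
      px <- which(sp$assignment == big)[1]
      m2[px] <- 0L
      lrs2 <- classify_superpixels(sp, m2)
      expect_false(big %in% lrs2$kept_ids)
      m2[px] <- 1L
      lrs3 <- classify_superpixels(sp, m2)
      expect_true(big %in% lrs3$kept_ids)
    }
  })
  # saturated gate: all-plant mask keeps everything
  ones <- matrix(1L, 64, 64)
  expect_equal(classify_superpixels(sp, ones)$kept_ids, seq_len(sp$n))
  expect_error(classify_superpixels(sp, matrix(1L, 10, 10)), "disagree")
})

test_that("gating is monotone in the mask", {
  cfg <- small_scene_config(width = 48L, height = 48L)
  sc <- generate_scene(cfg, default_groups()$C, seed = 5)
  sp <- compute_superpixels(sc$rgb, n_desired = 40)
  with_seed(9, {
    mask <- matrix(rbinom(48 * 48, 1, 0.7), 48, 48)
    n0 <- length(classify_superpixels(sp, mask)$kept_ids)
    for (rep in 1:5) {
      flips <- sample(which(mask == 0L), min(50, sum(mask == 0L)))
      mask[flips] <- 1L
      n1 <- length(classify_superpixels(sp, mask)$kept_ids)
      expect_gte(n1, n0)
      n0 <- n1
    }
  })
})

test_that("run-length JSON export reconstructs the kept regions", {
  cfg <- small_scene_config(width = 48L, height = 48L)
  sc <- generate_scene(cfg, default_groups()$C, seed = 6)
  sp <- compute_superpixels(sc$rgb, n_desired = 30)
  lrs <- classify_superpixels(sp, sc$plant_mask)
  js <- jsonlite::fromJSON(leaf_regions_to_json(lrs), simplifyVector = FALSE)
  expect_equal(js$height, 48)
  expect_equal(length(js$regions), length(lrs$kept_ids))
  if (length(js$regions)) {
    r1 <- js$regions[[1]]
    runs <- do.call(rbind, lapply(r1$runs, unlist))
    pix <- unlist(mapply(function(s, l) s:(s + l - 1), runs[, 1], runs[, 2],
                         SIMPLIFY = FALSE))
    expect_setequal(pix, which(lrs$assignment == r1$id))
  }
})

test_that("the superpixel-count sweep tabulates end-to-end metrics per count", {
  m <- toy_segmenter()
  toys <- lapply(1:2, function(i) {
    t <- toy_two_color_image(seed = 80 + i)
    list(rgb = t$rgb, plant_mask = t$mask)
  })
  tab <- sweep_superpixel_count(toys, m, counts = c(40L, 80L), stride = 4L)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_superpixels, c(40L, 80L))
  vals <- unlist(tab[, c("precision", "recall", "f1", "accuracy")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  single <- sweep_superpixel_count(toys, m, counts = 60L, stride = 4L)
  expect_equal(nrow(single), 1)
  expect_error(sweep_superpixel_count(toys, m, counts = integer(0)),
               "non-empty")
})
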