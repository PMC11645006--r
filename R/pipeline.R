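# End-to-end orchestration: recognition -> leaf detection -> depth ->
# 3D reconstruction -> stress classification.

#' Pipeline configuration
#'
#' Bundles the three trained models with the geometric and algorithmic
#' parameters of a run. Models may be given as objects or as checkpoint paths
#' (loaded lazily at run time; a missing checkpoint errors naming its stage).
#'
#' @param seg_model,depth_model,stress_model Trained models or checkpoint
#'   paths.
#' @param camera A [camera_model()].
#' @param patch Patch size in pixels.
#' @param seg_stride,depth_stride Sliding-window strides.
#' @param slic List with `n_desired`, `iterations`, `smoothing`.
#' @param feature_mode `"heights"` or `"full_centroids"`.
#' @param merge_regions Merge adjacent kept superpixels into connected leaf
#'   regions before reconstruction (see [merge_leaf_regions()]).
#' @param pad_value Feature-vector filler.
#' @param seed Seed recorded in reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seg_model, depth_model, stress_model,
                            camera = camera_model(), patch = 32L,
                            seg_stride = 1L, depth_stride = 1L,
                            slic = list(n_desired = 999L, iterations = 9L,
                                        smoothing = 5),
                            feature_mode = "heights", merge_regions = TRUE,
                            pad_value = 0, seed = 1L) {
  structure(list(seg_model = seg_model, depth_model = depth_model,
                 stress_model = stress_model, camera = camera,
                 patch = as.integer(patch),
                 seg_stride = as.integer(seg_stride),
                 depth_stride = as.integer(depth_stride),
                 slic = utils::modifyList(list(n_desired = 999L,
                                               iterations = 9L,
                                               smoothing = 5), slic),
                 feature_mode = feature_mode,
                 merge_regions = isTRUE(merge_regions),
                 pad_value = pad_value, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_model <- function(m, class, stage) {
  if (inherits(m, class)) return(m)
  if (is.character(m)) {
    if (!file.exists(m)) {
      stop(sprintf("stage '%s': checkpoint not found: %s", stage, m),
           call. = FALSE)
    }
    m <- load_model(m)
  }
  assert_that(inherits(m, class),
              sprintf("stage '%s': model is not a %s", stage, class))
  m
}

#' Run the full stress-detection pipeline on one RGB image
#'
#' Stages, in order: sliding-window plant segmentation, SLIC superpixels and
#' purity gating, dense depth inference, per-leaf pinhole reconstruction and
#' centroids, feature-vector construction and DNN stress classification.
#' A plantless image yields zero kept superpixels, a fully padded feature
#' vector, and a report flagged `no_foliage` / low-confidence (classification
#' still runs on the padded vector).
#'
#' @param config A [pipeline_config()].
#' @param image H x W x 3 RGB array or a [generate_scene()] scene.
#' @return A `pipeline_result`: list with `mask`, `superpixels`, `regions`,
#'   `depth`, `leaves`, `feature`, `label`, `score` and a `report` of
#'   per-stage counts, parameters, seeds and timings.
#' @export
run_pipeline <- function(config, image) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  if (inherits(image, "scene")) image <- image$rgb
  assert_that(length(dim(image)) == 3L, "image must be an H x W x 3 array")
  seg <- resolve_model(config$seg_model, "seg_model", "recognition")
  dep <- resolve_model(config$depth_model, "depth_model", "depth")
  str <- resolve_model(config$stress_model, "stress_model", "classification")
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  mask <- segment_image(seg, image, stride = config$seg_stride)
  timings["segmentation"] <- tic() - t0

  t0 <- tic()
  sp <- compute_superpixels(image, n_desired = config$slic$n_desired,
                            iterations = config$slic$iterations,
                            smoothing = config$slic$smoothing)
  regions <- classify_superpixels(sp, mask)
  if (config$merge_regions) regions <- merge_leaf_regions(regions)
  timings["leaf_detection"] <- tic() - t0

  t0 <- tic()
  dm <- infer_depth(dep, image, stride = config$depth_stride)
  timings["depth"] <- tic() - t0

  t0 <- tic()
  leaves <- lapply(regions$kept_ids, function(id) {
    reconstruct_leaf(region_pixels(regions, id), dm, config$camera, id = id)
  })
  feature <- build_feature_vector(leaves, mode = config$feature_mode,
                                  pad_value = config$pad_value)
  timings["reconstruction"] <- tic() - t0

  t0 <- tic()
  cls <- classify_stress(str, feature)
  timings["classification"] <- tic() - t0

  no_foliage <- length(regions$kept_ids) == 0L
  report <- list(
    n_windows_segmented = mask$n_windows,
    n_superpixels = sp$n,
    n_kept_superpixels = length(regions$kept_ids),
    n_leaf_pixels = sum(regions$phi[regions$kept_ids]),
    no_foliage = no_foliage,
    low_confidence = no_foliage,
    params = list(patch = config$patch, seg_stride = config$seg_stride,
                  depth_stride = config$depth_stride, slic = config$slic,
                  feature_mode = config$feature_mode,
                  camera = unclass(config$camera)),
    seeds = list(pipeline = config$seed,
                 seg = seg$meta$seed, depth = dep$meta$seed,
                 stress = str$meta$seed),
    timings = timings)
  structure(list(mask = mask, superpixels = sp, regions = regions,
                 depth = dm, leaves = leaves, feature = feature,
                 label = cls$label, score = cls$score, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<pipeline_result> label %d (%s), score %.3f\n",
                     "  %d superpixels, %d kept, %d leaf pixels%s\n"),
              x$label, if (x$label == 1L) "stressed" else "without stress",
              x$score, r$n_superpixels, r$n_kept_superpixels,
              r$n_leaf_pixels,
              if (r$no_foliage) " [no foliage: low confidence]" else ""))
  invisible(x)
}
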