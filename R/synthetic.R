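# Seeded synthetic top-view plant scenes: paired RGB + depth-code images with
# plant masks, leaf instance labels and stress labels, organised in the eight
# irrigation groups. This is the stand-in for dataset records of top-view
# potted strawberry plants imaged together with an 8-bit depth map.
#
# The rendered world is deliberately simple: a textured soil plane at a fixed
# distance, and a rosette of flat elliptical leaves, each at a camera distance
# drawn uniformly from the group's height band (unstressed foliage sits at
# 0.65-0.74 m from the camera, stressed foliage has declined to 0.75-0.80 m).
# Leaf brightness falls off linearly with distance (uniform-illumination
# shading), which is the monocular cue the depth network learns from.

#' Irrigation group specification
#'
#' Eight groups (A-H) follow the irrigation design: A-D watered, E-H watered
#' with NPK nutrients; dose 250 mL at 1/5/2/3-day intervals giving categories
#' excess / deficit / without stress / moderate stress. Groups without stress
#' keep their foliage at 0.65-0.74 m from the camera; all stressed categories
#' decline to 0.75-0.80 m.
#'
#' @param name Group letter, one of `"A"`-`"H"`.
#' @param dose_ml Irrigation dose in milliliters.
#' @param watering_interval Days between irrigations.
#' @param category One of `"excess"`, `"deficit"`, `"without stress"`,
#'   `"moderate stress"`.
#' @param nutrients Logical; `TRUE` for NPK-supplemented irrigation.
#' @param leaf_distance_range Camera-to-leaf distance range in meters.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, dose_ml = 250, watering_interval = 2,
                       category = c("without stress", "excess", "deficit",
                                    "moderate stress"),
                       nutrients = FALSE, leaf_distance_range = NULL) {
  category <- match.arg(category)
  stressed <- category != "without stress"
  if (is.null(leaf_distance_range)) {
    leaf_distance_range <- if (stressed) c(0.75, 0.80) else c(0.65, 0.74)
  }
  assert_that(length(leaf_distance_range) == 2 &&
                leaf_distance_range[1] <= leaf_distance_range[2] &&
                leaf_distance_range[1] >= 0,
              "leaf_distance_range must be a non-empty non-negative range")
  structure(list(name = as.character(name), dose_ml = dose_ml,
                 watering_interval = watering_interval, category = category,
                 nutrients = nutrients, stressed = stressed,
                 leaf_distance_range = leaf_distance_range),
            class = "group_spec")
}

#' The eight default irrigation groups
#'
#' @return Named list of [group_spec()] objects A-H.
#' @export
default_groups <- function() {
  defs <- list(
    A = list(1, "excess", FALSE),
    B = list(5, "deficit", FALSE),
    C = list(2, "without stress", FALSE),
    D = list(3, "moderate stress", FALSE),
    E = list(1, "excess", TRUE),
    F = list(5, "deficit", TRUE),
    G = list(2, "moderate stress", TRUE),
    H = list(3, "without stress", TRUE))
  out <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    group_spec(nm, dose_ml = 250, watering_interval = d[[1]],
               category = d[[2]], nutrients = d[[3]])
  })
  names(out) <- names(defs)
  out
}

#' Synthetic scene configuration
#'
#' @param width,height Image size in pixels (both must exceed 32).
#' @param groups List of [group_spec()]s; defaults to [default_groups()].
#' @param leaves_per_plant Integer range `c(min, max)` of leaves per rosette.
#' @param leaf_axis_lengths List with `major` and `minor` pixel ranges for the
#'   leaf ellipse semi-axes (before perspective scaling).
#' @param leaf_hue_range Leaf hue range in degrees (greens by default).
#' @param noise_sd RGB sensor noise standard deviation in gray levels (0-255).
#' @param camera A [camera_model()]; its `k` sets the depth-code scale.
#' @param soil_distance Camera-to-soil distance in meters.
#' @param background_texture_seed Extra seed offset for the soil texture.
#' @param invert_depth_code If `TRUE`, exported depth PNGs use the
#'   near-bright (Kinect-style) convention `255 - z` instead of the literal
#'   `z = 255 * Z / k` code.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 640L, height = 480L, groups = default_groups(),
                         leaves_per_plant = c(5L, 10L),
                         leaf_axis_lengths = NULL,
                         leaf_hue_range = c(95, 140), noise_sd = 2,
                         camera = NULL, soil_distance = 0.85,
                         background_texture_seed = 0L,
                         invert_depth_code = FALSE) {
  width <- as.integer(width)
  height <- as.integer(height)
  assert_that(width > 32L && height > 32L, "width and height must exceed 32")
  leaves_per_plant <- as.integer(leaves_per_plant)
  assert_that(length(leaves_per_plant) == 2 &&
                leaves_per_plant[1] >= 1L &&
                leaves_per_plant[1] <= leaves_per_plant[2],
              "leaves_per_plant must be an integer range with min >= 1")
  if (is.null(leaf_axis_lengths)) {
    base <- min(width, height)
    leaf_axis_lengths <- list(major = round(c(0.17, 0.24) * base),
                              minor = round(c(0.09, 0.13) * base))
  }
  assert_that(all(unlist(leaf_axis_lengths) > 0) &&
                diff(leaf_axis_lengths$major) >= 0 &&
                diff(leaf_axis_lengths$minor) >= 0,
              "leaf_axis_lengths ranges must be positive and non-empty")
  assert_that(diff(leaf_hue_range) >= 0, "leaf_hue_range must be non-empty")
  if (is.null(camera)) {
    camera <- camera_model(f = 525, k = 4, width = width, height = height)
  }
  assert_that(soil_distance > 0 && soil_distance <= camera$k,
              "soil_distance must lie in (0, k]")
  structure(list(width = width, height = height, groups = groups,
                 leaves_per_plant = leaves_per_plant,
                 leaf_axis_lengths = leaf_axis_lengths,
                 leaf_hue_range = leaf_hue_range, noise_sd = noise_sd,
                 camera = camera, soil_distance = soil_distance,
                 background_texture_seed = as.integer(background_texture_seed),
                 invert_depth_code = invert_depth_code),
            class = "scene_config")
}

# Leaf brightness (HSV value) as a function of camera distance: a linear
# illumination falloff calibrated so that the 0.60-0.90 m working band spans a
# clearly resolvable brightness range.
leaf_shade <- function(Z) clamp(0.95 - 1.1 * (Z - 0.60), 0.25, 1)

#' Generate one synthetic scene
#'
#' Deterministic for a fixed `(config, group, seed)` triple. Leaves are filled
#' ellipses arranged in a rosette; each leaf's camera distance `Z` is drawn
#' uniformly from the group's `leaf_distance_range` and encoded as
#' `z = round(255 * Z / k)`; the soil sits at `config$soil_distance`.
#'
#' @param config A [scene_config()].
#' @param group A [group_spec()] or the name of a group in `config$groups`.
#' @param seed Integer seed.
#' @return An object of class `scene`: list with `rgb` (H x W x 3 in
#'   `[0, 1]`), `depth` (integer code matrix, larger = farther), `plant_mask`
#'   (0/1), `leaf_instances` (0 = background), `leaf_z` (true per-leaf
#'   distances, meters), `stress_label` (0/1), `group`, `seed`.
#' @export
generate_scene <- function(config, group, seed) {
  assert_that(inherits(config, "scene_config"), "config must be a scene_config")
  if (is.character(group)) {
    assert_that(group %in% names(config$groups),
                sprintf("group '%s' is not part of the configuration", group))
    group <- config$groups[[group]]
  }
  assert_that(inherits(group, "group_spec"), "group must be a group_spec")
  k <- config$camera$k
  if (group$leaf_distance_range[2] > k) {
    stop(sprintf("group '%s' distance range exceeds the sensor depth k = %g m",
                 group$name, k), call. = FALSE)
  }
  H <- config$height
  W <- config$width
  with_seed(seed + config$background_texture_seed, {
    soil_base <- c(0.36, 0.27, 0.17)
    soil_tex <- matrix(stats::runif(H * W, -0.04, 0.04), H, W)
    rgb <- array(0, c(H, W, 3))
    for (ch in 1:3) rgb[, , ch] <- soil_base[ch] + soil_tex
  })
  depth <- matrix(depth_to_code(config$soil_distance, k), H, W)
  instances <- matrix(0L, H, W)
  with_seed(seed, {
    n_leaves <- if (config$leaves_per_plant[1] == config$leaves_per_plant[2]) {
      config$leaves_per_plant[1]
    } else {
      sample(config$leaves_per_plant[1]:config$leaves_per_plant[2], 1L)
    }
    ctr <- c(H, W) / 2 + stats::runif(2, -0.04, 0.04) * c(H, W)
    angles <- seq(0, 2 * pi, length.out = n_leaves + 1L)[-1L] +
      stats::runif(n_leaves, -0.3, 0.3) * 2 * pi / n_leaves
    leaf_z <- stats::runif(n_leaves, group$leaf_distance_range[1],
                           group$leaf_distance_range[2])
    axl <- config$leaf_axis_lengths
    cc <- matrix(rep(seq_len(W), each = H), H, W)
    rr <- matrix(rep(seq_len(H), W), H, W)
    z_ref <- 0.70
    for (i in seq_len(n_leaves)) {
      scale <- z_ref / leaf_z[i]
      a <- stats::runif(1, axl$major[1], axl$major[2]) * scale
      b <- stats::runif(1, axl$minor[1], axl$minor[2]) * scale
      rad <- stats::runif(1, 0.45, 0.75) * a + 0.12 * min(H, W)
      lc_r <- ctr[1] + rad * sin(angles[i])
      lc_c <- ctr[2] + rad * cos(angles[i])
      dr <- rr - lc_r
      dc <- cc - lc_c
      u <- dc * cos(angles[i]) + dr * sin(angles[i])
      v <- -dc * sin(angles[i]) + dr * cos(angles[i])
      inside <- (u / a)^2 + (v / b)^2 <= 1
      hue <- stats::runif(1, config$leaf_hue_range[1],
                          config$leaf_hue_range[2]) / 360
      sat <- stats::runif(1, 0.62, 0.72)
      val <- leaf_shade(leaf_z[i]) * stats::runif(1, 0.98, 1.02)
      col <- grDevices::col2rgb(grDevices::hsv(hue, sat, clamp(val, 0, 1))) / 255
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[inside] <- col[ch]
        rgb[, , ch] <- plane
      }
      depth[inside] <- depth_to_code(leaf_z[i], k)
      instances[inside] <- i
    }
    if (config$noise_sd > 0) {
      rgb <- rgb + array(stats::rnorm(H * W * 3, sd = config$noise_sd / 255),
                         c(H, W, 3))
    }
    rgb <- clamp(rgb, 0, 1)
  })
  structure(list(rgb = rgb, depth = depth,
                 plant_mask = matrix(as.integer(instances > 0L), H, W),
                 leaf_instances = instances,
                 leaf_z = leaf_z_of(instances, depth, k),
                 stress_label = as.integer(group$stressed),
                 group = group$name, seed = seed, camera = config$camera,
                 invert_depth_code = config$invert_depth_code),
            class = "scene")
}

# True per-leaf distances recovered from the (exact) instance/depth rasters;
# leaves fully occluded by later siblings are dropped.
leaf_z_of <- function(instances, depth, k) {
  ids <- sort(unique(instances[instances > 0L]))
  if (!length(ids)) return(numeric())
  z <- vapply(ids, function(i) code_to_depth(depth[instances == i][1], k),
              numeric(1))
  names(z) <- ids
  z
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> group %s (%s), %d x %d, %d leaves, seed %d\n",
              x$group, if (x$stress_label == 1) "stressed" else "unstressed",
              nrow(x$depth), ncol(x$depth), length(x$leaf_z), x$seed))
  invisible(x)
}

#' Generate a dataset of paired RGB/depth PNG records
#'
#' Writes `n_per_group` scenes for every group in the configuration as paired
#' 8-bit PNG files (`*_rgb.png`, `*_depth.png`, plus a `*_mask.png` plant
#' mask) and a manifest CSV with header `file_rgb,file_depth,group,stress,seed`.
#'
#' @param config A [scene_config()].
#' @param n_per_group Scenes per group (>= 1).
#' @param dir Output directory (created if missing).
#' @param seed Base seed; record `r` of group `g` uses
#'   `seed + (g - 1) * n_per_group + (r - 1)`.
#' @return The manifest as a data frame, invisibly.
#' @export
generate_dataset <- function(config, n_per_group, dir, seed = 1L) {
  assert_that(n_per_group >= 1, "n_per_group must be >= 1")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  rows <- vector("list", length(config$groups) * n_per_group)
  rec <- 0L
  for (gi in seq_along(config$groups)) {
    grp <- config$groups[[gi]]
    for (r in seq_len(n_per_group)) {
      rec <- rec + 1L
      sc_seed <- as.integer(seed + (gi - 1L) * n_per_group + (r - 1L))
      sc <- generate_scene(config, grp, sc_seed)
      stem <- sprintf("%s_%03d", grp$name, r)
      f_rgb <- file.path(dir, paste0(stem, "_rgb.png"))
      f_depth <- file.path(dir, paste0(stem, "_depth.png"))
      f_mask <- file.path(dir, paste0(stem, "_mask.png"))
      png::writePNG(sc$rgb, f_rgb)
      codes <- sc$depth
      if (config$invert_depth_code) codes <- 255L - codes
      png::writePNG(codes / 255, f_depth)
      png::writePNG(sc$plant_mask + 0, f_mask) # 0/255 single-channel
      rows[[rec]] <- data.frame(file_rgb = basename(f_rgb),
                                file_depth = basename(f_depth),
                                group = grp$name, stress = sc$stress_label,
                                seed = sc_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a paired RGB/depth record written by [generate_dataset()]
#'
#' @param file_rgb,file_depth PNG paths.
#' @param invert_depth_code `TRUE` if the depth file uses the near-bright
#'   convention.
#' @return List with `rgb` (H x W x 3) and `depth` (integer code matrix in
#'   the package-internal convention: larger = farther).
#' @export
read_scene_pair <- function(file_rgb, file_depth, invert_depth_code = FALSE) {
  rgb <- png::readPNG(file_rgb)
  depth <- round(255 * png::readPNG(file_depth))
  if (length(dim(depth)) == 3L) depth <- depth[, , 1]
  if (invert_depth_code) depth <- 255 - depth
  storage.mode(depth) <- "integer"
  list(rgb = rgb, depth = depth)
}
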