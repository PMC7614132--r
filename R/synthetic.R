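# Synthetic organoid scenes with complete ground truth.
#
# Brightfield scenes: organoids darker than background ("dying" organoids
# darker still), spheroids as smooth ellipses, budding organoids as a body
# with 2-6 overlapping lobe disks so that lobe count, not texture, carries
# the class signal. Confocal scenes: dense nuclei blobs inside organoids and
# sparse bright Gaussian puncta (tuft-cell marker) whose per-class frequency
# emulates tuft cells appearing primarily in budding organoids.
#
# Noise model: mild multiplicative shading field plus additive Gaussian
# noise; no optics simulation. Everything is a pure function of
# (parameters, seed).

#' Default synthetic-scene parameters
#'
#' Intensity layout (fractions of the dynamic range): background 0.8,
#' organoid interiors 0.2-0.6, so organoids are darker than background and
#' darker interiors read as dying. Geometry: body radius 12-26 px,
#' budding lobes 2-6 at 0.4-0.65 body radius.
#'
#' @param ... named overrides.
#' @return parameter list.
#' @export
scene_params <- function(...) {
  p <- list(
    bit_depth = 8L,
    pixel_size_um = 1.0,
    radius_range = c(12, 26),
    aspect_range = c(0.75, 1.0),
    min_separation = 15,
    lobe_count_range = c(2L, 6L),
    lobe_radius_frac = c(0.45, 0.65),
    lobe_dist_frac = c(1.0, 1.25),
    interior_gray_frac = c(0.2, 0.6),
    background_gray_frac = 0.8,
    noise_sd_frac = 0.02,
    shading_amp = 0.04,
    max_place_attempts = 2000L,
    # confocal layer
    nuclei_density = 0.02,        # nuclei per mask pixel
    nucleus_sigma = 1.5,
    nucleus_amp_frac = c(0.35, 0.6),
    marker_baseline_frac = 0.05,
    spot_sigma = 2.0,
    spot_amp_frac = c(0.25, 0.4),
    spot_min_separation = 7,
    spot_margin = 3,
    max_spots_per_organoid = 12L
  )
  modifyList(p, list(...))
}

# --- geometry -------------------------------------------------------------

# Paint a rotated ellipse into an integer mask (modified by reference style:
# returns updated mask). Center in 1-based (row, col).
paint_ellipse <- function(mask, center, a, b, theta, id) {
  ext <- ceiling(max(a, b)) + 1
  r0 <- max(1, floor(center[1] - ext)); r1 <- min(nrow(mask), ceiling(center[1] + ext))
  c0 <- max(1, floor(center[2] - ext)); c1 <- min(ncol(mask), ceiling(center[2] + ext))
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mask[rr, cc]
  sub[inside] <- id
  mask[rr, cc] <- sub
  mask
}

paint_disk <- function(mask, center, radius, id) {
  paint_ellipse(mask, center, radius, radius, 0, id)
}

# Sample one object's geometry; returns list(kind, center, body_r, extent,
# pieces) where pieces are the disks/ellipse to paint.
sample_object <- function(class, shape, params) {
  r <- stats::runif(1, params$radius_range[1], params$radius_range[2])
  if (class == "spheroid") {
    asp <- stats::runif(1, params$aspect_range[1], params$aspect_range[2])
    theta <- stats::runif(1, 0, pi)
    list(class = class, body_r = r, extent = r,
         pieces = list(list(type = "ellipse", a = r, b = r * asp, theta = theta)))
  } else {
    k <- sample(seq(params$lobe_count_range[1], params$lobe_count_range[2]), 1)
    angles <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(k) / k +
      stats::runif(k, -0.25, 0.25)
    lr <- r * stats::runif(k, params$lobe_radius_frac[1], params$lobe_radius_frac[2])
    ld <- r * stats::runif(k, params$lobe_dist_frac[1], params$lobe_dist_frac[2])
    pieces <- c(list(list(type = "disk", radius = r, dr = 0, dc = 0)),
                lapply(seq_len(k), function(j)
                  list(type = "disk", radius = lr[j],
                       dr = ld[j] * sin(angles[j]), dc = ld[j] * cos(angles[j]))))
    list(class = class, body_r = r, extent = max(ld + lr, r), pieces = pieces)
  }
}

# Place objects with pairwise center distance >= extents + min_separation.
place_objects <- function(objects, shape, params) {
  centers <- matrix(NA_real_, length(objects), 2)
  for (i in seq_along(objects)) {
    ext <- objects[[i]]$extent
    lo <- ext + 2
    ok <- FALSE
    for (attempt in seq_len(params$max_place_attempts)) {
      cand <- c(stats::runif(1, lo, shape[1] - lo), stats::runif(1, lo, shape[2] - lo))
      if (i == 1) { ok <- TRUE } else {
        prev <- seq_len(i - 1)
        d <- sqrt((centers[prev, 1] - cand[1])^2 + (centers[prev, 2] - cand[2])^2)
        need <- vapply(objects[prev], function(o) o$extent, 0) + ext + params$min_separation
        ok <- all(d >= need)
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (!ok)
      stop(sprintf(paste0("placement error: could not place object %d of %d ",
                          "within separation constraint after %d attempts"),
                   i, length(objects), params$max_place_attempts))
  }
  centers
}

rasterize_layout <- function(objects, centers, shape) {
  mask <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(objects)) {
    ob <- objects[[i]]
    for (p in ob$pieces) {
      if (p$type == "ellipse") {
        mask <- paint_ellipse(mask, centers[i, ], p$a, p$b, p$theta, i)
      } else {
        mask <- paint_disk(mask, centers[i, ] + c(p$dr, p$dc), p$radius, i)
      }
    }
  }
  mask
}

# Smooth multiplicative shading field with mean ~1.
shading_field <- function(shape, amp) {
  pr <- stats::runif(2, 0, 2 * pi)
  fr <- stats::runif(2, 0.5, 1.5)
  row_w <- sin(2 * pi * fr[1] * seq_len(shape[1]) / shape[1] + pr[1])
  col_w <- sin(2 * pi * fr[2] * seq_len(shape[2]) / shape[2] + pr[2])
  1 + amp * outer(row_w, col_w)
}

compose_brightfield <- function(mask, gray_values, params, shape) {
  rng <- 2^params$bit_depth - 1
  img <- matrix(params$background_gray_frac * rng, shape[1], shape[2])
  nz <- mask > 0
  img[nz] <- gray_values[mask[nz]]
  img <- img * shading_field(shape, params$shading_amp)
  img <- img + stats::rnorm(length(img), 0, params$noise_sd_frac * rng)
  round(clip(img, 0, rng))
}

# --- public generators ----------------------------------------------------

#' Generate a brightfield organoid scene with ground truth
#'
#' Objects 1..n_spheroid are spheroids, the rest budding. The returned
#' ground truth carries the true label mask, per-object class and nominal
#' interior gray value, and the generation parameters, so that
#' segmentation, feature extraction and classification can be scored
#' without any manual annotation.
#'
#' @param n_spheroid,n_budding object counts (>= 0).
#' @param image_shape c(rows, cols).
#' @param params see [scene_params()].
#' @param seed integer seed; identical seed + parameters give a
#'   bit-identical scene.
#' @return list with `image` (an `img2d`) and `truth` (a `scene_truth`:
#'   true_mask, true_classes, true_gray, true_spots, seed, params).
#' @export
generate_brightfield_scene <- function(n_spheroid, n_budding,
                                       image_shape = c(512, 512),
                                       params = scene_params(), seed = 1) {
  stopifnot(n_spheroid >= 0, n_budding >= 0)
  with_seed(seed, {
    layout <- build_layout(n_spheroid, n_budding, image_shape, params)
    rng <- 2^params$bit_depth - 1
    gray <- stats::runif(length(layout$objects),
                         params$interior_gray_frac[1] * rng,
                         params$interior_gray_frac[2] * rng)
    img <- compose_brightfield(layout$mask, gray, params, image_shape)
    truth <- new_scene_truth(layout, gray, params, seed)
    list(image = img2d(img, "brightfield", params$pixel_size_um, params$bit_depth),
         truth = truth)
  })
}

build_layout <- function(n_spheroid, n_budding, shape, params) {
  classes <- c(rep("spheroid", n_spheroid), rep("budding", n_budding))
  objects <- lapply(classes, sample_object, shape = shape, params = params)
  if (length(objects) > 0) {
    centers <- place_objects(objects, shape, params)
    mask <- rasterize_layout(objects, centers, shape)
  } else {
    centers <- matrix(numeric(0), 0, 2)
    mask <- matrix(0L, shape[1], shape[2])
  }
  list(objects = objects, centers = centers, mask = mask, classes = classes)
}

new_scene_truth <- function(layout, gray, params, seed, spots = NULL) {
  n <- length(layout$objects)
  ids <- as.character(seq_len(n))
  if (is.null(spots)) spots <- lapply(seq_len(n), function(i) matrix(numeric(0), 0, 2))
  structure(list(
    true_mask = label_mask(layout$mask, params$pixel_size_um),
    true_classes = stats::setNames(layout$classes, ids),
    true_gray = stats::setNames(gray, ids),
    true_spots = stats::setNames(spots, ids),
    centers = layout$centers,
    seed = seed, params = params), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d organoids (%d spheroid, %d budding), %d spots, seed %d\n",
              length(x$true_classes), sum(x$true_classes == "spheroid"),
              sum(x$true_classes == "budding"),
              sum(vapply(x$true_spots, nrow, 0L)), x$seed))
  invisible(x)
}

#' Generate a confocal scene (nuclei + marker channel) with ground truth
#'
#' Reuses the brightfield geometry for organoid masks. The nuclei channel
#' carries dense small blobs inside every organoid; the marker channel
#' carries bright Gaussian puncta at the true tuft-spot positions, whose
#' per-organoid counts are drawn from `spots_per_organoid_law`:
#' either a list of per-class Poisson means, e.g.
#' `list(spheroid = 0.5, budding = 5)` (the budding-enriched default), or
#' `list(fixed = c("1" = 6, "2" = 0))` for exact per-organoid counts.
#'
#' Confocal organoids default to a larger body radius (20-32 px) and a
#' slimmer spot margin than brightfield scenes, so that the packing capacity
#' at the default 7 px spot separation comfortably exceeds the maximum
#' per-organoid count of 12.
#'
#' @inheritParams generate_brightfield_scene
#' @param spots_per_organoid_law per-class spot-count law (see above).
#' @return list with `channels` (named list of `img2d`: nuclei, marker)
#'   and `truth` (a `scene_truth` including `true_spots`, 1-based
#'   (row, col) centers).
#' @export
generate_confocal_scene <- function(n_spheroid, n_budding,
                                    spots_per_organoid_law = list(spheroid = 0.5,
                                                                  budding = 5),
                                    image_shape = c(640, 640),
                                    params = scene_params(radius_range = c(20, 32),
                                                          spot_margin = 2),
                                    seed = 1) {
  with_seed(seed, {
    layout <- build_layout(n_spheroid, n_budding, image_shape, params)
    n <- length(layout$objects)
    rng <- 2^params$bit_depth - 1

    counts <- draw_spot_counts(layout$classes, spots_per_organoid_law, params)
    spots <- lapply(seq_len(n), function(i)
      sample_spot_positions(layout$mask, i, counts[i], params))

    nuclei <- render_nuclei(layout$mask, params, image_shape)
    marker <- render_marker(spots, params, image_shape)

    gray <- stats::setNames(rep(NA_real_, n), as.character(seq_len(n)))
    truth <- new_scene_truth(layout, gray, params, seed, spots = spots)
    list(channels = list(
           nuclei = img2d(nuclei, "nuclei", params$pixel_size_um, params$bit_depth),
           marker = img2d(marker, "marker", params$pixel_size_um, params$bit_depth)),
         truth = truth)
  })
}

draw_spot_counts <- function(classes, law, params) {
  n <- length(classes)
  if (!is.null(law$fixed)) {
    counts <- integer(n)
    idx <- as.integer(names(law$fixed))
    counts[idx] <- as.integer(law$fixed)
    return(counts)
  }
  means <- vapply(classes, function(cl) {
    if (is.null(law[[cl]])) 0 else as.numeric(law[[cl]])
  }, 0)
  pmin(stats::rpois(n, means), params$max_spots_per_organoid)
}

# Spot centers inside the organoid, away from the boundary, pairwise
# separated by spot_min_separation. Pool-based dart throwing: candidates
# within the separation of an accepted spot are removed from the pool, so
# placement reliably reaches the packing limit and fails only when the
# request genuinely exceeds the organoid's capacity.
sample_spot_positions <- function(mask, id, count, params) {
  if (count == 0) return(matrix(numeric(0), 0, 2))
  interior <- erode_label(mask == id, params$spot_margin)
  cand <- which(interior, arr.ind = TRUE)
  if (nrow(cand) == 0)
    stop(sprintf("placement error: organoid %d has no interior for spots", id))
  placed <- matrix(NA_real_, count, 2)
  for (k in seq_len(count)) {
    if (nrow(cand) == 0)
      stop(sprintf("placement error: placed %d of %d spots in organoid %d (capacity exhausted)",
                   k - 1, count, id))
    p <- cand[sample.int(nrow(cand), 1), ]
    placed[k, ] <- p
    keep <- (cand[, 1] - p[1])^2 + (cand[, 2] - p[2])^2 >=
      params$spot_min_separation^2
    cand <- cand[keep, , drop = FALSE]
  }
  placed
}

erode_label <- function(binary, radius) {
  if (radius <= 0) return(binary)
  k <- EBImage::makeBrush(2 * ceiling(radius) + 1, shape = "disc")
  EBImage::erode(binary * 1, k) > 0.5
}

# Additive Gaussian blob at (row, col); modifies a sub-window of img.
add_gaussian_blob <- function(img, center, sigma, amp) {
  ext <- ceiling(3 * sigma)
  r0 <- max(1, round(center[1]) - ext); r1 <- min(nrow(img), round(center[1]) + ext)
  c0 <- max(1, round(center[2]) - ext); c1 <- min(ncol(img), round(center[2]) + ext)
  rr <- r0:r1; cc <- c0:c1
  g <- exp(-outer((rr - center[1])^2, (cc - center[2])^2, "+") / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

render_nuclei <- function(mask, params, shape) {
  rng <- 2^params$bit_depth - 1
  img <- matrix(0.02 * rng, shape[1], shape[2])
  for (id in seq_len(max(mask))) {
    px <- which(mask == id, arr.ind = TRUE)
    n_nuc <- max(1L, round(nrow(px) * params$nuclei_density))
    sel <- px[sample.int(nrow(px), n_nuc, replace = n_nuc > nrow(px)), , drop = FALSE]
    amps <- stats::runif(n_nuc, params$nucleus_amp_frac[1] * rng,
                         params$nucleus_amp_frac[2] * rng)
    for (j in seq_len(n_nuc))
      img <- add_gaussian_blob(img, sel[j, ], params$nucleus_sigma, amps[j])
  }
  img <- img + stats::rnorm(length(img), 0, params$noise_sd_frac * rng)
  round(clip(img, 0, rng))
}

render_marker <- function(spots, params, shape) {
  rng <- 2^params$bit_depth - 1
  img <- matrix(params$marker_baseline_frac * rng, shape[1], shape[2])
  for (sp in spots) {
    if (nrow(sp) == 0) next
    amps <- stats::runif(nrow(sp), params$spot_amp_frac[1] * rng,
                         params$spot_amp_frac[2] * rng)
    for (j in seq_len(nrow(sp)))
      img <- add_gaussian_blob(img, sp[j, ], params$spot_sigma, amps[j])
  }
  img <- img + stats::rnorm(length(img), 0, params$noise_sd_frac * rng)
  round(clip(img, 0, rng))
}

#' Darken selected organoids in a brightfield scene
#'
#' Re-renders the scene from its ground truth with the selected objects'
#' interior gray multiplied by `darkening_factor` before shading and noise,
#' emulating the darker appearance of dying organoids. The ground truth's
#' `true_gray` is updated accordingly.
#'
#' @param image the scene's `img2d` (shape and calibration reference).
#' @param truth the scene's `scene_truth`.
#' @param darkening_factor multiplicative factor in (0, 1].
#' @param blur_scale optional Gaussian blur sigma applied after composition
#'   (0 = none).
#' @param seed seed for the new shading/noise draw.
#' @param object_ids integer ids to darken; NULL darkens all objects.
#' @return list with the degraded `image` and the updated `truth`.
#' @export
degrade_scene <- function(image, truth, darkening_factor, blur_scale = 0,
                          seed = 1, object_ids = NULL) {
  if (!is.numeric(darkening_factor) || darkening_factor <= 0 || darkening_factor > 1)
    stop("darkening_factor must be in (0, 1]")
  params <- truth$params
  gray <- truth$true_gray
  if (is.null(object_ids)) object_ids <- seq_along(gray)
  gray[object_ids] <- gray[object_ids] * darkening_factor
  img <- with_seed(seed, {
    out <- compose_brightfield(truth$true_mask$labels, gray, params,
                               dim(image$pixels))
    if (blur_scale > 0) {
      rng <- 2^params$bit_depth - 1
      out <- round(clip(EBImage::gblur(out, sigma = blur_scale), 0, rng))
    }
    out
  })
  truth$true_gray <- gray
  list(image = img2d(img, image$channel, image$pixel_size_um, image$bit_depth),
       truth = truth)
}

#' Wrap a 2-D scene as a thin z-stack
#'
#' Replicates the plane `n` times with independent per-plane Gaussian
#' noise, for exercising projection code on synthetic scenes.
#'
#' @param image an `img2d`.
#' @param n number of planes.
#' @param noise_sd per-plane additive noise SD (native intensity units).
#' @param seed seed for the per-plane noise.
#' @return a `zstack`.
#' @export
scene_zstack <- function(image, n = 3, noise_sd = 2, seed = 1) {
  rng <- 2^image$bit_depth - 1
  planes <- with_seed(seed, lapply(seq_len(n), function(i)
    round(clip(image$pixels + stats::rnorm(length(image$pixels), 0, noise_sd),
               0, rng))))
  zstack(planes, image$channel, image$pixel_size_um, image$bit_depth)
}

#' Write a scene's ground truth as text sidecars
#'
#' Writes the true label mask as TIFF plus a JSON sidecar with classes,
#' nominal grays and 0-based spot coordinates.
#'
#' @param truth a `scene_truth`.
#' @param dir output directory.
#' @param stem filename stem.
#' @return invisible vector of paths written.
#' @export
write_scene_truth <- function(truth, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, paste0(stem, "_truth_mask.tif"))
  write_label_mask(truth$true_mask, mask_path)
  json_path <- file.path(dir, paste0(stem, "_truth.json"))
  spots0 <- lapply(truth$true_spots, function(m) {
    if (nrow(m) == 0) list() else unname(apply(m - 1, 1, as.list))
  })
  jsonlite::write_json(list(classes = as.list(truth$true_classes),
                            gray = as.list(truth$true_gray),
                            spots_rowcol_0based = spots0,
                            seed = truth$seed),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(mask_path, json_path))
}
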