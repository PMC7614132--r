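# Projection and classical segmentation of brightfield organoid images:
# smooth -> threshold (Otsu or fixed, dark objects by default) -> fill
# holes -> drop small objects -> optional distance-transform watershed split
# of touching objects -> optional border drop -> compacted labels.
# Deterministic for fixed input and parameters.

#' Project a z-stack to a single plane
#'
#' Pixelwise reduction across z. Brightfield stacks default to `min`
#' (organoids are darker than background, so the darkest plane keeps them),
#' confocal stacks to `max`.
#'
#' @param stack a `zstack` with at least one plane.
#' @param method one of "min", "max", "mean".
#' @return an `img2d` with the stack's metadata.
#' @export
project_stack <- function(stack, method = c("min", "max", "mean")) {
  method <- match.arg(method)
  if (!inherits(stack, "zstack")) stop("project_stack expects a zstack")
  n <- n_planes(stack)
  if (n < 1) stop("empty stack")
  out <- stack$planes[1, , ]
  if (n > 1) {
    for (i in 2:n) {
      p <- stack$planes[i, , ]
      out <- switch(method, min = pmin(out, p), max = pmax(out, p),
                    mean = out + p)
    }
    if (method == "mean") out <- out / n
  }
  img2d(out, stack$channel, stack$pixel_size_um, stack$bit_depth)
}

#' Segment organoids in a projected brightfield image
#'
#' @param image an `img2d` (projected brightfield plane).
#' @param cfg a `quant_config`; the `segmentation` block supplies smoothing
#'   sigma, threshold mode and polarity, hole filling, minimum object area
#'   (um^2), watershed splitting and border policy.
#' @return a `label_mask` with labels 1..N.
#' @export
segment_brightfield <- function(image, cfg = quant_config()) {
  s <- cfg$segmentation
  px <- image$pixels
  if (any(!is.finite(px))) stop("image contains non-finite pixels")
  rng <- 2^image$bit_depth - 1

  sm <- if (s$smoothing_sigma > 0) EBImage::gblur(px, sigma = s$smoothing_sigma) else px
  norm <- sm / rng
  thr <- if (s$threshold_mode == "background") {
    # background-referenced: the background is the dominant, tight mode of a
    # brightfield field; objects sit k robust-SDs away on the stated polarity.
    # Robust to arbitrarily broad object-intensity distributions, where
    # minimum-variance (Otsu) thresholds can land inside the object class.
    bg <- stats::median(norm)
    dev <- stats::mad(norm)
    if (s$polarity == "dark_objects") bg - s$background_k * dev
    else bg + s$background_k * dev
  } else if (s$threshold_mode == "otsu") {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    if (!is.numeric(s$fixed_threshold) || is.na(s$fixed_threshold) ||
        s$fixed_threshold < 0 || s$fixed_threshold > rng)
      stop(sprintf("fixed threshold must lie in [0, %d]", rng))
    s$fixed_threshold / rng
  }
  binary <- if (s$polarity == "dark_objects") norm < thr else norm > thr

  if (s$fill_holes) binary <- EBImage::fillHull(binary * 1) > 0.5

  labels <- EBImage::bwlabel(binary * 1)
  labels <- drop_small(labels, s$min_area_um2, image$pixel_size_um)

  if (isTRUE(s$split_touching) && max(labels) > 0) {
    labels <- watershed_split(labels, s$watershed_tolerance, s$watershed_footprint)
    labels <- drop_small(labels, s$min_area_um2, image$pixel_size_um)
  }

  if (s$border_policy == "drop") labels <- drop_border_objects(labels)

  if (isTRUE(s$refine_boundaries) && max(labels) > 0 &&
      s$threshold_mode != "fixed")
    labels <- refine_object_boundaries(labels, norm, s)

  compact_labels(label_mask(labels, image$pixel_size_um))
}

# Per-object boundary refinement: organoid interiors vary in gray value, so
# a single global threshold cuts each object's smoothed edge ramp at a
# different (biased) height. Re-threshold each object locally at the
# midpoint between the global background level and the object's median
# interior intensity — the half-height of its own edge ramp — keeping the
# connected component that overlaps the initial object. Deterministic.
refine_object_boundaries <- function(labels, norm, s) {
  bg <- stats::median(norm)
  dark <- s$polarity == "dark_objects"
  out <- matrix(0L, nrow(labels), ncol(labels))
  pad <- 5L
  for (id in seq_len(max(labels))) {
    sel <- labels == id
    if (!any(sel)) next
    pos <- which(sel, arr.ind = TRUE)
    r0 <- max(1, min(pos[, 1]) - pad); r1 <- min(nrow(labels), max(pos[, 1]) + pad)
    c0 <- max(1, min(pos[, 2]) - pad); c1 <- min(ncol(labels), max(pos[, 2]) + pad)
    loc <- norm[r0:r1, c0:c1]
    obj_level <- stats::median(norm[sel])
    thr <- (bg + obj_level) / 2
    bin <- if (dark) loc < thr else loc > thr
    if (isTRUE(s$fill_holes)) bin <- EBImage::fillHull(bin * 1) > 0.5
    comp <- EBImage::bwlabel(bin * 1)
    hit <- unique(comp[cbind(pos[, 1] - r0 + 1, pos[, 2] - c0 + 1)])
    hit <- hit[hit > 0]
    if (length(hit) == 0) { out[sel] <- id; next }
    keepsel <- matrix(FALSE, nrow(loc), ncol(loc))
    keepsel[comp %in% hit] <- TRUE
    sub <- out[r0:r1, c0:c1]
    free <- keepsel & sub == 0
    sub[free] <- id
    out[r0:r1, c0:c1] <- sub
  }
  out
}

drop_small <- function(labels, min_area_um2, pixel_size_um) {
  if (max(labels) == 0 || min_area_um2 <= 0) return(labels)
  areas_px <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- areas_px * pixel_size_um^2 >= min_area_um2
  labels[!keep[pmax(labels, 1)] & labels > 0] <- 0L
  labels
}

# Split touching objects by watershed on the interior distance transform;
# seeds are the distance-map maxima within `tolerance`, ties broken
# deterministically by EBImage's fixed scan order.
watershed_split <- function(labels, tolerance, footprint) {
  binary <- labels > 0
  d <- EBImage::distmap(binary * 1)
  w <- EBImage::watershed(d, tolerance = tolerance, ext = max(1, (footprint - 1) / 2))
  matrix(as.integer(w), nrow(labels), ncol(labels))
}

drop_border_objects <- function(labels) {
  edge_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
  edge_ids <- edge_ids[edge_ids > 0]
  labels[labels %in% edge_ids] <- 0L
  labels
}

#' Per-organoid morphometrics from a label mask
#'
#' One record per label. `area_um2` is pixel count times the squared pixel
#' size; `mean_gray` the mean intensity over the object's pixels on the
#' native bit-depth scale. Shape features used by the fallback classifier
#' (solidity, circularity, equivalent diameter) are appended, along with
#' 0-based centroid coordinates.
#'
#' @param mask a `label_mask`.
#' @param image the `img2d` the mask was derived from (same shape).
#' @param image_id identifier copied into the records.
#' @param treatment treatment label copied into the records.
#' @return record data frame (class fields unset: label "unclassified").
#' @export
extract_features <- function(mask, image, image_id = "", treatment = "") {
  if (!identical(dim(mask$labels), dim(image$pixels)))
    stop("mask and image shapes differ")
  n <- max(mask$labels)
  if (n == 0) return(cbind(empty_records(),
                           data.frame(solidity = numeric(0), circularity = numeric(0),
                                      equiv_diameter_um = numeric(0),
                                      centroid_row = numeric(0), centroid_col = numeric(0))))
  lab <- mask$labels
  px2 <- mask$pixel_size_um^2
  areas_px <- tabulate(lab[lab > 0], nbins = n)
  idx <- which(lab > 0)
  ids <- lab[idx]
  sums <- vapply(split(image$pixels[idx], ids), sum, 0)
  mean_gray <- as.numeric(sums) / areas_px[as.integer(names(sums))]

  shp <- EBImage::computeFeatures.shape(lab)
  perim <- shp[, "s.perimeter"]
  sol <- solidity_per_object(lab, n)
  circ <- pmin(4 * pi * areas_px / pmax(perim, 1)^2, 1)

  coords <- which(lab > 0, arr.ind = TRUE)
  cr <- vapply(split(coords[, 1], ids), mean, 0)
  cc <- vapply(split(coords[, 2], ids), mean, 0)

  rec <- data.frame(
    organoid_id = seq_len(n),
    area_um2 = areas_px * px2,
    mean_gray = mean_gray,
    class_label = "unclassified",
    confidence = NA_real_,
    review_status = "auto",
    image_id = image_id,
    treatment = treatment,
    solidity = sol,
    circularity = circ,
    equiv_diameter_um = 2 * sqrt(areas_px * px2 / pi),
    centroid_row = as.numeric(cr) - 1,
    centroid_col = as.numeric(cc) - 1,
    stringsAsFactors = FALSE)
  rec
}

# Solidity = object area / convex hull area (shoelace on the hull of the
# pixel corners, i.e. pixel centers padded by 0.5 in each direction).
solidity_per_object <- function(labels, n) {
  out <- numeric(n)
  coords <- which(labels > 0, arr.ind = TRUE)
  ids <- labels[labels > 0]
  for (id in seq_len(n)) {
    pts <- coords[ids == id, , drop = FALSE]
    if (nrow(pts) < 3) { out[id] <- 1; next }
    # use the 4 corners of each pixel so small objects are not degenerate
    corners <- rbind(pts + rep(c(-0.5, -0.5), each = nrow(pts)),
                     pts + rep(c(-0.5,  0.5), each = nrow(pts)),
                     pts + rep(c( 0.5, -0.5), each = nrow(pts)),
                     pts + rep(c( 0.5,  0.5), each = nrow(pts)))
    h <- grDevices::chull(corners)
    hull <- corners[h, , drop = FALSE]
    a <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                 hull[, 2] * c(hull[-1, 1], hull[1, 1]))) / 2
    out[id] <- min(nrow(pts) / max(a, 1), 1)
  }
  out
}

#' Match predicted objects against ground-truth objects by IoU
#'
#' Greedy one-to-one matching in decreasing IoU order at a minimum-overlap
#' threshold; returns detection precision, recall and the mean IoU over
#' matched pairs — the standard scoring of a segmentation against its
#' ground truth.
#'
#' @param pred predicted `label_mask`.
#' @param truth ground-truth `label_mask`.
#' @param iou_threshold minimum IoU for a valid match (default 0.5).
#' @return list: `matches` data frame (pred_id, true_id, iou), `precision`,
#'   `recall`, `mean_iou`, `n_pred`, `n_true`.
#' @export
match_objects <- function(pred, truth, iou_threshold = 0.5) {
  pl <- pred$labels; tl <- truth$labels
  np <- max(pl); nt <- max(tl)
  if (np == 0 || nt == 0) {
    return(list(matches = data.frame(pred_id = integer(0), true_id = integer(0),
                                     iou = numeric(0)),
                precision = ifelse(np == 0 && nt == 0, 1, 0),
                recall = ifelse(nt == 0, 1, 0),
                mean_iou = NA_real_, n_pred = np, n_true = nt))
  }
  both <- pl > 0 | tl > 0
  inter <- table(factor(pl[both], levels = 0:np), factor(tl[both], levels = 0:nt))
  inter <- unclass(inter)[-1, -1, drop = FALSE]   # drop background row/col
  area_p <- tabulate(pl[pl > 0], nbins = np)
  area_t <- tabulate(tl[tl > 0], nbins = nt)
  union <- outer(area_p, area_t, "+") - inter
  iou <- inter / union
  cand <- which(iou >= iou_threshold, arr.ind = TRUE)
  if (nrow(cand) > 0)
    cand <- cand[order(-iou[cand]), , drop = FALSE]
  used_p <- logical(np); used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_p[i] && !used_t[j]) { used_p[i] <- TRUE; used_t[j] <- TRUE; keep[k] <- TRUE }
  }
  m <- cand[keep, , drop = FALSE]
  matches <- data.frame(pred_id = m[, 1], true_id = m[, 2], iou = iou[m])
  list(matches = matches,
       precision = nrow(matches) / np,
       recall = nrow(matches) / nt,
       mean_iou = if (nrow(matches) > 0) mean(matches$iou) else NA_real_,
       n_pred = np, n_true = nt)
}
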