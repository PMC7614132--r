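# Per-organoid and per-ROI marker quantification: multi-scale
# Laplacian-of-Gaussian spot detection for tuft-cell counting,
# positive-pixel fractions ("positive" is strictly above the threshold),
# ROI ratio statistics, proximity ratios, and per-subject aggregation.

as_pixels <- function(x) if (inherits(x, "img2d")) x$pixels else x

#' Fraction of positive pixels in a region
#'
#' A pixel is positive when its intensity is strictly above the threshold.
#'
#' @param channel an `img2d` or numeric matrix.
#' @param region logical matrix (the ROI), same shape; must be nonempty.
#' @param threshold intensity threshold on the native scale.
#' @return fraction in [0, 1].
#' @export
positive_pixel_fraction <- function(channel, region, threshold) {
  px <- as_pixels(channel)
  if (!identical(dim(px), dim(region))) stop("channel and region shapes differ")
  n <- sum(region)
  if (n == 0) stop("empty region")
  sum(px[region] > threshold) / n
}

log_kernel <- function(sigma) {
  ext <- ceiling(3 * sigma)
  x <- -ext:ext
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g <- g / sum(g)
  r2 <- outer(x^2, x^2, "+")
  k <- g * (r2 - 2 * sigma^2) / sigma^4
  k - mean(k)   # zero-sum: flat regions give zero response
}

local_maxima_2d <- function(r) {
  H <- nrow(r); W <- ncol(r)
  inner <- r[2:(H - 1), 2:(W - 1)]
  ok <- matrix(TRUE, H - 2, W - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (inner > r[2:(H - 1) + dr, 2:(W - 1) + dc])
  }
  out <- matrix(FALSE, H, W)
  out[2:(H - 1), 2:(W - 1)] <- ok
  out
}

#' Detect marker puncta (tuft-cell spots) per organoid
#'
#' Multi-scale scale-normalised Laplacian-of-Gaussian blob detection over
#' the configured scale range. A candidate is a spatial local maximum of
#' the response that also dominates the adjacent scales; candidates whose
#' (lightly smoothed) peak intensity falls below the threshold criterion
#' are discarded; survivors pass greedy non-maximum suppression at the
#' configured minimum separation (strongest response first, ties broken by
#' row then column). Each detection is assigned the mask label under its
#' centroid (0 = background). Deterministic.
#'
#' Threshold modes: `"snr"` keeps peaks above median + snr_factor * MAD of
#' the smoothed channel (robust to the sparse spots themselves);
#' `"absolute"` uses a fixed intensity value.
#'
#' @param marker an `img2d` (marker channel, typically a max projection).
#' @param mask aligned `label_mask` of organoids (may be all-zero).
#' @param cfg a `quant_config` (`spots` block).
#' @return data frame: row, col (0-based), peak_intensity, scale,
#'   organoid_id, curated.
#' @export
detect_spots <- function(marker, mask, cfg = quant_config()) {
  sp <- cfg$spots
  if (sp$sigma_min <= 0 || sp$sigma_max < sp$sigma_min || sp$n_scales < 1)
    stop("invalid scale range")
  px <- as_pixels(marker)
  if (!identical(dim(px), dim(mask$labels))) stop("marker and mask shapes differ")
  sigmas <- if (sp$n_scales == 1) sp$sigma_min else
    exp(seq(log(sp$sigma_min), log(sp$sigma_max), length.out = sp$n_scales))

  responses <- lapply(sigmas, function(s)
    -s^2 * EBImage::filter2(px, log_kernel(s)))
  sm1 <- EBImage::gblur(px, sigma = 1)

  if (sp$threshold_mode == "snr") {
    bg <- stats::median(sm1)
    noise <- stats::mad(sm1)
    intensity_cut <- bg + sp$snr_factor * noise
  } else {
    if (!is.numeric(sp$absolute_threshold) || is.na(sp$absolute_threshold))
      stop("absolute threshold mode requires a numeric absolute_threshold")
    intensity_cut <- sp$absolute_threshold
  }

  cand <- list()
  for (k in seq_along(sigmas)) {
    r <- responses[[k]]
    lm <- local_maxima_2d(r)
    if (length(sigmas) > 1) {
      if (k > 1) lm <- lm & (r >= responses[[k - 1]])
      if (k < length(sigmas)) lm <- lm & (r >= responses[[k + 1]])
    }
    pos <- which(lm & sm1 > intensity_cut & r > 0, arr.ind = TRUE)
    if (nrow(pos) > 0)
      cand[[length(cand) + 1]] <- data.frame(
        row = pos[, 1], col = pos[, 2],
        response = r[pos], peak_intensity = sm1[pos], scale = sigmas[k])
  }
  empty <- data.frame(row = integer(0), col = integer(0),
                      peak_intensity = numeric(0), scale = numeric(0),
                      organoid_id = integer(0), curated = logical(0))
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$response, cand$row, cand$col), ]

  keep <- logical(nrow(cand))
  kept_r <- numeric(0); kept_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept_r) == 0 ||
        all((kept_r - cand$row[i])^2 + (kept_c - cand$col[i])^2 >=
            sp$min_separation^2)) {
      keep[i] <- TRUE
      kept_r <- c(kept_r, cand$row[i]); kept_c <- c(kept_c, cand$col[i])
    }
  }
  cand <- cand[keep, ]
  out <- data.frame(row = cand$row - 1L, col = cand$col - 1L,
                    peak_intensity = cand$peak_intensity,
                    scale = cand$scale,
                    organoid_id = mask$labels[cbind(cand$row, cand$col)],
                    curated = FALSE)
  rownames(out) <- NULL
  out[order(out$row, out$col), ]
}

#' Tuft-cell counts per organoid
#'
#' Counts detections per organoid over the supplied records (rejected
#' records must be excluded upstream; organoids without detections count
#' 0). Background-assigned detections are dropped, or reassigned to the
#' nearest organoid within `capture_radius` pixels when a mask is given.
#' The curated policy first applies a detection-level review table with
#' columns (action in {add, remove}, organoid_id, row, col).
#'
#' @param detections data frame from [detect_spots()].
#' @param records record data frame (no rejected rows).
#' @param policy "auto" or "curated".
#' @param review curated-policy edit table (required when policy = "curated").
#' @param mask optional `label_mask` enabling capture-radius reassignment.
#' @param capture_radius radius (px) for reassigning background detections.
#' @return named integer vector organoid_id -> count, with attribute
#'   `dropped` = number of background detections discarded.
#' @export
count_tufts_per_organoid <- function(detections, records,
                                     policy = c("auto", "curated"),
                                     review = NULL, mask = NULL,
                                     capture_radius = 0) {
  policy <- match.arg(policy)
  if (any(records$review_status == "rejected"))
    stop("records must exclude rejected organoids")
  ids <- records$organoid_id

  if (policy == "curated") {
    if (is.null(review)) stop("curated policy requires a review table")
    for (k in seq_len(nrow(review))) {
      act <- review$action[k]
      oid <- review$organoid_id[k]
      if (!oid %in% ids) stop(sprintf("review references unknown organoid %d", oid))
      if (act == "add") {
        detections <- rbind(detections,
                            data.frame(row = review$row[k], col = review$col[k],
                                       peak_intensity = NA_real_, scale = NA_real_,
                                       organoid_id = oid, curated = TRUE))
      } else if (act == "remove") {
        cand <- which(detections$organoid_id == oid)
        if (length(cand) == 0)
          stop(sprintf("cannot remove a detection from organoid %d: none assigned", oid))
        if (is.finite(review$row[k])) {
          d2 <- (detections$row[cand] - review$row[k])^2 +
                (detections$col[cand] - review$col[k])^2
          cand <- cand[which.min(d2)]
        } else cand <- cand[1]
        detections <- detections[-cand, ]
      } else stop(sprintf("unknown review action '%s'", act))
    }
  }

  if (capture_radius > 0 && !is.null(mask)) {
    bg <- which(detections$organoid_id == 0)
    for (i in bg) {
      r <- detections$row[i] + 1; c <- detections$col[i] + 1
      win <- ceiling(capture_radius)
      rr <- max(1, r - win):min(nrow(mask$labels), r + win)
      cc <- max(1, c - win):min(ncol(mask$labels), c + win)
      sub <- mask$labels[rr, cc]
      d2 <- outer((rr - r)^2, (cc - c)^2, "+")
      hit <- which(sub > 0 & d2 <= capture_radius^2)
      if (length(hit) > 0)
        detections$organoid_id[i] <- sub[hit[which.min(d2[hit])]]
    }
  }

  unknown <- setdiff(unique(detections$organoid_id), c(0L, ids))
  if (length(unknown) > 0)
    stop(sprintf("detections reference unknown organoid(s): %s",
                 paste(unknown, collapse = ", ")))
  assigned <- detections$organoid_id[detections$organoid_id > 0]
  counts <- stats::setNames(integer(length(ids)), ids)
  tab <- table(assigned)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "dropped") <- sum(detections$organoid_id == 0)
  counts
}

#' Percentage of organoids with more than `cutoff` tuft cells
#'
#' Strict inequality: an organoid with exactly `cutoff` tuft cells does not
#' count as high.
#'
#' @param counts per-organoid counts (nonempty).
#' @param cutoff strict lower bound, default from `tuft_high_cutoff` (8).
#' @return percentage in [0, 100].
#' @export
fraction_high_tuft <- function(counts, cutoff = 8) {
  if (length(counts) == 0) stop("empty counts: percentage undefined")
  100 * sum(counts > cutoff) / length(counts)
}

#' Tuft-count distributions per morphology class
#'
#' @param counts named per-organoid counts from [count_tufts_per_organoid()].
#' @param records record data frame carrying class labels.
#' @return list: `distributions` (counts split by class), `means` per class,
#'   `total` (sum over all organoids). Unclassified organoids are reported
#'   separately, never folded into a class.
#' @export
tufts_by_class <- function(counts, records) {
  cl <- records$class_label[match(as.integer(names(counts)), records$organoid_id)]
  if (any(is.na(cl))) stop("count for organoid absent from records")
  split_counts <- split(as.integer(counts), factor(cl, levels = VALID_CLASSES))
  list(distributions = split_counts,
       means = vapply(split_counts, function(x) if (length(x)) mean(x) else NA_real_, 0),
       total = sum(counts))
}

#' Construct a named ROI set
#'
#' @param regions named list of logical matrices over one image (e.g.
#'   crypt, villus, background); names must be unique.
#' @param subject_id subject (e.g. mouse) the image belongs to.
#' @return a `roi_set`.
#' @export
roi_set <- function(regions, subject_id = "") {
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("ROI names must be unique and non-empty")
  for (nm in names(regions))
    if (!is.logical(regions[[nm]])) regions[[nm]] <- regions[[nm]] > 0
  structure(list(regions = regions, subject_id = subject_id), class = "roi_set")
}

get_roi <- function(rois, name) {
  if (!name %in% names(rois$regions)) stop(sprintf("missing ROI '%s'", name))
  rois$regions[[name]]
}

#' Ratio of positive-pixel counts between two ROIs or two channels
#'
#' Two modes, matching the two quantification patterns used on stained
#' tissue: (1) one channel, two ROIs — e.g. marker-positive pixels in the
#' crypt divided by marker-positive pixels in the villus; (2) two channels,
#' one ROI — e.g. pSMAD2-positive pixels divided by DAPI-positive pixels in
#' the same region. Pass a single `img2d` for mode 1 (names refer to ROIs)
#' or a named list of two `img2d` for mode 2 (names refer to channels, and
#' `roi` selects the common region, default the first ROI).
#'
#' @param channel an `img2d`, or named list of two `img2d`.
#' @param rois a `roi_set`.
#' @param numerator_name,denominator_name ROI names (mode 1) or channel
#'   names (mode 2).
#' @param thresholds single threshold or named vector keyed like the names.
#' @param roi ROI name for mode 2 (default: first region).
#' @return list: `ratio` (NA when undefined), `undefined` flag,
#'   `n_pos_numerator`, `n_pos_denominator`.
#' @export
roi_positive_ratio <- function(channel, rois, numerator_name, denominator_name,
                               thresholds, roi = NULL) {
  thr <- function(nm) {
    if (length(thresholds) == 1 && is.null(names(thresholds))) return(thresholds)
    if (!nm %in% names(thresholds)) stop(sprintf("no threshold for '%s'", nm))
    thresholds[[nm]]
  }
  if (inherits(channel, "img2d")) {
    px <- channel$pixels
    num_region <- get_roi(rois, numerator_name)
    den_region <- get_roi(rois, denominator_name)
    if (sum(num_region) == 0 || sum(den_region) == 0) stop("empty ROI")
    n_num <- sum(px[num_region] > thr(numerator_name))
    n_den <- sum(px[den_region] > thr(denominator_name))
  } else {
    for (nm in c(numerator_name, denominator_name))
      if (!nm %in% names(channel)) stop(sprintf("missing channel '%s'", nm))
    region <- if (is.null(roi)) rois$regions[[1]] else get_roi(rois, roi)
    if (sum(region) == 0) stop("empty ROI")
    n_num <- sum(as_pixels(channel[[numerator_name]])[region] > thr(numerator_name))
    n_den <- sum(as_pixels(channel[[denominator_name]])[region] > thr(denominator_name))
  }
  if (n_den == 0)
    return(list(ratio = NA_real_, undefined = TRUE,
                n_pos_numerator = n_num, n_pos_denominator = 0L))
  list(ratio = n_num / n_den, undefined = FALSE,
       n_pos_numerator = n_num, n_pos_denominator = n_den)
}

#' Mean signal near a reference mask relative to background
#'
#' "Immediate vicinity" is realised as morphological dilation of the
#' reference mask by a configured radius (in micrometres); the background
#' mask is taken minus any overlap with the dilated reference. Returns the
#' ratio of mean signal per pixel (vicinity / background). Manually drawn
#' reference and background masks are accepted as-is with
#' `dilation_radius_um = 0`.
#'
#' @param signal an `img2d`.
#' @param reference_mask logical matrix (e.g. tuft-cell marker area).
#' @param background_mask logical matrix (cells not positive for the
#'   reference marker).
#' @param dilation_radius_um dilation radius in micrometres (default 5).
#' @return list: `ratio`, `mean_near`, `mean_background`, `n_near`,
#'   `n_background`.
#' @export
proximity_signal_ratio <- function(signal, reference_mask, background_mask,
                                   dilation_radius_um = 5) {
  px <- as_pixels(signal)
  psz <- if (inherits(signal, "img2d")) signal$pixel_size_um else 1
  rad_px <- dilation_radius_um / psz
  near <- reference_mask
  if (rad_px > 0) {
    k <- EBImage::makeBrush(2 * ceiling(rad_px) + 1, shape = "disc")
    near <- EBImage::dilate(reference_mask * 1, k) > 0.5
  }
  bg <- background_mask & !near
  if (sum(near) == 0) stop("empty reference mask after dilation")
  if (sum(bg) == 0) stop("empty background mask after excluding the vicinity")
  mean_near <- mean(px[near]); mean_bg <- mean(px[bg])
  if (mean_bg == 0)
    return(list(ratio = NA_real_, mean_near = mean_near, mean_background = 0,
                n_near = sum(near), n_background = sum(bg)))
  list(ratio = mean_near / mean_bg, mean_near = mean_near,
       mean_background = mean_bg, n_near = sum(near), n_background = sum(bg))
}

#' Count cell-scale blobs per ROI
#'
#' Blob detection (same Laplacian-of-Gaussian machinery as
#' [detect_spots()]) restricted to each named ROI — e.g. OLFM4-positive
#' cells per crypt.
#'
#' @param channel an `img2d`.
#' @param rois a `roi_set` (each region must be nonempty).
#' @param cfg a `quant_config`; set the `spots` scale range to the cell
#'   scale.
#' @return named integer vector of per-ROI counts.
#' @export
count_positive_cells <- function(channel, rois, cfg = quant_config()) {
  nms <- names(rois$regions)
  lab <- matrix(0L, nrow(as_pixels(channel)), ncol(as_pixels(channel)))
  for (i in seq_along(nms)) {
    reg <- rois$regions[[i]]
    if (sum(reg) == 0) stop(sprintf("empty ROI '%s'", nms[i]))
    lab[reg] <- i
  }
  det <- detect_spots(channel, label_mask(lab,
                        if (inherits(channel, "img2d")) channel$pixel_size_um else 1),
                      cfg)
  counts <- stats::setNames(integer(length(nms)), nms)
  tab <- table(det$organoid_id[det$organoid_id > 0])
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Per-subject means over ROIs, with a minimum-ROI rule
#'
#' Subjects (e.g. mice) contributing fewer than `min_rois` ROIs (e.g.
#' crypts) are excluded from the means and listed in the report — the
#' "mean of at least 5 crypts in one mouse" aggregation rule.
#'
#' @param values numeric vector of per-ROI measurements.
#' @param subjects subject id per value.
#' @param min_rois minimum ROI count per subject (default 5).
#' @return list: `means` data frame (subject, n, mean), `excluded` data
#'   frame (subject, n).
#' @export
aggregate_by_subject <- function(values, subjects, min_rois = 5) {
  stopifnot(length(values) == length(subjects))
  subjects <- as.character(subjects)
  n <- tapply(values, subjects, length)
  m <- tapply(values, subjects, mean)
  ord <- sort(names(n))
  ok <- n[ord] >= min_rois
  list(means = data.frame(subject = ord[ok], n = as.integer(n[ord][ok]),
                          mean = as.numeric(m[ord][ok]), stringsAsFactors = FALSE),
       excluded = data.frame(subject = ord[!ok], n = as.integer(n[ord][!ok]),
                             stringsAsFactors = FALSE))
}
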