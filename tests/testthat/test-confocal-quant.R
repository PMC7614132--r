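# Marker quantification: positive pixels, spot detection, counts, ratios.

test_that("positive_pixel_fraction uses a strict threshold", {
  img <- matrix(c(rep(50, 50), rep(150, 50)), 10, 10)
  region <- matrix(TRUE, 10, 10)
  expect_equal(positive_pixel_fraction(img, region, 100), 0.5)
  expect_equal(positive_pixel_fraction(img, region, 150), 0.0)  # strict >
  expect_equal(positive_pixel_fraction(img, region, 49), 1.0)
  expect_error(positive_pixel_fraction(img, matrix(FALSE, 10, 10), 1), "empty")
})

test_that("positive fraction is non-increasing in the threshold", {
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(sample(0:255, 400, TRUE), 20, 20)
    region <- matrix(sample(c(TRUE, FALSE), 400, TRUE), 20, 20)
    if (!any(region)) region[1] <- TRUE
    fr <- vapply(seq(0, 260, by = 20), function(thr)
      positive_pixel_fraction(img, region, thr), 0)
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("spot detection finds nothing in a flat channel", {
  img <- img2d(matrix(13, 128, 128))
  mask <- label_mask(matrix(0L, 128, 128))
  expect_equal(nrow(detect_spots(img, mask)), 0)
  expect_error(detect_spots(img, mask, quant_config(spots = list(sigma_min = -1))),
               "scale range")
})

test_that("well-separated spots are all detected and assigned to their organoid", {
  sc <- generate_confocal_scene(1, 1,
                                spots_per_organoid_law = list(fixed = c("1" = 6, "2" = 0)),
                                image_shape = c(384, 384), seed = 5)
  det <- detect_spots(sc$channels$marker, sc$truth$true_mask)
  expect_equal(nrow(det), 6)
  expect_true(all(det$organoid_id == 1))
  # every detection within 2 px of a true spot
  ts <- sc$truth$true_spots[["1"]]
  for (k in seq_len(nrow(det))) {
    d <- sqrt(min((ts[, 1] - (det$row[k] + 1))^2 + (ts[, 2] - (det$col[k] + 1))^2))
    expect_lte(d, 2)
  }
})

test_that("tuft counting drops background, conserves totals, applies curation", {
  rec <- make_records(2)
  det <- data.frame(row = c(10, 11, 12, 200, 201), col = c(10, 30, 50, 10, 30),
                    peak_intensity = 50, scale = 2,
                    organoid_id = c(1L, 1L, 1L, 0L, 0L), curated = FALSE)
  counts <- count_tufts_per_organoid(det, rec)
  expect_equal(as.integer(counts), c(3L, 0L))
  expect_equal(attr(counts, "dropped"), 2)
  # conservation: assigned + dropped = total
  expect_equal(sum(counts) + attr(counts, "dropped"), nrow(det))

  # curated edits: remove 1, add 2 -> 3 - 1 + 2 = 4
  review <- data.frame(action = c("remove", "add", "add"),
                       organoid_id = 1L, row = c(10, 60, 70), col = c(10, 60, 70))
  cc <- count_tufts_per_organoid(det, rec, policy = "curated", review = review)
  expect_equal(unname(cc["1"]), 4L)

  # capture radius reassigns near-boundary background detections
  m <- matrix(0L, 250, 100); m[5:20, 5:60] <- 1L
  det2 <- data.frame(row = c(10, 22), col = c(10, 30), peak_intensity = 50,
                     scale = 2, organoid_id = c(1L, 0L), curated = FALSE)
  cc2 <- count_tufts_per_organoid(det2, rec, mask = label_mask(m), capture_radius = 5)
  expect_equal(unname(cc2["1"]), 2L)

  # rejected records are refused; unknown organoid detected
  rej <- rec; rej$review_status[2] <- "rejected"
  expect_error(count_tufts_per_organoid(det, rej), "rejected")
  det$organoid_id[1] <- 9L
  expect_error(count_tufts_per_organoid(det, rec), "unknown organoid")
})

test_that("fraction_high_tuft uses strict 'more than' and rejects empty input", {
  expect_equal(fraction_high_tuft(c(0, 9, 12, 3), 8), 50.0)
  expect_equal(fraction_high_tuft(rep(8, 5), 8), 0.0)
  expect_equal(fraction_high_tuft(c(9, 10, 11), 8), 100.0)
  expect_error(fraction_high_tuft(integer(0), 8), "empty")
})

test_that("tuft counts split by class conserve the total", {
  rec <- make_records(4, class_label = c("spheroid", "budding", "budding", "unclassified"))
  counts <- stats::setNames(c(0L, 7L, 9L, 2L), 1:4)
  tb <- tufts_by_class(counts, rec)
  expect_equal(unname(tb$means["spheroid"]), 0)
  expect_equal(unname(tb$means["budding"]), 8)
  expect_equal(sum(unlist(tb$distributions)), tb$total)
  expect_equal(tb$total, 18)
  expect_error(tufts_by_class(stats::setNames(1L, 99), rec), "absent")
})

test_that("budding-biased generation yields zero spheroid tufts when law says so", {
  sc <- generate_confocal_scene(2, 2,
                                spots_per_organoid_law = list(spheroid = 0, budding = 4),
                                image_shape = c(512, 512), seed = 21)
  cnt <- vapply(sc$truth$true_spots, nrow, 0L)
  expect_true(all(cnt[sc$truth$true_classes == "spheroid"] == 0))
})

test_that("roi_positive_ratio supports both modes and flags undefined ratios", {
  img <- matrix(0, 20, 20)
  crypt <- matrix(FALSE, 20, 20); crypt[1:10, ] <- TRUE
  villus <- !crypt
  img[crypt][1:30] <- 200   # 30 positives in crypt
  img[villus][1:60] <- 200  # 60 positives in villus
  rois <- roi_set(list(crypt = crypt, villus = villus), "m1")
  r <- roi_positive_ratio(img2d(img), rois, "crypt", "villus", thresholds = 100)
  expect_equal(r$ratio, 0.5)
  expect_false(r$undefined)

  # self-ratio is exactly 1
  rs <- roi_positive_ratio(img2d(img), rois, "crypt", "crypt", thresholds = 100)
  expect_equal(rs$ratio, 1.0)

  # two-channel mode (e.g. pSMAD2 / DAPI in one region)
  ch <- list(pSMAD2 = img2d(img), DAPI = img2d(matrix(200, 20, 20)))
  r2 <- roi_positive_ratio(ch, rois, "pSMAD2", "DAPI",
                           thresholds = c(pSMAD2 = 100, DAPI = 100), roi = "crypt")
  expect_equal(r2$ratio, 30 / 200)

  # denominator without positives -> undefined, never infinity
  dark <- img2d(matrix(0, 20, 20))
  r3 <- roi_positive_ratio(list(a = img2d(img), b = dark), rois, "a", "b",
                           thresholds = 100, roi = "crypt")
  expect_true(r3$undefined)
  expect_true(is.na(r3$ratio))
  expect_error(roi_positive_ratio(img2d(img), rois, "nope", "villus", 100),
               "missing ROI")
})

test_that("proximity_signal_ratio measures vicinity vs background signal", {
  sig <- matrix(25, 60, 60)
  ref <- matrix(FALSE, 60, 60); ref[28:32, 28:32] <- TRUE
  near_true <- matrix(FALSE, 60, 60); near_true[23:37, 23:37] <- TRUE
  sig[near_true] <- 100
  bg <- matrix(TRUE, 60, 60)
  r <- proximity_signal_ratio(img2d(sig), ref, bg, dilation_radius_um = 5)
  expect_equal(r$ratio, 4.0, tolerance = 0.15)   # 100 near vs 25 background

  # spatially uniform signal: ratio exactly 1
  ru <- proximity_signal_ratio(img2d(matrix(42, 60, 60)), ref, bg, 5)
  expect_equal(ru$ratio, 1.0)

  # invariant to padding the image with a zero border excluded from both masks
  sig_p <- rbind(0, cbind(0, sig, 0), 0)
  ref_p <- rbind(FALSE, cbind(FALSE, ref, FALSE), FALSE)
  bg_p <- rbind(FALSE, cbind(FALSE, bg, FALSE), FALSE)
  rp <- proximity_signal_ratio(img2d(sig_p), ref_p, bg_p, 5)
  expect_equal(rp$ratio, r$ratio)

  expect_error(proximity_signal_ratio(img2d(sig), matrix(FALSE, 60, 60), bg, 5),
               "empty reference")
  expect_error(proximity_signal_ratio(img2d(sig), ref, ref, 5), "empty background")
})

test_that("cell counting per ROI is exact on planted blobs and additive", {
  img <- matrix(10, 256, 256)
  set.seed(2)
  repeat {
    ctrs <- cbind(sample(30:120, 14), sample(30:220, 14))
    if (min(dist(ctrs)) >= 12) break
  }
  for (k in 1:14) img <- organoquant:::add_gaussian_blob(img, ctrs[k, ], 2.5, 120)
  img <- round(pmin(pmax(img + rnorm(length(img), 0, 2), 0), 255))
  crypt <- matrix(FALSE, 256, 256); crypt[1:128, ] <- TRUE
  rois <- roi_set(list(crypt = crypt, villus = !crypt), "m1")
  cfg <- quant_config(spots = list(sigma_min = 2, sigma_max = 4, n_scales = 3))
  cc <- count_positive_cells(img2d(img), rois, cfg)
  expect_lte(abs(cc[["crypt"]] - 14), 1)
  expect_equal(cc[["villus"]], 0)

  # additivity over a disjoint split of the same region
  left <- crypt; left[, 129:256] <- FALSE
  right <- crypt & !left
  cc2 <- count_positive_cells(img2d(img), roi_set(list(l = left, r = right)), cfg)
  expect_equal(cc2[["l"]] + cc2[["r"]], cc[["crypt"]])
  expect_error(count_positive_cells(img2d(img),
                                    roi_set(list(x = matrix(FALSE, 256, 256))), cfg),
               "empty ROI")
})

test_that("per-subject aggregation enforces the minimum-ROI rule", {
  values <- c(1, 2, 3, 4, 5, 10, 20, 30, 40)
  subjects <- c(rep("m1", 5), rep("m2", 4))
  ag <- aggregate_by_subject(values, subjects, min_rois = 5)
  expect_equal(ag$means$subject, "m1")
  expect_equal(ag$means$mean, 3.0)
  expect_equal(ag$excluded$subject, "m2")
  expect_equal(ag$excluded$n, 4L)
  # order invariance
  set.seed(1)
  o <- sample(length(values))
  ag2 <- aggregate_by_subject(values[o], subjects[o], min_rois = 5)
  expect_equal(ag2$means, ag$means)
})
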