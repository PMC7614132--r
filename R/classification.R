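# Spheroid/budding classification: crop extraction, the CNN and a
# deterministic shape-feature fallback, and the manual-correction cycle
# (review sheets, corrections, concordance).

#' Extract per-organoid crops for classification
#'
#' For each labelled object: tight bounding box plus a fractional margin,
#' masked to the object (non-object pixels set to `pad_value`), padded to a
#' square and resampled to the configured side length. Objects with fewer
#' than `min_crop_pixels` pixels are emitted flagged unclassifiable.
#'
#' @param image an `img2d`.
#' @param mask aligned `label_mask`.
#' @param cfg a `quant_config` (`classifier` block: crop_side, crop_margin,
#'   min_crop_pixels, pad_value).
#' @param image_id identifier recorded on each crop.
#' @return list of `organoid_crop` objects (pixels, organoid_id, image_id,
#'   unclassifiable flag).
#' @export
make_crops <- function(image, mask, cfg = quant_config(), image_id = "") {
  if (!identical(dim(mask$labels), dim(image$pixels)))
    stop("mask and image shapes differ")
  cc <- cfg$classifier
  n <- max(mask$labels)
  out <- vector("list", n)
  for (id in seq_len(n)) {
    sel <- mask$labels == id
    npx <- sum(sel)
    pos <- which(sel, arr.ind = TRUE)
    r0 <- min(pos[, 1]); r1 <- max(pos[, 1])
    c0 <- min(pos[, 2]); c1 <- max(pos[, 2])
    mr <- ceiling(cc$crop_margin * (r1 - r0 + 1))
    mc <- ceiling(cc$crop_margin * (c1 - c0 + 1))
    r0 <- max(1, r0 - mr); r1 <- min(nrow(sel), r1 + mr)
    c0 <- max(1, c0 - mc); c1 <- min(ncol(sel), c1 + mc)
    patch <- matrix(cc$pad_value, r1 - r0 + 1, c1 - c0 + 1)
    subsel <- sel[r0:r1, c0:c1]
    subimg <- image$pixels[r0:r1, c0:c1]
    patch[subsel] <- subimg[subsel]
    # pad to square, centring the object
    h <- nrow(patch); w <- ncol(patch)
    side <- max(h, w)
    sq <- matrix(cc$pad_value, side, side)
    ro <- (side - h) %/% 2; co <- (side - w) %/% 2
    sq[(ro + 1):(ro + h), (co + 1):(co + w)] <- patch
    resamp <- EBImage::resize(sq, w = cc$crop_side, h = cc$crop_side)
    out[[id]] <- structure(list(pixels = resamp, organoid_id = id,
                                image_id = image_id,
                                unclassifiable = npx < cc$min_crop_pixels,
                                pad_value = cc$pad_value,
                                bit_depth = image$bit_depth),
                           class = "organoid_crop")
  }
  out
}

#' Generate labelled training crops from synthetic single-organoid scenes
#'
#' Draws one organoid per small scene (alternating or balanced classes),
#' segments nothing — crops are taken on the ground-truth mask — and
#' returns crops with their true class labels. This is the benchmark
#' training set for [train_classifier()].
#'
#' @param n total number of crops (split evenly between classes).
#' @param cfg a `quant_config`.
#' @param params generator parameters, see [scene_params()].
#' @param seed integer seed.
#' @return list with `crops` (list of `organoid_crop`) and `labels`
#'   (character vector, "spheroid"/"budding").
#' @export
generate_training_crops <- function(n, cfg = quant_config(),
                                    params = scene_params(), seed = 1) {
  n_sph <- n %/% 2
  labels <- rep(c("spheroid", "budding"), c(n_sph, n - n_sph))
  with_seed(seed, {
    scene_seeds <- sample.int(2^30, n)
    crops <- vector("list", n)
    shape <- c(128, 128)
    p <- modifyList(params, list(radius_range = pmin(params$radius_range, c(12, 24))))
    for (i in seq_len(n)) {
      sc <- if (labels[i] == "spheroid")
        generate_brightfield_scene(1, 0, shape, p, seed = scene_seeds[i])
      else generate_brightfield_scene(0, 1, shape, p, seed = scene_seeds[i])
      crops[[i]] <- make_crops(sc$image, sc$truth$true_mask, cfg)[[1]]
    }
    list(crops = crops, labels = labels)
  })
}

CLASS_LEVELS <- c("spheroid", "budding")

crop_to_input <- function(crop) {
  rng <- 2^crop$bit_depth - 1
  crop$pixels / rng - 0.5
}

# Shape features of a crop: recovered object mask = pixels above a small
# offset from the pad value (crops are masked, pad 0, interiors >= 0.2 of
# the dynamic range).
crop_shape_features <- function(crop) {
  rng <- 2^crop$bit_depth - 1
  bin <- crop$pixels > (crop$pad_value + 0.05 * rng)
  lab <- EBImage::bwlabel(bin * 1)
  if (max(lab) == 0) return(c(solidity = 1, circularity = 1, extent = 0))
  # keep largest component (resampling can shed tiny satellites)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  main <- which.max(areas)
  lab <- matrix(as.integer(lab == main), nrow(lab), ncol(lab))
  shp <- EBImage::computeFeatures.shape(lab)
  area <- shp[1, "s.area"]; perim <- max(shp[1, "s.perimeter"], 1)
  sol <- solidity_per_object(lab, 1)
  circ <- min(4 * pi * area / perim^2, 1)
  c(solidity = sol, circularity = circ, extent = area / length(lab))
}

#' Train a spheroid/budding classifier
#'
#' `kind = "cnn"` trains the compact three-block convolutional network on
#' the raw crops; `kind = "shape_features"` fits a logistic rule on crop
#' solidity, circularity and extent — deterministic, interpretable, and the
#' cross-check for the CNN. A stratified hold-out fraction measures
#' validation accuracy, recorded in the model's metadata. Fixed seed gives
#' reproducible weights on a fixed platform.
#'
#' @param crops list of `organoid_crop` (unclassifiable crops are refused).
#' @param labels character vector in {"spheroid","budding"}, one per crop.
#' @param kind "cnn" or "shape_features".
#' @param epochs training epochs (CNN only).
#' @param lr Adam learning rate (CNN only).
#' @param val_frac stratified hold-out fraction for validation accuracy.
#' @param seed integer seed (init + shuffling).
#' @return an `organoid_classifier` model.
#' @export
train_classifier <- function(crops, labels, kind = c("cnn", "shape_features"),
                             epochs = 6, lr = 1e-3, val_frac = 0.2, seed = 1) {
  kind <- match.arg(kind)
  if (length(crops) == 0) stop("empty training set")
  if (length(crops) != length(labels)) stop("crops and labels lengths differ")
  if (!all(labels %in% CLASS_LEVELS)) stop("labels must be spheroid/budding")
  if (length(unique(labels)) < 2) stop("training needs both classes present")
  y <- match(labels, CLASS_LEVELS)

  with_seed(seed, {
    idx_val <- unlist(lapply(1:2, function(cl) {
      ii <- which(y == cl)
      sample(ii, max(1, round(val_frac * length(ii))))
    }))
    idx_tr <- setdiff(seq_along(y), idx_val)

    if (kind == "shape_features") {
      feats <- t(vapply(crops, crop_shape_features, numeric(3)))
      df <- data.frame(y = y - 1, feats)
      fit <- suppressWarnings(stats::glm(y ~ solidity + circularity + extent,
                                         data = df[idx_tr, ], family = stats::binomial()))
      coefs <- stats::coef(fit)
      coefs[!is.finite(coefs)] <- 0
      p_val <- as.vector(1 / (1 + exp(-(cbind(1, feats[idx_val, , drop = FALSE]) %*% coefs))))
      acc <- mean((p_val > 0.5) == (y[idx_val] == 2))
      model <- list(kind = "shape_features", coefficients = coefs)
    } else {
      side <- nrow(crops[[1]]$pixels)
      net <- cnn_init(side)
      st <- adam_state(net)
      for (ep in seq_len(epochs)) {
        ord <- sample(idx_tr)
        for (i in ord) {
          oh <- c(0, 0); oh[y[i]] <- 1
          stp <- cnn_train_step(net, st, crop_to_input(crops[[i]]), oh, lr)
          net <- stp$model; st <- stp$st
        }
      }
      pv <- t(vapply(idx_val, function(i) cnn_forward(net, crop_to_input(crops[[i]])),
                     numeric(2)))
      acc <- mean(max.col(pv, ties.method = "first") == y[idx_val])
      model <- list(kind = "cnn", net = net)
    }
    model$class_map <- CLASS_LEVELS
    model$meta <- list(seed = seed, epochs = if (kind == "cnn") epochs else NA,
                       n_train = length(idx_tr), n_val = length(idx_val),
                       validation_accuracy = acc)
    structure(model, class = "organoid_classifier")
  })
}

#' @export
print.organoid_classifier <- function(x, ...) {
  cat(sprintf("<organoid_classifier> kind=%s, val accuracy %.3f (n_val=%d)\n",
              x$kind, x$meta$validation_accuracy, x$meta$n_val))
  invisible(x)
}

#' Class probabilities for a set of crops
#'
#' @param model an `organoid_classifier`.
#' @param crops list of `organoid_crop`.
#' @return matrix n x 2 with columns (spheroid, budding); rows for
#'   unclassifiable crops are NA.
#' @export
predict_classifier <- function(model, crops) {
  probs <- matrix(NA_real_, length(crops), 2,
                  dimnames = list(NULL, CLASS_LEVELS))
  for (i in seq_along(crops)) {
    cr <- crops[[i]]
    if (isTRUE(cr$unclassifiable)) next
    if (model$kind == "cnn") {
      if (nrow(cr$pixels) != model$net$side)
        stop(sprintf("crop side %d does not match model side %d",
                     nrow(cr$pixels), model$net$side))
      probs[i, ] <- cnn_forward(model$net, crop_to_input(cr))
    } else {
      f <- crop_shape_features(cr)
      p_bud <- 1 / (1 + exp(-sum(model$coefficients * c(1, f))))
      probs[i, ] <- c(1 - p_bud, p_bud)
    }
  }
  probs
}

#' Classify organoid records from their crops
#'
#' Assigns the argmax class with its probability as confidence.
#' Unclassifiable crops and predictions within `decision_margin` of 0.5 are
#' left "unclassified" and queued for manual review.
#'
#' @param records record data frame (from [extract_features()]).
#' @param crops crops from [make_crops()] for the same mask.
#' @param model an `organoid_classifier`.
#' @param cfg a `quant_config` (decision_margin).
#' @return updated records with class_label and confidence filled in.
#' @export
classify_organoids <- function(records, crops, model, cfg = quant_config()) {
  ids <- vapply(crops, function(cr) cr$organoid_id, 0L)
  probs <- predict_classifier(model, crops)
  margin <- cfg$classifier$decision_margin
  for (i in seq_along(crops)) {
    row <- which(records$organoid_id == ids[i])
    if (length(row) != 1) next
    p <- probs[i, ]
    if (any(is.na(p)) || abs(max(p) - 0.5) < margin) {
      records$class_label[row] <- "unclassified"
      records$confidence[row] <- NA_real_
    } else {
      records$class_label[row] <- CLASS_LEVELS[which.max(p)]
      records$confidence[row] <- max(p)
    }
  }
  records
}

# --- manual-correction cycle ---------------------------------------------

REVIEW_COLUMNS <- c("image_id", "organoid_id", "predicted_class", "confidence",
                    "corrected_class", "reject")

#' Export a review sheet for manual correction
#'
#' One row per organoid: predicted class and confidence, plus empty
#' `corrected_class` and `reject` columns for the reviewer to fill.
#' Unclassified organoids sort first so difficult calls are reviewed first.
#'
#' @param records record data frame.
#' @param path optional CSV path; if NULL the sheet is only returned.
#' @return the review-sheet data frame, invisibly if written.
#' @export
export_review_sheet <- function(records, path = NULL) {
  sheet <- data.frame(image_id = records$image_id,
                      organoid_id = records$organoid_id,
                      predicted_class = records$class_label,
                      confidence = records$confidence,
                      corrected_class = "",
                      reject = FALSE,
                      stringsAsFactors = FALSE)
  sheet <- sheet[order(sheet$predicted_class != "unclassified",
                       sheet$image_id, sheet$organoid_id), ]
  rownames(sheet) <- NULL
  if (!is.null(path)) {
    utils::write.csv(sheet, path, row.names = FALSE)
    return(invisible(sheet))
  }
  sheet
}

#' Read a review sheet CSV
#' @param path CSV with the review-sheet header.
#' @return review-sheet data frame.
#' @export
read_review_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
  miss <- setdiff(REVIEW_COLUMNS, names(sheet))
  if (length(miss) > 0)
    stop(sprintf("review sheet missing columns: %s", paste(miss, collapse = ", ")))
  sheet$corrected_class <- as.character(sheet$corrected_class)
  sheet$corrected_class[is.na(sheet$corrected_class)] <- ""
  sheet$reject <- as.logical(sheet$reject)
  sheet
}

#' Apply manual corrections to records
#'
#' A non-empty `corrected_class` overrides the class label and marks the
#' record corrected (the pre-correction label is kept in a
#' `precorrection_class` column); a reject flag marks the record rejected,
#' which excludes it from all downstream statistics. Untouched rows are
#' unchanged. Idempotent for a fixed sheet.
#'
#' @param records record data frame.
#' @param sheet review-sheet data frame (or CSV path).
#' @return corrected records.
#' @export
apply_corrections <- function(records, sheet) {
  if (is.character(sheet)) sheet <- read_review_sheet(sheet)
  if (!"precorrection_class" %in% names(records))
    records$precorrection_class <- NA_character_
  for (k in seq_len(nrow(sheet))) {
    row <- which(records$organoid_id == sheet$organoid_id[k] &
                 records$image_id == sheet$image_id[k])
    if (length(row) == 0)
      stop(sprintf("review sheet references unknown organoid %s/%d",
                   sheet$image_id[k], sheet$organoid_id[k]))
    if (isTRUE(sheet$reject[k])) {
      records$review_status[row] <- "rejected"
      next
    }
    cl <- sheet$corrected_class[k]
    if (!nzchar(cl)) next
    if (!cl %in% CLASS_LEVELS)
      stop(sprintf("invalid corrected_class '%s' for organoid %s/%d",
                   cl, sheet$image_id[k], sheet$organoid_id[k]))
    if (cl != records$class_label[row]) {
      if (is.na(records$precorrection_class[row]))
        records$precorrection_class[row] <- records$class_label[row]
      records$class_label[row] <- cl
      records$review_status[row] <- "corrected"
      records$confidence[row] <- NA_real_
    }
  }
  records
}

#' Agreement between automatic and corrected classifications
#'
#' @param auto_records records as produced by the classifier.
#' @param corrected_records the same records after [apply_corrections()].
#' @return list: `agreement` fraction in [0,1], `confusion` table
#'   (auto class x corrected class), `n`.
#' @export
concordance <- function(auto_records, corrected_records) {
  key_a <- paste(auto_records$image_id, auto_records$organoid_id)
  key_c <- paste(corrected_records$image_id, corrected_records$organoid_id)
  if (!setequal(key_a, key_c) || length(key_a) != length(key_c))
    stop("record sets do not match")
  corrected_records <- corrected_records[match(key_a, key_c), ]
  a <- factor(auto_records$class_label, levels = VALID_CLASSES)
  b <- factor(corrected_records$class_label, levels = VALID_CLASSES)
  list(agreement = mean(a == b),
       confusion = table(auto = a, corrected = b),
       n = length(a))
}
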