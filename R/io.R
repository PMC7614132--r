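# TIFF and CSV input/output. Images travel as plain TIFF; the TIFF baseline
# has no pixel-size tag writable through the tiff package, so calibration is
# carried in a small JSON sidecar (<path>.meta.json) written next to every
# stack this package writes, and read back when present. Foreign TIFFs
# without a sidecar fall back to 1 um/px with a warning unless the caller
# overrides.

meta_path <- function(path) paste0(path, ".meta.json")

#' Read a TIFF z-stack
#'
#' Multi-page TIFFs are resolved into one or more stacks via `channel_map`,
#' a named list mapping channel name to the 1-based page indices belonging
#' to that channel. With `channel_map = NULL` all pages form a single stack.
#' Plane order follows page order (deterministic).
#'
#' @param path TIFF file.
#' @param channel_map named list of page-index vectors, or NULL.
#' @param pixel_size_um calibration override; if NULL, taken from the
#'   sidecar written by [write_zstack()], else defaults to 1 with a warning.
#' @return a `zstack`, or a named list of `zstack`s if `channel_map` has
#'   more than one entry.
#' @export
read_zstack <- function(path, channel_map = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read TIFF: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- lapply(pages, dim)
  for (i in seq_along(shapes)) {
    if (!identical(shapes[[i]], shapes[[1]]))
      stop(sprintf("page %d has shape %s, inconsistent with page 1 (%s)", i,
                   paste(shapes[[i]], collapse = "x"),
                   paste(shapes[[1]], collapse = "x")))
  }
  info <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
  bit_depth <- attr(info, "bits.per.sample")
  if (is.null(bit_depth) || !bit_depth %in% c(8, 16)) bit_depth <- 8L

  meta <- NULL
  if (file.exists(meta_path(path)))
    meta <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  if (is.null(pixel_size_um)) {
    if (!is.null(meta$pixel_size_um)) {
      pixel_size_um <- meta$pixel_size_um
    } else {
      warning(sprintf("no pixel size for %s; defaulting to 1 um/px", basename(path)))
      pixel_size_um <- 1.0
    }
  }
  if (!is.null(meta$bit_depth)) bit_depth <- meta$bit_depth

  if (is.null(channel_map)) {
    ch <- if (!is.null(meta$channel)) meta$channel else "gray"
    channel_map <- stats::setNames(list(seq_along(pages)), ch)
  }
  out <- lapply(names(channel_map), function(ch) {
    idx <- channel_map[[ch]]
    if (any(idx < 1 | idx > length(pages)))
      stop(sprintf("channel_map for '%s' indexes page outside 1..%d", ch, length(pages)))
    zstack(lapply(idx, function(i) pages[[i]] + 0), channel = ch,
           pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth))
  })
  names(out) <- names(channel_map)
  if (length(out) == 1) out[[1]] else out
}

#' Write a z-stack (or single image) as a multi-page TIFF
#'
#' Lossless for integer-valued intensities at the stack's bit depth. A JSON
#' sidecar records channel name, pixel size and bit depth so that
#' [read_zstack()] round-trips calibration.
#'
#' @param stack a `zstack` or `img2d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  if (inherits(stack, "img2d"))
    stack <- zstack(list(stack$pixels), stack$channel, stack$pixel_size_um,
                    stack$bit_depth)
  rng <- 2^stack$bit_depth - 1
  planes <- lapply(seq_len(n_planes(stack)),
                   function(i) round(stack$planes[i, , ]) / rng)
  tiff::writeTIFF(planes, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  jsonlite::write_json(list(channel = stack$channel,
                            pixel_size_um = stack$pixel_size_um,
                            bit_depth = stack$bit_depth),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a label mask as a 16-bit single-page TIFF
#'
#' @param mask a `label_mask` with at most 65535 objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  mx <- max(mask$labels)
  if (mx > 65535)
    stop(sprintf("mask has %d labels; 16-bit storage caps at 65535", mx))
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size_um, kind = "label_mask"),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path TIFF path.
#' @return a `label_mask`.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read TIFF: %s", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  px <- 1.0
  if (file.exists(meta_path(path))) {
    meta <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
  }
  label_mask(m, pixel_size_um = px)
}

#' Write organoid records to CSV
#'
#' Fixed header: organoid_id, area_um2, mean_gray, class_label, confidence,
#' review_status, image_id, treatment. Extra columns (shape features,
#' provenance) are appended after the fixed block.
#'
#' @param records record data frame, see [empty_records()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  extra <- setdiff(names(records), RECORD_COLUMNS)
  utils::write.csv(records[, c(RECORD_COLUMNS, extra), drop = FALSE], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read organoid records from CSV
#'
#' Malformed rows (unknown class or status, non-positive area) are reported
#' with their line number.
#'
#' @param path CSV written by [write_records()].
#' @return validated record data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read records: %s", path))
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(RECORD_COLUMNS, names(rec))
  if (length(miss) > 0)
    stop(sprintf("%s missing columns: %s", path, paste(miss, collapse = ", ")))
  for (col in c("class_label", "review_status", "image_id", "treatment"))
    rec[[col]] <- ifelse(is.na(rec[[col]]), "", as.character(rec[[col]]))
  rec$class_label[rec$class_label == ""] <- "unclassified"
  rec$review_status[rec$review_status == ""] <- "auto"
  bad <- which(!rec$class_label %in% VALID_CLASSES)
  if (length(bad) > 0)
    stop(sprintf("%s line %d: invalid class_label '%s'", path, bad[1] + 1,
                 rec$class_label[bad[1]]))
  bad <- which(!rec$review_status %in% VALID_STATUS)
  if (length(bad) > 0)
    stop(sprintf("%s line %d: invalid review_status '%s'", path, bad[1] + 1,
                 rec$review_status[bad[1]]))
  bad <- which(!is.finite(rec$area_um2) | rec$area_um2 <= 0)
  if (length(bad) > 0)
    stop(sprintf("%s line %d: area_um2 must be a positive number", path, bad[1] + 1))
  rec
}

#' Write tuft detections to CSV
#' @param detections detection data frame from [detect_spots()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' Read tuft detections from CSV
#' @param path CSV written by [write_detections()].
#' @return detection data frame.
#' @export
read_detections <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
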