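# Shared domain types. All images are plain numeric matrices indexed
# (row, col), 0-based coordinates in exported tables, intensities on the
# native bit-depth scale [0, 2^bit_depth - 1].

#' Construct a 2-D image
#'
#' A single intensity plane with channel name and physical calibration.
#' Intensities are kept on the native bit-depth scale; "higher value is
#' whiter" on brightfield images.
#'
#' @param pixels numeric matrix indexed (row, col).
#' @param channel channel name string.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param bit_depth integer, 8 or 16.
#' @return an object of class `img2d`.
#' @export
img2d <- function(pixels, channel = "gray", pixel_size_um = 1, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (any(!is.finite(pixels))) stop("image contains non-finite pixels")
  rng <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > rng)
    stop(sprintf("intensities outside [0, %d] for bit depth %d", rng, bit_depth))
  structure(list(pixels = pixels, channel = channel,
                 pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth)),
            class = "img2d")
}

#' Construct a z-stack
#'
#' An ordered set of 2-D planes sharing one channel and calibration.
#'
#' @param planes 3-D numeric array indexed (z, row, col), or a list of
#'   equally sized matrices.
#' @inheritParams img2d
#' @return an object of class `zstack`.
#' @export
zstack <- function(planes, channel = "gray", pixel_size_um = 1, bit_depth = 8L) {
  if (is.list(planes)) {
    dims <- lapply(planes, dim)
    if (length(planes) == 0) stop("a z-stack needs at least one plane")
    for (i in seq_along(dims)) {
      if (!identical(dims[[i]], dims[[1]]))
        stop(sprintf("plane %d has shape %s, expected %s", i,
                     paste(dims[[i]], collapse = "x"),
                     paste(dims[[1]], collapse = "x")))
    }
    arr <- array(0, c(length(planes), dims[[1]]))
    for (i in seq_along(planes)) arr[i, , ] <- planes[[i]]
    planes <- arr
  }
  stopifnot(is.array(planes), length(dim(planes)) == 3)
  if (dim(planes)[1] < 1) stop("a z-stack needs at least one plane")
  if (any(!is.finite(planes))) stop("stack contains non-finite pixels")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(planes = planes, channel = channel,
                 pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth)),
            class = "zstack")
}

#' Number of planes in a z-stack
#' @param stack a `zstack`.
#' @return integer plane count.
#' @export
n_planes <- function(stack) dim(stack$planes)[1]

#' Construct a label mask
#'
#' Integer image in which background is 0 and each object's pixels share a
#' unique positive id.
#'
#' @param labels non-negative integer matrix.
#' @param pixel_size_um calibration carried along for area computations.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um = 1) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("label mask must be non-negative")
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' Renumber mask labels to a contiguous 1..N range
#'
#' Object pixel sets are preserved; only ids change. Ids are assigned in
#' increasing order of the original ids.
#'
#' @param mask a `label_mask`.
#' @return a `label_mask` with labels in 1..N.
#' @export
compact_labels <- function(mask) {
  ids <- sort(unique(as.vector(mask$labels)))
  ids <- ids[ids > 0]
  if (length(ids) == 0) return(mask)
  lut <- integer(max(ids) + 1)
  lut[ids + 1] <- seq_along(ids)
  mask$labels <- matrix(lut[mask$labels + 1], nrow(mask$labels), ncol(mask$labels))
  mask
}

#' @export
print.img2d <- function(x, ...) {
  cat(sprintf("<img2d> %dx%d, channel '%s', %.3g um/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$channel, x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<zstack> %d planes of %dx%d, channel '%s', %.3g um/px, %d-bit\n",
              d[1], d[2], d[3], x$channel, x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %dx%d, %d objects\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

VALID_CLASSES <- c("spheroid", "budding", "unclassified")
VALID_STATUS <- c("auto", "corrected", "rejected")

#' Create an empty organoid record table
#'
#' The canonical per-organoid table: id, area in square micrometres, mean
#' brightfield gray value, morphology class, classifier confidence, review
#' status, and provenance columns.
#'
#' @return zero-row data frame with the canonical columns.
#' @export
empty_records <- function() {
  data.frame(organoid_id = integer(0), area_um2 = numeric(0),
             mean_gray = numeric(0), class_label = character(0),
             confidence = numeric(0), review_status = character(0),
             image_id = character(0), treatment = character(0),
             stringsAsFactors = FALSE)
}

RECORD_COLUMNS <- c("organoid_id", "area_um2", "mean_gray", "class_label",
                    "confidence", "review_status", "image_id", "treatment")

validate_records <- function(records, where = "records") {
  miss <- setdiff(RECORD_COLUMNS, names(records))
  if (length(miss) > 0)
    stop(sprintf("%s missing columns: %s", where, paste(miss, collapse = ", ")))
  bad <- which(!records$class_label %in% VALID_CLASSES)
  if (length(bad) > 0)
    stop(sprintf("%s: invalid class_label '%s' at row %d", where,
                 records$class_label[bad[1]], bad[1]))
  bad <- which(!records$review_status %in% VALID_STATUS)
  if (length(bad) > 0)
    stop(sprintf("%s: invalid review_status '%s' at row %d", where,
                 records$review_status[bad[1]], bad[1]))
  if (any(records$area_um2 <= 0, na.rm = TRUE))
    stop(sprintf("%s: area_um2 must be positive", where))
  invisible(records)
}

# Run an expression under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
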