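# Quantification configuration: one nested list with every tunable knob the
# pipeline reads, serialised as YAML. Defaults are documented per field in
# quant_config().

#' Default quantification configuration
#'
#' Returns the full configuration tree with defaults; any supplied value
#' overrides the matching default (partial lists are merged recursively).
#'
#' Key fields:
#' \describe{
#'   \item{projection}{per-channel projection method; brightfield defaults
#'     to `min` (organoids are darker than background), confocal channels
#'     to `max`.}
#'   \item{segmentation}{smoothing sigma (px), threshold mode (`otsu` or a
#'     fixed value), polarity, hole filling, minimum object area (um^2),
#'     border policy, watershed splitting of touching objects.}
#'   \item{classifier}{square crop side (px), minimum object pixels for a
#'     crop to be classifiable, decision margin routing uncertain calls to
#'     manual review.}
#'   \item{spots}{Laplacian-of-Gaussian scale range (px), number of scales,
#'     peak threshold mode and SNR factor, non-maximum-suppression minimum
#'     separation (px).}
#'   \item{positive_pixel}{per-marker intensity thresholds; pixels strictly
#'     above the threshold count as positive.}
#'   \item{tuft_high_cutoff}{strict lower bound for the "high tuft" call;
#'     an organoid counts only with more than this many tuft cells
#'     (default 8).}
#'   \item{min_rois_per_subject}{minimum ROIs (e.g. crypts) required before
#'     a subject mean is reported (default 5).}
#' }
#'
#' @param ... named overrides, e.g. `segmentation = list(smoothing_sigma = 3)`.
#' @return configuration list of class `quant_config`.
#' @export
quant_config <- function(...) {
  cfg <- list(
    pixel_size_um = 1.0,
    seed = 1L,
    projection = list(brightfield = "min", nuclei = "max", marker = "max"),
    segmentation = list(
      smoothing_sigma = 2,
      threshold_mode = "background",  # "background", "otsu" or "fixed"
      background_k = 4,               # threshold = median -/+ k * MAD
      fixed_threshold = NA,
      polarity = "dark_objects",
      fill_holes = TRUE,
      min_area_um2 = 200,
      border_policy = "keep",      # or "drop"
      split_touching = TRUE,
      watershed_footprint = 7,
      watershed_tolerance = 2,
      refine_boundaries = TRUE
    ),
    classifier = list(
      crop_side = 64L,
      crop_margin = 0.15,
      min_crop_pixels = 50L,
      pad_value = 0,
      decision_margin = 0.1
    ),
    spots = list(
      sigma_min = 1.5,
      sigma_max = 4,
      n_scales = 4,
      threshold_mode = "snr",      # or "absolute"
      snr_factor = 6,              # above the expected extreme of smoothed
                                   # background noise over a megapixel field
      absolute_threshold = NA,
      min_separation = 5,
      capture_radius = 0
    ),
    positive_pixel = list(default = 100),
    tuft_high_cutoff = 8L,
    min_rois_per_subject = 5L,
    proximity_dilation_um = 5
  )
  modifyList(structure(cfg, class = "quant_config"), list(...))
}

#' Read a configuration file
#'
#' YAML (or JSON, which YAML subsumes) key-value file; missing keys fall
#' back to the defaults of [quant_config()].
#'
#' @param path file path.
#' @return a `quant_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- modifyList(quant_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a configuration file
#' @param cfg a `quant_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  s <- cfg$segmentation
  if (s$smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  if (s$min_area_um2 < 0) stop("min_area_um2 must be >= 0")
  if (!s$threshold_mode %in% c("background", "otsu", "fixed"))
    stop("threshold_mode must be 'background', 'otsu' or 'fixed'")
  if (!s$polarity %in% c("dark_objects", "bright_objects"))
    stop("polarity must be 'dark_objects' or 'bright_objects'")
  if (!s$border_policy %in% c("keep", "drop"))
    stop("border_policy must be 'keep' or 'drop'")
  if (cfg$spots$sigma_min <= 0 || cfg$spots$sigma_max < cfg$spots$sigma_min)
    stop("invalid spot scale range")
  if (any(unlist(cfg$positive_pixel) < 0))
    stop("positive-pixel thresholds must be non-negative")
  if (cfg$tuft_high_cutoff < 0) stop("tuft_high_cutoff must be non-negative")
  if (cfg$min_rois_per_subject < 1) stop("min_rois_per_subject must be >= 1")
  invisible(cfg)
}
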