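# End-to-end pipeline: project -> segment -> features -> classify ->
# [corrections] -> spot detection -> tuft counts -> treatment summaries.
# Every run writes a machine-readable manifest (parameters, seed, stage
# list, package version) and a log, and is bit-reproducible for a fixed
# config and seed.

#' Run the full organoid quantification pipeline
#'
#' Inputs are declared in the config under `inputs`: a list of image
#' entries, each with `brightfield` (TIFF z-stack path), optional `marker`
#' and `nuclei` (confocal TIFF paths), an `image_id` and a `treatment`.
#' Optional elements: `model_path` (a classifier saved with
#' [save_classifier()]); `review_sheet` (CSV of manual corrections).
#'
#' Stages: projection (brightfield: min, marker: max), segmentation,
#' feature extraction, classification (skipped with a log note when no
#' model is given), correction (when a review sheet is given), spot
#' detection + tuft counting (when a marker channel is given), treatment
#' summary. Any stage error aborts the run naming the stage and input.
#'
#' @param config a `quant_config` (or path to one) with an `inputs` block.
#' @param out_dir output directory (created if needed).
#' @return invisible list: records, counts, summary, manifest (also written
#'   under `out_dir` as CSV/JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_config(config) else config
  validate_config(cfg)
  if (is.null(cfg$inputs) || length(cfg$inputs) == 0)
    stop("config has no inputs to process")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  stage <- function(name, input, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed on %s: %s", name, input,
                   conditionMessage(e)), call. = FALSE))
  }

  model <- NULL
  if (!is.null(cfg$model_path)) {
    model <- stage("load_model", cfg$model_path, load_classifier(cfg$model_path))
    logf("loaded %s classifier from %s", model$kind, cfg$model_path)
  } else logf("no model_path given: classification stage skipped")

  all_records <- list()
  all_counts <- list()
  stages_run <- c("project", "segment", "extract_features")

  for (inp in cfg$inputs) {
    iid <- inp$image_id
    bf_stack <- stage("read", inp$brightfield,
                      read_zstack(inp$brightfield,
                                  pixel_size_um = cfg$pixel_size_um))
    bf <- stage("project", iid,
                project_stack(bf_stack, cfg$projection$brightfield))
    mask <- stage("segment", iid, segment_brightfield(bf, cfg))
    write_label_mask(mask, file.path(out_dir, paste0(iid, "_mask.tif")))
    rec <- stage("extract_features", iid,
                 extract_features(mask, bf, image_id = iid,
                                  treatment = inp$treatment))
    logf("%s: %d organoids segmented", iid, nrow(rec))

    if (!is.null(model) && nrow(rec) > 0) {
      crops <- stage("make_crops", iid, make_crops(bf, mask, cfg, image_id = iid))
      rec <- stage("classify", iid, classify_organoids(rec, crops, model, cfg))
      stages_run <- union(stages_run, "classify")
    }

    if (!is.null(inp$marker) && nrow(rec) > 0) {
      mk_stack <- stage("read", inp$marker,
                        read_zstack(inp$marker, pixel_size_um = cfg$pixel_size_um))
      mk <- project_stack(mk_stack, cfg$projection$marker)
      det <- stage("detect_spots", iid, detect_spots(mk, mask, cfg))
      write_detections(det, file.path(out_dir, paste0(iid, "_detections.csv")))
      cnt <- stage("count_tufts", iid,
                   count_tufts_per_organoid(det, rec, policy = "auto"))
      all_counts[[iid]] <- stats::setNames(as.integer(cnt),
                                           paste(iid, names(cnt)))
      stages_run <- union(stages_run, c("detect_spots", "count_tufts"))
    }
    all_records[[iid]] <- rec
  }

  records <- do.call(rbind, all_records)
  rownames(records) <- NULL

  if (!is.null(cfg$review_sheet)) {
    records <- stage("apply_corrections", cfg$review_sheet,
                     apply_corrections(records, cfg$review_sheet))
    stages_run <- union(stages_run, "apply_corrections")
  }
  write_records(records, file.path(out_dir, "records.csv"))

  counts <- if (length(all_counts) > 0) do.call(c, unname(all_counts)) else NULL
  if (!is.null(counts))
    utils::write.csv(data.frame(key = names(counts), tuft_count = as.integer(counts)),
                     file.path(out_dir, "tuft_counts.csv"), row.names = FALSE)

  kept <- records[records$review_status != "rejected", , drop = FALSE]
  summary_tab <- stage("summarize", "records",
                       summarize_treatment(kept, counts))
  utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  stages_run <- union(stages_run, "summarize")

  manifest <- list(
    package = "organoquant",
    version = as.character(utils::packageVersion("organoquant")),
    seed = cfg$seed,
    stages = stages_run,
    n_images = length(cfg$inputs),
    n_organoids = nrow(records),
    config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete: %d organoids across %d images",
       nrow(records), length(cfg$inputs))
  invisible(list(records = records, counts = counts, summary = summary_tab,
                 manifest = manifest))
}

#' Save / load a trained classifier as JSON text
#'
#' Weights are written at full double precision (~1e-15 relative
#' round-trip accuracy), so models are diffable text files. The precomputed
#' convolution index tables are dropped on save and rebuilt on load.
#'
#' @param model an `organoid_classifier`.
#' @param path output path (.json).
#' @return `path` invisibly, or the model for [load_classifier()].
#' @export
save_classifier <- function(model, path) {
  m <- unclass(model)
  if (m$kind == "cnn")
    for (b in seq_along(m$net$conv)) m$net$conv[[b]]$ci <- NULL
  jsonlite::write_json(m, path, digits = NA, auto_unbox = TRUE, null = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(model$kind, "cnn")) {
    model$net$side <- as.integer(model$net$side)
    conv <- model$net$conv
    # read_json returns the conv block as a data-frame-like list; normalise
    if (is.data.frame(conv)) {
      conv <- lapply(seq_len(nrow(conv)), function(i) as.list(conv[i, ]))
      conv <- lapply(conv, function(ly) lapply(ly, function(x)
        if (is.list(x)) x[[1]] else x))
    }
    for (b in seq_along(conv)) {
      ly <- conv[[b]]
      ly$k <- as.integer(ly$k)
      ly$H_in <- as.integer(ly$H_in)
      ly$W <- as.matrix(ly$W)
      ly$b <- as.numeric(ly$b)
      ly$ci <- conv_index(ly$H_in, ly$H_in, ly$k, ly$k)
      conv[[b]] <- ly
    }
    model$net$conv <- conv
    model$net$W1 <- as.matrix(model$net$W1)
    model$net$W2 <- as.matrix(model$net$W2)
  } else {
    model$coefficients <- unlist(model$coefficients)
  }
  structure(model, class = "organoid_classifier")
}
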