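# Shared fixtures, built in code at test time.

# A small brightfield scene cached per (spheroid, budding, seed).
fixture_scene <- local({
  cache <- list()
  function(ns = 3, nb = 2, shape = c(256, 256), seed = 7) {
    key <- paste(ns, nb, paste(shape, collapse = "x"), seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_brightfield_scene(ns, nb, shape, seed = seed)
    cache[[key]]
  }
})

# A logistic shape-feature model with hand-set coefficients, for testing the
# decision plumbing (margin rule, confidence) with known probabilities.
fake_shape_model <- function(coefficients) {
  structure(list(kind = "shape_features",
                 coefficients = coefficients,
                 class_map = c("spheroid", "budding"),
                 meta = list(seed = 0, epochs = NA, n_train = 0, n_val = 0,
                             validation_accuracy = NA)),
            class = "organoid_classifier")
}

# Minimal valid record table.
make_records <- function(n, class_label = "spheroid", image_id = "img1",
                         treatment = "ctrl") {
  data.frame(organoid_id = seq_len(n),
             area_um2 = 100 + seq_len(n),
             mean_gray = 50 + seq_len(n),
             class_label = rep_len(class_label, n),
             confidence = 0.9,
             review_status = "auto",
             image_id = image_id,
             treatment = rep_len(treatment, n),
             stringsAsFactors = FALSE)
}

# Rasterised disk oracle: pixel centers within radius (brute force).
disk_matrix <- function(nrow, ncol, center, radius) {
  m <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) for (c in seq_len(ncol))
    if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) m[r, c] <- TRUE
  m
}
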