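# Crop extraction, classifier training/inference and the correction cycle.

test_that("crops are centred, masked, square and deterministic", {
  disk <- disk_matrix(80, 80, c(40, 40), 12)
  img <- matrix(204, 80, 80); img[disk] <- 90
  mask <- label_mask(matrix(as.integer(disk), 80, 80))
  crops <- make_crops(img2d(img), mask)
  expect_length(crops, 1)
  cr <- crops[[1]]
  side <- quant_config()$classifier$crop_side
  expect_equal(dim(cr$pixels), c(side, side))
  expect_false(cr$unclassifiable)
  # centre of mass of nonzero pixels within +-1 px of the crop centre
  nz <- which(cr$pixels > 10, arr.ind = TRUE)
  expect_lt(abs(mean(nz[, 1]) - (side + 1) / 2), 1)
  expect_lt(abs(mean(nz[, 2]) - (side + 1) / 2), 1)
  # masked: far corners are pad value
  expect_equal(cr$pixels[1, 1], 0)
  # determinism
  crops2 <- make_crops(img2d(img), mask)
  expect_identical(cr$pixels, crops2[[1]]$pixels)
})

test_that("tiny objects are flagged unclassifiable and never classified", {
  m <- matrix(0L, 64, 64); m[30:32, 30:32] <- 1L   # 9 px object
  img <- matrix(204, 64, 64); img[m == 1] <- 90
  crops <- make_crops(img2d(img), label_mask(m))   # min_crop_pixels = 50
  expect_true(crops[[1]]$unclassifiable)
  rec <- extract_features(label_mask(m), img2d(img))
  model <- fake_shape_model(c(10, 0, 0, 0))        # would be confident
  out <- classify_organoids(rec, crops, model)
  expect_equal(out$class_label, "unclassified")
  expect_true(is.na(out$confidence))
})

test_that("training refuses degenerate inputs", {
  tc <- generate_training_crops(8, seed = 2)
  expect_error(train_classifier(list(), character(0)), "empty")
  expect_error(train_classifier(tc$crops, rep("budding", 8)), "both classes")
  expect_error(train_classifier(tc$crops, rep("x", 8)), "spheroid/budding")
  expect_error(train_classifier(tc$crops[1:3], tc$labels), "lengths differ")
})

test_that("training twice with the same seed reproduces the model exactly", {
  tc <- generate_training_crops(40, seed = 2)
  a <- train_classifier(tc$crops, tc$labels, kind = "cnn", epochs = 1, seed = 5)
  b <- train_classifier(tc$crops, tc$labels, kind = "cnn", epochs = 1, seed = 5)
  expect_identical(a$meta$validation_accuracy, b$meta$validation_accuracy)
  expect_identical(a$net$W1, b$net$W1)
  s1 <- train_classifier(tc$crops, tc$labels, kind = "shape_features", seed = 5)
  s2 <- train_classifier(tc$crops, tc$labels, kind = "shape_features", seed = 5)
  expect_identical(s1$coefficients, s2$coefficients)
})

test_that("classification assigns argmax class with confidence, margin routes to review", {
  sc <- fixture_scene(2, 2, shape = c(384, 384), seed = 3)
  rec <- extract_features(sc$truth$true_mask, sc$image)
  crops <- make_crops(sc$image, sc$truth$true_mask)

  confident <- fake_shape_model(c(50, 0, 0, 0))   # saturated logit: p = 1
  out <- classify_organoids(rec, crops, confident)
  expect_true(all(out$class_label == "budding"))
  expect_true(all(out$confidence > 0.5 + quant_config()$classifier$decision_margin))

  # all-zero coefficients: p = 0.5 exactly -> inside any positive margin
  fence <- fake_shape_model(c(0, 0, 0, 0))
  out2 <- classify_organoids(rec, crops, fence)
  expect_true(all(out2$class_label == "unclassified"))
  expect_true(all(is.na(out2$confidence)))
})

test_that("trained classifiers recover ground-truth classes on a fresh scene", {
  tc <- generate_training_crops(120, seed = 3)
  model <- train_classifier(tc$crops, tc$labels, kind = "shape_features", seed = 3)
  sc <- generate_brightfield_scene(4, 4, c(512, 512), seed = 77)
  mask <- segment_brightfield(sc$image)
  rec <- classify_organoids(extract_features(mask, sc$image),
                            make_crops(sc$image, mask), model)
  m <- match_objects(mask, sc$truth$true_mask)
  hit <- 0
  for (k in seq_len(nrow(m$matches))) {
    pred <- rec$class_label[rec$organoid_id == m$matches$pred_id[k]]
    if (pred == sc$truth$true_classes[[m$matches$true_id[k]]]) hit <- hit + 1
  }
  expect_gte(hit / nrow(m$matches), 0.9)
})

test_that("classifier models round trip through JSON text", {
  td <- withr::local_tempdir()
  tc <- generate_training_crops(40, seed = 2)
  for (kind in c("shape_features", "cnn")) {
    m <- train_classifier(tc$crops, tc$labels, kind = kind,
                          epochs = 1, seed = 5)
    p <- file.path(td, paste0(kind, ".json"))
    save_classifier(m, p)
    m2 <- load_classifier(p)
    pr1 <- predict_classifier(m, tc$crops[1:6])
    pr2 <- predict_classifier(m2, tc$crops[1:6])
    expect_equal(pr1, pr2, tolerance = 1e-12)
  }
})

test_that("review sheets round trip and corrections are local and idempotent", {
  td <- withr::local_tempdir()
  rec <- make_records(4, class_label = c("spheroid", "spheroid", "budding", "budding"))
  p <- file.path(td, "sheet.csv")
  export_review_sheet(rec, p)
  sheet <- read_review_sheet(p)
  expect_equal(nrow(sheet), 4)

  # no edits: records unchanged (up to the provenance column)
  out <- apply_corrections(rec, sheet)
  expect_equal(out[, names(rec)], rec)

  # one correction: exactly that record changes, provenance retained
  sheet$corrected_class[sheet$organoid_id == 1] <- "budding"
  out <- apply_corrections(rec, sheet)
  expect_equal(out$class_label[out$organoid_id == 1], "budding")
  expect_equal(out$review_status[out$organoid_id == 1], "corrected")
  expect_equal(out$precorrection_class[out$organoid_id == 1], "spheroid")
  expect_equal(out$class_label[out$organoid_id != 1], rec$class_label[rec$organoid_id != 1])

  # idempotence for a fixed sheet
  expect_equal(apply_corrections(out, sheet), out)

  # reject flag excludes from downstream summaries
  sheet$reject[sheet$organoid_id == 2] <- TRUE
  out2 <- apply_corrections(rec, sheet)
  expect_equal(out2$review_status[out2$organoid_id == 2], "rejected")
  smry <- summarize_treatment(out2)
  expect_equal(smry$n_organoids, 3)

  # errors: unknown id, invalid class
  bad <- sheet; bad$organoid_id[1] <- 99
  expect_error(apply_corrections(rec, bad), "unknown organoid")
  bad <- sheet; bad$corrected_class[bad$organoid_id == 3] <- "weird"
  expect_error(apply_corrections(rec, bad), "invalid corrected_class")
})

test_that("concordance measures agreement with exact marginals", {
  rec <- make_records(4, class_label = c("spheroid", "spheroid", "budding", "budding"))
  expect_equal(concordance(rec, rec)$agreement, 1.0)
  edited <- rec
  edited$class_label[1] <- "budding"
  cc <- concordance(rec, edited)
  expect_equal(cc$agreement, 0.75)
  expect_equal(unname(rowSums(cc$confusion)[c("spheroid", "budding")]), c(2, 2))
  expect_equal(unname(colSums(cc$confusion)[c("spheroid", "budding")]), c(1, 3))
  expect_error(concordance(rec, rec[1:3, ]), "do not match")
})
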