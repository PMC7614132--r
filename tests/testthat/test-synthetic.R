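# Ground-truth scene generator.

test_that("brightfield scenes have the requested composition and ground truth", {
  sc <- fixture_scene(3, 2, seed = 1)
  expect_equal(max(sc$truth$true_mask$labels), 5)
  expect_equal(as.vector(table(sc$truth$true_classes)[c("budding", "spheroid")]),
               c(2L, 3L))
  # connected components of the mask equal the declared object count
  comp <- EBImage::bwlabel(sc$truth$true_mask$labels > 0)
  expect_equal(max(comp), 5)
  # objects darker than background
  bg <- median(sc$image$pixels[sc$truth$true_mask$labels == 0])
  for (id in 1:5)
    expect_lt(mean(sc$image$pixels[sc$truth$true_mask$labels == id]), bg)
})

test_that("identical seed and parameters give bit-identical scenes", {
  a <- generate_brightfield_scene(2, 2, c(256, 256), seed = 42)
  b <- generate_brightfield_scene(2, 2, c(256, 256), seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$true_mask$labels, b$truth$true_mask$labels)
  expect_identical(a$truth$true_classes, b$truth$true_classes)
  c <- generate_brightfield_scene(2, 2, c(256, 256), seed = 43)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("budding objects have visibly lower solidity than spheroids", {
  sol <- lapply(0:9, function(s) {
    sc <- generate_brightfield_scene(2, 2, c(384, 384), seed = s)
    ft <- extract_features(sc$truth$true_mask, sc$image)
    split(ft$solidity, sc$truth$true_classes)
  })
  m_sph <- mean(unlist(lapply(sol, `[[`, "spheroid")))
  m_bud <- mean(unlist(lapply(sol, `[[`, "budding")))
  expect_lt(m_bud, m_sph)
  expect_lt(m_bud, 0.92)
  expect_gt(m_sph, 0.94)
})

test_that("impossible placement requests raise a placement error", {
  expect_error(
    generate_brightfield_scene(20, 20, c(128, 128),
                               scene_params(max_place_attempts = 50L), seed = 1),
    "placement error")
})

test_that("confocal scenes honour fixed spot counts and keep spots on-label", {
  sc <- generate_confocal_scene(1, 1,
                                spots_per_organoid_law = list(fixed = c("1" = 6, "2" = 0)),
                                image_shape = c(384, 384), seed = 5)
  expect_equal(vapply(sc$truth$true_spots, nrow, 0L), c("1" = 6L, "2" = 0L))
  sp <- sc$truth$true_spots[["1"]]
  expect_true(all(sc$truth$true_mask$labels[sp] == 1))
  # pairwise separation respected
  expect_gte(min(dist(sp)), scene_params()$spot_min_separation)
})

test_that("zero marker amplitude leaves the marker channel as pure background", {
  p <- scene_params(spot_amp_frac = c(0, 0))
  sc <- generate_confocal_scene(1, 1, image_shape = c(384, 384),
                                params = modifyList(scene_params(radius_range = c(20, 32)),
                                                    list(spot_amp_frac = c(0, 0))),
                                seed = 2)
  px <- sc$channels$marker$pixels
  rng <- 255
  base <- p$marker_baseline_frac * rng
  expect_lt(abs(mean(px) - base), 1)
  expect_lt(max(px), base + 6 * p$noise_sd_frac * rng)
})

test_that("sampled spot counts recover the configured Poisson means", {
  tot <- c(budding = 0, spheroid = 0); n <- c(budding = 0, spheroid = 0)
  for (s in 0:19) {
    sc <- generate_confocal_scene(3, 3, image_shape = c(640, 640), seed = 500 + s)
    cnt <- vapply(sc$truth$true_spots, nrow, 0L)
    cl <- sc$truth$true_classes
    for (k in c("budding", "spheroid")) {
      tot[k] <- tot[k] + sum(cnt[cl == k]); n[k] <- n[k] + sum(cl == k)
    }
  }
  # sample mean within 2 SE of the law (budding mean truncated at 12:
  # truncation shifts a Poisson(5) mean by < 0.01)
  se_b <- sqrt(5 / n["budding"]); se_s <- sqrt(0.5 / n["spheroid"])
  expect_lt(abs(tot["budding"] / n["budding"] - 5), 2 * se_b)
  expect_lt(abs(tot["spheroid"] / n["spheroid"] - 0.5), 2 * se_s)
})

test_that("degrade_scene darkens selected objects multiplicatively", {
  sc <- fixture_scene(2, 1, seed = 9)
  tm <- sc$truth$true_mask$labels
  m0 <- vapply(1:3, function(id) mean(sc$image$pixels[tm == id]), 0)

  dg <- degrade_scene(sc$image, sc$truth, 0.5, seed = 99, object_ids = 1)
  m1 <- vapply(1:3, function(id) mean(dg$image$pixels[tm == id]), 0)
  expect_lt(abs(m1[1] / m0[1] - 0.5), 0.07)           # darkened to half
  expect_lt(abs(m1[2] / m0[2] - 1), 0.1)              # others unchanged
  expect_equal(unname(dg$truth$true_gray[1]), unname(sc$truth$true_gray[1]) * 0.5)

  # monotonicity: every darkened object's measured gray strictly decreases
  dg_all <- degrade_scene(sc$image, sc$truth, 0.7, seed = 99)
  m2 <- vapply(1:3, function(id) mean(dg_all$image$pixels[tm == id]), 0)
  expect_true(all(m2 < m0))

  # factor 1 leaves the noiseless content unchanged (same gray within noise)
  dg_id <- degrade_scene(sc$image, sc$truth, 1, seed = 99)
  m3 <- vapply(1:3, function(id) mean(dg_id$image$pixels[tm == id]), 0)
  expect_true(all(abs(m3 / m0 - 1) < 0.1))
  expect_error(degrade_scene(sc$image, sc$truth, 0), "darkening_factor")
  expect_error(degrade_scene(sc$image, sc$truth, 1.2), "darkening_factor")
})

test_that("scene ground truth writes as diffable text sidecars", {
  td <- withr::local_tempdir()
  sc <- generate_confocal_scene(1, 1, image_shape = c(384, 384), seed = 3)
  paths <- write_scene_truth(sc$truth, td, "s1")
  expect_true(all(file.exists(paths)))
  j <- jsonlite::read_json(file.path(td, "s1_truth.json"), simplifyVector = TRUE)
  expect_equal(unlist(j$classes), sc$truth$true_classes)
  expect_identical(read_label_mask(file.path(td, "s1_truth_mask.tif"))$labels,
                   sc$truth$true_mask$labels)
})
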