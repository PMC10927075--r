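# analytic annulus object used for the rim/core contrast checks: the band is
# defined by distance-to-boundary, exactly as the feature computes it
make_annulus <- function(radius = 10, band = NULL, rim = 1000, core = 400,
                         shape = c(40L, 40L), bg = 0) {
  ctr <- shape / 2
  d <- sqrt(outer((seq_len(shape[1]) - ctr[1])^2,
                  (seq_len(shape[2]) - ctr[2])^2, "+"))
  mask <- d <= radius
  # render the rim over exactly the boundary band the feature measures
  # (the outermost 1 px ring is excluded from the measurement but rendered
  # as rim so the band is homogeneous)
  if (is.null(band)) band <- 1 + ceiling(0.3 * sqrt(sum(mask) / pi))
  img <- matrix(bg, shape[1], shape[2])
  D <- EBImage::distmap(mask * 1)
  img[mask] <- ifelse(D[mask] <= band, rim, core)
  list(img = img, mask = mask)
}

test_that("connectivity governs whether corner-touching blocks merge", {
  m <- matrix(0, 10, 10); m[2:4, 2:4] <- 1; m[5:7, 5:7] <- 1
  expect_equal(nrow(label_objects(m, connectivity = 8L,
                                  min_object_size = 1L)$table), 1L)
  expect_equal(nrow(label_objects(m, connectivity = 4L,
                                  min_object_size = 1L)$table), 2L)
})

test_that("labelling filters small components and renumbers densely", {
  m <- matrix(0, 20, 20)
  m[2:4, 2:4] <- 1          # 9 px
  m[10:13, 10:14] <- 1      # 20 px
  objs <- label_objects(m, min_object_size = 10L)
  expect_equal(objs$table$id, 1L)
  expect_equal(objs$table$area_px, 20)
  expect_equal(nrow(label_objects(matrix(0, 5, 5))$table), 0L)
})

test_that("the rim/core contrast recovers the constructed annulus ratio", {
  an <- make_annulus()
  objs <- label_objects(an$mask)
  objs <- compute_object_features(an$img, objs, band_fraction = 0.3)
  # r_eq ~ 10 so the 0.3 band is ceiling(3) px: exactly the rendered rim
  expect_equal(objs$table$rim_core_contrast, 2.5, tolerance = 1e-6)
  expect_lt(objs$table$radial_slope, 0)  # darker towards the centre
  # uniform object: contrast 1, slope ~ 0
  un <- make_annulus(rim = 700, core = 700)
  ou <- compute_object_features(un$img, label_objects(un$mask), 0.3)
  expect_equal(ou$table$rim_core_contrast, 1.0, tolerance = 1e-9)
  expect_equal(ou$table$radial_slope, 0, tolerance = 1e-9)
  # filled circle is convex
  expect_gt(ou$table$convexity, 0.9)
  expect_lte(ou$table$convexity, 1.01)
})

test_that("tiny objects degrade gracefully to a flagged whole-object core", {
  m <- matrix(0, 10, 10); m[4:5, 4:6] <- 1
  objs <- label_objects(m, min_object_size = 1L)
  objs <- compute_object_features(matrix(500, 10, 10), objs, 0.3)
  expect_true(objs$table$degenerate_core)
  expect_equal(objs$table$rim_core_contrast, 1.0, tolerance = 1e-9)
  expect_true(all(is.finite(as.matrix(
    objs$table[, c("mean_int", "var_int", "skew_int", "rim_core_contrast",
                   "radial_slope", "convexity")]))))
})

test_that("p8 rendering follows round-half-away-from-zero at the key levels", {
  r255 <- function(p) as.integer(thromboquant:::round_half_up(255 * p))
  expect_identical(r255(c(0, 1)), c(0L, 255L))
  expect_identical(r255(c(0.4706, 0.5882)), c(120L, 150L))
  expect_identical(r255(c(0.16, 0.98)), c(41L, 250L))
})

test_that("object model training separates generator classes and is symmetric", {
  sp <- experiment_scene_params()
  mk <- function(seed) generate_scene(modifyList(sp, list(seed = seed)))
  feat_of <- function(g) {
    objs <- label_objects(gt_mask(g$scene), min_object_size = 5L)
    objs <- compute_object_features(g$image$pixels, objs, 0.3)
    cls <- match_objects_to_truth(objs, g$scene)
    list(objs = objs, cls = cls)
  }
  tr <- feat_of(mk(501)); te <- feat_of(mk(502))
  mod <- train_object_classifier(tr$objs, tr$cls)
  pred <- predict_objects(mod, te$objs)
  acc <- mean((pred$table$p_compacted > 0.5) ==
                (te$cls[as.character(pred$table$id)] == "compacted"))
  expect_gte(acc, 0.95)
  # p -> p8 -> p/255 round trip within 1/510
  expect_true(all(abs(pred$table$p8 / 255 - pred$table$p_compacted)
                  <= 1 / 510 + 1e-12))
  # determinism
  mod2 <- train_object_classifier(tr$objs, tr$cls)
  expect_identical(predict_objects(mod2, te$objs)$table$p_compacted,
                   pred$table$p_compacted)
  # label swap complements probabilities
  sw <- ifelse(tr$cls == "compacted", "non_compacted", "compacted")
  names(sw) <- names(tr$cls)
  mod3 <- train_object_classifier(tr$objs, sw)
  p3 <- predict_objects(mod3, te$objs)$table$p_compacted
  expect_lt(max(abs(pred$table$p_compacted - (1 - p3))), 1e-9)
  # single-class training is rejected
  all_comp <- setNames(rep("compacted", length(tr$cls)), names(tr$cls))
  expect_error(train_object_classifier(tr$objs, all_comp), "both")
  # band-fraction mismatch is rejected
  te_other <- compute_object_features(mk(502)$image$pixels, te$objs, 0.5)
  expect_error(predict_objects(mod, te_other), "mismatch")
})

test_that("probability maps render, round-trip, and threshold strictly", {
  m <- matrix(0, 12, 12); m[2:6, 2:6] <- 1; m[8:11, 8:11] <- 1
  objs <- label_objects(m, min_object_size = 1L)
  objs$table$p_compacted <- c(200, 100) / 255
  objs$table$p8 <- c(200L, 100L)
  map <- render_probability_map(objs)
  expect_equal(sum(map == 200L), 25)
  expect_equal(sum(map == 100L), 16)
  expect_equal(sum(map == 0L), 144 - 41)
  # re-extract per-object values: round trip
  expect_equal(unique(map[objs$labels == 1L]), 200L)
  expect_equal(unique(map[objs$labels == 2L]), 100L)
  # empty set renders all zero
  empty <- label_objects(matrix(0, 5, 5))
  empty$table$p8 <- integer()
  expect_true(all(render_probability_map(empty) == 0L))
})

test_that("compacted selection is strict and monotone in the threshold", {
  m <- matrix(0, 20, 20)
  m[2:4, 2:4] <- 1; m[8:10, 8:10] <- 1; m[14:16, 14:16] <- 1
  objs <- label_objects(m, min_object_size = 1L)
  objs$table$p8 <- c(200L, 100L, 50L)
  expect_equal(nrow(select_compacted(objs, 120L)$table), 1L)
  expect_equal(nrow(select_compacted(objs, 255L)$table), 0L)
  objs$table$p8 <- c(120L, 100L, 50L)
  expect_false(1L %in% select_compacted(objs, 120L)$table$id)  # strict
  expect_equal(nrow(select_compacted(objs, -1L)$table), 3L)
  # monotone nesting over a sweep
  objs$table$p8 <- c(200L, 100L, 50L)
  prev <- select_compacted(objs, 0L)$table$id
  for (T in c(49L, 99L, 150L, 255L)) {
    cur <- select_compacted(objs, T)$table$id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # label raster of dropped objects is zeroed
  sel <- select_compacted(objs, 120L)
  expect_equal(sort(unique(as.vector(sel$labels))), c(0L, 1L))
})
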