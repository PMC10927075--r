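test_that("an empty scene is background plus noise with an all-zero mask", {
  p <- scene_params(n_objects = 0L, image_shape = c(64L, 64L), seed = 7L)
  g <- generate_scene(p)
  expect_true(all(g$scene$label_mask == 0L))
  expect_equal(nrow(g$scene$objects), 0L)
  expect_lt(abs(mean(g$image$pixels) - p$background_level), 5)
})

test_that("a noiseless unblurred compacted object renders the exact three levels", {
  p <- scene_params(noise_sigma = 0, psf_sigma = 0, n_objects = 1L,
                    compacted_fraction = 1, intensity_sdlog = 0,
                    image_shape = c(128L, 128L), seed = 2L)
  g <- generate_scene(p)
  expect_setequal(unique(as.vector(g$image$pixels)), c(100, 400, 1000))
  # mask is exactly the set of pixels whose noiseless intensity exceeds bg
  expect_identical(g$scene$label_mask > 0L, g$image$pixels > 100)
  # rim strictly brighter than core, pixel for pixel
  rim <- g$image$pixels == 1000
  core <- g$image$pixels == 400
  expect_gt(sum(rim), 0); expect_gt(sum(core), 0)
})

test_that("degenerate compacted fractions give single-class scenes", {
  g1 <- generate_scene(scene_params(compacted_fraction = 1,
                                    n_objects = 20L, seed = 3L))
  expect_true(all(g1$scene$objects$class == "compacted"))
  g0 <- generate_scene(scene_params(compacted_fraction = 0,
                                    n_objects = 10L, seed = 3L))
  expect_true(all(g0$scene$objects$class == "non_compacted"))
})

test_that("scene generation is bit-deterministic in (params, seed)", {
  a <- generate_scene(scene_params(seed = 11L, image_shape = c(128L, 128L),
                                   n_objects = 6L))
  b <- generate_scene(scene_params(seed = 11L, image_shape = c(128L, 128L),
                                   n_objects = 6L))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$scene$label_mask, b$scene$label_mask)
  c <- generate_scene(scene_params(seed = 12L, image_shape = c(128L, 128L),
                                   n_objects = 6L))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("labels and rendered footprints are mutually consistent", {
  g <- generate_scene(scene_params(seed = 21L))
  lab <- g$scene$label_mask
  ids <- sort(unique(lab[lab > 0L]))
  expect_identical(ids, g$scene$objects$id)        # every label in objects
  expect_true(all(tabulate(lab[lab > 0L]) >= 1L))  # every object >= 1 px
  # no merging: footprints are pairwise disjoint by construction, so the
  # label raster area equals the sum of per-object areas
  expect_identical(sum(lab > 0L), sum(tabulate(lab[lab > 0L])))
})

test_that("noiseless compacted objects have brighter rims than cores after blur", {
  p <- scene_params(noise_sigma = 0, psf_sigma = 1.5, n_objects = 8L,
                    compacted_fraction = 1, seed = 31L)
  g <- generate_scene(p)
  lab <- g$scene$label_mask
  for (id in g$scene$objects$id) {
    m <- lab == id
    D <- EBImage::distmap(m * 1)
    depth <- D[m]
    r_eq <- sqrt(sum(m) / pi)
    band <- depth <= p$rim_width_fraction * r_eq
    expect_gt(mean(g$image$pixels[m][band]),
              mean(g$image$pixels[m][!band]))
  }
})

test_that("overcrowded scenes fail with a density error", {
  expect_error(
    generate_scene(scene_params(image_shape = c(64L, 64L), n_objects = 60L,
                                size_meanlog = log(8), seed = 4L)),
    "density")
})

test_that("fibrinogen scenes hit the layer coverage and honour zero patches", {
  p <- scene_params(confluent_layer = TRUE, layer_coverage = 0.9,
                    n_layer_patches = 0L, seed = 5L)
  g <- generate_fibrinogen_scene(p)
  expect_equal(sum(g$scene$objects$class == "compacted"), 0L)
  cov <- mean(g$scene$label_mask == 1L)
  expect_lt(abs(cov - 0.9) / 0.9, 0.02)
  # determinism
  g2 <- generate_fibrinogen_scene(p)
  expect_identical(g$image$pixels, g2$image$pixels)
  # with patches: patches are labelled compacted and disjoint from the layer
  p2 <- scene_params(confluent_layer = TRUE, seed = 6L)
  g3 <- generate_fibrinogen_scene(p2)
  expect_equal(sum(g3$scene$objects$class == "compacted"),
               p2$n_layer_patches)
  expect_error(generate_fibrinogen_scene(scene_params()), "confluent")
})

test_that("paired experiments have the right manifest arithmetic and donor pairing", {
  sp <- scale_scene_params(scene_params(), 0.25, n_objects = 6L)
  ex <- paired_experiment(n_donors = 3L, images_per_arm = 2L,
                          base_params = sp, seed = 9L)
  ds <- generate_paired_experiment(ex)
  expect_equal(nrow(ds$manifest), 3L * 2L * 2L)
  expect_setequal(unique(ds$manifest$arm), c("control", "treated"))
  # full-size design: 6 donors x 8 images x 2 arms = 96 rows
  ex6 <- paired_experiment(n_donors = 6L, images_per_arm = 8L,
                           base_params = sp, seed = 9L)
  expect_equal(ex6$n_donors * 2L * ex6$images_per_arm, 96L)
})

test_that("coverage conservation keeps per-donor arm areas within 5%", {
  sp <- scale_scene_params(scene_params(), 0.4, n_objects = 12L)
  for (seed in 1:3) {
    ex <- paired_experiment(n_donors = 3L, images_per_arm = 4L,
                            base_params = sp, treatment_effect = 0.5,
                            coverage_conservation = TRUE, seed = seed)
    ds <- generate_paired_experiment(ex)
    agg <- tapply(ds$manifest$gt_area_px,
                  list(ds$manifest$donor, ds$manifest$arm), sum)
    rel <- abs(agg[, "control"] - agg[, "treated"]) / agg[, "control"]
    expect_true(all(rel < 0.05))
  }
})

test_that("halving the compacted fraction halves the expected compacted count", {
  sp <- scale_scene_params(scene_params(), 0.3, n_objects = 10L)
  counts <- sapply(1:6, function(seed) {
    ex <- paired_experiment(n_donors = 2L, images_per_arm = 4L,
                            base_params = sp, treatment_effect = 0.5,
                            coverage_conservation = FALSE, seed = seed)
    ds <- generate_paired_experiment(ex)
    n_comp <- sapply(ds$scenes, function(s)
      sum(s$objects$class == "compacted"))
    n_tot <- sapply(ds$scenes, function(s) nrow(s$objects))
    c(ctrl = sum(n_comp[ds$manifest$arm == "control"]) /
        sum(n_tot[ds$manifest$arm == "control"]),
      trt = sum(n_comp[ds$manifest$arm == "treated"]) /
        sum(n_tot[ds$manifest$arm == "treated"]))
  })
  # pooled empirical fractions: 0.5 vs 0.25 up to binomial noise
  expect_lt(abs(mean(counts["ctrl", ]) - 0.5), 0.08)
  expect_lt(abs(mean(counts["trt", ]) - 0.25), 0.08)
})

test_that("on-disk datasets round-trip and are byte-reproducible", {
  sp <- scale_scene_params(scene_params(), 0.25, n_objects = 5L)
  ex <- paired_experiment(n_donors = 2L, images_per_arm = 2L,
                          base_params = sp, seed = 17L)
  d1 <- file.path(tempdir(), "pe1"); d2 <- file.path(tempdir(), "pe2")
  r1 <- generate_paired_experiment(ex, out_dir = d1)
  r2 <- generate_paired_experiment(ex, out_dir = d2)
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 8L)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  img <- load_image(man$image_path[1])
  expect_equal(dim(img$pixels), sp$image_shape)
  # identical seeds -> identical bytes
  expect_identical(readBin(man$image_path[1], "raw", 1e6),
                   readBin(file.path(d2, basename(man$image_path[1])),
                           "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
})
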