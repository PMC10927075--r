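# small in-memory scenes + the experiment-scale models from the fixtures
wf_scenes <- function(seeds) {
  sp <- experiment_scene_params()
  lapply(seeds, function(s) generate_scene(modifyList(sp, list(seed = s))))
}

wf_config <- function(n_images, ms = experiment_models(), ...) {
  run_config(
    manifest = data.frame(image_path = rep(NA_character_, n_images)),
    pixel_model = ms$pixel_model, object_model = ms$object_model,
    ball_radius = 0, object_thresholds = c(120L, 150L),
    min_object_size = 5L, pixel_size = experiment_scene_params()$pixel_size,
    ...)
}

test_that("an empty manifest yields an empty report without error", {
  rep0 <- run_pipeline(wf_config(0L), images = list())
  expect_equal(nrow(rep0$summaries), 0L)
  expect_equal(nrow(rep0$errors), 0L)
})

test_that("summary rows are images x modes and deterministic across runs", {
  gs <- wf_scenes(c(600, 601))
  imgs <- lapply(gs, `[[`, "image")
  d1 <- file.path(tempdir(), "wf1"); d2 <- file.path(tempdir(), "wf2")
  r1 <- run_pipeline(wf_config(2L, out_dir = d1), images = imgs)
  expect_equal(nrow(r1$summaries), 2L * 3L)
  expect_setequal(unique(r1$summaries$mode), c("all", "T120", "T150"))
  # every image appears exactly once per mode
  expect_true(all(table(r1$summaries$image, r1$summaries$mode) == 1L))
  r2 <- run_pipeline(wf_config(2L, out_dir = d2), images = imgs)
  expect_identical(readLines(file.path(d1, "summaries.csv")),
                   readLines(file.path(d2, "summaries.csv")))
  expect_identical(readLines(file.path(d1, "objects.csv")),
                   readLines(file.path(d2, "objects.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("compacted modes are subsets of the all-objects mode", {
  gs <- wf_scenes(610)
  r <- run_pipeline(wf_config(1L), images = list(gs[[1]]$image))
  s <- r$summaries
  cov_all <- s$coverage_px[s$mode == "all"]
  expect_gte(cov_all, s$coverage_px[s$mode == "T120"])
  expect_gte(s$coverage_px[s$mode == "T120"],
             s$coverage_px[s$mode == "T150"])
  expect_gte(s$n_objects[s$mode == "all"], s$n_objects[s$mode == "T120"])
})

test_that("swapping the object model touches only object-stage outputs", {
  gs <- wf_scenes(620)
  imgs <- list(gs[[1]]$image)
  ms <- experiment_models()
  r1 <- run_pipeline(wf_config(1L), images = imgs)
  # retrain the object stage only, different seed
  tr <- wf_scenes(c(630, 631))
  ms2 <- train_two_stage(lapply(tr, `[[`, "image"),
                         lapply(tr, `[[`, "scene"),
                         pixel_cfg = experiment_pixel_config(),
                         object_cfg = object_config(seed = 99L),
                         n_scribbles = 150L, ball_radius = 0,
                         min_object_size = 5L)
  cfg2 <- wf_config(1L)
  cfg2$object_model <- ms2$object_model
  r2 <- run_pipeline(cfg2, images = imgs)
  s1 <- r1$summaries; s2 <- r2$summaries
  # the all-objects quantification is untouched by the object-model swap
  expect_equal(s1[s1$mode == "all", -(1:2)], s2[s2$mode == "all", -(1:2)])
  expect_equal(r1$objects$area_px, r2$objects$area_px)
})

test_that("per-image failures are surfaced; majority failure aborts", {
  gs <- wf_scenes(640)
  imgs <- list(gs[[1]]$image, "not an image", gs[[1]]$image)
  r <- run_pipeline(wf_config(3L), images = imgs)
  expect_equal(nrow(r$errors), 1L)
  expect_equal(r$errors$image, 2L)
  expect_equal(sort(unique(r$summaries$image)), c(1L, 3L))
  expect_error(
    run_pipeline(wf_config(2L),
                 images = list("bad", "also bad")),
    "failed on 2 of 2")
})

test_that("run configs round-trip through YAML with model paths", {
  ms <- experiment_models()
  td <- file.path(tempdir(), "cfg")
  dir.create(td, showWarnings = FALSE)
  pm_path <- file.path(td, "pixel.rds")
  om_path <- file.path(td, "object.rds")
  save_model(ms$pixel_model, pm_path)
  save_model(ms$object_model, om_path)
  man_path <- file.path(td, "manifest.csv")
  write.csv(data.frame(image_path = character()), man_path,
            row.names = FALSE)
  yml <- file.path(td, "run.yml")
  yaml::write_yaml(list(manifest = man_path, pixel_model = pm_path,
                        object_model = om_path, ball_radius = 20,
                        min_object_size = 5), yml)
  cfg <- read_run_config(yml)
  expect_s3_class(cfg$pixel_model, "pixel_model")
  expect_s3_class(cfg$object_model, "object_model")
  expect_equal(cfg$ball_radius, 20)
  rep0 <- run_pipeline(cfg)
  expect_equal(nrow(rep0$summaries), 0L)
  # invalid configs are refused
  yaml::write_yaml(list(manifest = man_path), file.path(td, "bad.yml"))
  expect_error(read_run_config(file.path(td, "bad.yml")), "missing")
  unlink(td, recursive = TRUE)
})

test_that("the fibrinogen experiment separates compacted from carpet coverage", {
  ms <- experiment_models()
  sp <- modifyList(experiment_scene_params(),
                   list(confluent_layer = TRUE, n_layer_patches = 3L))
  res <- experiment_fibrinogen(ms$pixel_model, ms$object_model,
                               params = sp, n_rep = 3L,
                               ball_radius = 0, min_object_size = 5L,
                               seed = 700L)
  expect_equal(dim(res$coverage), c(3L, 3L))
  expect_equal(nrow(res$anova$tukey), 3L)       # k(k-1)/2 pairs
  expect_true(all(res$coverage[, "all"] >= res$coverage[, "T120"]))
  expect_true(all(res$compacted_over_all < 1))
})

test_that("a zero-patch carpet yields near-zero compacted coverage", {
  ms <- experiment_models()
  sp <- modifyList(experiment_scene_params(),
                   list(confluent_layer = TRUE, n_layer_patches = 0L))
  g <- generate_fibrinogen_scene(modifyList(sp, list(seed = 711L)))
  st <- apply_two_stage(ms$pixel_model, ms$object_model, g$image,
                        ball_radius = 0, min_object_size = 5L)
  rec <- morphometry_records(st$objects)
  keep <- st$objects$table$id[st$objects$table$p8 > 120L]
  cov_comp <- sum(rec$area_px[rec$id %in% keep])
  cov_all <- sum(rec$area_px)
  expect_gt(cov_all, 0.5 * prod(dim(g$image$pixels)))  # carpet segmented
  expect_lt(cov_comp, 0.05 * cov_all)                  # nothing compacted
})

test_that("the treatment experiment emits the 3x3 comparison table", {
  ms <- experiment_models()
  ex <- paired_experiment(n_donors = 3L, images_per_arm = 2L,
                          base_params = experiment_scene_params(),
                          treatment_effect = 0.5, seed = 5L)
  res <- experiment_treatment(ms$pixel_model, ms$object_model, exp = ex,
                              ball_radius = 0, min_object_size = 5L)
  expect_equal(nrow(res$tests), 9L)
  expect_setequal(unique(res$tests$metric),
                  c("coverage", "median_area", "median_feret"))
  expect_setequal(unique(res$tests$mode), c("all", "T120", "T150"))
  expect_true(all(res$tests$n_donors == 3L))
  # compacted coverage falls under treatment by design
  cov120 <- res$tests[res$tests$metric == "coverage" &
                        res$tests$mode == "T120", ]
  expect_lt(cov120$mean_treated, cov120$mean_control)
})
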