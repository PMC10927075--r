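# Shared, lazily built fixtures. Training the two-stage model is the
# expensive part of the suite, so it is done once per scale and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr),
                                              envir = .fixtures)
  get(key, envir = .fixtures)
}

# --- full-scale fixtures (512x512 default scenes) --------------------------

default_train_scenes <- function(n = 10L) memo("train_full", {
  lapply(seq_len(n), function(i) generate_scene(scene_params(seed = 1000 + i)))
})

default_holdout_scenes <- function(n = 10L) memo("holdout_full", {
  lapply(seq_len(n), function(i) generate_scene(scene_params(seed = 2000 + i)))
})

default_models <- function() memo("models_full", {
  tr <- default_train_scenes()
  train_two_stage(lapply(tr, `[[`, "image"), lapply(tr, `[[`, "scene"))
})

# --- experiment-scale fixtures (coarser sampling, reduced filter bank) -----

experiment_scene_params <- function() {
  scale_scene_params(scene_params(), 0.4, n_objects = 12L)
}

experiment_pixel_config <- function() {
  pixel_config(families = c("gaussian", "gradient", "log", "hessian"))
}

experiment_models <- function() memo("models_small", {
  sp <- experiment_scene_params()
  tr <- lapply(1:8, function(i)
    generate_scene(modifyList(sp, list(seed = 3000 + i))))
  # flat synthetic background: the rolling-ball stage is exercised at the
  # default scale and skipped here (radius 0) for speed
  train_two_stage(lapply(tr, `[[`, "image"), lapply(tr, `[[`, "scene"),
                  pixel_cfg = experiment_pixel_config(),
                  n_scribbles = 150L, ball_radius = 0,
                  min_object_size = 5L)
})

experiment_paired_design <- function(seed = 1L, treatment_effect = 0.5) {
  paired_experiment(
    n_donors = 6L, images_per_arm = 8L,
    base_params = experiment_scene_params(),
    treatment_effect = treatment_effect,
    coverage_conservation = TRUE, seed = seed)
}

run_experiment_seed <- function(seed) {
  ms <- experiment_models()
  experiment_treatment(ms$pixel_model, ms$object_model,
                       exp = experiment_paired_design(seed = seed),
                       ball_radius = 0, min_object_size = 5L)
}
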