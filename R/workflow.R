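#' Run configuration for the end-to-end workflow
#'
#' A single structured object (readable from YAML via
#' \code{\link{read_run_config}}) holding everything a headless run needs.
#' Quantification modes are "all" (every segmented structure) plus one
#' compacted mode per entry of \code{object_thresholds}.
#'
#' @param manifest path to a manifest CSV (columns \code{image_path},
#'   optionally \code{mask_path}, \code{donor}, \code{arm}) or a data.frame.
#' @param pixel_model,object_model trained models or paths to models saved
#'   with \code{\link{save_model}}.
#' @param ball_radius rolling-ball radius in px (0 skips background
#'   subtraction).
#' @param pixel_threshold foreground probability cut in (0, 1).
#' @param object_thresholds integer 8-bit thresholds for the compacted modes.
#' @param min_object_size,connectivity object labelling parameters.
#' @param pixel_size um/px used for physical units.
#' @param out_dir optional directory for the CSV outputs.
#' @param seed master seed recorded in the report.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(manifest, pixel_model, object_model,
                       ball_radius = 50, pixel_threshold = 0.5,
                       object_thresholds = c(120L, 150L),
                       min_object_size = 20L, connectivity = 8L,
                       pixel_size = 0.65, out_dir = NULL, seed = 1L) {
  if (any(object_thresholds < 0 | object_thresholds > 255))
    stop("object thresholds must lie in [0, 255]")
  structure(list(
    manifest = manifest, pixel_model = pixel_model,
    object_model = object_model, ball_radius = ball_radius,
    pixel_threshold = pixel_threshold,
    object_thresholds = as.integer(object_thresholds),
    min_object_size = as.integer(min_object_size),
    connectivity = as.integer(connectivity),
    pixel_size = pixel_size, out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Model paths in the file are loaded into model objects; referenced paths
#' must exist at run start.
#'
#' @param path YAML file with fields as in \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  for (f in c("manifest", "pixel_model", "object_model"))
    if (is.null(y[[f]])) stop("config field missing: ", f)
  for (f in c("manifest", "pixel_model", "object_model"))
    if (is.character(y[[f]]) && !file.exists(y[[f]]))
      stop("configured path does not exist: ", y[[f]])
  y$pixel_model <- load_model(y$pixel_model)
  y$object_model <- load_model(y$object_model)
  do.call(run_config, y)
}

#' Apply the trained two-stage model to one image
#'
#' Preprocess (rolling ball), pixel probability, foreground threshold,
#' object labelling, object features, compacted probability.
#'
#' @param pixel_model,object_model trained models.
#' @param img a \code{fluor_image} or matrix.
#' @param ball_radius,pixel_threshold,min_object_size,connectivity as in
#'   \code{\link{run_config}}.
#' @return list: \code{objects} (an \code{object_set} with \code{p8}),
#'   \code{foreground} (logical mask), \code{prob_map} (pixel
#'   probabilities), \code{map8} (8-bit object-probability map).
#' @export
apply_two_stage <- function(pixel_model, object_model, img,
                            ball_radius = 50, pixel_threshold = 0.5,
                            min_object_size = 20L, connectivity = 8L) {
  work <- if (ball_radius > 0) subtract_background(img, ball_radius) else img
  p <- predict_pixel_probability(pixel_model, work)
  fg <- threshold_foreground(p, pixel_threshold)
  objs <- label_objects(fg, connectivity = connectivity,
                        min_object_size = min_object_size)
  objs <- compute_object_features(work, objs,
                                  band_fraction = object_model$band_fraction)
  objs <- predict_objects(object_model, objs)
  list(objects = objs, foreground = fg, prob_map = p,
       map8 = render_probability_map(objs))
}

#' Train both stages on annotated scenes
#'
#' Convenience trainer mirroring the interactive workflow: pixel scribbles
#' are sampled from the ground truth of each training scene, the pixel model
#' is fitted, its own segmentations are labelled against ground truth by
#' majority overlap, and the object model is fitted on those objects.
#'
#' @param images list of \code{fluor_image}s.
#' @param scenes matching list of \code{gt_scene}s.
#' @param pixel_cfg,object_cfg stage configurations.
#' @param n_scribbles scribble pixels per class per image.
#' @param ball_radius preprocessing radius applied before both stages.
#' @param pixel_threshold,min_object_size,connectivity segmentation
#'   parameters used when building the object training set.
#' @return list with \code{pixel_model} and \code{object_model}.
#' @export
train_two_stage <- function(images, scenes,
                            pixel_cfg = pixel_config(),
                            object_cfg = object_config(),
                            n_scribbles = 200L, ball_radius = 50,
                            pixel_threshold = 0.5, min_object_size = 20L,
                            connectivity = 8L) {
  stopifnot(length(images) == length(scenes), length(images) >= 1L)
  work <- lapply(images, function(im)
    if (ball_radius > 0) subtract_background(im, ball_radius) else im)
  scribbles <- lapply(seq_along(scenes), function(i)
    sample_scribbles(scenes[[i]], n_per_class = n_scribbles,
                     seed = pixel_cfg$seed + i))
  pm <- train_pixel_classifier(work, scribbles, pixel_cfg)
  feats <- list(); labels <- list()
  for (i in seq_along(work)) {
    p <- predict_pixel_probability(pm, work[[i]])
    objs <- label_objects(threshold_foreground(p, pixel_threshold),
                          connectivity = connectivity,
                          min_object_size = min_object_size)
    objs <- compute_object_features(work[[i]], objs,
                                    band_fraction = object_cfg$band_fraction)
    gt <- match_objects_to_truth(objs, scenes[[i]])
    tb <- objs$table
    tb$class_gt <- gt[as.character(tb$id)]
    feats[[i]] <- tb
  }
  all_tb <- do.call(rbind, feats)
  all_tb$id <- seq_len(nrow(all_tb))
  om <- train_object_classifier(
    all_tb, setNames(all_tb$class_gt, all_tb$id), object_cfg)
  om$band_fraction <- object_cfg$band_fraction
  list(pixel_model = pm, object_model = om)
}

#' Run the full quantification workflow over a manifest
#'
#' For every image: preprocessing, pixel classification, object
#' classification, thresholding, particle morphometry, and per-image
#' summaries in every quantification mode ("all" plus "T<threshold>" for
#' each configured compacted threshold). Per-image failures are recorded and
#' surfaced; the run aborts only if more than half the images fail. The run
#' is deterministic given the configuration.
#'
#' @param config a \code{\link{run_config}}.
#' @param images optional list of in-memory images matching the manifest
#'   rows (bypasses \code{image_path} loading).
#' @return list of class \code{run_report}: \code{summaries} (one row per
#'   image x mode), \code{objects} (per-object table), \code{errors},
#'   \code{config_hash}, \code{modes}.
#' @export
run_pipeline <- function(config, images = NULL) {
  stopifnot(inherits(config, "run_config"))
  man <- config$manifest
  if (is.character(man)) man <- read.csv(man, stringsAsFactors = FALSE)
  pm <- if (is.character(config$pixel_model))
    load_model(config$pixel_model) else config$pixel_model
  om <- if (is.character(config$object_model))
    load_model(config$object_model) else config$object_model
  modes <- c("all", paste0("T", config$object_thresholds))
  n <- nrow(man)
  sum_rows <- list(); obj_rows <- list(); err_rows <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- if (!is.null(images)) images[[i]] else
        load_image(man$image_path[i], pixel_size = config$pixel_size)
      st <- apply_two_stage(pm, om, img,
                            ball_radius = config$ball_radius,
                            pixel_threshold = config$pixel_threshold,
                            min_object_size = config$min_object_size,
                            connectivity = config$connectivity)
      rec_all <- morphometry_records(st$objects,
                                     pixel_size = config$pixel_size)
      field_px <- prod(dim(st$objects$labels))
      out_i <- list()
      for (m in seq_along(modes)) {
        if (modes[m] == "all") {
          rec <- rec_all
        } else {
          keep <- st$objects$table$id[
            st$objects$table$p8 > config$object_thresholds[m - 1L]]
          rec <- rec_all[rec_all$id %in% keep, , drop = FALSE]
        }
        s <- summarize_image(rec, field_px, pixel_size = config$pixel_size)
        out_i[[m]] <- cbind(data.frame(image = i, mode = modes[m]), s)
      }
      ot <- st$objects$table
      ot <- cbind(data.frame(image = rep(i, nrow(ot))), ot)
      list(summaries = do.call(rbind, out_i), objects = ot)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err_rows[[length(err_rows) + 1L]] <-
        data.frame(image = i, message = conditionMessage(res))
    } else {
      sum_rows[[i]] <- res$summaries
      obj_rows[[i]] <- res$objects
    }
  }
  n_err <- length(err_rows)
  if (n > 0L && n_err > n / 2)
    stop("pipeline failed on ", n_err, " of ", n, " images; first error: ",
         err_rows[[1L]]$message)
  summaries <- if (length(sum_rows)) do.call(rbind, sum_rows) else
    data.frame()
  objects <- if (length(obj_rows)) do.call(rbind, obj_rows) else
    data.frame()
  errors <- if (n_err) do.call(rbind, err_rows) else
    data.frame(image = integer(), message = character())
  cfg_hash <- rlang::hash(list(
    ball_radius = config$ball_radius,
    pixel_threshold = config$pixel_threshold,
    object_thresholds = config$object_thresholds,
    min_object_size = config$min_object_size,
    connectivity = config$connectivity, pixel_size = config$pixel_size,
    seed = config$seed))
  report <- structure(list(summaries = summaries, objects = objects,
                           errors = errors, config_hash = cfg_hash,
                           modes = modes),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
              row.names = FALSE)
    write.csv(objects, file.path(config$out_dir, "objects.csv"),
              row.names = FALSE)
    if (n_err) write.csv(errors, file.path(config$out_dir, "errors.csv"),
                         row.names = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d summary rows (%s), %d objects, %d errors\n",
              nrow(x$summaries), paste(x$modes, collapse = "/"),
              nrow(x$objects), nrow(x$errors)))
  invisible(x)
}

#' Save / load a trained model
#'
#' Models are written as a single RDS file embedding the feature
#' configuration and seed, so a saved model file can be swapped into a
#' workflow without retraining the other stage.
#'
#' @param model a \code{pixel_model} or \code{object_model}.
#' @param path destination file.
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pixel_model") ||
              inherits(model, "object_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  m <- readRDS(path)
  if (!inherits(m, "pixel_model") && !inherits(m, "object_model"))
    stop("not a thromboquant model file: ", path)
  m
}
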