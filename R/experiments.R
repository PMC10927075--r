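#' Fibrinogen-specificity experiment on synthetic scenes
#'
#' Generates \code{n_rep} confluent-layer scenes (thin platelet carpet plus a
#' few dense compacted patches), quantifies each with the two-stage model in
#' the "all structures" mode and in the compacted mode at each threshold,
#' and compares the coverage areas across the three segmentation modes with
#' a repeated-measures ANOVA and Tukey post-hoc tests (scenes are the
#' matched subjects). On such scenes the compacted modes should recover only
#' the dense patches, a small fraction of the carpet-dominated total.
#'
#' @param pixel_model,object_model trained models.
#' @param params a \code{\link{scene_params}} with \code{confluent_layer =
#'   TRUE}.
#' @param n_rep replicate scenes (>= 2; the design analogue uses 5).
#' @param thresholds compacted-mode 8-bit thresholds.
#' @param ball_radius,pixel_threshold,min_object_size preprocessing /
#'   segmentation parameters.
#' @param seed base seed; replicate i uses \code{seed + i}.
#' @return list: \code{coverage} (matrix, replicate x mode, in um^2),
#'   \code{anova} (\code{rm_anova_result}),
#'   \code{compacted_over_all} (mean coverage ratio of each compacted mode
#'   to the all mode).
#' @export
experiment_fibrinogen <- function(pixel_model, object_model,
                                  params = scene_params(
                                    confluent_layer = TRUE),
                                  n_rep = 5L,
                                  thresholds = c(120L, 150L),
                                  ball_radius = 50, pixel_threshold = 0.5,
                                  min_object_size = 20L, seed = 100L) {
  stopifnot(n_rep >= 2L)
  modes <- c("all", paste0("T", thresholds))
  cov <- matrix(NA_real_, n_rep, length(modes),
                dimnames = list(NULL, modes))
  for (r in seq_len(n_rep)) {
    p <- params; p$seed <- as.integer(seed + r)
    gen <- generate_fibrinogen_scene(p)
    st <- apply_two_stage(pixel_model, object_model, gen$image,
                          ball_radius = ball_radius,
                          pixel_threshold = pixel_threshold,
                          min_object_size = min_object_size)
    rec <- morphometry_records(st$objects, pixel_size = p$pixel_size)
    cov[r, "all"] <- sum(rec$area_um2)
    for (T in thresholds) {
      keep <- st$objects$table$id[st$objects$table$p8 > T]
      cov[r, paste0("T", T)] <-
        sum(rec$area_um2[rec$id %in% keep])
    }
  }
  ratios <- colMeans(cov[, -1L, drop = FALSE] / cov[, "all"])
  list(coverage = cov, anova = rm_anova_tukey(cov),
       compacted_over_all = ratios)
}

# Donor-level aggregation: per donor x arm x mode, the mean over that arm's
# images of a per-image metric.
aggregate_donor_values <- function(summaries, manifest, metric) {
  key <- paste(manifest$donor[summaries$image],
               manifest$arm[summaries$image], summaries$mode)
  vals <- tapply(summaries[[metric]], key, mean, na.rm = TRUE)
  vals
}

#' Paired control/treated comparison of quantification strategies
#'
#' Generates (or reuses) a paired synthetic experiment, quantifies every
#' image in the "all" mode and in the compacted mode at each threshold, and
#' runs a two-tailed paired t-test per metric (coverage area, median object
#' area, median Feret diameter) and mode, on donor-level values (each
#' donor's value is the mean of its per-image values in that arm).
#'
#' @param pixel_model,object_model trained models.
#' @param exp a \code{\link{paired_experiment}}.
#' @param dataset optional pre-generated output of
#'   \code{\link{generate_paired_experiment}} (in-memory form).
#' @param thresholds compacted-mode thresholds.
#' @param ball_radius,pixel_threshold,min_object_size pipeline parameters.
#' @return list: \code{tests} (data.frame metric x mode with t, df, p,
#'   donor-arm means), \code{donor_values} (long data.frame),
#'   \code{report} (the underlying \code{run_report}).
#' @export
experiment_treatment <- function(pixel_model, object_model,
                                 exp = paired_experiment(),
                                 dataset = NULL,
                                 thresholds = c(120L, 150L),
                                 ball_radius = 50, pixel_threshold = 0.5,
                                 min_object_size = 20L) {
  if (is.null(dataset)) dataset <- generate_paired_experiment(exp)
  if (is.null(dataset$images))
    stop("experiment_treatment needs the in-memory dataset form")
  cfg <- run_config(
    manifest = dataset$manifest, pixel_model = pixel_model,
    object_model = object_model, ball_radius = ball_radius,
    pixel_threshold = pixel_threshold, object_thresholds = thresholds,
    min_object_size = min_object_size,
    pixel_size = exp$base_params$pixel_size, seed = exp$seed)
  report <- run_pipeline(cfg, images = dataset$images)
  man <- dataset$manifest
  metrics <- c(coverage = "coverage_um2", median_area = "median_area_um2",
               median_feret = "median_feret_um")
  modes <- c("all", paste0("T", thresholds))
  sm <- report$summaries
  rows <- list(); dv_rows <- list()
  for (mi in seq_along(metrics)) {
    for (mo in modes) {
      sub <- sm[sm$mode == mo, ]
      donor <- man$donor[sub$image]; arm <- man$arm[sub$image]
      agg <- tapply(sub[[metrics[mi]]], list(donor, arm), mean,
                    na.rm = TRUE)
      ctrl <- agg[, "control"]; trt <- agg[, "treated"]
      ok <- is.finite(ctrl) & is.finite(trt)
      tt <- if (sum(ok) >= 2L) paired_t_test(ctrl[ok], trt[ok]) else
        list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = names(metrics)[mi], mode = mo,
        n_donors = sum(ok), statistic = tt$statistic, df = tt$df,
        p_value = tt$p_value,
        mean_control = mean(ctrl[ok]), mean_treated = mean(trt[ok]))
      dv_rows[[length(dv_rows) + 1L]] <- data.frame(
        metric = names(metrics)[mi], mode = mo,
        donor = as.integer(rownames(agg)),
        control = ctrl, treated = trt, row.names = NULL)
    }
  }
  list(tests = do.call(rbind, rows),
       donor_values = do.call(rbind, dv_rows),
       report = report)
}
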