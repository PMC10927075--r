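#' Design of a paired control/treated flow-chamber experiment
#'
#' Emulates the paired design of an antiplatelet-drug study: each donor's
#' blood sample is split, one half is treated, and at least eight fields are
#' imaged per arm. Treatment multiplies the compacted fraction and the
#' compacted object area by \code{treatment_effect} (an
#' \eqn{\alpha_{IIb}\beta_3} antagonist yields fewer, flatter thrombi), while
#' \code{coverage_conservation} forces the total platelet-covered area of the
#' two arms to agree per donor: the treated arm draws objects against the
#' same per-donor footprint budget as the control arm.
#'
#' Donor-to-donor variability enters as log-normal multiplicative offsets on
#' the object count and the size distribution, shared by both arms of a
#' donor.
#'
#' @param n_donors number of donors (>= 2).
#' @param images_per_arm fields imaged per donor and arm (>= 1).
#' @param base_params \code{\link{scene_params}} of a control-arm field.
#' @param treatment_effect multiplier on compacted fraction and compacted
#'   area; 1 = null treatment.
#' @param coverage_conservation logical; keep per-donor total object area
#'   matched between arms (within a few percent).
#' @param donor_sdlog sdlog of the donor-level offsets.
#' @param seed master seed; per-image seeds are drawn once from it and
#'   recorded in the manifest so any single image can be regenerated alone.
#' @return An object of class \code{paired_experiment}.
#' @export
paired_experiment <- function(n_donors = 6L,
                              images_per_arm = 8L,
                              base_params = scene_params(),
                              treatment_effect = 0.5,
                              coverage_conservation = TRUE,
                              donor_sdlog = 0.15,
                              seed = 1L) {
  if (n_donors < 2L) stop("need at least 2 donors")
  if (images_per_arm < 1L) stop("need at least 1 image per arm")
  if (treatment_effect <= 0) stop("treatment_effect must be positive")
  structure(list(
    n_donors = as.integer(n_donors),
    images_per_arm = as.integer(images_per_arm),
    base_params = base_params,
    treatment_effect = treatment_effect,
    coverage_conservation = isTRUE(coverage_conservation),
    donor_sdlog = donor_sdlog,
    seed = as.integer(seed)
  ), class = "paired_experiment")
}

# Expected footprint area (px^2) of one object drawn from `params` with the
# given compacted fraction/multiplier (lognormal moment, clamp ignored).
expected_object_area <- function(params, fraction = params$compacted_fraction,
                                 mult = params$size_multiplier_compacted) {
  er2 <- exp(2 * params$size_meanlog + 2 * params$size_sdlog^2)
  pi * er2 * (fraction * mult^2 + (1 - fraction))
}

# Draw object geometries for one image of one arm. Under coverage
# conservation, objects are accepted while the analytic footprint total stays
# below the budget; the first object is always kept (its radius clamped to
# the budget if needed).
draw_arm_objects <- function(params, budget = NULL, max_factor = 6L) {
  geoms <- list()
  cum <- 0
  n_cap <- max(1L, params$n_objects * max_factor)
  repeat {
    cl <- if (runif(1L) < params$compacted_fraction) "compacted" else
      "non_compacted"
    g <- sample_object_geometry(params, cl)
    a <- pi * g$r_eq^2
    if (is.null(budget)) {
      geoms[[length(geoms) + 1L]] <- g
      if (length(geoms) >= params$n_objects) break
    } else {
      if (cum + a > budget) {
        # top up: shrink this draw to consume the remaining budget exactly
        rem <- budget - cum
        if (rem >= pi * params$r_min^2 || length(geoms) == 0L) {
          g$r_eq <- max(params$r_min, sqrt(rem / pi))
          geoms[[length(geoms) + 1L]] <- g
        }
        break
      }
      geoms[[length(geoms) + 1L]] <- g
      cum <- cum + a
      if (length(geoms) >= n_cap) break
    }
  }
  geoms
}

#' Generate a paired control/treated dataset
#'
#' Renders every field of the experiment. With \code{out_dir} set, images and
#' ground-truth label masks are written as uncompressed 16-bit TIFFs and a
#' \code{manifest.csv} (image_path, mask_path, donor, arm, image, seed,
#' params_hash) is produced; otherwise everything is returned in memory.
#'
#' @param exp a \code{\link{paired_experiment}}.
#' @param out_dir optional output directory (created if missing).
#' @return list with \code{manifest} (data.frame), and — when generating in
#'   memory — \code{images} and \code{scenes} lists indexed as the manifest
#'   rows.
#' @export
generate_paired_experiment <- function(exp, out_dir = NULL) {
  stopifnot(inherits(exp, "paired_experiment"))
  base <- exp$base_params
  n_img <- exp$n_donors * 2L * exp$images_per_arm
  phash <- substr(rlang::hash(unclass(exp)), 1L, 12L)

  plan <- withr::with_seed(exp$seed, {
    list(
      m_n = rlnorm(exp$n_donors, 0, exp$donor_sdlog),
      m_s = rlnorm(exp$n_donors, 0, exp$donor_sdlog),
      jitter = matrix(runif(exp$n_donors * 2L, 0.985, 1.015),
                      exp$n_donors, 2L),
      img_seeds = sample.int(.Machine$integer.max - 1L, n_img)
    )
  })

  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)

  rows <- vector("list", n_img)
  images <- if (!write_out) vector("list", n_img)
  scenes <- if (!write_out) vector("list", n_img)
  k <- 0L
  for (d in seq_len(exp$n_donors)) {
    donor_par <- modifyList(unclass(base), list(
      n_objects = max(1L, as.integer(round(base$n_objects * plan$m_n[d]))),
      size_meanlog = base$size_meanlog + log(plan$m_s[d])
    ))
    budget_img <- donor_par$n_objects *
      expected_object_area(donor_par, fraction = base$compacted_fraction,
                           mult = base$size_multiplier_compacted)
    for (arm_i in 1:2) {
      arm <- c("control", "treated")[arm_i]
      arm_par <- donor_par
      if (arm == "treated") {
        arm_par$compacted_fraction <-
          base$compacted_fraction * exp$treatment_effect
        arm_par$size_multiplier_compacted <-
          base$size_multiplier_compacted * sqrt(exp$treatment_effect)
      }
      arm_par <- structure(arm_par, class = "scene_params")
      for (im in seq_len(exp$images_per_arm)) {
        k <- k + 1L
        sd_k <- plan$img_seeds[k]
        out <- withr::with_seed(sd_k, {
          geoms <- draw_arm_objects(
            arm_par,
            budget = if (exp$coverage_conservation)
              budget_img * plan$jitter[d, arm_i] else NULL)
          generate_scene_impl(arm_par, geoms = geoms)
        })
        row <- data.frame(
          donor = d, arm = arm, image = im, seed = sd_k,
          params_hash = phash,
          gt_area_px = sum(out$scene$label_mask > 0L),
          image_path = NA_character_, mask_path = NA_character_,
          stringsAsFactors = FALSE
        )
        if (write_out) {
          stem <- sprintf("d%02d_%s_%02d", d, arm, im)
          ip <- file.path(out_dir, paste0(stem, ".tif"))
          mp <- file.path(out_dir, paste0(stem, "_mask.tif"))
          save_image(out$image, ip)
          tiff::writeTIFF(out$scene$label_mask / 65535, mp,
                          bits.per.sample = 16L, compression = "none")
          row$image_path <- ip; row$mask_path <- mp
        } else {
          images[[k]] <- out$image
          scenes[[k]] <- out$scene
        }
        rows[[k]] <- row
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (write_out) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    list(manifest = manifest)
  } else {
    list(manifest = manifest, images = images, scenes = scenes)
  }
}
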