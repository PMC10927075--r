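#' Parameters of a synthetic flow-chamber scene
#'
#' Describes one simulated wide-field fluorescence image of platelet
#' aggregates. Two morphological classes are rendered: \emph{compacted}
#' thrombi as annuli with a bright rim and a darker core (limited antibody
#' penetration into the dense interior), and \emph{non-compacted} aggregates
#' stained quasi-uniformly. Boundary staining is class-independent
#' (\code{uniform_intensity} defaults to \code{rim_intensity}); the class
#' signal is the darkness of the interior. Objects are ellipses (axis ratio
#' at most 2:1) with low-order radial harmonics so that nothing in the
#' pipeline can key on perfect circularity. A confluent-layer mode emulates
#' platelets adhering to fibrinogen: a thin near-confluent carpet plus a few
#' dense compacted patches.
#'
#' @param image_shape integer (rows, cols) of the field, default 512 x 512.
#' @param pixel_size physical pixel size, um/px.
#' @param n_objects number of aggregates to place.
#' @param compacted_fraction probability that an object is compacted.
#' @param size_meanlog,size_sdlog log-normal parameters of the equivalent
#'   radius in px.
#' @param size_multiplier_compacted multiplicative factor on the equivalent
#'   radius of compacted objects (compacted thrombi are larger on average).
#' @param rim_intensity,core_intensity,uniform_intensity AFU of the compacted
#'   rim, compacted core and non-compacted interior. Requires
#'   \code{rim_intensity > core_intensity}.
#' @param rim_width_fraction rim thickness as a fraction of the local radius.
#' @param intensity_sdlog sdlog of a per-object log-normal staining
#'   multiplier (clamped to [0.5, 2]) applied to the object's intensities;
#'   emulates heterogeneous antibody staining so absolute brightness does not
#'   identify the class.
#' @param background_level,noise_sigma background AFU and additive Gaussian
#'   read-noise sigma.
#' @param psf_sigma Gaussian blur sigma (px) emulating wide-field optics.
#' @param confluent_layer logical; render the fibrinogen-style carpet.
#' @param layer_intensity,layer_coverage AFU and target area fraction of the
#'   carpet.
#' @param n_layer_patches,patch_meanlog number and size (log-normal meanlog of
#'   radius, px) of dense compacted patches embedded in the carpet.
#' @param r_min,r_max clamp on sampled equivalent radii (px).
#' @param seed integer master seed; identical parameters and seed give
#'   bit-identical output.
#' @return An object of class \code{scene_params}.
#' @export
scene_params <- function(image_shape = c(512L, 512L),
                         pixel_size = 0.65,
                         n_objects = 30L,
                         compacted_fraction = 0.5,
                         size_meanlog = log(10),
                         size_sdlog = 0.35,
                         size_multiplier_compacted = 1.6,
                         rim_intensity = 1000,
                         core_intensity = 400,
                         uniform_intensity = 1000,
                         rim_width_fraction = 0.25,
                         intensity_sdlog = 0.25,
                         background_level = 100,
                         noise_sigma = 50,
                         psf_sigma = 1.5,
                         confluent_layer = FALSE,
                         layer_intensity = 450,
                         layer_coverage = 0.9,
                         n_layer_patches = 6L,
                         patch_meanlog = log(8),
                         r_min = 4,
                         r_max = 40,
                         seed = 1L) {
  p <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_objects = as.integer(n_objects),
    compacted_fraction = compacted_fraction,
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    size_multiplier_compacted = size_multiplier_compacted,
    rim_intensity = rim_intensity, core_intensity = core_intensity,
    uniform_intensity = uniform_intensity,
    rim_width_fraction = rim_width_fraction,
    intensity_sdlog = intensity_sdlog,
    background_level = background_level, noise_sigma = noise_sigma,
    psf_sigma = psf_sigma,
    confluent_layer = confluent_layer,
    layer_intensity = layer_intensity, layer_coverage = layer_coverage,
    n_layer_patches = as.integer(n_layer_patches),
    patch_meanlog = patch_meanlog,
    r_min = r_min, r_max = r_max,
    seed = as.integer(seed)
  )
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  stopifnot(length(p$image_shape) == 2L, all(p$image_shape >= 16L))
  if (p$compacted_fraction < 0 || p$compacted_fraction > 1)
    stop("compacted_fraction must lie in [0, 1]")
  ints <- c(p$rim_intensity, p$core_intensity, p$uniform_intensity,
            p$background_level, p$layer_intensity)
  if (any(ints < 0)) stop("all intensities must be >= 0")
  if (p$rim_intensity <= p$core_intensity)
    stop("rim_intensity must exceed core_intensity (dark-centre phenotype)")
  if (p$noise_sigma < 0 || p$psf_sigma < 0)
    stop("noise_sigma and psf_sigma must be >= 0")
  if (p$rim_width_fraction <= 0 || p$rim_width_fraction >= 1)
    stop("rim_width_fraction must lie in (0, 1)")
  if (p$intensity_sdlog < 0) stop("intensity_sdlog must be >= 0")
  if (p$r_min < 1 || p$r_max <= p$r_min)
    stop("need 1 <= r_min < r_max")
  invisible(p)
}

#' Rescale the geometry of a scene to a coarser or finer pixel grid
#'
#' Multiplies every pixel-dimensioned parameter (image shape, radii, PSF) by
#' \code{factor} and divides the physical pixel size accordingly, i.e. the
#' same optical scene sampled at a different magnification. Used to run the
#' paired-experiment replications at desk scale.
#'
#' @param params a \code{\link{scene_params}}.
#' @param factor geometric scale factor (0.4 halves-ish the linear size).
#' @param n_objects optionally override the object count of the scaled scene.
#' @param min_radius lower clamp on the scaled \code{r_min}.
#' @return A rescaled \code{scene_params}.
#' @export
scale_scene_params <- function(params, factor, n_objects = NULL,
                               min_radius = 2) {
  p <- unclass(params)
  p$image_shape <- as.integer(round(p$image_shape * factor))
  p$pixel_size <- p$pixel_size / factor
  p$size_meanlog <- p$size_meanlog + log(factor)
  p$patch_meanlog <- p$patch_meanlog + log(factor)
  p$psf_sigma <- p$psf_sigma * factor
  p$r_min <- max(min_radius, p$r_min * factor)
  p$r_max <- max(p$r_min + 1, p$r_max * factor)
  if (!is.null(n_objects)) p$n_objects <- as.integer(n_objects)
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

# ---- object geometry ------------------------------------------------------

# Draw the geometry of one aggregate. Consumes the caller's RNG stream.
sample_object_geometry <- function(params, class,
                                   meanlog = params$size_meanlog,
                                   size_mult_compacted =
                                     params$size_multiplier_compacted) {
  r <- rlnorm(1L, meanlog, params$size_sdlog)
  if (class == "compacted") r <- r * size_mult_compacted
  r <- min(max(r, params$r_min), params$r_max)
  q <- exp(runif(1L, 0, log(2)))          # axis ratio <= 2:1
  list(
    class = class, r_eq = r, axis_ratio = q,
    theta0 = runif(1L, 0, pi),
    amps = runif(3L, 0, 0.06),            # radial harmonics k = 2..4
    phases = runif(3L, 0, 2 * pi),
    int_mult = min(max(rlnorm(1L, 0, params$intensity_sdlog), 0.5), 2)
  )
}

object_max_radius <- function(g) {
  g$r_eq * sqrt(g$axis_ratio) * (1 + sum(g$amps))
}

# Boundary radius of the perturbed ellipse in image-frame direction phi.
object_boundary_radius <- function(g, phi) {
  a <- g$r_eq * sqrt(g$axis_ratio)
  b <- g$r_eq / sqrt(g$axis_ratio)
  ph <- phi - g$theta0
  re <- a * b / sqrt((b * cos(ph))^2 + (a * sin(ph))^2)
  harm <- 1 + g$amps[1L] * cos(2 * phi + g$phases[1L]) +
    g$amps[2L] * cos(3 * phi + g$phases[2L]) +
    g$amps[3L] * cos(4 * phi + g$phases[3L])
  re * harm
}

# Rejection-sample non-overlapping centres for a list of geometries. If an
# object cannot be placed after max_tries candidates, its radius is shrunk
# (never below r_min) and placement is retried; a genuinely overcrowded
# scene still fails with a density error after the bounded shrink rounds.
place_objects <- function(geoms, shape, max_tries = 300L, r_min = 2,
                          shrink_rounds = 5L) {
  n <- length(geoms)
  centres <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (round in 0:shrink_rounds) {
      ri <- object_max_radius(geoms[[i]])
      lo <- ri + 2; hi_r <- shape[1L] - ri - 1; hi_c <- shape[2L] - ri - 1
      if (hi_r > lo && hi_c > lo) {
        for (k in seq_len(max_tries)) {
          cand <- c(runif(1L, lo, hi_r), runif(1L, lo, hi_c))
          ok <- if (i == 1L) TRUE else {
            prev <- seq_len(i - 1L)
            rprev <- vapply(geoms[prev], object_max_radius, numeric(1L))
            d <- sqrt((centres[prev, 1L] - cand[1L])^2 +
                        (centres[prev, 2L] - cand[2L])^2)
            all(d >= rprev + ri + 2)
          }
          if (ok) { centres[i, ] <- cand; placed <- TRUE; break }
        }
      }
      if (placed) break
      if (geoms[[i]]$r_eq <= r_min) break
      geoms[[i]]$r_eq <- max(r_min, geoms[[i]]$r_eq * 0.8)
    }
    if (!placed)
      stop("failed to place object ", i, " of ", n, " after ", max_tries,
           " tries per size: object density too high for the field")
  }
  list(geoms = geoms, centres = centres)
}

# Paint one object onto canvas/label (modified in place via return).
render_object <- function(canvas, label, g, centre, id, params) {
  rmax <- object_max_radius(g)
  nr <- nrow(canvas); nc <- ncol(canvas)
  i0 <- max(1L, floor(centre[1L] - rmax - 1)); i1 <- min(nr, ceiling(centre[1L] + rmax + 1))
  j0 <- max(1L, floor(centre[2L] - rmax - 1)); j1 <- min(nc, ceiling(centre[2L] + rmax + 1))
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - centre[1L], length(ii), length(jj))
  dx <- matrix(jj - centre[2L], length(ii), length(jj), byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  rb <- matrix(object_boundary_radius(g, as.vector(phi)), length(ii))
  inside <- rho <= rb
  im <- if (is.null(g$int_mult)) 1 else g$int_mult
  if (!any(inside)) { # guarantee a footprint of at least one pixel
    ci <- min(max(round(centre[1L]), 1L), nr)
    cj <- min(max(round(centre[2L]), 1L), nc)
    canvas[ci, cj] <- im * if (g$class == "compacted")
      params$core_intensity else params$uniform_intensity
    label[ci, cj] <- id
    return(list(canvas = canvas, label = label))
  }
  if (g$class == "compacted") {
    u <- rho / rb
    val <- im * ifelse(u >= 1 - params$rim_width_fraction,
                       params$rim_intensity, params$core_intensity)
  } else {
    val <- matrix(im * params$uniform_intensity, nrow(rho), ncol(rho))
  }
  sub_c <- canvas[ii, jj]; sub_l <- label[ii, jj]
  sub_c[inside] <- val[inside]
  sub_l[inside] <- id
  canvas[ii, jj] <- sub_c; label[ii, jj] <- sub_l
  list(canvas = canvas, label = label)
}

# Blur + read noise + quantisation. Consumes RNG when noise_sigma > 0.
finalize_scene_image <- function(canvas, params) {
  out <- gauss_blur(canvas, params$psf_sigma)
  if (params$noise_sigma > 0)
    out <- out + rnorm(length(out), 0, params$noise_sigma)
  out <- round(pmin(pmax(out, 0), 65535))
  fluor_image(out, pixel_size = params$pixel_size, history = "synthetic")
}

new_gt_scene <- function(objects, label_mask) {
  class_of <- setNames(as.character(objects$class), objects$id)
  structure(list(objects = objects, label_mask = label_mask,
                 class_of = class_of),
            class = "gt_scene")
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("<gt_scene> %d objects (%s)\n", nrow(x$objects),
              paste(names(table(x$objects$class)),
                    table(x$objects$class), sep = ":", collapse = ", ")))
  invisible(x)
}

geoms_to_df <- function(geoms, centres) {
  n <- length(geoms)
  data.frame(
    id = seq_len(n),
    class = vapply(geoms, `[[`, character(1L), "class"),
    row = centres[, 1L], col = centres[, 2L],
    r_eq = vapply(geoms, `[[`, numeric(1L), "r_eq"),
    axis_ratio = vapply(geoms, `[[`, numeric(1L), "axis_ratio"),
    stringsAsFactors = FALSE
  )
}

render_geoms <- function(geoms, centres, params) {
  shape <- params$image_shape
  canvas <- matrix(params$background_level, shape[1L], shape[2L])
  label <- matrix(0L, shape[1L], shape[2L])
  for (i in seq_along(geoms)) {
    res <- render_object(canvas, label, geoms[[i]], centres[i, ], i, params)
    canvas <- res$canvas; label <- res$label
  }
  list(canvas = canvas, label = label)
}

#' Generate one synthetic scene with ground truth
#'
#' Renders \code{n_objects} aggregates (compacted with probability
#' \code{compacted_fraction}) on a noisy background, blurs with the PSF and
#' adds Gaussian read noise. The ground-truth label mask marks the noiseless
#' object footprints (a pixel belongs to an object iff its pre-blur intensity
#' exceeds the background there).
#'
#' @param params a \code{\link{scene_params}}.
#' @return \code{list(image = fluor_image, scene = gt_scene)}.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, {
    out <- generate_scene_impl(params)
  })
  out
}

# Same as generate_scene but consumes the caller's RNG stream (used by the
# paired-experiment generator which manages its own seeds).
generate_scene_impl <- function(params, geoms = NULL) {
  if (is.null(geoms)) {
    n <- params$n_objects
    cls <- if (n > 0L)
      ifelse(rbinom(n, 1L, params$compacted_fraction) == 1L,
             "compacted", "non_compacted") else character()
    geoms <- lapply(cls, function(cl) sample_object_geometry(params, cl))
  }
  if (length(geoms) == 0L) {
    shape <- params$image_shape
    canvas <- matrix(params$background_level, shape[1L], shape[2L])
    img <- finalize_scene_image(canvas, params)
    scene <- new_gt_scene(geoms_to_df(list(), matrix(numeric(), 0L, 2L)),
                          matrix(0L, shape[1L], shape[2L]))
    return(list(image = img, scene = scene))
  }
  pl <- place_objects(geoms, params$image_shape, r_min = params$r_min)
  geoms <- pl$geoms; centres <- pl$centres
  res <- render_geoms(geoms, centres, params)
  img <- finalize_scene_image(res$canvas, params)
  list(image = img, scene = new_gt_scene(geoms_to_df(geoms, centres),
                                         res$label))
}

#' Generate a fibrinogen-style confluent-layer scene
#'
#' Emulates platelets adhering to a fibrinogen-coated surface: a thin,
#' near-confluent textured carpet covering \code{layer_coverage} of the field
#' (rendered at \code{layer_intensity}) plus \code{n_layer_patches} dense
#' compacted patches, each separated from the carpet by a narrow clearance so
#' they remain distinct structures. Ground-truth classes: the carpet is a
#' single \code{layer} object, the patches are \code{compacted}.
#'
#' @param params a \code{\link{scene_params}} with \code{confluent_layer =
#'   TRUE}.
#' @return \code{list(image = fluor_image, scene = gt_scene)}.
#' @export
generate_fibrinogen_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (!isTRUE(params$confluent_layer))
    stop("confluent_layer mode must be enabled in the scene parameters")
  withr::with_seed(params$seed, {
    shape <- params$image_shape
    field <- gauss_blur(matrix(runif(prod(shape)), shape[1L], shape[2L]), 4)
    thr <- quantile(field, 1 - params$layer_coverage, names = FALSE)
    layer <- field > thr
    npatch <- params$n_layer_patches
    geoms <- lapply(seq_len(npatch), function(i)
      sample_object_geometry(params, "compacted",
                             meanlog = params$patch_meanlog,
                             size_mult_compacted = 1))
    if (npatch > 0L) {
      pl <- place_objects(geoms, shape, r_min = params$r_min)
      geoms <- pl$geoms; centres <- pl$centres
    } else {
      centres <- matrix(numeric(), 0L, 2L)
    }

    canvas <- matrix(params$background_level, shape[1L], shape[2L])
    canvas[layer] <- params$layer_intensity
    label <- matrix(0L, shape[1L], shape[2L])
    label[layer] <- 1L
    # clearance moat around each patch, wide enough that the PSF cannot
    # bridge patch and carpet
    moat_px <- 4 + 2 * params$psf_sigma
    for (i in seq_len(npatch)) {
      moat <- grow_geometry(geoms[[i]], moat_px)
      cleared <- matrix(0L, shape[1L], shape[2L])
      res <- render_object(canvas, cleared, moat, centres[i, ], 1L,
                           modifyList(params, list(
                             uniform_intensity = params$background_level)))
      canvas[res$label == 1L] <- params$background_level
      label[res$label == 1L] <- 0L
    }
    for (i in seq_len(npatch)) {
      res <- render_object(canvas, label, geoms[[i]], centres[i, ],
                           i + 1L, params)
      canvas <- res$canvas; label <- res$label
    }
    img <- finalize_scene_image(canvas, params)
    objects <- rbind(
      data.frame(id = 1L, class = "layer",
                 row = NA_real_, col = NA_real_,
                 r_eq = NA_real_, axis_ratio = NA_real_,
                 stringsAsFactors = FALSE),
      if (npatch > 0L) {
        d <- geoms_to_df(geoms, centres); d$id <- d$id + 1L; d
      }
    )
    out <- list(image = img, scene = new_gt_scene(objects, label))
  })
  out
}

# A copy of geometry g enlarged by `extra` px in every boundary direction
# (crude dilation used for the clearance moat around layer patches).
grow_geometry <- function(g, extra) {
  g2 <- g
  g2$class <- "non_compacted"
  g2$int_mult <- 1
  scale <- 1 + extra / g$r_eq
  g2$r_eq <- g$r_eq * scale
  g2
}

#' Sample sparse training scribbles from ground truth
#'
#' Emulates interactive annotation: foreground scribbles are drawn from
#' object interiors (>= 1.5 px from the object boundary where possible) and
#' background scribbles are stratified, half tight against the object
#' outlines (within 6 px) and half in open background, the way an annotator
#' both outlines structures and marks empty field. Consumes the current RNG
#' stream unless \code{seed} is given.
#'
#' @param scene a \code{gt_scene}.
#' @param n_per_class scribble pixels per class.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{row}, \code{col} (1-based) and
#'   \code{class} ("platelet" / "background").
#' @export
sample_scribbles <- function(scene, n_per_class = 200L, seed = NULL) {
  draw <- function() {
    fg <- scene$label_mask > 0L
    fgd <- EBImage::distmap(fg * 1)
    cand_fg <- which(fgd > 1.5)
    if (length(cand_fg) < n_per_class) cand_fg <- which(fg)
    bgd <- EBImage::distmap((!fg) * 1)
    pick <- function(cand, n) cand[sample.int(length(cand),
                                              min(n, length(cand)))]
    near <- which(bgd >= 1 & bgd <= 6)
    far <- which(bgd > 6)
    if (length(far) == 0L) far <- near
    cand_bg <- c(pick(near, ceiling(n_per_class / 2)),
                 pick(far, n_per_class))
    cand_bg <- cand_bg[seq_len(min(n_per_class, length(cand_bg)))]
    idx <- c(pick(cand_fg, n_per_class), cand_bg)
    cls <- rep(c("platelet", "background"),
               c(min(n_per_class, length(cand_fg)), length(cand_bg)))
    nr <- nrow(scene$label_mask)
    data.frame(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L,
               class = cls, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Ground-truth foreground mask of a scene
#' @param scene a \code{gt_scene}.
#' @return logical matrix, TRUE on object pixels.
#' @export
gt_mask <- function(scene) scene$label_mask > 0L

#' Assign ground-truth classes to segmented objects by majority overlap
#'
#' Each segmented object inherits the class of the ground-truth object its
#' pixels overlap most; the confluent \code{layer} class and pure-background
#' detections map to \code{non_compacted} (they are not compacted thrombi).
#'
#' @param objs an \code{object_set} from \code{\link{label_objects}}.
#' @param scene the \code{gt_scene} the segmentation came from.
#' @return named character vector, object id -> "compacted"/"non_compacted".
#' @export
match_objects_to_truth <- function(objs, scene) {
  stopifnot(inherits(objs, "object_set"))
  lab <- objs$labels
  gt <- scene$label_mask
  stopifnot(all(dim(lab) == dim(gt)))
  out <- setNames(character(nrow(objs$table)), objs$table$id)
  idx_by_id <- split(which(lab > 0L), lab[lab > 0L])
  for (id in objs$table$id) {
    pix <- idx_by_id[[as.character(id)]]
    gtv <- gt[pix]
    gtv <- gtv[gtv > 0L]
    if (length(gtv) == 0L) { out[as.character(id)] <- "non_compacted"; next }
    best <- names(which.max(table(gtv)))
    cls <- scene$class_of[[best]]
    out[as.character(id)] <- if (identical(cls, "compacted"))
      "compacted" else "non_compacted"
  }
  out
}
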