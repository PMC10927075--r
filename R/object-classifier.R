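#' Object-classification configuration
#'
#' @param n_trees trees in the probability random forest.
#' @param band_fraction rim-band thickness as a fraction of the equivalent
#'   radius, used by \code{\link{compute_object_features}}.
#' @param mtry candidate features per split. The feature set is small and
#'   contains a few strong morphology descriptors (rim/core contrast, radial
#'   slope), so a high \code{mtry} lets them win splits over incidental
#'   correlates such as absolute size, which generalise poorly to structures
#'   outside the training size range (e.g. confluent platelet layers).
#' @param seed training seed.
#' @return An object of class \code{object_config}.
#' @export
object_config <- function(n_trees = 100L, band_fraction = 0.3, mtry = 7L,
                          seed = 43L) {
  if (band_fraction <= 0 || band_fraction >= 1)
    stop("band_fraction must lie in (0, 1)")
  structure(list(n_trees = as.integer(n_trees),
                 band_fraction = band_fraction, mtry = as.integer(mtry),
                 seed = as.integer(seed)),
            class = "object_config")
}

# union-find with path compression (label merging for 8-connectivity)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Group foreground pixels into objects
#'
#' Connected-component labelling of a binary foreground mask under 4- or
#' 8-connectivity; components smaller than \code{min_object_size} pixels are
#' discarded and the surviving ids are renumbered densely from 1 (in raster
#' order of first appearance).
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_object_size minimum component area in px.
#' @return An object of class \code{object_set}: \code{labels} (integer
#'   matrix) and \code{table} (data.frame with \code{id}, \code{area_px}).
#' @export
label_objects <- function(mask, connectivity = 8L, min_object_size = 20L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- (as_pixels(mask) > 0) * 1
  lab <- EBImage::bwlabel(m)          # 4-connected components
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab > 0L && connectivity == 8L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # "\" diagonals
    a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]   # "/" diagonals
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      for (r in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[r, 1L])
        rb <- uf_find(parent, pairs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), function(i) uf_find(parent, i),
                      integer(1L))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_size)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    areas <- sizes[keep]
  } else {
    areas <- integer()
  }
  structure(list(
    labels = lab,
    table = data.frame(id = seq_along(areas), area_px = as.numeric(areas))
  ), class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d objects, %d foreground px\n",
              nrow(x$table), sum(x$labels > 0L)))
  invisible(x)
}

object_pixel_index <- function(objs) {
  lab <- objs$labels
  split(which(lab > 0L), lab[lab > 0L])
}

skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# convex hull area over the pixel-corner polygon (shoelace)
convex_hull_area <- function(rows, cols) {
  pts <- pixel_corner_points(rows, cols)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(0)
  x <- hp[, 1L]; y <- hp[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Unique corner vertices (x = col, y = row) of the unit squares occupied by
# the given pixels; the boundary convention used for Feret and convexity.
pixel_corner_points <- function(rows, cols) {
  x <- c(cols - 1L, cols, cols - 1L, cols)
  y <- c(rows - 1L, rows - 1L, rows, rows)
  key <- x * (max(y) + 2) + y
  keep <- !duplicated(key)
  cbind(x = x[keep], y = y[keep])
}

#' Compute morphology-aware features for every object
#'
#' Encodes the visual criteria of the compacted phenotype directly: the
#' rim/core contrast (mean intensity of the boundary band over mean intensity
#' of the core, the band being pixels within \code{band_fraction} of the
#' equivalent radius from the object boundary), the radial intensity slope
#' (intensity regressed on normalised depth; negative when the interior is
#' darker), plus area, intensity mean/variance/skewness, and convexity
#' (area / convex-hull area). Intensity profiles are measured over the
#' hole-filled footprint, so a structure segmented as a hollow ring is still
#' profiled across its whole area. For objects too small to leave a core
#' after erosion, the core defaults to the whole-object mean and the
#' \code{degenerate_core} flag is set.
#'
#' @param img the intensity image the objects were segmented from.
#' @param objs an \code{object_set}.
#' @param band_fraction rim-band thickness as a fraction of the equivalent
#'   radius.
#' @return The \code{object_set} with feature columns added to its table.
#' @export
compute_object_features <- function(img, objs, band_fraction = 0.3) {
  stopifnot(inherits(objs, "object_set"))
  if (band_fraction <= 0 || band_fraction >= 1)
    stop("band_fraction must lie in (0, 1)")
  px <- as_pixels(img)
  lab <- objs$labels
  stopifnot(all(dim(px) == dim(lab)))
  nr <- nrow(lab)
  idx <- object_pixel_index(objs)
  tb <- objs$table
  n <- nrow(tb)
  feat <- data.frame(
    mean_int = numeric(n), var_int = numeric(n), skew_int = numeric(n),
    rim_core_contrast = numeric(n), radial_slope = numeric(n),
    convexity = numeric(n), degenerate_core = logical(n)
  )
  for (k in seq_len(n)) {
    pix <- idx[[as.character(tb$id[k])]]
    rows <- (pix - 1L) %% nr + 1L
    cols <- (pix - 1L) %/% nr + 1L
    r0 <- min(rows); c0 <- min(cols)
    crop <- matrix(0, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
    crop[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1
    # profile over the hole-filled footprint ("include holes" convention):
    # a faint thrombus whose dark core dropped below the pixel threshold is
    # still measured across its entire area
    crop <- EBImage::fillHull(crop)
    w <- which(crop > 0)
    rows <- (w - 1L) %% nrow(crop) + 1L + r0 - 2L
    cols <- (w - 1L) %/% nrow(crop) + 1L + c0 - 2L
    pixf <- (cols - 1L) * nr + rows
    ints <- px[pixf]
    D <- EBImage::distmap(crop)
    depth <- D[w]
    pix <- pixf
    # Band radius from the local thickness: for compact blobs max depth is
    # the equivalent radius, while sprawling shapes (e.g. confluent layers)
    # are much thinner than their equivalent radius suggests. The outermost
    # 1 px ring is excluded from band, core and slope: there the PSF mixes
    # object and background and the measured profile reflects the blur, not
    # the staining.
    margin <- 1
    r_eq <- min(sqrt(length(pix) / pi), max(depth))
    band_r <- margin + ceiling(band_fraction * r_eq)
    in_band <- depth > margin & depth <= band_r
    in_core <- depth > band_r
    degen <- !any(in_core) || !any(in_band)
    if (!any(in_band)) in_band <- depth <= band_r       # paper-thin object
    core_mean <- if (!any(in_core)) mean(ints) else mean(ints[in_core])
    band_mean <- if (!any(in_band)) mean(ints) else mean(ints[in_band])
    interior <- depth > margin
    if (sum(interior) < 4L) interior <- rep(TRUE, length(depth))
    maxd <- max(depth[interior])
    slope <- 0
    if (maxd > 0 && length(unique(depth[interior])) > 1L) {
      nd <- depth[interior] / maxd
      slope <- stats::cov(nd, ints[interior]) / stats::var(nd)
    }
    hull_a <- convex_hull_area(rows, cols)
    feat$mean_int[k] <- mean(ints)
    feat$var_int[k] <- if (length(ints) > 1L) var(ints) else 0
    feat$skew_int[k] <- skewness(ints)
    feat$rim_core_contrast[k] <- band_mean / max(core_mean, 1e-6)
    feat$radial_slope[k] <- slope
    feat$convexity[k] <- if (hull_a > 0) length(pix) / hull_a else 1
    feat$degenerate_core[k] <- degen
  }
  stopifnot(all(vapply(feat[, 1:6], function(x) all(is.finite(x)),
                       logical(1L))))
  objs$table <- cbind(tb[, c("id", "area_px")], feat)
  attr(objs, "band_fraction") <- band_fraction
  objs
}

object_feature_names <- c("area_px", "mean_int", "var_int", "skew_int",
                          "rim_core_contrast", "radial_slope", "convexity")

#' Train the stage-two compacted-thrombus classifier
#'
#' Probability random forest mapping object features to the probability of
#' the compacted class; reproducible for a fixed seed.
#'
#' @param objs an \code{object_set} with features, or a data.frame of
#'   feature rows (one per object, including \code{id}).
#' @param labels named vector or data.frame (\code{id}, \code{class}) with
#'   ground-truth classes "compacted"/"non_compacted" for every object.
#' @param config an \code{\link{object_config}}.
#' @return An object of class \code{object_model}.
#' @export
train_object_classifier <- function(objs, labels, config = object_config()) {
  tb <- if (inherits(objs, "object_set")) objs$table else objs
  if (!all(object_feature_names %in% names(tb)))
    stop("object features missing; run compute_object_features() first")
  if (is.data.frame(labels)) labels <- setNames(labels$class, labels$id)
  cls <- labels[as.character(tb$id)]
  if (any(is.na(cls))) stop("every object id needs a ground-truth label")
  if (length(unique(cls)) < 2L)
    stop("both object classes required in the training set")
  df <- tb[, object_feature_names]
  df$class <- factor(cls, levels = c("non_compacted", "compacted"))
  rf <- ranger::ranger(class ~ ., data = df, probability = TRUE,
                       num.trees = config$n_trees,
                       mtry = min(config$mtry, length(object_feature_names)),
                       seed = config$seed, num.threads = 1L)
  structure(list(rf = rf,
                 feature_names = object_feature_names,
                 band_fraction = if (inherits(objs, "object_set"))
                   attr(objs, "band_fraction") else NA_real_,
                 config = config),
            class = "object_model")
}

#' @export
print.object_model <- function(x, ...) {
  cat(sprintf("<object_model> %d-tree probability forest on %s\n",
              x$config$n_trees, paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Score objects with the compacted-class probability
#'
#' Adds \code{p_compacted} in [0, 1] and its 8-bit rendering \code{p8 =
#' round(255 p)} (half away from zero) to the object table.
#'
#' @param model an \code{object_model}.
#' @param objs an \code{object_set} whose features were computed with the
#'   same band fraction as the training set.
#' @return The \code{object_set} with probability columns set.
#' @export
predict_objects <- function(model, objs) {
  stopifnot(inherits(model, "object_model"))
  tb <- if (inherits(objs, "object_set")) objs$table else objs
  if (!all(model$feature_names %in% names(tb)))
    stop("feature configuration mismatch: missing feature columns")
  bf <- if (inherits(objs, "object_set")) attr(objs, "band_fraction") else NA
  if (!is.na(model$band_fraction) && !is.na(bf) &&
      !isTRUE(all.equal(bf, model$band_fraction)))
    stop("feature configuration mismatch: band_fraction differs from model")
  if (nrow(tb) > 0L) {
    pr <- predict(model$rf, data = tb[, model$feature_names, drop = FALSE],
                  num.threads = 1L)$predictions
    p <- pr[, "compacted"]
  } else p <- numeric()
  tb$p_compacted <- p
  tb$p8 <- as.integer(round_half_up(255 * p))
  if (inherits(objs, "object_set")) { objs$table <- tb; objs } else tb
}

#' Render the 8-bit object-probability map
#'
#' Background is 0; every pixel of an object carries that object's \code{p8}
#' (piecewise-constant map, the substrate for integer thresholding).
#'
#' @param objs an \code{object_set} with \code{p8} set.
#' @param shape optional output dimensions (defaults to the label raster).
#' @return integer matrix with values in 0..255.
#' @export
render_probability_map <- function(objs, shape = NULL) {
  stopifnot(inherits(objs, "object_set"))
  if (!"p8" %in% names(objs$table))
    stop("objects carry no p8; run predict_objects() first")
  lab <- objs$labels
  if (!is.null(shape)) stopifnot(all(dim(lab) == shape))
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (nrow(objs$table) > 0L) {
    lut <- integer(max(lab, 1L))
    lut[objs$table$id] <- objs$table$p8
    sel <- lab > 0L
    out[sel] <- lut[lab[sel]]
  }
  out
}

#' Select objects above an 8-bit probability threshold
#'
#' Keeps objects whose probability is strictly higher than the threshold
#' (\code{p8 > T}); pixels of discarded objects are zeroed in the label
#' raster. At T2 >= T1 the selection at T2 is a subset of that at T1.
#'
#' @param objs an \code{object_set} with \code{p8}.
#' @param T integer threshold in [0, 255]; -1 selects everything.
#' @return A filtered \code{object_set}.
#' @export
select_compacted <- function(objs, T) {
  stopifnot(inherits(objs, "object_set"))
  if (T < -1 || T > 255) stop("threshold must lie in [0, 255]")
  if (!"p8" %in% names(objs$table))
    stop("objects carry no p8; run predict_objects() first")
  keep <- objs$table$p8 > T
  kept_ids <- objs$table$id[keep]
  lab <- objs$labels
  lab[!(lab %in% kept_ids)] <- 0L
  out <- objs
  out$labels <- lab
  out$table <- objs$table[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  out
}
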