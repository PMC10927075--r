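#' Fill internal holes of a single-object mask
#'
#' Background regions that cannot reach the image border without crossing the
#' object are absorbed into it, so hollow segmentations are measured over
#' their entire footprint. Bays open to the border are left untouched.
#' Idempotent; never decreases the area.
#'
#' @param mask logical (or 0/1) matrix containing one object.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- (as_pixels(mask) > 0) * 1
  if (!any(m > 0)) stop("empty object mask")
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0, nr + 2L, nc + 2L)   # border ring = certain outside
  padded[2:(nr + 1L), 2:(nc + 1L)] <- m
  filled <- EBImage::fillHull(padded)
  filled[2:(nr + 1L), 2:(nc + 1L), drop = FALSE] > 0
}

#' Physical area of an object
#'
#' @param mask single-object mask (holes filled per configuration).
#' @param pixel_size um/px.
#' @return list with \code{area_px} and \code{area_um2}.
#' @export
object_area <- function(mask, pixel_size = 0.65) {
  a <- sum(as_pixels(mask) > 0)
  list(area_px = a, area_um2 = a * pixel_size^2)
}

# ---- Feret diameter -------------------------------------------------------

# Convex hull (CCW order) of the pixel-corner polygon of a mask or of a
# coordinate set; columns x (= image col) and y (= image row).
corner_hull <- function(rows, cols) {
  pts <- pixel_corner_points(rows, cols)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n >= 3L) {
    # orient counter-clockwise (positive signed area)
    x <- hp[, 1L]; y <- hp[, 2L]
    s <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
    if (s < 0) hp <- hp[n:1L, , drop = FALSE]
  }
  hp
}

# Rotating-calipers diameter of a convex polygon given in CCW order.
caliper_diameter <- function(hp) {
  n <- nrow(hp)
  d2 <- function(i, j) sum((hp[i, ] - hp[j, ])^2)
  if (n == 1L) return(0)
  if (n == 2L) return(sqrt(d2(1L, 2L)))
  area2 <- function(i, j, k) {
    abs((hp[j, 1L] - hp[i, 1L]) * (hp[k, 2L] - hp[i, 2L]) -
          (hp[k, 1L] - hp[i, 1L]) * (hp[j, 2L] - hp[i, 2L]))
  }
  best <- 0
  j <- 2L
  guard <- 0L
  for (i in seq_len(n)) {
    ni <- i %% n + 1L
    repeat {
      nj <- j %% n + 1L
      if (area2(i, ni, nj) > area2(i, ni, j)) {
        j <- nj
        guard <- guard + 1L
        if (guard > 4L * n) stop("rotating calipers failed to terminate")
      } else break
    }
    best <- max(best, d2(i, j), d2(ni, j))
  }
  sqrt(best)
}

#' Feret diameter of an object
#'
#' The longest distance between any two points of the object boundary, under
#' the pixel-corner convention (each pixel is a unit square; the boundary is
#' the polygon over the square corners, so a single pixel has Feret
#' \eqn{\sqrt 2}). Computed as the rotating-calipers diameter of the convex
#' hull of the corner vertices.
#'
#' @param mask single-object logical mask, or a 2-column matrix of pixel
#'   (row, col) coordinates.
#' @param pixel_size optional um/px; when given, the length is also returned
#'   in micrometres.
#' @return Feret diameter in px (numeric scalar), with attribute
#'   \code{feret_um} when \code{pixel_size} is supplied.
#' @export
feret_diameter <- function(mask, pixel_size = NULL) {
  is_coords <- is.matrix(mask) && !is.logical(mask) && ncol(mask) == 2L &&
    nrow(mask) >= 1L && all(mask == round(mask)) && max(mask) > 1L
  if (is_coords) {
    rows <- mask[, 1L]; cols <- mask[, 2L]
  } else {
    m <- as_pixels(mask) > 0
    if (!any(m)) stop("empty object")
    w <- which(m)
    rows <- (w - 1L) %% nrow(m) + 1L
    cols <- (w - 1L) %/% nrow(m) + 1L
  }
  f <- caliper_diameter(corner_hull(rows, cols))
  if (!is.null(pixel_size)) attr(f, "feret_um") <- f * pixel_size
  f
}

#' Per-object morphometry table
#'
#' Reproduces the particle-analysis stage: for every object, holes are
#' filled, then the area and the Feret diameter are measured, in px and in
#' physical units.
#'
#' @param objs an \code{object_set}.
#' @param pixel_size um/px.
#' @param fill fill holes before measuring (default TRUE).
#' @return data.frame with \code{id}, \code{area_px}, \code{area_um2},
#'   \code{feret_px}, \code{feret_um}.
#' @export
morphometry_records <- function(objs, pixel_size = 0.65, fill = TRUE) {
  stopifnot(inherits(objs, "object_set"))
  lab <- objs$labels
  nr <- nrow(lab)
  idx <- object_pixel_index(objs)
  ids <- objs$table$id
  out <- data.frame(id = ids, area_px = NA_real_, area_um2 = NA_real_,
                    feret_px = NA_real_, feret_um = NA_real_)
  for (k in seq_along(ids)) {
    pix <- idx[[as.character(ids[k])]]
    rows <- (pix - 1L) %% nr + 1L
    cols <- (pix - 1L) %/% nr + 1L
    if (fill) {
      r0 <- min(rows); c0 <- min(cols)
      crop <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
      crop[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
      filled <- fill_holes(crop)
      w <- which(filled)
      rows <- (w - 1L) %% nrow(filled) + 1L + r0 - 1L
      cols <- (w - 1L) %/% nrow(filled) + 1L + c0 - 1L
    }
    a <- length(rows)
    f <- caliper_diameter(corner_hull(rows, cols))
    out$area_px[k] <- a
    out$area_um2[k] <- a * pixel_size^2
    out$feret_px[k] <- f
    out$feret_um[k] <- f * pixel_size
  }
  out
}

median_mid2 <- function(x) {
  # median with the mean-of-middle-two convention for even counts
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

#' Per-image summary of morphometry records
#'
#' Coverage is the summed object area; means and medians (mean-of-middle-two
#' for even counts) summarise the per-object parameters. An empty record set
#' yields zero counts/coverage and NA central tendencies.
#'
#' @param records output of \code{\link{morphometry_records}}.
#' @param field_px total pixel count of the imaged field (for % coverage).
#' @param pixel_size um/px.
#' @return one-row data.frame: \code{n_objects}, \code{coverage_px},
#'   \code{coverage_um2}, \code{coverage_pct}, \code{mean_area_um2},
#'   \code{median_area_um2}, \code{mean_feret_um}, \code{median_feret_um}.
#' @export
summarize_image <- function(records, field_px, pixel_size = 0.65) {
  n <- nrow(records)
  cov_px <- if (n) sum(records$area_px) else 0
  data.frame(
    n_objects = n,
    coverage_px = cov_px,
    coverage_um2 = cov_px * pixel_size^2,
    coverage_pct = 100 * cov_px / field_px,
    mean_area_um2 = if (n) mean(records$area_um2) else NA_real_,
    median_area_um2 = median_mid2(records$area_um2),
    mean_feret_um = if (n) mean(records$feret_um) else NA_real_,
    median_feret_um = median_mid2(records$feret_um)
  )
}
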