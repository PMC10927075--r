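#' Fluorescence image container
#'
#' A single-channel 2-D intensity raster in arbitrary fluorescence units (AFU)
#' together with its pixel size and a short processing history. This is the
#' unit every stage of the pipeline consumes and returns.
#'
#' @param pixels numeric matrix (rows x cols) of non-negative intensities.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param history character vector of processing steps already applied.
#' @return An object of class \code{fluor_image}.
#' @export
fluor_image <- function(pixels, pixel_size = 0.65, history = character()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix (single channel, 2-D)")
  if (any(!is.finite(pixels)))
    stop("`pixels` contains non-finite values")
  if (any(pixels < 0))
    stop("negative intensities are not allowed")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size, history = history),
    class = "fluor_image"
  )
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    min(x$pixels), max(x$pixels)
  ))
  if (length(x$history))
    cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.fluor_image <- function(x) dim(x$pixels)

as_pixels <- function(img) {
  if (inherits(img, "fluor_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a fluor_image or a matrix")
}

#' Read a single-channel 16-bit (or 8-bit) TIFF
#'
#' Loads a grayscale TIFF into a \code{\link{fluor_image}}. Integer sample
#' values are preserved exactly, so \code{save_image} followed by
#' \code{load_image} is the identity on pixels.
#'
#' @param path path to a TIFF file.
#' @param pixel_size physical pixel size in um/px to attach (TIFF resolution
#'   tags are not interpreted).
#' @return A \code{fluor_image}.
#' @export
load_image <- function(path, pixel_size = 0.65) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2L)
    stop("expected single channel, got ", tail(dim(px), 1L),
         " channels in ", path)
  storage.mode(px) <- "double"
  fluor_image(px, pixel_size = pixel_size,
              history = paste0("loaded:", basename(path)))
}

#' Write an image as an uncompressed single-channel 16-bit TIFF
#'
#' Values are clamped to [0, 65535] and rounded; the round trip through
#' \code{\link{load_image}} is lossless for integer-valued images.
#'
#' @param img a \code{fluor_image} or numeric matrix.
#' @param path destination path; the parent directory must exist.
#' @return \code{path}, invisibly.
#' @export
save_image <- function(img, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  px <- round(pmin(pmax(as_pixels(img), 0), 65535))
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
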