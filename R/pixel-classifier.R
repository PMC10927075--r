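#' Pixel-classification configuration
#'
#' The filter bank mirrors the default feature set of interactive
#' pixel-classification tools: per scale, a Gaussian-smoothed intensity,
#' gradient magnitude, Laplacian of Gaussian, the two Hessian eigenvalues and
#' the two structure-tensor eigenvalues, plus the raw intensity. The
#' classifier is a gradient-boosted tree ensemble (about 100 trees), trained
#' on sparse scribbles.
#'
#' @param scales smoothing scales in px (each >= 0.3).
#' @param families feature families to keep, a subset of
#'   \code{c("gaussian","gradient","log","hessian","structure")}.
#' @param n_rounds,max_depth,learning_rate boosting hyperparameters.
#' @param threshold probability cut used by
#'   \code{\link{threshold_foreground}}.
#' @param seed training seed (reproducible models).
#' @return An object of class \code{pixel_config}.
#' @export
pixel_config <- function(scales = c(0.7, 1.0, 1.6, 3.5, 5.0),
                         families = c("gaussian", "gradient", "log",
                                      "hessian", "structure"),
                         n_rounds = 100L, max_depth = 6L,
                         learning_rate = 0.3,
                         threshold = 0.5, seed = 42L) {
  if (length(scales) == 0L) stop("scale list must not be empty")
  if (any(scales < 0.3)) stop("scales must be >= 0.3 px")
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("gaussian", "gradient", "log",
                                    "hessian", "structure"))
  structure(list(scales = scales, families = families,
                 n_rounds = as.integer(n_rounds),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pixel_config")
}

family_width <- c(gaussian = 1L, gradient = 1L, log = 1L,
                  hessian = 2L, structure = 2L)

#' Compute the per-pixel feature stack
#'
#' Deterministic multi-scale filter bank; borders are handled by reflection.
#' The feature count is \code{sum(family widths) * length(scales) + 1} (the
#' raw intensity comes first).
#'
#' @param img a \code{\link{fluor_image}} or matrix.
#' @param config a \code{\link{pixel_config}} (only \code{scales} and
#'   \code{families} are used).
#' @return numeric matrix, one row per pixel (column-major order), with named
#'   columns; attribute \code{shape} holds the image dimensions.
#' @export
compute_pixel_features <- function(img, config = pixel_config()) {
  px <- as_pixels(img)
  fams <- config$families
  n_feat <- 1L + sum(family_width[fams]) * length(config$scales)
  out <- matrix(NA_real_, length(px), n_feat)
  nms <- character(n_feat)
  out[, 1L] <- as.vector(px); nms[1L] <- "raw"
  j <- 1L
  for (s in config$scales) {
    G <- gauss_blur(px, s)
    need_d <- any(fams %in% c("gradient", "log", "hessian", "structure"))
    if (need_d) {
      gx <- deriv_x(G); gy <- deriv_y(G)
    }
    if (any(fams %in% c("log", "hessian"))) {
      gxx <- deriv_xx(G); gyy <- deriv_yy(G); gxy <- deriv_xy(G)
    }
    for (f in fams) {
      if (f == "gaussian") {
        j <- j + 1L; out[, j] <- as.vector(G)
        nms[j] <- sprintf("gauss_s%g", s)
      } else if (f == "gradient") {
        j <- j + 1L; out[, j] <- as.vector(sqrt(gx^2 + gy^2))
        nms[j] <- sprintf("gradmag_s%g", s)
      } else if (f == "log") {
        j <- j + 1L; out[, j] <- as.vector(gxx + gyy)
        nms[j] <- sprintf("log_s%g", s)
      } else if (f == "hessian") {
        ev <- sym_eig2(gxx, gxy, gyy)
        out[, j + 1L] <- as.vector(ev$e1); out[, j + 2L] <- as.vector(ev$e2)
        nms[j + 1L] <- sprintf("hess1_s%g", s)
        nms[j + 2L] <- sprintf("hess2_s%g", s)
        j <- j + 2L
      } else if (f == "structure") {
        jxx <- gauss_blur(gx * gx, s); jyy <- gauss_blur(gy * gy, s)
        jxy <- gauss_blur(gx * gy, s)
        ev <- sym_eig2(jxx, jxy, jyy)
        out[, j + 1L] <- as.vector(ev$e1); out[, j + 2L] <- as.vector(ev$e2)
        nms[j + 1L] <- sprintf("st1_s%g", s)
        nms[j + 2L] <- sprintf("st2_s%g", s)
        j <- j + 2L
      }
    }
  }
  stopifnot(all(is.finite(out)))
  colnames(out) <- nms
  attr(out, "shape") <- dim(px)
  attr(out, "feature_sig") <- feature_signature(config)
  out
}

feature_signature <- function(config) {
  paste(c(config$families, sprintf("%g", config$scales)), collapse = "|")
}

#' Train the stage-one pixel classifier
#'
#' Learns platelet-vs-background pixel probabilities from sparse scribbles.
#' Training is reproducible: the configuration seed fixes the ensemble.
#'
#' @param images list of \code{fluor_image}s (or matrices).
#' @param scribbles list (same length) of data.frames with columns
#'   \code{row}, \code{col}, \code{class}; classes must include both
#'   "platelet" and "background" across the set.
#' @param config a \code{\link{pixel_config}}.
#' @return An object of class \code{pixel_model}.
#' @export
train_pixel_classifier <- function(images, scribbles,
                                   config = pixel_config()) {
  if (!is.list(images) || length(images) == 0L)
    stop("need at least one training image")
  stopifnot(length(images) == length(scribbles))
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    px <- as_pixels(images[[i]])
    sc <- scribbles[[i]]
    stopifnot(all(c("row", "col", "class") %in% names(sc)))
    if (any(sc$row < 1L | sc$row > nrow(px) | sc$col < 1L |
              sc$col > ncol(px)))
      stop("scribble coordinates outside image bounds (image ", i, ")")
    fe <- compute_pixel_features(px, config)
    idx <- (sc$col - 1L) * nrow(px) + sc$row
    xs[[i]] <- fe[idx, , drop = FALSE]
    ys[[i]] <- sc$class
  }
  X <- do.call(rbind, xs)
  y <- unlist(ys)
  if (!all(y %in% c("platelet", "background")))
    stop("scribble classes must be 'platelet' or 'background'")
  if (length(unique(y)) < 2L)
    stop("both pixel classes required in the training scribbles")
  dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y == "platelet"))
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$max_depth,
                  eta = config$learning_rate,
                  nthread = 1L, seed = config$seed),
    data = dtr, nrounds = config$n_rounds
  )
  structure(list(raw = xgboost::xgb.save.raw(bst),
                 config = config, n_train = nrow(X)),
            class = "pixel_model")
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf(
    "<pixel_model> %d boosted trees, %d training pixels, %d features\n",
    x$config$n_rounds, x$n_train,
    1L + sum(family_width[x$config$families]) * length(x$config$scales)))
  invisible(x)
}

#' Predict the per-pixel platelet probability map
#'
#' @param model a \code{pixel_model}.
#' @param img a \code{fluor_image} or matrix.
#' @param features optional precomputed feature stack for \code{img}; must
#'   have been produced with the model's feature configuration.
#' @return numeric matrix of probabilities in [0, 1], same shape as the
#'   image.
#' @export
predict_pixel_probability <- function(model, img, features = NULL) {
  stopifnot(inherits(model, "pixel_model"))
  px <- as_pixels(img)
  if (is.null(features)) {
    features <- compute_pixel_features(px, model$config)
  } else if (!identical(attr(features, "feature_sig"),
                        feature_signature(model$config))) {
    stop("feature configuration mismatch between model and feature stack")
  }
  bst <- xgboost::xgb.load.raw(model$raw)
  p <- predict(bst, xgboost::xgb.DMatrix(features))
  matrix(p, nrow(px), ncol(px))
}

#' Threshold a probability map into a foreground mask
#'
#' Strict inequality: a pixel is foreground iff its probability exceeds
#' \code{t}.
#'
#' @param p probability matrix in [0, 1].
#' @param t threshold in (0, 1).
#' @return logical matrix.
#' @export
threshold_foreground <- function(p, t = 0.5) {
  if (t <= 0 || t >= 1) stop("pixel threshold must lie in (0, 1)")
  p > t
}
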