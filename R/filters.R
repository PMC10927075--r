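# Low-level raster helpers shared by the preprocessing stage, the synthetic
# generator (PSF blur) and the pixel feature stack. All convolutions reflect
# the image at its borders before filtering so no wrap-around artefacts leak
# into the field of view.

reflect_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  if (pad >= nr || pad >= nc)
    stop("pad width exceeds image extent")
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1))
  m[ri, ci]
}

gauss_kernel_1d <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# Gaussian smoothing with reflective borders; sigma in pixels.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k1 <- gauss_kernel_1d(sigma)
  pad <- (length(k1) - 1L) / 2L
  pad <- min(pad, nrow(m) - 1L, ncol(m) - 1L)
  if (pad < (length(k1) - 1L) / 2L) { # small image: shrink kernel
    k1 <- gauss_kernel_1d(sigma, radius = pad)
  }
  if (pad == 0L) return(m)
  mp <- reflect_pad(m, pad)
  out <- EBImage::filter2(mp, outer(k1, k1), boundary = "circular")
  out[(pad + 1L):(pad + nrow(m)), (pad + 1L):(pad + ncol(m))]
}

# Shift a matrix by (dr, dc) with replicated edges (used for finite
# differences; replication keeps gradients zero on flat borders).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci]
}

# Central first derivatives. x = column direction, y = row direction.
deriv_x <- function(m) (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2
deriv_y <- function(m) (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2
deriv_xx <- function(m) shift_mat(m, 0L, 1L) - 2 * m + shift_mat(m, 0L, -1L)
deriv_yy <- function(m) shift_mat(m, 1L, 0L) - 2 * m + shift_mat(m, -1L, 0L)
deriv_xy <- function(m) deriv_y(deriv_x(m))

# Eigenvalues of the symmetric 2x2 field [[a, b], [b, c]]; returns the larger
# eigenvalue first.
sym_eig2 <- function(a, b, c) {
  tr2 <- (a + c) / 2
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  list(e1 = tr2 + disc, e2 = tr2 - disc)
}

# ---- grayscale morphology with a disc ------------------------------------
# Exact min/max filters built from the disc's horizontal chords: a dyadic
# (power-of-two) running minimum gives each chord's 1-D min filter in
# O(log w) vector operations, and the disc erosion is the minimum of the
# row-shifted chord filters. Out-of-image values act as +Inf (erosion) /
# -Inf (dilation), which keeps the opening anti-extensive.

shift_cols_fill <- function(m, d, fill) {
  if (d == 0L) return(m)
  nc <- ncol(m)
  out <- matrix(fill, nrow(m), nc)
  if (abs(d) >= nc) return(out)
  if (d > 0L) out[, 1:(nc - d)] <- m[, (1L + d):nc]
  else out[, (1L - d):nc] <- m[, 1:(nc + d)]
  out
}

shift_rows_fill <- function(m, d, fill) {
  if (d == 0L) return(m)
  nr <- nrow(m)
  out <- matrix(fill, nr, ncol(m))
  if (abs(d) >= nr) return(out)
  if (d > 0L) out[1:(nr - d), ] <- m[(1L + d):nr, ]
  else out[(1L - d):nr, ] <- m[1:(nr + d), ]
  out
}

gray_erode_disc <- function(m, radius) {
  r <- as.integer(radius)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  widths <- vapply(seq_len(nrow(brush)),
                   function(i) sum(brush[i, ] > 0), integer(1L))
  wmax <- max(widths)
  # Inf-pad so border windows see out-of-image values as +Inf
  nr0 <- nrow(m); nc0 <- ncol(m)
  mp <- matrix(Inf, nr0 + 2L * r, nc0 + 2L * r)
  mp[r + (1:nr0), r + (1:nc0)] <- m
  m <- mp
  # left-aligned dyadic running minima along columns
  K <- max(0L, floor(log2(wmax)))
  P <- vector("list", K + 1L)
  P[[1L]] <- m
  j <- 1L
  for (k in seq_len(K)) {
    P[[k + 1L]] <- pmin(P[[k]], shift_cols_fill(P[[k]], j, Inf))
    j <- j * 2L
  }
  # centred horizontal min filter for each distinct chord width
  H <- new.env(parent = emptyenv())
  h_for <- function(w) {
    key <- as.character(w)
    if (!is.null(H[[key]])) return(H[[key]])
    h <- (w - 1L) %/% 2L
    k <- max(0L, floor(log2(w)))
    Pk <- P[[k + 1L]]
    res <- pmin(shift_cols_fill(Pk, -h, Inf),
                shift_cols_fill(Pk, w - 2L^k - h, Inf))
    H[[key]] <- res
    res
  }
  acc <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(brush))) {
    if (widths[i] == 0L) next
    dy <- i - r - 1L
    acc <- pmin(acc, shift_rows_fill(h_for(widths[i]), dy, Inf))
  }
  acc[r + (1:nr0), r + (1:nc0)]
}

gray_dilate_disc <- function(m, radius) -gray_erode_disc(-m, radius)

gray_opening_disc <- function(m, radius) {
  gray_dilate_disc(gray_erode_disc(m, radius), radius)
}
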