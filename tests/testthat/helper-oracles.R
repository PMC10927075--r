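# Independent brute-force oracles used to validate the fast implementations.

# Grayscale erosion/dilation by looping over structuring-element offsets;
# O(pixels x brush) but exact. Used as the rolling-ball oracle.
bf_morph <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  offs <- which(brush > 0, arr.ind = TRUE) - radius - 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- radius
  big <- matrix(if (op == "erode") Inf else -Inf,
                nr + 2L * pad, nc + 2L * pad)
  big[pad + (1:nr), pad + (1:nc)] <- m
  acc <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  f <- if (op == "erode") pmin else pmax
  for (k in seq_len(nrow(offs))) {
    acc <- f(acc, big[pad + (1:nr) + offs[k, 1L], pad + (1:nc) + offs[k, 2L]])
  }
  acc
}

bf_opening <- function(m, radius) {
  er <- bf_morph(m, radius, "erode")
  # dilation of the eroded image; erosion padded with +Inf outside, but the
  # opening must not exceed the original, so clamp the border effect by
  # padding the eroded image with -Inf (handled inside bf_morph dilate)
  bf_morph(er, radius, "dilate")
}

# All-pairs max distance over the pixel-corner vertices of an object mask.
bf_feret <- function(mask) {
  w <- which(mask > 0)
  rows <- (w - 1L) %% nrow(mask) + 1L
  cols <- (w - 1L) %/% nrow(mask) + 1L
  x <- c(cols - 1L, cols, cols - 1L, cols)
  y <- c(rows - 1L, rows - 1L, rows, rows)
  pts <- unique(cbind(x, y))
  d2 <- as.matrix(dist(pts))^2
  sqrt(max(d2))
}

# Border flood fill: the set of background pixels reachable from the image
# border without crossing the object (4-connectivity); oracle for fill_holes.
bf_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  border_idx <- which(col(mask) == 1L | col(mask) == nc |
                        row(mask) == 1L | row(mask) == nr)
  queue <- border_idx[!mask[border_idx]]
  outside[queue] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
        j <- (cc - 1L) * nr + rr
        if (!mask[j] && !outside[j]) { outside[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  !outside
}

# random blob mask for property tests (a few overlapping discs)
random_blob <- function(nr = 30L, nc = 30L, n_discs = 3L) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(n_discs)) {
    r0 <- runif(1, 6, nr - 6); c0 <- runif(1, 6, nc - 6)
    rad <- runif(1, 2, 6)
    m <- m | (outer(seq_len(nr), seq_len(nc),
                    function(i, j) (i - r0)^2 + (j - c0)^2 <= rad^2))
  }
  m
}
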