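# Shared low-level image helpers. All images are plain numeric matrices
# indexed [row, col]; coordinates are 0-based (row, col) pixel positions
# so that tables and images share one convention.

# Integer translation with zero fill: output[r, c] = img[r - dy, c - dx].
# Positive dy moves content down, positive dx moves it right.
shift_image <- function(img, dy, dx) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

# Circular translation (used by simulations and equivariance checks).
roll_image <- function(img, dy, dx) {
  dy <- as.integer(round(dy)) %% nrow(img)
  dx <- as.integer(round(dx)) %% ncol(img)
  if (dy != 0) img <- rbind(img[(nrow(img) - dy + 1L):nrow(img), , drop = FALSE],
                            img[seq_len(nrow(img) - dy), , drop = FALSE])
  if (dx != 0) img <- cbind(img[, (ncol(img) - dx + 1L):ncol(img), drop = FALSE],
                            img[, seq_len(ncol(img) - dx), drop = FALSE])
  img
}

# Block-mean downsample by integer factor f; trailing partial blocks are
# averaged over the pixels they actually contain.
block_downsample <- function(img, f) {
  f <- as.integer(f)
  stopifnot(f >= 1L)
  if (f == 1L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  ri <- (seq_len(nr) - 1L) %/% f + 1L
  ci <- (seq_len(nc) - 1L) %/% f + 1L
  sums <- rowsum(img, ri)                       # sum rows within blocks
  sums <- t(rowsum(t(sums), ci))                # then columns
  cnt <- outer(tabulate(ri), tabulate(ci))
  out <- sums / cnt
  dimnames(out) <- NULL
  out
}

# Minimum filter over a (2k+1)-sided square neighbourhood, neighbourhood
# clipped at image borders (out-of-image cells do not participate).
min_filter <- function(img, side) {
  k <- (as.integer(side) - 1L) %/% 2L
  out <- img
  for (dy in -k:k) {
    for (dx in -k:k) {
      if (dy == 0L && dx == 0L) next
      sh <- shift_image_fill(img, dy, dx, fill = Inf)
      out <- pmin(out, sh)
    }
  }
  out
}

shift_image_fill <- function(img, dy, dx, fill = 0) {
  out <- shift_image(img, dy, dx)
  if (fill != 0) {
    nr <- nrow(img); nc <- ncol(img)
    if (dy > 0) out[seq_len(min(dy, nr)), ] <- fill
    if (dy < 0) out[(nr + dy + 1L):nr, ] <- fill
    if (dx > 0) out[, seq_len(min(dx, nc))] <- fill
    if (dx < 0) out[, (nc + dx + 1L):nc] <- fill
  }
  out
}

# Strict 8-connected local maxima with a deterministic raster-scan
# tie-break: on an equal-valued plateau only the first pixel in scan order
# (column-major, as stored) is kept. Returns a logical matrix.
local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  keep <- matrix(TRUE, nr, nc)
  for (d in list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L),
                 c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
    # nb[r, c] = img[r - dy, c - dx]: the neighbour at offset (-dy, -dx)
    nb <- shift_image_fill(img, d[1L], d[2L], fill = -Inf)
    # a neighbour earlier in column-major scan order must be strictly
    # smaller; later neighbours may be equal (plateau keeps first pixel)
    earlier <- d[2L] > 0L || (d[2L] == 0L && d[1L] > 0L)
    keep <- keep & if (earlier) img > nb else img >= nb
  }
  keep
}

as_matrix_image <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a 2D numeric image matrix", call. = FALSE)
  }
  x
}

check_finite_image <- function(img, what = "image") {
  if (!all(is.finite(img))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(img)
}
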