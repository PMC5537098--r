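# Internal helpers shared across modules.

# Run `code` under a local, seeded RNG without touching the caller's RNG state.
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Population standard deviation (divide by N, not N-1).  All normalisation and
# class statistics in the package use this convention.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Shannon entropy in bits of a vector of counts (zeros ignored).
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Binary dilation of a logical matrix by a disc of radius `r` pixels.
dilate_mask <- function(mask, r) {
  stopifnot(r >= 1)
  b <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, b) > 0.5
}

erode_mask <- function(mask, r) {
  b <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::erode(mask * 1, b) > 0.5
}

# Bounding box of a logical matrix as list(r1, r2, c1, c2).
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(r1 = min(idx[, 1]), r2 = max(idx[, 1]),
       c1 = min(idx[, 2]), c2 = max(idx[, 2]))
}

# Centroid (row, col) of a logical matrix.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Bilinear interpolation of matrix `img` at fractional (row, col) positions.
# Positions outside the grid are clamped to the border.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  v00 <- img[cbind(r0, c0)];     v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]; v11 <- img[cbind(r0 + 1, c0 + 1)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

# Quantize intensities to 1..levels over the range of `x` (equal width).
# A constant vector maps entirely to level 1.
quantize_levels <- function(x, levels) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  q <- floor((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  pmin(as.integer(q), as.integer(levels))
}
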