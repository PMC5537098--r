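# Fixture builders used across test files.  These construct masks and
# images with plain coordinate arithmetic, independent of the package's
# own rendering code.

grid_coords <- function(size) {
  list(r = matrix(seq_len(size), size, size),
       c = matrix(seq_len(size), size, size, byrow = TRUE))
}

disk_mask <- function(size, center, radius) {
  g <- grid_coords(size)
  (g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2
}

rect_mask <- function(size, r1, r2, c1, c2) {
  m <- matrix(FALSE, size, size)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# Constant-intensity disk lesion on a flat background.
disk_image <- function(size = 64, radius = 12, level = 100, bg = 50,
                       center = c(size / 2, size / 2)) {
  m <- disk_mask(size, center, radius)
  px <- matrix(bg, size, size)
  px[m] <- level
  lesion_image(px, m)
}

# Star-shaped (spiky) mask with approximately the same area as a disk.
star_mask <- function(size, center, r_out, r_in, points = 8) {
  g <- grid_coords(size)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  ang <- atan2(dr, dc)
  rad <- r_in + (r_out - r_in) * (cos(points * ang) + 1) / 2
  sqrt(dr^2 + dc^2) <= rad
}

# Direct plug-in mutual information from a joint count table (oracle).
mi_oracle <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  pr <- rowSums(p); pc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        s <- s + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  s
}

# Direct evaluation of the thresholding objective from first principles
# (oracle; recomputes every statistic from the raw pixel classes).
j_oracle <- function(img, lambda, T) {
  crop <- if (is.null(img$crop)) {
    matrix(TRUE, nrow(img$pixels), ncol(img$pixels))
  } else img$crop
  vals <- img$pixels[crop]
  dark <- mean(img$pixels[img$mask]) <= mean(img$pixels[crop & !img$mask])
  lesion <- if (dark) vals[vals <= T] else vals[vals > T]
  backgr <- if (dark) vals[vals > T] else vals[vals <= T]
  if (length(lesion) == 0 || length(backgr) == 0) return(Inf)
  pv <- function(x) mean((x - mean(x))^2)
  sw <- sqrt(length(lesion) / length(vals) * pv(lesion) +
               length(backgr) / length(vals) * pv(backgr))
  (1 - lambda) * sw - lambda * abs(mean(lesion) - mean(backgr))
}
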