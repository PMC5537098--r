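# The five traditional feature blocks.  Each extractor takes a lesion_image
# and returns a named vector whose names match feature_descriptors().

#' Intensity block (6 features)
#'
#' Median and entropy (bits, over integer-rounded values) of the lesion
#' intensities, proportion of lesion pixels above a threshold (by default
#' the image's within-class-variance optimum), and the lesion-vs-ring mean
#' intensity difference at three dilation scales.
#'
#' @param img A [lesion_image()].
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 6.
#' @export
extract_intensity_block <- function(img, cfg = feature_config()) {
  stopifnot(inherits(img, "lesion_image"))
  v <- img$pixels[img$mask]
  if (length(v) == 0L) abort("primary mask is empty.")
  thr <- cfg$proportion_threshold
  if (is.null(thr)) {
    thr <- as.numeric(optimize_threshold(img, as.numeric(select_lambda(img))))
  }
  diffs <- vapply(cfg$intensity_ring_radii, function(r) {
    ring <- dilate_mask(img$mask, r) & !img$mask
    mean(v) - mean(img$pixels[ring])
  }, numeric(1))
  out <- c(median(v), entropy_bits(table(round(v))), mean(v > thr), diffs)
  names(out) <- c("intensity_median", "intensity_entropy",
                  "intensity_prop_thresh",
                  paste0("intensity_diff_r", cfg$intensity_ring_radii))
  out
}

# ---- GLCM -------------------------------------------------------------

glcm_features <- function(img, cfg) {
  lv <- cfg$glcm_levels
  q <- matrix(NA_integer_, nrow(img$pixels), ncol(img$pixels))
  q[img$mask] <- quantize_levels(img$pixels[img$mask], lv)
  offsets <- list(`000` = c(0L, 1L), `045` = c(-1L, 1L),
                  `090` = c(-1L, 0L), `135` = c(-1L, -1L))
  idx <- which(img$mask, arr.ind = TRUE)
  nr <- nrow(q); nc <- ncol(q)
  stats <- purrr::map(offsets, function(off) {
    r2 <- idx[, 1] + off[1]; c2 <- idx[, 2] + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- img$mask[cbind(r2[ok], c2[ok])]
    if (!any(ok)) return(c(contrast = 0, correlation = 0, energy = 1))
    a <- q[idx[ok, , drop = FALSE]]
    b <- q[cbind(r2[ok], c2[ok])]
    # symmetric co-occurrence probabilities
    tab <- table(factor(c(a, b), levels = 1:lv),
                 factor(c(b, a), levels = 1:lv))
    p <- tab / sum(tab)
    i <- row(p); j <- col(p)
    contrast <- sum(p * (i - j)^2)
    energy <- sum(p^2)
    mi <- sum(p * i); mj <- sum(p * j)
    si <- sqrt(sum(p * (i - mi)^2)); sj <- sqrt(sum(p * (j - mj)^2))
    correlation <- if (si > 0 && sj > 0) {
      sum(p * (i - mi) * (j - mj)) / (si * sj)
    } else 0
    c(contrast = contrast, correlation = correlation, energy = energy)
  })
  out <- c(vapply(stats, `[[`, numeric(1), "contrast"),
           vapply(stats, `[[`, numeric(1), "correlation"),
           vapply(stats, `[[`, numeric(1), "energy"))
  names(out) <- paste0("glcm_", rep(c("contrast", "correlation", "energy"),
                                    each = 4),
                       "_", rep(names(offsets), 3))
  out
}

# ---- Gabor ------------------------------------------------------------

gabor_kernel <- function(wavelength, theta, phase) {
  sigma <- 0.56 * wavelength
  hs <- ceiling(2.5 * sigma)
  g <- expand.grid(r = -hs:hs, c = -hs:hs)
  # wave vector along angle theta measured from the column axis
  u <- g$c * cos(theta) + g$r * sin(theta)
  env <- exp(-(g$r^2 + g$c^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * u / wavelength + phase)
  matrix(k - mean(k) * (phase == 0), 2 * hs + 1, 2 * hs + 1)
}

gabor_features <- function(img, cfg) {
  bb <- mask_bbox(img$mask)
  max_hs <- ceiling(2.5 * 0.56 * max(cfg$gabor_wavelengths))
  r1 <- max(1, bb$r1 - max_hs); r2 <- min(nrow(img$pixels), bb$r2 + max_hs)
  c1 <- max(1, bb$c1 - max_hs); c2 <- min(ncol(img$pixels), bb$c2 + max_hs)
  patch <- img$pixels[r1:r2, c1:c2]
  sub_mask <- img$mask[r1:r2, c1:c2]
  thetas <- c(0, 45, 90, 135) * pi / 180
  out <- numeric(0)
  for (w in cfg$gabor_wavelengths) {
    for (th in thetas) {
      even <- EBImage::filter2(patch, gabor_kernel(w, th, 0),
                               boundary = "replicate")
      odd <- EBImage::filter2(patch, gabor_kernel(w, th, pi / 2),
                              boundary = "replicate")
      mag <- sqrt(even^2 + odd^2)[sub_mask]
      out <- c(out, mean(mag), pop_sd(mag))
    }
  }
  names(out) <- paste0("gabor_w", rep(cfg$gabor_wavelengths, each = 8),
                       "_o", rep(rep(c("000", "045", "090", "135"),
                                     each = 2), 4),
                       "_", rep(c("mean", "sd"), 16))
  out
}

# ---- Wavelets ---------------------------------------------------------

# Orthonormal Daubechies-4 (8-tap) scaling filter.
DB4_H <- c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
           -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
           0.03288301166698295, -0.01059740178499728)

# One periodic analysis step along the rows of x: returns list(lo, hi),
# each with nrow(x)/2 rows.
dwt_rows <- function(x, h) {
  n <- nrow(x); L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  k <- seq_len(n / 2)
  lo <- matrix(0, n / 2, ncol(x)); hi <- lo
  for (m in seq_len(L)) {
    src <- ((2 * k - 2 + m - 1) %% n) + 1
    lo <- lo + h[m] * x[src, , drop = FALSE]
    hi <- hi + g[m] * x[src, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# One 2-D separable step: list(ll, lh, hl, hh); lh = detail along rows.
dwt2_step <- function(x, h) {
  rowpass <- dwt_rows(x, h)
  lo <- dwt_rows(t(rowpass$lo), h)
  hi <- dwt_rows(t(rowpass$hi), h)
  list(ll = t(lo$lo), hl = t(lo$hi), lh = t(hi$lo), hh = t(hi$hi))
}

# RMS energy of a subband pooled on a 6 x 6 spatial grid (36 values).
pool_subband <- function(s, grid = 6L) {
  cuts_r <- round(seq(0, nrow(s), length.out = grid + 1))
  cuts_c <- round(seq(0, ncol(s), length.out = grid + 1))
  out <- numeric(grid * grid)
  k <- 1L
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      blk <- s[(cuts_r[i] + 1):cuts_r[i + 1],
               (cuts_c[j] + 1):cuts_c[j + 1], drop = FALSE]
      out[k] <- sqrt(mean(blk^2))
      k <- k + 1L
    }
  }
  out
}

lesion_patch <- function(img, size) {
  bb <- mask_bbox(img$mask)
  patch <- img$pixels[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
  as.matrix(EBImage::resize(patch, w = size, h = size))
}

daube_features <- function(img, cfg) {
  patch <- lesion_patch(img, cfg$wavelet_size)
  out <- numeric(0)
  x <- patch
  for (lev in 1:3) {
    st <- dwt2_step(x, DB4_H)
    out <- c(out, pool_subband(st$lh), pool_subband(st$hl),
             pool_subband(st$hh))
    x <- st$ll
  }
  names(out) <- paste0("daube_l", rep(1:3, each = 108),
                       rep(rep(c("h", "v", "d"), each = 36), 3),
                       "_b", sprintf("%02d", rep(1:36, 9)))
  out
}

haar_feature <- function(img, cfg) {
  patch <- lesion_patch(img, cfg$wavelet_size)
  st <- dwt2_step(patch, c(1, 1) / sqrt(2))
  c(haar_detail_energy = mean(st$lh^2) + mean(st$hl^2) + mean(st$hh^2))
}

# ---- Run-length matrix ------------------------------------------------

# Run-length matrix of the masked lesion along image rows; runs break at
# mask boundaries.  Returns counts indexed [gray level, run length].
run_length_matrix <- function(img, levels) {
  q <- matrix(NA_integer_, nrow(img$pixels), ncol(img$pixels))
  q[img$mask] <- quantize_levels(img$pixels[img$mask], levels)
  runs_lv <- integer(0); runs_ln <- integer(0)
  for (r in seq_len(nrow(q))) {
    row_vals <- q[r, ]
    if (all(is.na(row_vals))) next
    enc <- rle(ifelse(is.na(row_vals), -1L, row_vals))
    keep <- enc$values != -1L
    runs_lv <- c(runs_lv, enc$values[keep])
    runs_ln <- c(runs_ln, enc$lengths[keep])
  }
  max_len <- max(runs_ln)
  tab <- matrix(0, levels, max_len)
  for (i in seq_along(runs_lv)) {
    tab[runs_lv[i], runs_ln[i]] <- tab[runs_lv[i], runs_ln[i]] + 1
  }
  tab
}

rle_features <- function(img, cfg) {
  p <- run_length_matrix(img, cfg$rle_levels)
  n_runs <- sum(p)
  n_px <- sum(img$mask)
  i <- row(p); j <- col(p)
  out <- c(
    sre = sum(p / j^2) / n_runs,
    lre = sum(p * j^2) / n_runs,
    gln = sum(rowSums(p)^2) / n_runs,
    rln = sum(colSums(p)^2) / n_runs,
    rp = n_runs / n_px,
    lgre = sum(p / i^2) / n_runs,
    hgre = sum(p * i^2) / n_runs
  )
  names(out) <- paste0("rle_", names(out))
  out
}

#' Texture block (376 features)
#'
#' Concatenates, in order: 12 co-occurrence statistics (contrast,
#' correlation, energy at 4 offsets), 32 Gabor-bank statistics, 324 pooled
#' Daubechies-4 subband energies of the resampled lesion box, the total
#' 1-level Haar detail energy, and 7 classical run-length statistics.
#'
#' @inheritParams extract_intensity_block
#' @return Named numeric vector of length 376.
#' @export
extract_texture_block <- function(img, cfg = feature_config()) {
  stopifnot(inherits(img, "lesion_image"))
  bb <- mask_bbox(img$mask)
  if ((bb$r2 - bb$r1 + 1) < 8 || (bb$c2 - bb$c1 + 1) < 8) {
    abort("texture block: lesion bounding box must be at least 8 x 8 pixels.")
  }
  c(glcm_features(img, cfg), gabor_features(img, cfg),
    daube_features(img, cfg), haar_feature(img, cfg),
    rle_features(img, cfg))
}

# ---- Shape ------------------------------------------------------------

# Ordered 1-based (row, col) contour of the mask.
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(mask * 1)[[1]]
  oc + 1
}

polygon_perimeter <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((pts - nxt)^2)))
}

#' Shape block (20 features)
#'
#' Compactness (`4 * pi * A / P^2`), moment-ellipse eccentricity, contour
#' roughness (perimeter over convex-hull perimeter), the local area
#' integral invariant averaged over the contour at 15 kernel radii, and the
#' mean and sd of the centroid-to-contour radial distance.
#'
#' @inheritParams extract_intensity_block
#' @return Named numeric vector of length 20.
#' @export
extract_shape_block <- function(img, cfg = feature_config()) {
  stopifnot(inherits(img, "lesion_image"))
  mask <- img$mask
  if (mask_touches_border(mask)) {
    abort("shape block: mask touches the image border.")
  }
  area <- sum(mask)
  contour <- mask_contour(mask)
  perim <- polygon_perimeter(contour)
  compactness <- 4 * pi * area / perim^2
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  u <- sweep(idx, 2, ctr)
  ev <- eigen(crossprod(u) / nrow(u), symmetric = TRUE,
              only.values = TRUE)$values
  eccentricity <- if (ev[1] > 0) sqrt(1 - max(ev[2], 0) / ev[1]) else 0
  hull <- grDevices::chull(contour[, 2], contour[, 1])
  roughness <- perim / polygon_perimeter(contour[hull, , drop = FALSE])
  # local area integral invariant: fraction of a disc inside the mask,
  # averaged over contour pixels, per radius
  max_r <- max(cfg$li_radii)
  pad <- max_r + 1L
  pm <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  pm[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask * 1
  cpad <- cbind(contour[, 1] + pad, contour[, 2] + pad)
  li <- vapply(cfg$li_radii, function(r) {
    b <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    frac <- EBImage::filter2(pm, b / sum(b), boundary = "circular")
    mean(frac[cpad])
  }, numeric(1))
  rad <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  out <- c(compactness, eccentricity, roughness, li, mean(rad), pop_sd(rad))
  names(out) <- c("shape_compactness", "shape_eccentricity",
                  "shape_roughness",
                  paste0("li_r", sprintf("%02d", cfg$li_radii)),
                  "radial_mean", "radial_sd")
  out
}

# ---- Histogram --------------------------------------------------------

# Uniform LBP(P=8, R=1) codes of every mask pixel whose 8 neighbours also
# lie inside the mask, so the pattern statistics describe the lesion's own
# texture rather than its boundary.  Returns the integer codes (0..255).
lbp_codes <- function(img) {
  px <- img$pixels; mask <- img$mask
  idx <- which(mask & erode_mask(mask, 1), arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("histogram block: no interior lesion pixels.")
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  ctr <- px[idx]
  code <- integer(nrow(idx))
  for (b in seq_len(8)) {
    nb <- px[cbind(idx[, 1] + offs[b, 1], idx[, 2] + offs[b, 2])]
    code <- code + as.integer(nb >= ctr) * 2L^(b - 1L)
  }
  code
}

# Circular 0/1 transition count of an 8-bit code.
lbp_transitions <- function(code) {
  bits <- t(sapply(code, function(x) as.integer(intToBits(x)[1:8])))
  rot <- bits[, c(2:8, 1), drop = FALSE]
  rowSums(bits != rot)
}

lbp_features <- function(img) {
  code <- lbp_codes(img)
  ones <- vapply(code, function(x) sum(as.integer(intToBits(x)[1:8])),
                 numeric(1))
  trans <- lbp_transitions(code)
  uniform <- trans <= 2
  props <- vapply(0:8, function(k) mean(uniform & ones == k), numeric(1))
  out <- c(props, mean(!uniform), mean(code), pop_sd(code))
  names(out) <- c(paste0("lbp_u", 0:8), "lbp_nonuniform",
                  "lbp_code_mean", "lbp_code_sd")
  out
}

#' Histogram block (32 features)
#'
#' A 12-value summary of uniform LBP(8,1) codes (proportion of uniform
#' patterns by number of set bits, proportion non-uniform, and code
#' mean/sd) plus 20 equal-width intensity bin counts over the configured
#' HU window (out-of-window pixels clamped into the end bins, so counts
#' always sum to the lesion pixel count).
#'
#' @inheritParams extract_intensity_block
#' @return Named numeric vector of length 32.
#' @export
extract_histogram_block <- function(img, cfg = feature_config()) {
  stopifnot(inherits(img, "lesion_image"))
  v <- img$pixels[img$mask]
  breaks <- seq(cfg$hist_range[1], cfg$hist_range[2], length.out = 21)
  vc <- pmin(pmax(v, breaks[1]), breaks[21])
  bin <- pmin(findInterval(vc, breaks, rightmost.closed = TRUE), 20L)
  counts <- tabulate(bin, nbins = 20L)
  names(counts) <- paste0("histbin_", sprintf("%02d", 1:20))
  c(lbp_features(img), counts)
}

# ---- Edge -------------------------------------------------------------

# Sharpness of a sampled 1-D profile: maximum absolute finite-difference
# slope between consecutive samples.
profile_sharpness <- function(values, step) {
  max(abs(diff(values))) / step
}

# Radius of the mask boundary along direction (dr, dc) from the centroid.
radial_boundary <- function(mask, ctr, dr, dc) {
  t_max <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  ts <- seq(0, t_max, by = 0.25)
  rr <- round(ctr[1] + ts * dr); cc <- round(ctr[2] + ts * dc)
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  inside <- rep(FALSE, length(ts))
  inside[ok] <- mask[cbind(rr[ok], cc[ok])]
  last <- max(which(inside))
  ts[last]
}

#' Edge block (61 features)
#'
#' Samples the image along `edge_n_profiles` radial profiles crossing the
#' lesion contour at equally spaced angles; each profile contributes its
#' maximum finite-difference slope (edge sharpness).  The final value is
#' the entropy of the gradient-magnitude histogram on the one-pixel contour
#' band.
#'
#' @inheritParams extract_intensity_block
#' @return Named numeric vector of length 61.
#' @export
extract_edge_block <- function(img, cfg = feature_config()) {
  stopifnot(inherits(img, "lesion_image"))
  mask <- img$mask
  if (mask_touches_border(mask)) {
    abort("edge block: mask touches the image border.")
  }
  boundary_px <- sum(mask & !erode_mask(mask, 1))
  if (boundary_px < cfg$edge_n_profiles) {
    abort(sprintf(
      "edge block: contour has %d pixels, fewer than the %d profile points.",
      boundary_px, cfg$edge_n_profiles))
  }
  ctr <- mask_centroid(mask)
  angles <- (seq_len(cfg$edge_n_profiles) - 1) * 2 * pi / cfg$edge_n_profiles
  ts <- seq(-cfg$edge_profile_halflen, cfg$edge_profile_halflen,
            by = cfg$edge_profile_step)
  sharp <- vapply(angles, function(a) {
    dr <- sin(a); dc <- cos(a)
    rb <- radial_boundary(mask, ctr, dr, dc)
    prof <- bilinear_sample(img$pixels, ctr[1] + (rb + ts) * dr,
                            ctr[2] + (rb + ts) * dc)
    profile_sharpness(prof, cfg$edge_profile_step)
  }, numeric(1))
  band <- dilate_mask(mask, 1) & !erode_mask(mask, 1)
  px <- img$pixels
  gr <- (rbind(px[-1, ], px[nrow(px), ]) - rbind(px[1, ], px[-nrow(px), ])) / 2
  gc <- (cbind(px[, -1], px[, ncol(px)]) - cbind(px[, 1], px[, -ncol(px)])) / 2
  gm <- sqrt(gr^2 + gc^2)[band]
  edge_hist <- if (max(gm) > 0) {
    entropy_bits(tabulate(pmin(floor(gm / max(gm) * 16) + 1, 16), 16))
  } else 0
  out <- c(sharp, edge_hist)
  names(out) <- c(paste0("edge_sharp_",
                         sprintf("%02d", seq_len(cfg$edge_n_profiles))),
                  "edge_hist_entropy")
  out
}
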