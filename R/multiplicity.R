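#' Configuration for similar-lesion counting
#'
#' @param lambda Balance weight in `[0, 1]` between within-class spread and
#'   class-mean contrast in the thresholding objective; `NULL` (default)
#'   selects it from the primary lesion's intensity homogeneity, see
#'   [select_lambda()].
#' @param t_grid Ordered candidate thresholds; `NULL` uses every integer
#'   between the 1st and 99th intensity percentiles of the crop region.
#' @param min_cluster_px Smallest candidate cluster kept, in pixels.
#' @param similarity_threshold Acceptance radius in (alpha, beta) units for
#'   the Euclidean similarity distance.
#' @return A `multiplicity_config` list.
#' @export
multiplicity_config <- function(lambda = NULL, t_grid = NULL,
                                min_cluster_px = 9L,
                                similarity_threshold = 10) {
  if (!is.null(lambda) && (lambda < 0 || lambda > 1)) {
    abort("`lambda` must lie in [0, 1].")
  }
  if (!is.null(t_grid)) {
    if (length(t_grid) == 0L) abort("`t_grid` must be nonempty.")
    if (is.unsorted(t_grid, strictly = TRUE)) {
      abort("`t_grid` must be strictly increasing.")
    }
  }
  if (min_cluster_px < 1L) abort("`min_cluster_px` must be >= 1.")
  structure(list(lambda = lambda, t_grid = t_grid,
                 min_cluster_px = as.integer(min_cluster_px),
                 similarity_threshold = similarity_threshold),
            class = "multiplicity_config")
}

# Crop region of an image: the stored crop mask, or the primary-lesion
# bounding box expanded on every side by 4 x its diagonal, clipped.
derive_crop <- function(img) {
  if (!is.null(img$crop)) return(img$crop)
  bb <- mask_bbox(img$mask)
  diag_len <- sqrt((bb$r2 - bb$r1 + 1)^2 + (bb$c2 - bb$c1 + 1)^2)
  pad <- ceiling(4 * diag_len)
  crop <- matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
  crop[max(1, bb$r1 - pad):min(nrow(crop), bb$r2 + pad),
       max(1, bb$c1 - pad):min(ncol(crop), bb$c2 + pad)] <- TRUE
  crop
}

default_t_grid <- function(img) {
  vals <- img$pixels[derive_crop(img)]
  q <- quantile(vals, c(0.01, 0.99), names = FALSE, type = 1)
  lo <- ceiling(q[1]); hi <- floor(q[2])
  if (lo > hi) lo <- hi <- round(median(vals))
  seq(lo, hi)
}

#' Select the thresholding balance weight from lesion homogeneity
#'
#' Computes the fraction of primary-lesion pixels falling within one
#' (population) standard deviation of the lesion mean.  Homogeneous lesions
#' — where that fraction reaches the Gaussian value 0.68 — get
#' `lambda = 0.75`, weighting the class-mean contrast; heterogeneous lesions
#' get `lambda = 0.15`, weighting the within-class spread.  The 0.68
#' boundary is inclusive.
#'
#' @param img A [lesion_image()].
#' @return `0.75` or `0.15`, with attribute `frac_within_sigma`.
#' @export
select_lambda <- function(img) {
  stopifnot(inherits(img, "lesion_image"))
  v <- img$pixels[img$mask]
  if (length(v) == 0L) abort("primary mask is empty.")
  m <- mean(v); s <- pop_sd(v)
  frac <- mean(v >= m - s & v <= m + s)
  lam <- if (frac >= 0.68) 0.75 else 0.15
  attr(lam, "frac_within_sigma") <- frac
  lam
}

# Class split of crop pixels at threshold T.  The lesion class sits on the
# primary lesion's side of T: pixels <= T when the user-masked lesion is
# darker than the rest of the crop, pixels > T otherwise.
threshold_classes <- function(img, T) {
  crop <- derive_crop(img)
  vals <- img$pixels[crop]
  lesion_dark <- mean(img$pixels[img$mask]) <=
    mean(img$pixels[crop & !img$mask])
  in_lesion <- if (lesion_dark) vals <= T else vals > T
  list(lesion = vals[in_lesion], background = vals[!in_lesion],
       lesion_dark = lesion_dark)
}

#' Weighted within-class-variance thresholding objective
#'
#' Evaluates `J(lambda, T) = (1 - lambda) * sigma_w(T) -
#' lambda * |m_l(T) - m_b(T)|`, where `m_l`, `m_b` are the mean intensities
#' of the lesion-side and background-side classes induced by threshold `T`
#' on the crop region and `sigma_w` is the square root of the
#' probability-weighted within-class variance
#' `P_l * sigma_l^2 + P_b * sigma_b^2`.  A threshold that empties either
#' class returns `Inf` so optimisation skips it.
#'
#' @param img A [lesion_image()].
#' @param lambda Balance weight in `[0, 1]`.
#' @param T Candidate threshold.
#' @return The objective value `J` (scalar; `Inf` for a degenerate split).
#' @export
threshold_objective <- function(img, lambda, T) {
  cls <- threshold_classes(img, T)
  n_l <- length(cls$lesion); n_b <- length(cls$background)
  if (n_l == 0L || n_b == 0L) return(Inf)
  n <- n_l + n_b
  m_l <- mean(cls$lesion); m_b <- mean(cls$background)
  var_l <- sum((cls$lesion - m_l)^2) / n_l
  var_b <- sum((cls$background - m_b)^2) / n_b
  sigma_w <- sqrt((n_l / n) * var_l + (n_b / n) * var_b)
  (1 - lambda) * sigma_w - lambda * abs(m_l - m_b)
}

#' Optimise the segmentation threshold over a candidate grid
#'
#' Exhaustively evaluates [threshold_objective()] on `t_grid` and returns
#' the grid point attaining the minimum; ties are broken by the smallest
#' threshold.
#'
#' @inheritParams threshold_objective
#' @param t_grid Strictly increasing candidate thresholds; `NULL` uses the
#'   integer grid between the crop region's 1st and 99th percentiles.
#' @return The optimal threshold `T*`, with attribute `objective` holding
#'   the full vector of `J` values.
#' @export
optimize_threshold <- function(img, lambda, t_grid = NULL) {
  if (is.null(t_grid)) t_grid <- default_t_grid(img)
  if (length(t_grid) == 0L) abort("`t_grid` must be nonempty.")
  j <- vapply(t_grid, function(T) threshold_objective(img, lambda, T),
              numeric(1))
  if (all(!is.finite(j))) {
    abort("every candidate threshold empties one class.")
  }
  t_star <- t_grid[which.min(j)]   # which.min takes the first (smallest T)
  attr(t_star, "objective") <- j
  t_star
}

#' Label 4-connected foreground components
#'
#' Flood-fill connected-component labelling of a binary grid under
#' 4-connectivity.  Components smaller than `min_cluster_px` are discarded;
#' the rest are returned in scanline order of their topmost-leftmost pixel.
#'
#' @param binary_grid Logical (or 0/1) matrix.
#' @param min_cluster_px Minimum component size kept.
#' @return List of integer matrices, one per component, each row a (row,
#'   col) pixel coordinate.
#' @export
label_components <- function(binary_grid, min_cluster_px = 1L) {
  g <- as.matrix(binary_grid) > 0.5
  nr <- nrow(g)
  fg <- which(g)
  if (length(fg) == 0L) return(list())
  pos <- match(seq_len(nr * ncol(g)), fg)  # linear index -> vertex id
  edges <- integer(0)
  # vertical neighbours (same column, row + 1)
  v <- fg[(fg %% nr) != 0L & g[fg + 1L]]
  if (length(v)) edges <- c(edges, rbind(pos[v], pos[v + 1L]))
  # horizontal neighbours (same row, col + 1)
  hcand <- fg[fg + nr <= nr * ncol(g)]
  hcand <- hcand[g[hcand + nr]]
  if (length(hcand)) edges <- c(edges, rbind(pos[hcand], pos[hcand + nr]))
  gr <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(gr)$membership
  comps <- split(fg, memb)
  comps <- comps[lengths(comps) >= min_cluster_px]
  if (length(comps) == 0L) return(list())
  coords <- lapply(comps, function(idx) {
    cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
  })
  # scanline order of the topmost-leftmost pixel of each component
  first_px <- vapply(coords, function(m) {
    i <- order(m[, 1], m[, 2])[1]
    (m[i, 1] - 1) * 1e9 + m[i, 2]
  }, numeric(1))
  unname(coords[order(first_px)])
}

#' Signature statistics of a candidate lesion cluster
#'
#' Summarises a pixel cluster by `alpha`, the magnitude of its first-order
#' contrast against its surround — `sqrt(dmean^2 + dsd^2)` where the deltas
#' compare pixels inside the cluster with a two-pixel ring outside it — and
#' `beta >= 1`, the major/minor axis-length ratio of its second-moment
#' ellipse (minor axis floored at 1 px for degenerate clusters).
#'
#' @param img A [lesion_image()].
#' @param cluster_pixels Integer matrix of (row, col) coordinates.
#' @return A `cluster_signature` list: `alpha`, `beta`, `pixel_count`.
#' @export
cluster_signature <- function(img, cluster_pixels) {
  px <- img$pixels
  cl_mask <- matrix(FALSE, nrow(px), ncol(px))
  cl_mask[cluster_pixels] <- TRUE
  ring <- dilate_mask(cl_mask, 2) & !cl_mask
  inside <- px[cl_mask]
  outside <- px[ring]
  d_mean <- mean(inside) - mean(outside)
  d_sd <- pop_sd(inside) - pop_sd(outside)
  alpha <- sqrt(d_mean^2 + d_sd^2)
  # moment ellipse axis lengths: 4 * sqrt(eigenvalues of coordinate covariance)
  ctr <- colMeans(cluster_pixels)
  u <- sweep(cluster_pixels, 2, ctr)
  cv <- crossprod(u) / nrow(u)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- max(4 * sqrt(max(ev[2], 0)), 1)
  major <- max(major, minor)
  structure(list(alpha = alpha, beta = major / minor,
                 pixel_count = nrow(cluster_pixels)),
            class = "cluster_signature")
}

#' Euclidean similarity distance between cluster signatures
#'
#' `d = sqrt((alpha_p - alpha_c)^2 + (beta_p - beta_c)^2)`.
#'
#' @param sig_p,sig_c Two [cluster_signature()] objects.
#' @return Nonnegative distance; 0 for identical signatures.
#' @export
similarity_distance <- function(sig_p, sig_c) {
  sqrt((sig_p$alpha - sig_c$alpha)^2 + (sig_p$beta - sig_c$beta)^2)
}

#' Count lesions similar to the primary lesion
#'
#' Runs the full similar-lesion pipeline on the crop region: selects the
#' balance weight from lesion homogeneity, optimises the segmentation
#' threshold, labels 4-connected candidate clusters, discards clusters that
#' touch the primary mask, and accepts a cluster as a similar lesion when
#' its (alpha, beta) signature lies within `similarity_threshold` of the
#' primary's.
#'
#' @param img A [lesion_image()].
#' @param cfg A [multiplicity_config()].
#' @return A `multiplicity_result`: `count`, `t_star`, `lambda`, and a
#'   tibble `clusters` with one row per candidate (pixel count, alpha, beta,
#'   distance, overlap and acceptance flags).
#' @examples
#' ph <- similar_lesion_phantom(n_similar = 2, seed = 7)
#' count_similar_lesions(ph$image)$count
#' @export
count_similar_lesions <- function(img, cfg = multiplicity_config()) {
  stopifnot(inherits(img, "lesion_image"), inherits(cfg, "multiplicity_config"))
  lambda <- if (is.null(cfg$lambda)) as.numeric(select_lambda(img)) else
    cfg$lambda
  t_star <- optimize_threshold(img, lambda, cfg$t_grid)
  crop <- derive_crop(img)
  cls_dark <- threshold_classes(img, t_star)$lesion_dark
  binary <- if (cls_dark) img$pixels <= t_star else img$pixels > t_star
  binary <- binary & crop
  clusters <- label_components(binary, cfg$min_cluster_px)
  sig_p <- cluster_signature(img, which(img$mask, arr.ind = TRUE))
  rows <- purrr::map_dfr(seq_along(clusters), function(i) {
    cp <- clusters[[i]]
    overlaps <- any(img$mask[cp])
    sig <- cluster_signature(img, cp)
    d <- similarity_distance(sig_p, sig)
    tibble(cluster = i, pixel_count = nrow(cp), alpha = sig$alpha,
           beta = sig$beta, distance = d, overlaps_primary = overlaps,
           accepted = !overlaps & d <= cfg$similarity_threshold)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(cluster = integer(), pixel_count = integer(),
                   alpha = numeric(), beta = numeric(), distance = numeric(),
                   overlaps_primary = logical(), accepted = logical())
  }
  structure(list(count = sum(rows$accepted), clusters = rows,
                 t_star = as.numeric(t_star), lambda = lambda,
                 primary_signature = sig_p,
                 similarity_threshold = cfg$similarity_threshold,
                 cluster_pixels = clusters),
            class = "multiplicity_result")
}

#' @export
print.multiplicity_result <- function(x, ...) {
  cat(sprintf(
    "<multiplicity_result> %d similar lesion(s); T* = %g, lambda = %g, %d candidate cluster(s)\n",
    x$count, x$t_star, x$lambda, nrow(x$clusters)))
  invisible(x)
}
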