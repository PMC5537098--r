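#' Specify a synthetic elliptical lesion
#'
#' Lesions are rendered as filled rotated ellipses with one of three fill
#' textures: `"flat"` (constant at `mean_intensity`), `"speckle"` (per-pixel
#' Gaussian jitter of width `intensity_sigma`) or `"bimodal"` (a two-level
#' checker fill at `mean_intensity` +/- `intensity_sigma`).
#'
#' @param center Numeric length-2, lesion centre as (row, col) pixels.
#' @param axes Numeric length-2, (major, minor) semi-axis lengths in pixels;
#'   `major >= minor > 1`.
#' @param rotation Rotation of the major axis in radians.
#' @param mean_intensity Mean fill intensity (HU-like).
#' @param intensity_sigma Texture amplitude (HU-like), `>= 0`.
#' @param texture One of `"flat"`, `"speckle"`, `"bimodal"`.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, axes, rotation = 0, mean_intensity = 0,
                        intensity_sigma = 0,
                        texture = c("flat", "speckle", "bimodal")) {
  texture <- match.arg(texture)
  if (length(center) != 2L || length(axes) != 2L) {
    abort("`center` and `axes` must have length 2.")
  }
  if (!(axes[1] >= axes[2] && axes[2] > 1)) {
    abort("lesion axes must satisfy major >= minor > 1.")
  }
  if (intensity_sigma < 0) abort("`intensity_sigma` must be >= 0.")
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 rotation = rotation, mean_intensity = mean_intensity,
                 intensity_sigma = intensity_sigma, texture = texture),
            class = "lesion_spec")
}

#' Specify a CT-like lesion phantom
#'
#' A phantom is a `width` x `height` slice holding an elliptical "liver"
#' region at `liver_level` on a darker background, a primary lesion, and any
#' number of satellite lesions.  Intensities are HU-like signed integers;
#' i.i.d. Gaussian noise of width `noise_sigma` is added everywhere before
#' rounding.  Defaults emulate a contrast-enhanced portal-venous liver
#' slice (enhanced parenchyma near 110 HU, extrahepatic background near
#' -100 HU, hypodense lesions).
#'
#' @param width,height Canvas size in pixels, `>= 64`.
#' @param background_level,liver_level Background and liver intensities.
#' @param primary A [lesion_spec()] for the primary lesion.
#' @param satellites List of [lesion_spec()] satellites.
#' @param noise_sigma Global Gaussian noise sd (HU-like), `>= 0`.
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(primary, satellites = list(), width = 192L,
                         height = 192L, background_level = -100,
                         liver_level = 110, noise_sigma = 2, seed = 1L) {
  if (width < 64L || height < 64L) abort("phantom must be at least 64 x 64.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  stopifnot(inherits(primary, "lesion_spec"))
  for (s in satellites) stopifnot(inherits(s, "lesion_spec"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_level = background_level,
                 liver_level = liver_level, primary = primary,
                 satellites = satellites, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Liver region of a phantom: centred ellipse covering most of the canvas.
liver_region <- function(height, width) {
  ellipse_mask(height, width, c((height + 1) / 2, (width + 1) / 2),
               c(0.42 * height, 0.45 * width), 0)
}

# Filled rotated ellipse as a logical matrix.
ellipse_mask <- function(height, width, center, semi_axes, rotation) {
  r <- matrix(seq_len(height), height, width)
  c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
  u <- r - center[1]; v <- c_ - center[2]
  x <- u * cos(rotation) + v * sin(rotation)
  y <- -u * sin(rotation) + v * cos(rotation)
  (x / semi_axes[1])^2 + (y / semi_axes[2])^2 <= 1
}

lesion_mask <- function(spec, height, width) {
  ellipse_mask(height, width, spec$center, spec$axes, spec$rotation)
}

# Fill values for one lesion given its mask (uses the current RNG).
render_lesion_fill <- function(spec, mask) {
  n <- sum(mask)
  base <- rep(spec$mean_intensity, n)
  if (spec$texture == "speckle" && spec$intensity_sigma > 0) {
    base <- base + rnorm(n, 0, spec$intensity_sigma)
  } else if (spec$texture == "bimodal") {
    idx <- which(mask, arr.ind = TRUE)
    chk <- ((idx[, 1] %/% 2L) + (idx[, 2] %/% 2L)) %% 2L == 0L
    base <- base + ifelse(chk, spec$intensity_sigma, -spec$intensity_sigma)
  }
  base
}

#' Render a lesion phantom
#'
#' Deterministically renders the phantom described by a [phantom_spec()]:
#' identical spec + seed give bit-identical output.  Overlapping lesions or
#' lesion centres outside the liver are rejected with a diagnostic naming the
#' offending lesions.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (a [lesion_image()] whose crop region
#'   is the liver ellipse) and `truth` (list with `satellite_count` and
#'   `satellite_masks`, the planted ground truth).
#' @examples
#' ph <- make_lesion_phantom(phantom_spec(
#'   primary = lesion_spec(c(96, 96), c(12, 10), mean_intensity = 10)))
#' ph$truth$satellite_count
#' @export
make_lesion_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  liver <- liver_region(h, w)
  lesions <- c(list(primary = spec$primary), spec$satellites)
  nms <- c("primary",
           if (length(spec$satellites))
             paste0("satellite ", seq_along(spec$satellites)))
  masks <- lapply(lesions, lesion_mask, height = h, width = w)
  for (i in seq_along(masks)) {
    ctr <- round(lesions[[i]]$center)
    if (!liver[ctr[1], ctr[2]]) {
      abort(sprintf("lesion '%s' centre lies outside the liver region.",
                    nms[i]))
    }
  }
  if (length(masks) > 1L) {
    for (i in seq_len(length(masks) - 1L)) {
      for (j in seq(i + 1L, length(masks))) {
        if (any(masks[[i]] & masks[[j]])) {
          abort(sprintf("lesions '%s' and '%s' overlap.", nms[i], nms[j]))
        }
      }
    }
  }
  img <- with_local_seed(spec$seed, {
    px <- matrix(spec$background_level, h, w)
    px[liver] <- spec$liver_level
    for (i in seq_along(masks)) {
      px[masks[[i]]] <- render_lesion_fill(lesions[[i]], masks[[i]])
    }
    if (spec$noise_sigma > 0) {
      px <- px + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    px
  })
  px <- pmin(pmax(round(img), -32768), 32767)
  storage.mode(px) <- "integer"
  list(
    image = lesion_image(px, masks[[1]], crop = liver),
    truth = list(satellite_count = length(spec$satellites),
                 satellite_masks = masks[-1])
  )
}

#' Phantom with planted similar and dissimilar satellite lesions
#'
#' Convenience preset used throughout the tests and examples: a flat
#' hypodense primary lesion plus `n_similar` satellites sharing its intensity
#' and aspect ratio and `n_dissimilar` long thin streaks at the same
#' intensity whose axis-ratio signature lies far from the primary's, placed
#' at fixed angular slots inside the liver.
#'
#' @param n_similar,n_dissimilar Number of planted similar / dissimilar
#'   satellites (at most 5 in total).
#' @param seed Integer seed.
#' @param size Canvas side in pixels.
#' @param noise_sigma Global noise sd; 0 gives a noiseless phantom.
#' @return As [make_lesion_phantom()].
#' @export
similar_lesion_phantom <- function(n_similar, n_dissimilar = 0, seed = 1L,
                                   size = 192L, noise_sigma = 0) {
  k <- n_similar + n_dissimilar
  if (k > 5L) abort("at most 5 satellites fit the placement slots.")
  ctr <- (size + 1) / 2
  slot_r <- 0.55 * 0.42 * size
  # geometry varies with the seed even for noiseless phantoms
  geo <- with_local_seed(seed, list(
    angle0 = runif(1, 0, 2 * pi / 5),
    p_axes = sort(runif(2, 10, 14), decreasing = TRUE),
    p_rot = runif(1, 0, pi),
    s_minor = runif(5, 8, 10),
    s_rot = runif(5, 0, pi)
  ))
  angles <- (seq_len(5L) - 1L) * 2 * pi / 5 + geo$angle0
  sats <- list()
  for (i in seq_len(k)) {
    pos <- c(ctr + slot_r * sin(angles[i]), ctr + slot_r * cos(angles[i]))
    if (i <= n_similar) {
      ratio <- geo$p_axes[1] / geo$p_axes[2]
      sats[[i]] <- lesion_spec(pos, c(geo$s_minor[i] * ratio,
                                      geo$s_minor[i]),
                               rotation = geo$s_rot[i],
                               mean_intensity = 10)
    } else {
      sats[[i]] <- lesion_spec(pos, c(20, 1.1), rotation = geo$s_rot[i],
                               mean_intensity = 10)
    }
  }
  make_lesion_phantom(phantom_spec(
    primary = lesion_spec(c(ctr, ctr), geo$p_axes, rotation = geo$p_rot,
                          mean_intensity = 10),
    satellites = sats, width = size, height = size,
    noise_sigma = noise_sigma, seed = seed))
}
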