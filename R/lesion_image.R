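#' Bundle a CT slice with its primary-lesion mask
#'
#' A `lesion_image` is the unit all feature extraction operates on: a 2-D
#' grid of HU-like intensities, a binary mask of the radiologist-drawn
#' primary-lesion region of interest, and optionally a binary crop region
#' (e.g. a liver mask) restricting where satellite lesions are searched for.
#'
#' @param pixels Numeric matrix of intensities (HU-like; rows are image rows).
#' @param mask Logical or 0/1 matrix of the same dimensions marking the
#'   primary lesion.  Must contain at least 16 pixels and form a single
#'   4-connected component.
#' @param crop Optional logical matrix of the same dimensions marking the
#'   region (e.g. the liver) inside which similar lesions are counted.
#'
#' @return An object of class `lesion_image` with elements `pixels`, `mask`
#'   and `crop` (possibly `NULL`).
#' @examples
#' img <- matrix(0, 64, 64)
#' m <- matrix(FALSE, 64, 64); m[28:36, 28:36] <- TRUE
#' img[m] <- 80
#' li <- lesion_image(img, m)
#' @export
lesion_image <- function(pixels, mask, crop = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) abort("`pixels` must be a numeric matrix.")
  mask <- as.matrix(mask) > 0.5
  if (!all(dim(mask) == dim(pixels))) {
    abort("`mask` must have the same dimensions as `pixels`.")
  }
  npx <- sum(mask)
  if (npx < 16L) {
    abort(sprintf("primary mask has %d pixels; at least 16 are required.", npx))
  }
  comps <- label_components(mask, min_cluster_px = 1L)
  if (length(comps) != 1L) {
    abort(sprintf(
      "primary mask must be a single 4-connected component (found %d).",
      length(comps)))
  }
  if (!is.null(crop)) {
    crop <- as.matrix(crop) > 0.5
    if (!all(dim(crop) == dim(pixels))) {
      abort("`crop` must have the same dimensions as `pixels`.")
    }
  }
  structure(list(pixels = pixels, mask = mask, crop = crop),
            class = "lesion_image")
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf("<lesion_image> %d x %d, lesion %d px%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              if (is.null(x$crop)) "" else
                sprintf(", crop %d px", sum(x$crop))))
  invisible(x)
}

mask_touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}
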