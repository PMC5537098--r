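#' Feature-extraction configuration
#'
#' Fixes the internal parameters of every feature family so the 495
#' traditional dimensions are reproducible.  The block layout is: intensity
#' 6, texture 376 (GLCM 12 + Gabor 32 + Daubechies 324 + Haar 1 + run-length
#' 7), shape 20, histogram 32 (LBP 12 + 20 bins), edge 61 (60 contour
#' sharpness profiles + 1 edge-histogram entropy).
#'
#' @param proportion_threshold Intensity threshold for the
#'   proportion-above-threshold feature; `NULL` (default) uses the optimum
#'   of the within-class-variance thresholding objective for the image, see
#'   [optimize_threshold()].
#' @param intensity_ring_radii Dilation radii (px) of the three ring
#'   neighbourhoods used for the lesion-vs-surround intensity differences.
#' @param glcm_levels Gray levels for co-occurrence quantisation.
#' @param gabor_wavelengths Carrier wavelengths (px) of the Gabor bank; the
#'   bank uses 4 orientations (0, 45, 90, 135 degrees) and reports mean and
#'   sd of the response magnitude inside the mask.
#' @param wavelet_size Side of the square the lesion bounding box is
#'   resampled to before wavelet analysis.
#' @param rle_levels Gray levels for the run-length matrix.
#' @param hist_range Intensity window (HU-like) of the 20 equal-width
#'   histogram bins; out-of-window values are clamped into the end bins.
#' @param edge_n_profiles Number of equally spaced radial profiles sampled
#'   across the lesion contour.
#' @param edge_profile_halflen,edge_profile_step Half-length and sampling
#'   step (px) of each edge profile.
#' @param li_radii Kernel radii (px) of the local area integral invariant.
#' @return A `feature_config` list.
#' @export
feature_config <- function(proportion_threshold = NULL,
                           intensity_ring_radii = c(2, 4, 8),
                           glcm_levels = 32L,
                           gabor_wavelengths = c(3, 4, 6, 8),
                           wavelet_size = 64L,
                           rle_levels = 16L,
                           hist_range = c(-200, 400),
                           edge_n_profiles = 60L,
                           edge_profile_halflen = 4,
                           edge_profile_step = 0.5,
                           li_radii = 2:16) {
  structure(list(proportion_threshold = proportion_threshold,
                 intensity_ring_radii = intensity_ring_radii,
                 glcm_levels = as.integer(glcm_levels),
                 gabor_wavelengths = gabor_wavelengths,
                 wavelet_size = as.integer(wavelet_size),
                 rle_levels = as.integer(rle_levels),
                 hist_range = hist_range,
                 edge_n_profiles = as.integer(edge_n_profiles),
                 edge_profile_halflen = edge_profile_halflen,
                 edge_profile_step = edge_profile_step,
                 li_radii = as.integer(li_radii)),
            class = "feature_config")
}

#' Descriptor table of the full feature bank
#'
#' @param include_multiplicity Include the similar-lesion-count column
#'   (total 496) or only the 495 traditional features.
#' @return Tibble with columns `name`, `block` and `family`, in extraction
#'   order.
#' @export
feature_descriptors <- function(include_multiplicity = TRUE) {
  cfg <- feature_config()
  orient <- c("000", "045", "090", "135")
  d <- dplyr::bind_rows(
    tibble(name = c("intensity_median", "intensity_entropy",
                    "intensity_prop_thresh",
                    paste0("intensity_diff_r", cfg$intensity_ring_radii)),
           block = "intensity",
           family = c("IntensityM", "Entropy", "ProportionThres",
                      rep("IntensityDiff", 3))),
    tibble(name = paste0("glcm_",
                         rep(c("contrast", "correlation", "energy"),
                             each = 4),
                         "_", rep(orient, 3)),
           block = "texture", family = "GLCM"),
    tibble(name = paste0("gabor_w", rep(cfg$gabor_wavelengths, each = 8),
                         "_o", rep(rep(orient, each = 2), 4),
                         "_", rep(c("mean", "sd"), 16)),
           block = "texture", family = "Gabor"),
    tibble(name = paste0("daube_l", rep(1:3, each = 108),
                         rep(rep(c("h", "v", "d"), each = 36), 3),
                         "_b", sprintf("%02d", rep(1:36, 9))),
           block = "texture", family = "Daube"),
    tibble(name = "haar_detail_energy", block = "texture", family = "Haar"),
    tibble(name = paste0("rle_", c("sre", "lre", "gln", "rln", "rp",
                                   "lgre", "hgre")),
           block = "texture", family = "RLE"),
    tibble(name = c("shape_compactness", "shape_eccentricity",
                    "shape_roughness",
                    paste0("li_r", sprintf("%02d", cfg$li_radii)),
                    "radial_mean", "radial_sd"),
           block = "shape",
           family = c("Compactness", "Eccentricity", "Roughness",
                      rep("LocalIntegral", 15), "RadialSig", "RadialSig")),
    tibble(name = c(paste0("lbp_u", 0:8), "lbp_nonuniform",
                    "lbp_code_mean", "lbp_code_sd"),
           block = "histogram", family = "LBP"),
    tibble(name = paste0("histbin_", sprintf("%02d", 1:20)),
           block = "histogram", family = "HistogramBin"),
    tibble(name = c(paste0("edge_sharp_", sprintf("%02d",
                                                  1:cfg$edge_n_profiles)),
                    "edge_hist_entropy"),
           block = "edge",
           family = c(rep("EdgeSharpness", cfg$edge_n_profiles), "EdgeHist"))
  )
  if (include_multiplicity) {
    d <- dplyr::bind_rows(
      d, tibble(name = "n_similar_lesions", block = "multiplicity",
                family = "SimilarLesions"))
  }
  d
}
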