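#' Assemble the full feature vector for one lesion
#'
#' Concatenates the five traditional blocks in fixed order (intensity,
#' texture, shape, histogram, edge; 495 values) and appends the
#' similar-lesion count when given (496 values).  Block failures propagate
#' with the block name in the message.
#'
#' @param img A [lesion_image()].
#' @param similar_count Optional scalar count of similar lesions (the
#'   multiplicity feature).  Omit for the 495-dimensional traditional
#'   vector.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 495 or 496.
#' @export
assemble_feature_vector <- function(img, similar_count = NULL,
                                    cfg = feature_config()) {
  out <- c(extract_intensity_block(img, cfg),
           extract_texture_block(img, cfg),
           extract_shape_block(img, cfg),
           extract_histogram_block(img, cfg),
           extract_edge_block(img, cfg))
  if (!is.null(similar_count)) {
    out <- c(out, n_similar_lesions = as.numeric(similar_count))
  }
  expected <- feature_descriptors(!is.null(similar_count))$name
  stopifnot(identical(names(out), expected))
  out
}

#' Extract features for one image as a one-row tibble
#'
#' @param img A [lesion_image()].
#' @param sample_id Identifier stored in the `sample_id` column.
#' @param include_multiplicity Run the similar-lesion counter and append
#'   its count as the 496th feature.
#' @param cfg A [feature_config()].
#' @param mult_cfg A [multiplicity_config()] for the counter.
#' @return Tibble with `sample_id` and 495 or 496 feature columns.
#' @export
extract_features <- function(img, sample_id = "sample",
                             include_multiplicity = TRUE,
                             cfg = feature_config(),
                             mult_cfg = multiplicity_config()) {
  cnt <- if (include_multiplicity) {
    count_similar_lesions(img, mult_cfg)$count
  } else NULL
  v <- assemble_feature_vector(img, cnt, cfg)
  dplyr::bind_cols(tibble(sample_id = sample_id),
                   as_tibble(as.list(v)))
}

#' Extract features for a cohort of images
#'
#' @param images Named list of [lesion_image()] objects; names become
#'   sample ids.
#' @inheritParams extract_features
#' @return Tibble with one row per image.
#' @export
extract_cohort_features <- function(images, include_multiplicity = TRUE,
                                    cfg = feature_config(),
                                    mult_cfg = multiplicity_config()) {
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_along(images))
  purrr::map2_dfr(images, ids, function(im, id) {
    tryCatch(
      extract_features(im, id, include_multiplicity, cfg, mult_cfg),
      error = function(e) {
        abort(sprintf("feature extraction failed for sample '%s': %s",
                      id, conditionMessage(e)))
      })
  })
}

feature_columns <- function(tbl) {
  setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))], "sample_id")
}

#' Z-score normalise a feature matrix
#'
#' Centers every feature column to mean 0 and scales to standard deviation
#' 1 using the population convention (divide by N).  Constant columns map
#' to all zeros.  The per-column statistics are stored in the `norm_stats`
#' attribute for reuse on unseen data via [apply_norm_stats()].
#'
#' @param features Tibble with a `sample_id` column and numeric feature
#'   columns; at least 2 rows.
#' @return The normalised tibble with a `norm_stats` attribute (tibble:
#'   `feature`, `mean`, `sd`).
#' @export
zscore_normalize <- function(features) {
  if (nrow(features) < 2L) {
    abort("normalisation needs at least 2 samples.")
  }
  cols <- feature_columns(features)
  stats <- tibble(
    feature = cols,
    mean = unname(vapply(features[cols], mean, numeric(1))),
    sd = unname(vapply(features[cols], pop_sd, numeric(1)))
  )
  out <- apply_norm_stats(features, stats)
  attr(out, "norm_stats") <- stats
  out
}

#' Apply stored normalisation statistics to a feature matrix
#'
#' @param features Feature tibble (see [zscore_normalize()]).
#' @param stats A `norm_stats` tibble (`feature`, `mean`, `sd`), typically
#'   taken from a trained model so prediction-time data is scaled exactly
#'   as the training data was.
#' @return Normalised tibble.
#' @export
apply_norm_stats <- function(features, stats) {
  missing <- setdiff(stats$feature, names(features))
  if (length(missing)) {
    abort(sprintf("feature matrix lacks %d column(s) named in norm_stats (first: %s).",
                  length(missing), missing[1]))
  }
  out <- features
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    out[[f]] <- if (stats$sd[i] > 0) {
      (features[[f]] - stats$mean[i]) / stats$sd[i]
    } else {
      rep(0, nrow(features))
    }
  }
  out
}
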