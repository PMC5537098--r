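#' Specify a synthetic feature/label design
#'
#' Describes a samples x features matrix in which a known subset of columns
#' carries the label signal and every other column is label-independent
#' noise, used to exercise the feature-selection stage with planted ground
#' truth.  Labels are `sign(rowSums)` of the informative columns (ties map
#' to +1), then flipped independently with probability `label_noise_rate`.
#'
#' @param n_samples Number of rows; at least 10 (fivefold cross-validation
#'   needs at least two samples per fold).
#' @param n_features Number of columns.
#' @param informative Integer indices (1-based) of the signal-carrying
#'   columns; must lie in `1:n_features`.
#' @param label_noise_rate Probability of flipping each label, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A `label_design` list.
#' @export
label_design <- function(n_samples, n_features, informative,
                         label_noise_rate = 0, seed = 1L) {
  if (n_samples < 10L) {
    abort("`n_samples` must be >= 10 to support fivefold cross-validation.")
  }
  informative <- as.integer(informative)
  if (length(informative) &&
      (min(informative) < 1L || max(informative) > n_features)) {
    abort("`informative` indices must lie in 1:n_features.")
  }
  if (label_noise_rate < 0 || label_noise_rate >= 0.5) {
    abort("`label_noise_rate` must be in [0, 0.5).")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 informative = informative,
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed)),
            class = "label_design")
}

#' Generate a synthetic feature matrix with planted informative columns
#'
#' @param design A [label_design()].
#' @return A list with `features` (tibble: `sample_id` plus `f001`, `f002`,
#'   ... standard-normal columns) and `labels` (vector in \{1, -1\}).
#' @examples
#' d <- label_design(100, 20, informative = c(2, 7), seed = 42)
#' m <- make_feature_label_matrix(d)
#' table(m$labels)
#' @export
make_feature_label_matrix <- function(design) {
  stopifnot(inherits(design, "label_design"))
  n <- design$n_samples; p <- design$n_features
  out <- with_local_seed(design$seed, {
    x <- matrix(rnorm(n * p), n, p)
    if (length(design$informative)) {
      score <- rowSums(x[, design$informative, drop = FALSE])
      y <- ifelse(score >= 0, 1L, -1L)
    } else {
      y <- ifelse(runif(n) < 0.5, 1L, -1L)
    }
    if (design$label_noise_rate > 0) {
      flip <- runif(n) < design$label_noise_rate
      y[flip] <- -y[flip]
    }
    list(x = x, y = y)
  })
  colnames(out$x) <- sprintf("f%03d", seq_len(p))
  feats <- as_tibble(out$x)
  feats <- dplyr::bind_cols(
    tibble(sample_id = sprintf("s%03d", seq_len(n))), feats)
  list(features = feats, labels = out$y)
}

#' Generate a seeded phantom cohort with synthetic semantic terms
#'
#' Builds `n` lesion phantoms whose appearance varies along three
#' independent binary attributes, each driving one visual semantic term:
#' `water_density` (hypodense, cyst-like mean intensity vs a denser lesion),
#' `ovoid` (elongated vs round lesion), and `multiple_lesions` (three
#' planted similar satellites vs solitary).  A fourth term `lesion` is
#' present on every sample, so the 20-75% occurrence filter removes it.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param size Canvas side in pixels.
#' @return List with `images` (named list of [lesion_image()]), `truth`
#'   (tibble of the attribute draws) and `annotations` (wide tibble:
#'   `sample_id` plus one logical column per term).
#' @export
phantom_cohort <- function(n, seed = 1L, size = 160L) {
  draws <- with_local_seed(seed, {
    tibble(
      sample_id = sprintf("ph%03d", seq_len(n)),
      water = runif(n) < 0.5,
      ovoid = runif(n) < 0.5,
      multiple = runif(n) < 0.5,
      minor = runif(n, 9.5, 11.5),
      ratio_ov = runif(n, 1.8, 2.3),
      ratio_rd = runif(n, 1.0, 1.12),
      rot = runif(n, 0, pi),
      mean_w = runif(n, 0, 18),
      mean_s = runif(n, 45, 65),
      sub_seed = sample.int(1e6, n)
    )
  })
  ctr <- (size + 1) / 2
  slot_r <- 0.55 * 0.42 * size
  angles <- (seq_len(3L) - 1L) * 2 * pi / 3 + 0.7
  images <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[i, ]
    ratio <- if (d$ovoid) d$ratio_ov else d$ratio_rd
    mean_int <- if (d$water) d$mean_w else d$mean_s
    sats <- list()
    if (d$multiple) {
      sats <- lapply(seq_len(3L), function(j) {
        pos <- c(ctr + slot_r * sin(angles[j]), ctr + slot_r * cos(angles[j]))
        lesion_spec(pos, c(9, 9 / ratio), rotation = d$rot,
                    mean_intensity = mean_int, intensity_sigma = 2,
                    texture = "speckle")
      })
    }
    ph <- make_lesion_phantom(phantom_spec(
      primary = lesion_spec(c(ctr, ctr), c(d$minor * ratio, d$minor),
                            rotation = d$rot, mean_intensity = mean_int,
                            intensity_sigma = 2, texture = "speckle"),
      satellites = sats, width = size, height = size,
      noise_sigma = 1.5, seed = d$sub_seed))
    images[[i]] <- ph$image
  }
  names(images) <- draws$sample_id
  annotations <- tibble(
    sample_id = draws$sample_id,
    lesion = TRUE,
    water_density = draws$water,
    ovoid = draws$ovoid,
    multiple_lesions = draws$multiple
  )
  list(images = images,
       truth = draws[, c("sample_id", "water", "ovoid", "multiple")],
       annotations = annotations)
}
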