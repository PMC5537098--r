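BUNDLE_FORMAT_VERSION <- 1L

#' Filter a term vocabulary by occurrence
#'
#' Keeps the visual semantic terms whose occurrence fraction across the
#' cohort lies in `[min_frac, max_frac]` (both boundaries inclusive);
#' rarer terms give too few positive samples and near-universal terms too
#' few negatives for the per-term classifiers.
#'
#' @param annotations Wide tibble: `sample_id` plus one logical/0-1 column
#'   per term.
#' @param min_frac,max_frac Occurrence band (defaults 0.20 and 0.75).
#' @return Character vector of retained term names (possibly empty, with a
#'   warning).
#' @export
filter_vsts <- function(annotations, min_frac = 0.20, max_frac = 0.75) {
  if (nrow(annotations) < 1L) abort("`annotations` has no samples.")
  terms <- setdiff(names(annotations), "sample_id")
  occ <- vapply(annotations[terms], function(x) mean(as.logical(x)),
                numeric(1))
  keep <- terms[occ >= min_frac & occ <= max_frac]
  if (length(keep) == 0L) {
    warn("no term falls inside the occurrence band; vocabulary is empty.")
  }
  keep
}

#' Train per-term annotation models
#'
#' Full training pass over an extracted feature matrix: z-score
#' normalisation (statistics retained for prediction), occurrence
#' filtering of the vocabulary, one forward-selection run per retained
#' term, and a final Gaussian-kernel SVM refit on each term's selected
#' feature subset.
#'
#' @param features Feature tibble from [extract_cohort_features()]
#'   (un-normalised; `sample_id` plus 495/496 columns).
#' @param annotations Wide annotation tibble (`sample_id` + term columns)
#'   aligned to `features` by `sample_id`.
#' @param seed Integer seed controlling fold assignment.
#' @param min_frac,max_frac Vocabulary occurrence band.
#' @param n_bins,k Passed to [pmei_select()].
#' @param mult_cfg The [multiplicity_config()] the features were extracted
#'   with (stored for prediction-time extraction).
#' @return A `vst_model_bundle`.
#' @export
vst_train <- function(features, annotations, seed = 1L,
                      min_frac = 0.20, max_frac = 0.75,
                      n_bins = 8L, k = 5L,
                      mult_cfg = multiplicity_config()) {
  if (!all(annotations$sample_id %in% features$sample_id)) {
    abort("every annotated sample must have a feature row.")
  }
  annotations <- annotations[match(features$sample_id,
                                   annotations$sample_id), ]
  norm <- zscore_normalize(features)
  stats <- attr(norm, "norm_stats")
  vocab <- filter_vsts(annotations, min_frac, max_frac)
  models <- list()
  for (term in vocab) {
    labels <- ifelse(as.logical(annotations[[term]]), 1L, -1L)
    counts <- table(labels)
    if (length(counts) < 2L || min(counts) < k) {
      warn(sprintf(
        "term '%s' skipped: a class has fewer than %d samples.", term, k))
      next
    }
    trace <- pmei_select(norm, labels, seed = seed, n_bins = n_bins, k = k)
    fit <- svm_fit(as.matrix(norm[trace$selected]), labels)
    models[[term]] <- list(selected = trace$selected, trace = trace,
                           ranking = ranking_values(trace), svm = fit,
                           final_tau = trace$final_tau)
  }
  structure(list(format_version = BUNDLE_FORMAT_VERSION,
                 vocabulary = names(models), norm_stats = stats,
                 models = models, mult_cfg = mult_cfg,
                 seed = as.integer(seed),
                 n_features = length(feature_columns(features))),
            class = "vst_model_bundle")
}

#' @export
print.vst_model_bundle <- function(x, ...) {
  cat(sprintf(
    "<vst_model_bundle v%d> %d term model(s) over %d features\n",
    x$format_version, length(x$models), x$n_features))
  for (term in x$vocabulary) {
    m <- x$models[[term]]
    cat(sprintf("  %-20s %d feature(s), tau = %.3f\n", term,
                length(m$selected), m$final_tau))
  }
  invisible(x)
}

#' Predict visual semantic terms
#'
#' Applies a trained bundle to new data.  Features are normalised with the
#' statistics stored at training time (never re-fitted) and each per-term
#' SVM is evaluated on its selected columns; a term is annotated as
#' present when its decision is the positive class.
#'
#' @param object A `vst_model_bundle` from [vst_train()].
#' @param newdata Either an un-normalised feature tibble (as produced by
#'   [extract_features()] / [extract_cohort_features()]) or a single
#'   [lesion_image()], in which case features are extracted first with the
#'   bundle's multiplicity configuration.
#' @param ... Unused.
#' @return Tibble (`sample_id`, `vst`, `decision`, `present`) with one row
#'   per sample and modelled term.
#' @export
predict.vst_model_bundle <- function(object, newdata, ...) {
  if (object$format_version != BUNDLE_FORMAT_VERSION) {
    abort(sprintf("bundle format version %s is not supported.",
                  format(object$format_version)))
  }
  if (inherits(newdata, "lesion_image")) {
    newdata <- extract_features(
      newdata, include_multiplicity = object$n_features == 496L,
      mult_cfg = object$mult_cfg)
  }
  if (length(object$models) == 0L) {
    warn("bundle contains no term models; returning empty prediction.")
    return(tibble(sample_id = character(), vst = character(),
                  decision = character(), present = logical()))
  }
  norm <- apply_norm_stats(newdata, object$norm_stats)
  purrr::map_dfr(object$vocabulary, function(term) {
    m <- object$models[[term]]
    pred <- predict(m$svm, as.matrix(norm[m$selected]))
    present <- as.character(pred) == "1"
    tibble(sample_id = newdata$sample_id, vst = term,
           decision = ifelse(present, "present", "absent"),
           present = present)
  }) |>
    arrange(.data$sample_id, .data$vst)
}

#' Explicit feature-to-term mapping report
#'
#' One row per (term, selected feature) pair with the feature's relevance,
#' its 0-5 ranking value and the term's final cross-validated accuracy —
#' the explicit, human-readable association the selection stage derives.
#'
#' @param bundle A `vst_model_bundle`.
#' @return A `vst_mapping` tibble (`vst`, `feature`, `mi_bits`,
#'   `ranking_value`, `tau_final`), ordered by term then decreasing
#'   ranking value.
#' @export
mapping_report <- function(bundle) {
  stopifnot(inherits(bundle, "vst_model_bundle"))
  out <- purrr::map_dfr(bundle$vocabulary, function(term) {
    m <- bundle$models[[term]]
    rk <- dplyr::filter(m$ranking, .data$selected)
    tibble(vst = term, feature = rk$feature, mi_bits = rk$mi_bits,
           ranking_value = rk$ranking_value, tau_final = m$final_tau)
  }) |>
    arrange(.data$vst, desc(.data$ranking_value), .data$feature)
  class(out) <- c("vst_mapping", class(out))
  out
}

#' Save / load a model bundle
#'
#' Bundles are written as a single serialised file carrying a format
#' version; [load_bundle()] refuses files written under a different
#' version rather than risking silent model drift.
#'
#' @param bundle A `vst_model_bundle`.
#' @param path File path.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns
#'   the bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "vst_model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "vst_model_bundle")) {
    abort("file does not contain a vst_model_bundle.")
  }
  if (!identical(bundle$format_version, BUNDLE_FORMAT_VERSION)) {
    abort(sprintf(
      "bundle format version %s does not match supported version %d.",
      format(bundle$format_version), BUNDLE_FORMAT_VERSION))
  }
  bundle
}
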