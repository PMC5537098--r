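#' Equal-frequency discretisation
#'
#' Maps a continuous vector to at most `n_bins` integer codes with (near)
#' equal bin populations; ties at a bin edge are assigned to the lower bin,
#' and a constant vector collapses to a single code (which then carries
#' zero mutual information).
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins, `>= 2`.
#' @return Integer codes in `1:n_bins`.
#' @export
discretize <- function(values, n_bins = 8L) {
  if (n_bins < 2L) abort("`n_bins` must be >= 2.")
  br <- unique(quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                        names = FALSE, type = 1))
  findInterval(values, br, left.open = TRUE) + 1L
}

#' Plug-in mutual information in bits
#'
#' Estimates `I(f; a) = H(f) + H(a) - H(f, a)` from the empirical joint
#' distribution of a discretised feature and a binary annotation.  The
#' value is clamped at 0 to absorb floating-point round-off.
#'
#' @param f_disc Discrete codes (any integer/factor-like vector).
#' @param labels Annotation vector of the same length, two classes.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(f_disc, labels) {
  if (length(f_disc) != length(labels)) {
    abort("`f_disc` and `labels` must have the same length.")
  }
  joint <- table(f_disc, labels)
  n <- sum(joint)
  h_f <- entropy_bits(rowSums(joint))
  h_a <- entropy_bits(colSums(joint))
  h_fa <- entropy_bits(as.vector(joint))
  max(h_f + h_a - h_fa, 0)
}

#' Rank features by relevance to an annotation
#'
#' Computes the mutual information between each (equal-frequency
#' discretised) feature column and the binary annotation and orders the
#' features by decreasing relevance; ties are broken by ascending column
#' position.
#'
#' @param features Feature tibble (`sample_id` plus numeric columns),
#'   normally z-scored.
#' @param labels Vector in \{1, -1\} over the rows.
#' @param n_bins Discretisation bins for the mutual-information estimate.
#' @return Tibble (`feature`, `column`, `mi_bits`) sorted by decreasing
#'   `mi_bits`.
#' @export
rank_features <- function(features, labels, n_bins = 8L) {
  cols <- feature_columns(features)
  mi <- vapply(cols, function(f) {
    mutual_information(discretize(features[[f]], n_bins), labels)
  }, numeric(1))
  tibble(feature = cols, column = seq_along(cols), mi_bits = unname(mi)) |>
    arrange(desc(.data$mi_bits), .data$column)
}

# Per-step fold seed: a distinct, reproducible stream per CV execution,
# kept below 2^31.
fold_seed <- function(seed, step) {
  (as.integer(seed) * 1009L + as.integer(step)) %% 2147483647L
}

# Stratified fold assignment, reproducible from the seed: within each
# class, indices are shuffled and dealt round-robin over k folds.
make_cv_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        abort(sprintf(
          "class %s has %d samples, fewer than the %d folds.",
          format(cls), length(idx), k))
      }
      fold[idx] <- rep(seq_len(k), length.out = length(idx))[
        order(runif(length(idx)))]
    }
  })
  fold
}

svm_fit <- function(x, y) {
  e1071::svm(x = x, y = factor(y, levels = c(-1, 1)), kernel = "radial",
             cost = 1, gamma = 1 / ncol(x), scale = FALSE)
}

#' Pooled k-fold cross-validated SVM accuracy
#'
#' Trains a Gaussian-kernel SVM (`cost = 1`, `gamma = 1/d`, no re-scaling)
#' on k-1 folds and classifies the held-out fold; accuracy is pooled over
#' folds as `(TP + TN) / N`.  Folds are stratified by class and fully
#' determined by `seed`.
#'
#' @param features Feature tibble restricted to the candidate columns (a
#'   `sample_id` column is ignored), or a numeric matrix.
#' @param labels Vector in \{1, -1\}.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return Accuracy `tau` in `[0, 1]`.
#' @export
cv_accuracy <- function(features, labels, k = 5L, seed = 1L) {
  x <- if (is.matrix(features)) features else {
    as.matrix(features[feature_columns(features)])
  }
  if (nrow(x) != length(labels)) {
    abort("`features` and `labels` must have the same number of rows.")
  }
  fold <- make_cv_folds(labels, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- svm_fit(x[tr, , drop = FALSE], labels[tr])
    pred <- predict(model, x[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) ==
                               as.character(labels[!tr]))
  }
  correct / length(labels)
}

#' Forward feature selection gated on cross-validated accuracy
#'
#' Implements the iterative partial max-dependency scheme with equal
#' importance (PmEI): features are ranked once by mutual information with
#' the annotation, the selection starts from the top-ranked feature, and a
#' single pass over the remaining ranking accepts a feature if and only if
#' adding it strictly increases the pooled fivefold cross-validated SVM
#' accuracy.  Accepted features are never revisited or removed.
#'
#' @param features Feature tibble (`sample_id` plus numeric columns),
#'   normally z-scored.
#' @param labels Vector in \{1, -1\}; both classes must be present.
#' @param seed Integer seed (fold assignment).
#' @param n_bins Discretisation bins for the relevance ranking.
#' @param k Cross-validation folds.
#' @return A `pmei_trace` object: `steps` (tibble: feature, mi_bits, tau,
#'   accepted), `selected` (features in acceptance order), `final_tau`,
#'   `ranking`, `seed`.
#' @examples
#' m <- make_feature_label_matrix(label_design(60, 8, informative = 2))
#' tr <- pmei_select(m$features, m$labels, seed = 1)
#' tr$selected
#' @export
pmei_select <- function(features, labels, seed = 1L, n_bins = 8L, k = 5L) {
  if (length(unique(labels)) != 2L) {
    abort("both classes must be present in `labels`.")
  }
  ranking <- rank_features(features, labels, n_bins)
  sel <- ranking$feature[1]
  # the fold split is re-drawn at every CV execution (seeded per step), as
  # in repeated random subsampling; this keeps the accuracy gate honest on
  # uninformative features instead of ratcheting on one fixed split
  tau <- cv_accuracy(features[sel], labels, k, fold_seed(seed, 1L))
  steps <- tibble(feature = sel, mi_bits = ranking$mi_bits[1],
                  tau = tau, accepted = TRUE)
  if (nrow(ranking) > 1L) {
    for (i in seq(2L, nrow(ranking))) {
      cand <- ranking$feature[i]
      tau_i <- cv_accuracy(features[c(sel, cand)], labels, k,
                           fold_seed(seed, i))
      ok <- tau_i > tau
      steps <- dplyr::bind_rows(steps, tibble(
        feature = cand, mi_bits = ranking$mi_bits[i],
        tau = tau_i, accepted = ok))
      if (ok) {
        sel <- c(sel, cand)
        tau <- tau_i
      }
    }
  }
  structure(list(steps = steps, selected = sel, final_tau = tau,
                 ranking = ranking, seed = as.integer(seed), k = k),
            class = "pmei_trace")
}

#' @export
print.pmei_trace <- function(x, ...) {
  cat(sprintf(
    "<pmei_trace> %d/%d features selected, final tau = %.3f\n",
    length(x$selected), nrow(x$steps), x$final_tau))
  invisible(x)
}

#' Ranking values (0-5 scale) for a completed selection
#'
#' Rescales the relevance of the selected features linearly so that the
#' most relevant selected feature scores 5 and the least relevant scores 1
#' (all 5 when they tie); unselected features score 0, meaning the feature
#' is not mapped to the term.
#'
#' @param trace A [pmei_select()] result.
#' @return Tibble (`feature`, `mi_bits`, `selected`, `ranking_value`)
#'   covering every candidate feature.
#' @export
ranking_values <- function(trace) {
  stopifnot(inherits(trace, "pmei_trace"))
  rk <- trace$ranking
  sel <- rk$feature %in% trace$selected
  rv <- numeric(nrow(rk))
  if (any(sel)) {
    r <- rk$mi_bits[sel]
    rv[sel] <- if (max(r) > min(r)) {
      1 + 4 * (r - min(r)) / (max(r) - min(r))
    } else 5
  }
  tibble(feature = rk$feature, mi_bits = rk$mi_bits, selected = sel,
         ranking_value = rv)
}
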