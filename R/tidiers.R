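# broom-style tidiers and autoplot methods for the package's result types.

#' Tidy a forward-selection trace
#'
#' @param x A `pmei_trace`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated candidate (`step`, `feature`,
#'   `mi_bits`, `tau`, `accepted`).
#' @export
tidy.pmei_trace <- function(x, ...) {
  mutate(x$steps, step = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.pmei_trace
#' @export
glance.pmei_trace <- function(x, ...) {
  tibble(n_candidates = nrow(x$steps), n_selected = length(x$selected),
         final_tau = x$final_tau, seed = x$seed)
}

#' Tidy a similar-lesion counting result
#'
#' @param x A `multiplicity_result`.
#' @param ... Unused.
#' @return Tibble with one row per candidate cluster.
#' @export
tidy.multiplicity_result <- function(x, ...) x$clusters

#' @rdname tidy.multiplicity_result
#' @export
glance.multiplicity_result <- function(x, ...) {
  tibble(count = x$count, t_star = x$t_star, lambda = x$lambda,
         n_candidates = nrow(x$clusters),
         similarity_threshold = x$similarity_threshold)
}

#' Tidy a trained model bundle
#'
#' @param x A `vst_model_bundle`.
#' @param ... Unused.
#' @return The feature-to-term [mapping_report()].
#' @export
tidy.vst_model_bundle <- function(x, ...) mapping_report(x)

#' @rdname tidy.vst_model_bundle
#' @export
glance.vst_model_bundle <- function(x, ...) {
  sizes <- vapply(x$models, function(m) length(m$selected), numeric(1))
  taus <- vapply(x$models, function(m) m$final_tau, numeric(1))
  tibble(n_terms = length(x$models),
         mean_selected = if (length(sizes)) mean(sizes) else NA_real_,
         mean_tau = if (length(taus)) mean(taus) else NA_real_,
         n_features = x$n_features)
}

#' Plot the accuracy trace of a forward selection
#'
#' @param object A `pmei_trace`.
#' @param ... Unused.
#' @return A ggplot: pooled CV accuracy per evaluated candidate, accepted
#'   steps highlighted.
#' @export
autoplot.pmei_trace <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$tau)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "candidate (relevance order)",
                  y = "pooled CV accuracy", colour = "accepted") +
    ggplot2::theme_minimal()
}

#' Plot a feature-to-term mapping
#'
#' @param object A `vst_mapping` tibble from [mapping_report()].
#' @param ... Unused.
#' @return A ggplot: 0-5 ranking values of the selected features, one
#'   facet per term.
#' @export
autoplot.vst_mapping <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$ranking_value),
                               y = .data$ranking_value,
                               fill = .data$vst)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$vst), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ranking value (0-5)") +
    ggplot2::ylim(0, 5) +
    ggplot2::theme_minimal()
}

#' Plot a similar-lesion counting result
#'
#' @param object A `multiplicity_result`.
#' @param img The [lesion_image()] the result was computed from.
#' @param ... Unused.
#' @return A ggplot: the slice as a raster with candidate clusters marked
#'   at their centroids (accepted in blue, rejected in red).
#' @export
autoplot.multiplicity_result <- function(object, img, ...) {
  px <- img$pixels
  d <- tibble(row = rep(seq_len(nrow(px)), ncol(px)),
              col = rep(seq_len(ncol(px)), each = nrow(px)),
              value = as.vector(px))
  cent <- purrr::map_dfr(seq_along(object$cluster_pixels), function(i) {
    cp <- object$cluster_pixels[[i]]
    tibble(row = mean(cp[, 1]), col = mean(cp[, 2]),
           accepted = object$clusters$accepted[i])
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "HU") +
    ggplot2::theme_void()
  if (nrow(cent)) {
    p <- p + ggplot2::geom_point(
      data = cent,
      ggplot2::aes(colour = .data$accepted), shape = 1, size = 4,
      stroke = 1.2) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                              `FALSE` = "#b2182b"))
  }
  p
}
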