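# End-to-end prediction pipeline and the complex_thresh sweep experiment.

#' Predict protein complexes from a static network and expression data
#'
#' Runs the full two-phase pipeline: build the dynamic network
#' ([build_dynamic_network()]), predict candidate complexes from every
#' active subnetwork ([predict_candidates()]), drop candidates below the
#' minimum size, and resolve overlaps ([filter_overlaps()]). Fully
#' deterministic for fixed inputs.
#'
#' @inheritParams build_dynamic_network
#' @param complex_thresh Seed/density threshold in `[0, 1]`; default 0.1.
#' @param attach_thresh Attachment threshold; defaults to `complex_thresh`.
#' @param overlap_thresh Overlap-removal threshold; default `2/3`.
#' @param min_size Minimum reported complex size; default 2 (a bare seed
#'   edge with no admissible neighbour still counts as a complex).
#' @param overlap_method Overlap measure, see [overlap_degree()].
#' @return A `complex_set` of predicted complexes with their originating
#'   time points and densities.
#' @export
predict_complexes <- function(network, expr, pre_thresh = 0.5,
                              complex_thresh = 0.1,
                              attach_thresh = complex_thresh,
                              overlap_thresh = 2 / 3, min_size = 2,
                              window = c("cyclic", "truncate"),
                              constant_row_policy = c("faithful", "zero"),
                              transform = c("abs", "shift"),
                              overlap_method = c("affinity", "min"),
                              quiet = TRUE) {
  dyn <- build_dynamic_network(network, expr, pre_thresh = pre_thresh,
                               window = window,
                               constant_row_policy = constant_row_policy,
                               transform = transform, quiet = quiet)
  predict_from_dynamic(dyn, complex_thresh = complex_thresh,
                       attach_thresh = attach_thresh,
                       overlap_thresh = overlap_thresh, min_size = min_size,
                       overlap_method = overlap_method)
}

#' Predict complexes from a prebuilt dynamic network
#'
#' Second phase of [predict_complexes()]; useful when several parameter
#' settings are explored on one dynamic network (see
#' [sweep_complex_thresh()]).
#'
#' @inheritParams predict_complexes
#' @param dyn A `dynamic_network`.
#' @return A `complex_set`.
#' @export
predict_from_dynamic <- function(dyn, complex_thresh = 0.1,
                                 attach_thresh = complex_thresh,
                                 overlap_thresh = 2 / 3, min_size = 2,
                                 overlap_method = c("affinity", "min")) {
  overlap_method <- match.arg(overlap_method)
  cand <- predict_candidates(dyn, complex_thresh = complex_thresh,
                             attach_thresh = attach_thresh)
  cand <- cand[cand$size >= min_size, ]
  filter_overlaps(cand, overlap_thresh = overlap_thresh,
                  overlap_method = overlap_method)
}

#' Sweep the complex threshold and evaluate each setting
#'
#' Rebuilds nothing per step: the dynamic network is constructed once and
#' prediction plus evaluation is repeated for every grid value of
#' `complex_thresh`. When a benchmark is supplied the output mirrors the
#' usual parameter-study table (threshold, number of complexes, precision,
#' recall, F-score, Sn, PPV, Acc).
#'
#' @inheritParams predict_complexes
#' @param benchmark Optional benchmark `complex_set`; without it only the
#'   complex counts are reported.
#' @param thresholds Numeric grid of `complex_thresh` values; default
#'   `seq(0, 1, by = 0.1)`.
#' @param na_thresh Neighbourhood-affinity match threshold; default 0.2.
#' @return A `complex_sweep` tibble with one row per threshold.
#' @export
sweep_complex_thresh <- function(network, expr, benchmark = NULL,
                                 thresholds = seq(0, 1, by = 0.1),
                                 pre_thresh = 0.5,
                                 overlap_thresh = 2 / 3, min_size = 2,
                                 na_thresh = 0.2,
                                 window = c("cyclic", "truncate"),
                                 quiet = TRUE) {
  dyn <- build_dynamic_network(network, expr, pre_thresh = pre_thresh,
                               window = window, quiet = quiet)
  rows <- purrr::map(thresholds, function(th) {
    pred <- predict_from_dynamic(dyn, complex_thresh = th,
                                 overlap_thresh = overlap_thresh,
                                 min_size = min_size)
    row <- tibble(complex_thresh = th, n_complexes = nrow(pred))
    if (!is.null(benchmark)) {
      ev <- suppressWarnings(
        evaluate_complexes(pred, benchmark, na_thresh = na_thresh)
      )
      row <- dplyr::bind_cols(row, glance(ev)[c("precision", "recall",
                                                "f_score", "sn", "ppv",
                                                "acc")])
    }
    row
  })
  out <- bind_rows(rows)
  structure(out, class = c("complex_sweep", class(as_tibble(out))))
}

#' Plot a threshold sweep
#'
#' @param object A `complex_sweep` from [sweep_complex_thresh()].
#' @param ... Unused.
#' @return A ggplot of the evaluation metrics (or complex counts) against
#'   the complex threshold.
#' @exportS3Method ggplot2::autoplot
autoplot.complex_sweep <- function(object, ...) {
  df <- as_tibble(object)
  metric_cols <- intersect(c("precision", "recall", "f_score", "acc"),
                           names(df))
  if (length(metric_cols) > 0) {
    long <- tidyr::pivot_longer(df[c("complex_thresh", metric_cols)],
                                -"complex_thresh", names_to = "metric")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$complex_thresh,
                                       y = .data$value,
                                       colour = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Complex threshold", y = "Score",
                    title = "Effect of the complex threshold") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$complex_thresh,
                                     y = .data$n_complexes)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Complex threshold", y = "Predicted complexes") +
      ggplot2::theme_minimal()
  }
}
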