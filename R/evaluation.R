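# Matching predicted complexes to a benchmark catalogue and the six
# standard quality metrics.

#' Neighbourhood affinity between two complexes
#'
#' `|a ∩ b|^2 / (|a| * |b|)` on the protein sets: 1 when the complexes have
#' identical membership, 0 when they share no protein. A predicted/benchmark
#' pair is conventionally considered a match when the affinity exceeds 0.2.
#'
#' @param a,b Non-empty character vectors of protein identifiers.
#' @return Affinity in `[0, 1]`.
#' @examples
#' neighborhood_affinity(c("a", "b", "c", "d"), c("a", "b", "c", "e", "f"))
#' @export
neighborhood_affinity <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) {
    abort("Neighbourhood affinity needs non-empty sets.",
          class = "dynppi_domain_error")
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

members_list <- function(x) {
  if (is.data.frame(x)) {
    lapply(complex_set(x)$members, identity)
  } else {
    lapply(x, function(m) unique(as.character(m)))
  }
}

# affinity matrix (predicted x benchmark); NULL-safe for empty sides
affinity_matrix <- function(pred, bench) {
  outer(seq_along(pred), seq_along(bench),
        Vectorize(function(i, j) neighborhood_affinity(pred[[i]],
                                                       bench[[j]])))
}

#' Precision, recall and F-score of a predicted complex set
#'
#' A predicted and a benchmark complex match when their
#' [neighborhood_affinity()] is strictly greater than `na_thresh`. Precision
#' is the fraction of predicted complexes matching at least one benchmark
#' complex, recall the fraction of benchmark complexes matched at least
#' once, and the F-score their harmonic mean (0 when both are 0).
#'
#' @param predicted,benchmark `complex_set`s (or lists of protein vectors).
#' @param na_thresh Match threshold; default 0.2 (strict `>`).
#' @return One-row tibble: `n_ci`, `n_cb`, `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(predicted, benchmark, na_thresh = 0.2) {
  pred <- members_list(predicted)
  bench <- members_list(benchmark)
  if (length(pred) == 0) {
    warn("Empty predicted set; precision defined as 0.")
    return(tibble(n_ci = 0L, n_cb = 0L, precision = 0, recall = 0,
                  f_score = 0))
  }
  na_mat <- affinity_matrix(pred, bench)
  match_mat <- na_mat > na_thresh
  n_ci <- sum(apply(match_mat, 1, any))
  n_cb <- if (length(bench) > 0) sum(apply(match_mat, 2, any)) else 0L
  precision <- n_ci / length(pred)
  recall <- if (length(bench) > 0) n_cb / length(bench) else 0
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(n_ci = as.integer(n_ci), n_cb = as.integer(n_cb),
         precision = precision, recall = recall, f_score = f)
}

#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' With `T_ij = |benchmark_i ∩ predicted_j|`: Sn sums, over benchmark
#' complexes, the best coverage by any prediction, normalised by total
#' benchmark size; PPV sums, over predicted complexes, the largest single
#' benchmark contribution, normalised by each prediction's total overlap
#' with the benchmark. Predicted complexes sharing no protein with any
#' benchmark complex are excluded from both PPV sums (otherwise fully novel
#' predictions would be impossible to score). Acc is the geometric mean
#' `sqrt(Sn * PPV)`.
#'
#' @inheritParams precision_recall_f
#' @return One-row tibble: `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(predicted, benchmark) {
  pred <- members_list(predicted)
  bench <- members_list(benchmark)
  if (length(bench) == 0) {
    abort("Benchmark set must be non-empty.", class = "dynppi_domain_error")
  }
  if (length(pred) == 0) {
    return(tibble(sn = 0, ppv = 0, acc = 0))
  }
  t_mat <- outer(seq_along(bench), seq_along(pred),
                 Vectorize(function(i, j) {
                   length(intersect(bench[[i]], pred[[j]]))
                 }))
  sn <- sum(apply(t_mat, 1, max)) / sum(lengths(bench))
  col_tot <- colSums(t_mat)
  scored <- col_tot > 0
  ppv <- if (any(scored)) {
    sum(apply(t_mat[, scored, drop = FALSE], 2, max)) / sum(col_tot[scored])
  } else {
    0
  }
  tibble(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Evaluate predicted complexes against a benchmark
#'
#' Aggregates [precision_recall_f()] and [sn_ppv_acc()] with the underlying
#' match table into a single evaluation object with [tidy()] / [glance()]
#' methods.
#'
#' @inheritParams precision_recall_f
#' @return A `complex_eval` object: counts, the six metrics, and the sparse
#'   table of affinity scores (`pairs`, entries with affinity > 0).
#' @export
evaluate_complexes <- function(predicted, benchmark, na_thresh = 0.2) {
  pred <- members_list(predicted)
  bench <- members_list(benchmark)
  prf <- precision_recall_f(pred, bench, na_thresh = na_thresh)
  spa <- if (length(bench) > 0) {
    sn_ppv_acc(pred, bench)
  } else {
    tibble(sn = 0, ppv = 0, acc = 0)
  }
  pairs <- tibble(predicted_id = integer(0), benchmark_id = integer(0),
                  affinity = numeric(0))
  if (length(pred) > 0 && length(bench) > 0) {
    na_mat <- affinity_matrix(pred, bench)
    hit <- which(na_mat > 0, arr.ind = TRUE)
    pairs <- tibble(predicted_id = as.integer(hit[, 1]),
                    benchmark_id = as.integer(hit[, 2]),
                    affinity = na_mat[hit])
    pairs <- dplyr::arrange(pairs, .data$predicted_id,
                            dplyr::desc(.data$affinity))
  }
  structure(
    list(n_predicted = length(pred), n_benchmark = length(bench),
         n_ci = prf$n_ci, n_cb = prf$n_cb, precision = prf$precision,
         recall = prf$recall, f_score = prf$f_score, sn = spa$sn,
         ppv = spa$ppv, acc = spa$acc, na_thresh = na_thresh, pairs = pairs),
    class = "complex_eval"
  )
}

#' @export
print.complex_eval <- function(x, ...) {
  cat("Complex prediction evaluation (match: affinity > ", x$na_thresh,
      ")\n", sep = "")
  cat("  predicted: ", x$n_predicted, " (matched ", x$n_ci, ")",
      "   benchmark: ", x$n_benchmark, " (matched ", x$n_cb, ")\n", sep = "")
  cat(sprintf("  P = %.3f  R = %.3f  F = %.3f  Sn = %.3f  PPV = %.3f  Acc = %.3f\n",
              x$precision, x$recall, x$f_score, x$sn, x$ppv, x$acc))
  invisible(x)
}

#' Per-pair match table of an evaluation
#'
#' @param x A `complex_eval`.
#' @param ... Unused.
#' @return Tibble of predicted/benchmark pairs with positive affinity and a
#'   `matched` flag (affinity above the match threshold).
#' @exportS3Method generics::tidy
tidy.complex_eval <- function(x, ...) {
  dplyr::mutate(x$pairs, matched = .data$affinity > x$na_thresh)
}

#' One-row metric summary of an evaluation
#'
#' Columns follow the usual report layout: number of predicted complexes,
#' precision, recall, F-score, Sn, PPV, Acc, plus the match counts.
#'
#' @param x A `complex_eval`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.complex_eval <- function(x, ...) {
  tibble(n_complexes = x$n_predicted, precision = x$precision,
         recall = x$recall, f_score = x$f_score, sn = x$sn, ppv = x$ppv,
         acc = x$acc, n_ci = x$n_ci, n_cb = x$n_cb,
         n_benchmark = x$n_benchmark, na_thresh = x$na_thresh)
}

#' Write an evaluation report as a one-row TSV
#'
#' @param eval A `complex_eval`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return The evaluation, invisibly.
#' @export
write_eval_report <- function(eval, path, header = NULL) {
  g <- glance(eval)[c("n_complexes", "precision", "recall", "f_score",
                      "sn", "ppv", "acc")]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("#Complexes", "P", "R", "F", "Sn", "PPV", "Acc"),
                   collapse = "\t"), con)
  writeLines(paste(c(g$n_complexes, sprintf("%.6g", as.numeric(g[-1]))),
                   collapse = "\t"), con)
  invisible(eval)
}

#' Plot evaluation affinity profile
#'
#' @param object A `complex_eval`.
#' @param ... Unused.
#' @return A ggplot histogram of best-match affinities per predicted
#'   complex, with the match threshold marked.
#' @exportS3Method ggplot2::autoplot
autoplot.complex_eval <- function(object, ...) {
  best <- dplyr::summarise(dplyr::group_by(object$pairs, .data$predicted_id),
                           affinity = max(.data$affinity), .groups = "drop")
  ggplot2::ggplot(best, ggplot2::aes(x = .data$affinity)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$na_thresh, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "Best neighbourhood affinity", y = "Predicted complexes",
                  title = "Match quality against the benchmark") +
    ggplot2::theme_minimal()
}
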