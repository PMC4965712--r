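# Windowed co-expression: short-window Pearson correlation around each time
# point, thresholded to keep only convincing co-expression.

window_indices <- function(i, n_tp, window = c("cyclic", "truncate")) {
  window <- match.arg(window)
  idx <- c(i - 1, i, i + 1)
  if (window == "cyclic") {
    ((idx - 1) %% n_tp) + 1
  } else {
    idx[idx >= 1 & idx <= n_tp]
  }
}

#' Windowed Pearson correlation of two expression profiles
#'
#' Correlates the two profiles over a three-point window centred on time
#' point `i` (points `i - 1`, `i`, `i + 1`). At the series boundaries the
#' window either wraps cyclically (default; appropriate for periodic designs
#' such as cell-cycle time courses) or truncates to the two available points.
#' The default `"abs"` transform returns the absolute correlation, mapping it
#' into `[0, 1]`; `"shift"` returns `(r + 1)/2` for sensitivity analyses.
#' Windows with zero variance in either profile return 0 (no evidence of
#' co-expression).
#'
#' @param x,y Numeric expression profiles of equal length (`>= 3`).
#' @param i Time-point index of the window centre.
#' @param window `"cyclic"` (default) or `"truncate"` boundary handling.
#' @param transform `"abs"` (default) or `"shift"` mapping of `r` to `[0,1]`.
#' @return A correlation value in `[0, 1]`.
#' @examples
#' windowed_pearson(c(1, 2, 4), c(1, 3, 3), i = 2)
#' @export
windowed_pearson <- function(x, y, i, window = c("cyclic", "truncate"),
                             transform = c("abs", "shift")) {
  window <- match.arg(window)
  transform <- match.arg(transform)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n_tp <- length(x)
  if (length(y) != n_tp) {
    abort("Profiles must have equal length.", class = "dynppi_domain_error")
  }
  if (n_tp < 3) {
    abort("Windowed correlation needs at least 3 time points.",
          class = "dynppi_domain_error")
  }
  if (i < 1 || i > n_tp) {
    abort("Window centre out of range.", class = "dynppi_domain_error")
  }
  idx <- window_indices(i, n_tp, window)
  xw <- x[idx] - mean(x[idx])
  yw <- y[idx] - mean(y[idx])
  sx <- sum(xw^2)
  sy <- sum(yw^2)
  if (sx == 0 || sy == 0) {
    return(0)
  }
  r <- sum(xw * yw) / sqrt(sx * sy)
  if (transform == "abs") abs(r) else (r + 1) / 2
}

#' Thresholded co-expression weight
#'
#' Keeps a windowed correlation only when it reaches the predefined
#' co-expression threshold (boundary inclusive); smaller values are zeroed.
#'
#' @param r_abs Correlation magnitude in `[0, 1]` (vectorised).
#' @param pre_thresh Co-expression threshold in `[0, 1]`; default 0.5.
#' @return `r_abs` where `r_abs >= pre_thresh`, else 0.
#' @export
coexpression_weight <- function(r_abs, pre_thresh = 0.5) {
  ifelse(r_abs >= pre_thresh, r_abs, 0)
}

#' Activity weight of an interaction
#'
#' The activity component of an edge weight is the product of its endpoints'
#' active probabilities (the edge entry of the outer product of the activity
#' vector with itself).
#'
#' @param pr_u,pr_v Activity levels in `{0, 0.68, 0.95, 0.99}` (vectorised).
#' @return `pr_u * pr_v`.
#' @export
activity_edge_weight <- function(pr_u, pr_v) {
  pr_u * pr_v
}
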