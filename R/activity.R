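# Protein activity from expression profiles: damped k-sigma thresholds and
# the four-level active probability.

#' Damped k-sigma activity threshold
#'
#' The activity threshold of a gene is its profile mean plus `k` standard
#' deviations, damped by a factor `1 - 1/(1 + sd^2)` so that flat, low-noise
#' profiles (small sd) get thresholds close to their mean rather than being
#' filtered out entirely:
#' `thresh_k = mean + k * sd * (1 - 1/(1 + sd^2))`.
#'
#' @param mean Arithmetic mean of the profile (vectorised).
#' @param sd Standard deviation of the profile, `>= 0`.
#' @param k Sigma multiplier; one of 1, 2, 3.
#' @return Numeric threshold(s).
#' @examples
#' sigma_threshold(10, 2, k = 3) # 14.8
#' @export
sigma_threshold <- function(mean, sd, k) {
  if (length(k) != 1 || !k %in% c(1, 2, 3)) {
    abort("`k` must be 1, 2 or 3.", class = "dynppi_domain_error")
  }
  if (any(sd < 0)) {
    abort("`sd` must be non-negative.", class = "dynppi_domain_error")
  }
  mean + k * sd * (1 - 1 / (1 + sd^2))
}

#' Normal-coverage rationale for the activity levels
#'
#' The three graded activity probabilities (0.68, 0.95, 0.99) are rounded
#' normal-distribution coverage probabilities `P(|X - mean| < k sd) =
#' 2 * pnorm(k) - 1` for k = 1, 2, 3 (0.6827, 0.9545, 0.9973 — the familiar
#' "68-95-99.7" rule).
#'
#' @param k Sigma multiplier (vectorised).
#' @return Coverage probability `2 * pnorm(k) - 1`.
#' @examples
#' round(sigma_coverage(1:3), 4)
#' @export
sigma_coverage <- function(k) {
  2 * stats::pnorm(k) - 1
}

# the four graded activity levels, highest tier first
activity_levels <- c(0.99, 0.95, 0.68, 0)

#' Four-level active probability of one expression profile
#'
#' Grades each time point of a profile by comparing its value against the
#' profile's own damped 1/2/3-sigma thresholds: `0.99` for values at or above
#' the 3-sigma threshold, `0.95` and `0.68` for the 2- and 1-sigma bands, and
#' `0` below the 1-sigma threshold. Comparisons are inclusive at the lower
#' edge of each band, so a constant profile (sd = 0, all thresholds equal to
#' the mean) scores 0.99 everywhere under the default `"faithful"` policy;
#' `constant_row_policy = "zero"` instead marks constant profiles inactive.
#'
#' @param profile Numeric vector: one gene's expression across time points.
#' @param constant_row_policy `"faithful"` (default) or `"zero"`.
#' @return Numeric vector of the same length with values in
#'   `{0, 0.68, 0.95, 0.99}`.
#' @export
active_probability <- function(profile,
                               constant_row_policy = c("faithful", "zero")) {
  constant_row_policy <- match.arg(constant_row_policy)
  profile <- as.numeric(profile)
  if (any(!is.finite(profile))) {
    abort("Expression profile must be finite.", class = "dynppi_domain_error")
  }
  m <- mean(profile)
  s <- stats::sd(profile)
  if (s == 0 && constant_row_policy == "zero") {
    return(rep(0, length(profile)))
  }
  t1 <- sigma_threshold(m, s, 1)
  t2 <- sigma_threshold(m, s, 2)
  t3 <- sigma_threshold(m, s, 3)
  ifelse(profile >= t3, 0.99,
         ifelse(profile >= t2, 0.95,
                ifelse(profile >= t1, 0.68, 0)))
}

#' Per-gene activity statistics
#'
#' @param expr An `expression_matrix` (see [as_expression_matrix()]).
#' @return A tibble with one row per gene: `gene`, `mean`, `sd` and the three
#'   damped sigma thresholds `thresh_1`, `thresh_2`, `thresh_3`.
#' @export
activity_profile <- function(expr) {
  vals <- expr_values(as_expression_matrix(expr))
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  tibble(
    gene = rownames(vals),
    mean = m,
    sd = s,
    thresh_1 = sigma_threshold(m, s, 1),
    thresh_2 = sigma_threshold(m, s, 2),
    thresh_3 = sigma_threshold(m, s, 3)
  )
}

#' Activity matrix of an expression matrix
#'
#' Applies [active_probability()] to every gene.
#'
#' @inheritParams activity_profile
#' @inheritParams active_probability
#' @return A tibble shaped like `expr` (gene column plus one column per time
#'   point) holding activity levels in `{0, 0.68, 0.95, 0.99}`.
#' @export
activity_matrix <- function(expr,
                            constant_row_policy = c("faithful", "zero")) {
  constant_row_policy <- match.arg(constant_row_policy)
  expr <- as_expression_matrix(expr)
  vals <- expr_values(expr)
  n_const <- sum(apply(vals, 1, stats::sd) == 0)
  if (n_const > 0) {
    inform(paste0(n_const, " constant expression row(s); policy '",
                  constant_row_policy, "' applied."))
  }
  act <- t(apply(vals, 1, active_probability,
                 constant_row_policy = constant_row_policy))
  colnames(act) <- colnames(vals)
  dplyr::bind_cols(tibble(gene = rownames(vals)), as_tibble(act))
}
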