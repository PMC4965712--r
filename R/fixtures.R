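# Deterministic synthetic data with known ground truth: planted co-expressed
# near-clique complexes on a background of sinusoidally expressed proteins
# with sparse random interactions.

#' Specification for a synthetic fixture
#'
#' Defines the generative conditions: each planted complex is a near-clique
#' (every intra-complex edge kept with probability `intra_density`, with
#' isolated members re-connected) whose member genes share one expression
#' peak of height `peak_height * noise_sd` above baseline at the complex's
#' active time point; background proteins follow a sinusoid with random
#' phase plus Gaussian noise and are wired among themselves with sparse
#' random edges. The peak height of 3.5 noise-sd units makes planted members
#' exceed their own damped 3-sigma threshold at the planted time point with
#' probability above 0.99.
#'
#' @param n_timepoints Number of time points per cycle; default 12.
#' @param complex_sizes Planted complex sizes (all `>= 3`); default ten
#'   complexes of sizes 3-8.
#' @param active_timepoints Optional integer vector assigning each complex
#'   its active time point; sampled uniformly when `NULL`.
#' @param intra_density Probability of keeping each intra-complex edge;
#'   default 0.9.
#' @param n_background Number of background proteins; default 100.
#' @param background_edge_prob Background edge probability; default 0.02.
#' @param baseline Baseline expression level; default 5.
#' @param noise_sd Gaussian noise sd (expression units); default 0.3.
#' @param peak_height Planted peak height in noise-sd units; default 3.5.
#' @param background_amplitude Background sinusoid amplitude; default 1.
#' @param allow_overlap Allow planted complexes to share proteins (only
#'   relevant when memberships are supplied explicitly); default FALSE.
#' @param seed Integer seed driving the whole generator; default 42.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_timepoints = 12,
                         complex_sizes = c(3, 4, 4, 5, 5, 6, 6, 7, 7, 8),
                         active_timepoints = NULL,
                         intra_density = 0.9,
                         n_background = 100,
                         background_edge_prob = 0.02,
                         baseline = 5,
                         noise_sd = 0.3,
                         peak_height = 3.5,
                         background_amplitude = 1,
                         allow_overlap = FALSE,
                         seed = 42) {
  if (any(complex_sizes < 3)) {
    abort("Planted complex sizes must be >= 3.",
          class = "dynppi_domain_error")
  }
  if (n_timepoints < 3) {
    abort("Need at least 3 time points.", class = "dynppi_domain_error")
  }
  if (!is.null(active_timepoints) &&
      (length(active_timepoints) != length(complex_sizes) ||
       any(active_timepoints < 1 | active_timepoints > n_timepoints))) {
    abort("`active_timepoints` must assign one in-range time point per complex.",
          class = "dynppi_domain_error")
  }
  probs <- c(intra_density, background_edge_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must be in [0, 1].", class = "dynppi_domain_error")
  }
  structure(
    list(n_timepoints = n_timepoints, complex_sizes = complex_sizes,
         active_timepoints = active_timepoints,
         intra_density = intra_density, n_background = n_background,
         background_edge_prob = background_edge_prob, baseline = baseline,
         noise_sd = noise_sd, peak_height = peak_height,
         background_amplitude = background_amplitude,
         allow_overlap = allow_overlap, seed = seed),
    class = "fixture_spec"
  )
}

#' Generate a synthetic fixture
#'
#' Draws a static network, an expression matrix and the ground-truth complex
#' set from a [fixture_spec()]. The single integer seed drives all
#' randomness through an isolated RNG scope, so the same spec always yields
#' byte-identical outputs.
#'
#' @param spec A `fixture_spec`.
#' @return A `ppi_fixture` list: `network` (`ppi_network`), `expression`
#'   (`expression_matrix`), `truth` (`complex_set` with planted time
#'   points), and the `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  n_tp <- spec$n_timepoints
  sizes <- spec$complex_sizes
  n_cx <- length(sizes)

  planted_ids <- sprintf("P%03d", seq_len(sum(sizes)))
  membership <- split(planted_ids, rep(seq_len(n_cx), sizes))
  bg_ids <- if (spec$n_background > 0) {
    sprintf("B%03d", seq_len(spec$n_background))
  } else {
    character(0)
  }

  peaks <- spec$active_timepoints %||% sample(n_tp, n_cx, replace = TRUE)

  # intra-complex near-clique edges; re-connect members left isolated
  edges <- purrr::map(membership, function(m) {
    pairs <- t(utils::combn(m, 2))
    keep <- stats::runif(nrow(pairs)) < spec$intra_density
    kept <- pairs[keep, , drop = FALSE]
    isolated <- setdiff(m, unique(as.vector(kept)))
    for (p in isolated) {
      other <- setdiff(m, p)[1]
      kept <- rbind(kept, c(p, other))
    }
    tibble(protein_a = kept[, 1], protein_b = kept[, 2])
  })
  # sparse random edges among background proteins
  if (length(bg_ids) >= 2) {
    pairs <- t(utils::combn(bg_ids, 2))
    keep <- stats::runif(nrow(pairs)) < spec$background_edge_prob
    edges <- c(edges, list(tibble(protein_a = pairs[keep, 1],
                                  protein_b = pairs[keep, 2])))
  }
  network <- ppi_network(bind_rows(edges))

  # expression: planted = baseline + single peak + noise;
  # background = baseline + sinusoid with random phase + noise
  all_ids <- c(planted_ids, bg_ids)
  vals <- matrix(spec$baseline, nrow = length(all_ids), ncol = n_tp,
                 dimnames = list(all_ids, paste0("T", seq_len(n_tp))))
  for (cx in seq_len(n_cx)) {
    vals[membership[[cx]], peaks[cx]] <-
      vals[membership[[cx]], peaks[cx]] + spec$peak_height * spec$noise_sd
  }
  if (length(bg_ids) > 0) {
    phase <- stats::runif(length(bg_ids), 0, 2 * pi)
    t_grid <- 2 * pi * (seq_len(n_tp) - 1) / n_tp
    vals[bg_ids, ] <- vals[bg_ids, ] +
      spec$background_amplitude * sin(outer(phase, t_grid, "+"))
  }
  vals <- vals + matrix(stats::rnorm(length(vals), sd = spec$noise_sd),
                        nrow = nrow(vals))

  truth <- complex_set(membership,
                       timepoint = paste0("T", peaks))

  structure(list(network = network,
                 expression = as_expression_matrix(round(vals, 6)),
                 truth = truth, spec = spec),
            class = "ppi_fixture")
}

#' @export
print.ppi_fixture <- function(x, ...) {
  cat("# Synthetic PPI fixture: ", nrow(x$truth), " planted complexes, ",
      length(network_proteins(x$network)), " proteins, ",
      nrow(x$network), " edges, ",
      ncol(x$expression) - 1, " time points (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `edges.tsv`, `expr.tsv` and `truth.txt` in standard formats.
#'
#' @param fixture A `ppi_fixture` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @param header Optional comment lines for every file.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir, header = NULL) {
  stopifnot(inherits(fixture, "ppi_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(fixture$network, file.path(dir, "edges.tsv"),
                  header = header)
  write_expression_matrix(fixture$expression, file.path(dir, "expr.tsv"),
                          header = header)
  write_complex_set(fixture$truth, file.path(dir, "truth.txt"),
                    header = header)
  invisible(dir)
}
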