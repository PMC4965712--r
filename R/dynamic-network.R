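# Fusing the static network with activity and co-expression into a dynamic
# (time-resolved, weighted) PPI network: at every time point an edge weight
# is activity(u) * activity(v) * thresholded |windowed Pearson|, evaluated
# only on static edges (element-wise product with the static adjacency).

#' Build a dynamic PPI network
#'
#' For every time point `i` and every static interaction `(u, v)` the
#' subnetwork weight is
#' `Pr_i(u) * Pr_i(v) * coexpression_weight(windowed_pearson(u, v, i))`.
#' Proteins absent from the expression matrix get activity 0 at every time
#' point (identifier matching is exact and case-sensitive), so their edges
#' never enter any subnetwork. Only static edges are evaluated; co-expression
#' is never computed for non-interacting pairs. All weights lie in
#' `[0, 0.99^2) ⊂ [0, 1)`: activity levels cap at 0.99, so no edge can ever
#' reach weight 1.
#'
#' @param network Static PPI network (see [ppi_network()]).
#' @param expr Time-course expression matrix (see [as_expression_matrix()]).
#' @param pre_thresh Co-expression threshold in `[0, 1]`; default 0.5.
#' @param window Window boundary policy, `"cyclic"` (default) or
#'   `"truncate"`; see [windowed_pearson()].
#' @param constant_row_policy Handling of zero-variance expression rows; see
#'   [active_probability()].
#' @param transform Correlation-to-`[0,1]` mapping; see [windowed_pearson()].
#' @param quiet Suppress the per-time-point edge-count message.
#' @return A `dynamic_network` tibble with columns `timepoint`, `protein_a`,
#'   `protein_b`, `weight` (only nonzero-weight edges are stored), plus
#'   attributes `timepoints`, `proteins` and `params`.
#' @export
build_dynamic_network <- function(network, expr, pre_thresh = 0.5,
                                  window = c("cyclic", "truncate"),
                                  constant_row_policy = c("faithful", "zero"),
                                  transform = c("abs", "shift"),
                                  quiet = FALSE) {
  window <- match.arg(window)
  constant_row_policy <- match.arg(constant_row_policy)
  transform <- match.arg(transform)
  if (pre_thresh < 0 || pre_thresh > 1) {
    abort("`pre_thresh` must be in [0, 1].", class = "dynppi_domain_error")
  }
  network <- ppi_network(network)
  expr <- as_expression_matrix(expr)
  vals <- expr_values(expr)
  tps <- colnames(vals)
  n_tp <- ncol(vals)

  proteins <- network_proteins(network)
  missing <- setdiff(proteins, rownames(vals))
  if (length(missing) > 0 && !quiet) {
    inform(paste0(length(missing), " network protein(s) absent from the ",
                  "expression matrix; treated as never active."))
  }

  act <- withCallingHandlers(
    expr_values(activity_matrix(expr,
                                constant_row_policy = constant_row_policy)),
    message = function(m) if (quiet) invokeRestart("muffleMessage")
  )

  # activity per endpoint; edges with a missing endpoint drop out (activity 0)
  a_idx <- match(network$protein_a, rownames(vals))
  b_idx <- match(network$protein_b, rownames(vals))
  present <- !is.na(a_idx) & !is.na(b_idx)

  per_tp <- vector("list", n_tp)
  counts <- integer(n_tp)
  for (i in seq_len(n_tp)) {
    pr_a <- pr_b <- rep(0, nrow(network))
    pr_a[present] <- act[a_idx[present], i]
    pr_b[present] <- act[b_idx[present], i]
    live <- which(pr_a > 0 & pr_b > 0)
    if (length(live) == 0) {
      per_tp[[i]] <- tibble(timepoint = character(0),
                            protein_a = character(0),
                            protein_b = character(0),
                            weight = numeric(0))
      next
    }
    idx <- window_indices(i, n_tp, window)
    xw <- vals[a_idx[live], idx, drop = FALSE]
    yw <- vals[b_idx[live], idx, drop = FALSE]
    xw <- xw - rowMeans(xw)
    yw <- yw - rowMeans(yw)
    sx <- rowSums(xw^2)
    sy <- rowSums(yw^2)
    r <- ifelse(sx == 0 | sy == 0, 0,
                rowSums(xw * yw) / sqrt(pmax(sx * sy, .Machine$double.xmin)))
    r01 <- if (transform == "abs") abs(r) else (r + 1) / 2
    coe <- coexpression_weight(r01, pre_thresh)
    w <- activity_edge_weight(act[a_idx[live], i], act[b_idx[live], i]) * coe
    keep <- w > 0
    counts[i] <- sum(keep)
    per_tp[[i]] <- tibble(
      timepoint = tps[i],
      protein_a = network$protein_a[live][keep],
      protein_b = network$protein_b[live][keep],
      weight = as.numeric(w[keep])
    )
  }
  if (!quiet) {
    inform(paste0("Active edges per time point: ",
                  paste(tps, counts, sep = "=", collapse = ", ")))
  }
  out <- bind_rows(per_tp)
  structure(out,
            class = c("dynamic_network", class(as_tibble(out))),
            timepoints = tps,
            proteins = proteins,
            params = list(pre_thresh = pre_thresh, window = window,
                          constant_row_policy = constant_row_policy,
                          transform = transform))
}

#' Time-point labels of a dynamic network
#' @param dyn A `dynamic_network`.
#' @return Character vector of ordered time-point labels.
#' @export
timepoints <- function(dyn) {
  attr(dyn, "timepoints") %||% unique(dyn$timepoint)
}

#' Extract one active subnetwork
#'
#' @param dyn A `dynamic_network`.
#' @param tp Time-point label.
#' @return Tibble with columns `protein_a`, `protein_b`, `weight`.
#' @export
subnetwork <- function(dyn, tp) {
  if (!tp %in% timepoints(dyn)) {
    abort(paste0("Unknown time point: ", tp), class = "dynppi_domain_error")
  }
  as_tibble(dyn)[dyn$timepoint == tp,
                 c("protein_a", "protein_b", "weight")]
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("# A dynamic PPI network: ", length(timepoints(x)), " time points, ",
      nrow(x), " active edges\n", sep = "")
  NextMethod()
}

#' Per-time-point summary of a dynamic network
#'
#' @param x A `dynamic_network`.
#' @param ... Unused.
#' @return A tibble with one row per time point: number of active edges and
#'   proteins, and mean/max edge weight.
#' @exportS3Method generics::tidy
tidy.dynamic_network <- function(x, ...) {
  tps <- timepoints(x)
  df <- as_tibble(x)
  purrr::map_dfr(tps, function(tp) {
    sub <- df[df$timepoint == tp, ]
    tibble(
      timepoint = tp,
      n_edges = nrow(sub),
      n_proteins = length(unique(c(sub$protein_a, sub$protein_b))),
      mean_weight = if (nrow(sub)) mean(sub$weight) else NA_real_,
      max_weight = if (nrow(sub)) max(sub$weight) else NA_real_
    )
  })
}

#' One-row summary of a dynamic network
#' @param x A `dynamic_network`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.dynamic_network <- function(x, ...) {
  tibble(
    n_timepoints = length(timepoints(x)),
    n_proteins = length(attr(x, "proteins") %||%
                          unique(c(x$protein_a, x$protein_b))),
    n_active_edges = nrow(x),
    pre_thresh = attr(x, "params")$pre_thresh %||% NA_real_
  )
}

#' Plot active-edge counts over time
#'
#' @param object A `dynamic_network`.
#' @param ... Unused.
#' @return A ggplot: active edges per time point.
#' @exportS3Method ggplot2::autoplot
autoplot.dynamic_network <- function(object, ...) {
  df <- tidy.dynamic_network(object)
  df$timepoint <- factor(df$timepoint, levels = timepoints(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$n_edges)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Time point", y = "Active edges",
                  title = "Dynamic PPI network activity") +
    ggplot2::theme_minimal()
}

#' Serialise a dynamic network
#'
#' Writes one TSV per time point (`subnetwork_<tp>.tsv`: protein pair and
#' weight to six decimals), a combined `dynamic_network.tsv` with a
#' time-point column, and a `manifest.tsv` listing time points, edge counts
#' and construction parameters.
#'
#' @param dyn A `dynamic_network`.
#' @param dir Output directory (created if needed).
#' @param header Optional comment lines prepended to every file.
#' @return `dir`, invisibly.
#' @export
write_dynamic_network <- function(dyn, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(w) sprintf("%.6f", w)
  tps <- timepoints(dyn)
  df <- as_tibble(dyn)
  write_one <- function(lines, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    writeLines(lines, con)
  }
  for (tp in tps) {
    sub <- df[df$timepoint == tp, ]
    write_one(c("protein_a\tprotein_b\tweight",
                paste(sub$protein_a, sub$protein_b, fmt(sub$weight),
                      sep = "\t")),
              file.path(dir, paste0("subnetwork_", tp, ".tsv")))
  }
  write_one(c("timepoint\tprotein_a\tprotein_b\tweight",
              paste(df$timepoint, df$protein_a, df$protein_b,
                    fmt(df$weight), sep = "\t")),
            file.path(dir, "dynamic_network.tsv"))
  params <- attr(dyn, "params") %||% list()
  counts <- vapply(tps, function(tp) sum(df$timepoint == tp), integer(1))
  write_one(c("key\tvalue",
              paste(c("timepoints", "n_active_edges",
                      paste0("n_edges_", tps), names(params)),
                    c(paste(tps, collapse = ","), nrow(df), counts,
                      vapply(params, as.character, character(1))),
                    sep = "\t")),
            file.path(dir, "manifest.tsv"))
  invisible(dir)
}
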