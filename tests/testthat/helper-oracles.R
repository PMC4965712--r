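# Shared fixtures and independent oracle implementations used to cross-check
# the package's optimised code paths. Oracles are deliberately written as
# plain, slow loops that follow the defining formulas directly.

# -- small deterministic graphs ---------------------------------------------

# triangle a-b-c (all 0.9) with pendant d on c (0.9): the worked example
# used for core detection
trace_subnetwork <- function() {
  tibble::tibble(
    protein_a = c("a", "a", "b", "c"),
    protein_b = c("b", "c", "c", "d"),
    weight = c(0.9, 0.9, 0.9, 0.9)
  )
}

# random weighted subnetwork on n proteins with edge probability p
random_subnetwork <- function(n, p = 0.5) {
  ids <- sprintf("p%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  tibble::tibble(
    protein_a = pairs[keep, 1],
    protein_b = pairs[keep, 2],
    weight = round(stats::runif(sum(keep), 0.05, 0.98), 3)
  )
}

# random static network + expression matrix for dense-vs-sparse checks
random_network_expression <- function(n_proteins, n_tp = 6, p = 0.5) {
  ids <- sprintf("p%02d", seq_len(n_proteins))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  net <- ppi_network(tibble::tibble(a = pairs[keep, 1], b = pairs[keep, 2]))
  vals <- matrix(stats::rnorm(n_proteins * n_tp, mean = 5, sd = 1.5),
                 nrow = n_proteins,
                 dimnames = list(ids, paste0("T", seq_len(n_tp))))
  list(network = net, expr = as_expression_matrix(round(vals, 4)))
}

# -- dense-matrix oracle for the network fusion -----------------------------

# Full dense computation of every time point's weighted adjacency:
# outer(activity) * thresholded windowed correlation * static adjacency,
# evaluated entry by entry for ALL protein pairs.
dense_dynamic_oracle <- function(network, expr, pre_thresh = 0.5,
                                 window = "cyclic") {
  vals <- as.matrix(expr[-1])
  rownames(vals) <- expr$gene
  ids <- sort(unique(c(network$protein_a, network$protein_b)))
  n <- length(ids)
  n_tp <- ncol(vals)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(network))) {
    adj[network$protein_a[k], network$protein_b[k]] <- 1
    adj[network$protein_b[k], network$protein_a[k]] <- 1
  }
  pr <- matrix(0, n, n_tp, dimnames = list(ids, NULL))
  for (id in intersect(ids, rownames(vals))) {
    pr[id, ] <- active_probability(vals[id, ])
  }
  out <- list()
  for (i in seq_len(n_tp)) {
    act <- outer(pr[, i], pr[, i])
    coe <- matrix(0, n, n, dimnames = list(ids, ids))
    for (u in ids) {
      for (v in ids) {
        if (u < v && u %in% rownames(vals) && v %in% rownames(vals)) {
          r <- windowed_pearson(vals[u, ], vals[v, ], i, window = window)
          coe[u, v] <- coe[v, u] <- coexpression_weight(r, pre_thresh)
        }
      }
    }
    out[[i]] <- act * coe * adj
  }
  names(out) <- colnames(vals)
  out
}

# dynamic_network tibble -> list of dense matrices on the same protein set
sparse_to_dense <- function(dyn, ids) {
  lapply(timepoints(dyn), function(tp) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    sub <- subnetwork(dyn, tp)
    for (k in seq_len(nrow(sub))) {
      m[sub$protein_a[k], sub$protein_b[k]] <- sub$weight[k]
      m[sub$protein_b[k], sub$protein_a[k]] <- sub$weight[k]
    }
    m
  })
}

# -- step-by-step core-growth oracle ----------------------------------------

# Independent re-simulation of one core expansion using only the public
# scoring functions (no incremental sums): returns the grown core and checks
# every admission kept the density at or above the threshold.
oracle_grow_core <- function(sub, seed_pair, complex_thresh) {
  core <- sort(seed_pair)
  proteins <- unique(c(sub$protein_a, sub$protein_b))
  repeat {
    nbs <- Filter(function(v) {
      !(v %in% core) && attach_score(sub, v, core) > 0
    }, proteins)
    if (length(nbs) == 0) break
    scores <- vapply(nbs, function(v) attach_score(sub, v, core), numeric(1))
    nbs <- nbs[order(-scores, nbs)]
    admitted <- FALSE
    for (v in nbs) {
      if (subgraph_density(sub, c(core, v)) >= complex_thresh) {
        core <- c(core, v)
        admitted <- TRUE
        break
      }
    }
    if (!admitted) break
  }
  sort(core)
}

# -- explicit contingency-table oracle for the metrics ----------------------

oracle_metrics <- function(pred, bench, na_thresh = 0.2) {
  np <- length(pred)
  nb <- length(bench)
  t_tab <- matrix(0L, nrow = nb, ncol = np)
  na_tab <- matrix(0, nrow = np, ncol = nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(np)) {
      t_tab[i, j] <- length(intersect(bench[[i]], pred[[j]]))
      na_tab[j, i] <- t_tab[i, j]^2 / (length(pred[[j]]) * length(bench[[i]]))
    }
  }
  n_ci <- sum(sapply(seq_len(np), function(j) any(na_tab[j, ] > na_thresh)))
  n_cb <- sum(sapply(seq_len(nb), function(i) any(na_tab[, i] > na_thresh)))
  precision <- if (np > 0) n_ci / np else 0
  recall <- n_cb / nb
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  sn <- sum(apply(t_tab, 1, max)) / sum(lengths(bench))
  keep <- colSums(t_tab) > 0
  ppv <- if (any(keep)) {
    sum(apply(t_tab[, keep, drop = FALSE], 2, max)) / sum(t_tab[, keep])
  } else {
    0
  }
  list(precision = precision, recall = recall, f_score = f,
       sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# standard recovery fixture used across the suite
standard_fixture <- function() {
  generate_fixture(fixture_spec(seed = 42))
}
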