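# Scores used by the core-attachment clustering: weighted subgraph density,
# attachment score, and the seed-ranking cluster score.

check_subnetwork <- function(sub) {
  sub <- as_tibble(sub)
  need <- c("protein_a", "protein_b", "weight")
  if (!all(need %in% names(sub))) {
    abort("A subnetwork needs columns protein_a, protein_b, weight.",
          class = "dynppi_domain_error")
  }
  sub
}

#' Weighted density of a protein set in a subnetwork
#'
#' Twice the total weight of subnetwork edges among the members, divided by
#' the number of unordered member pairs — the weighted analogue of graph
#' density; 1 only for a complete clique of unit-weight edges.
#'
#' @param subnetwork Tibble with columns `protein_a`, `protein_b`, `weight`
#'   (one active subnetwork, e.g. from [subnetwork()]).
#' @param members Character vector of at least two protein identifiers.
#' @return Density in `[0, 1)` for dynamic-network weights.
#' @examples
#' tri <- tibble::tibble(protein_a = c("a", "a", "b"),
#'                       protein_b = c("b", "c", "c"), weight = 0.9)
#' subgraph_density(tri, c("a", "b", "c")) # 0.9
#' @export
subgraph_density <- function(subnetwork, members) {
  sub <- check_subnetwork(subnetwork)
  members <- unique(as.character(members))
  k <- length(members)
  if (k < 2) {
    abort("Density needs at least two members.", class = "dynppi_domain_error")
  }
  inside <- sub$protein_a %in% members & sub$protein_b %in% members
  2 * sum(sub$weight[inside]) / (k * (k - 1))
}

#' Attachment score of a protein towards a protein set
#'
#' Mean subnetwork edge weight from `v` to the members of the set (absent
#' edges contribute 0). Used to recruit attachment proteins around a core.
#'
#' @inheritParams subgraph_density
#' @param v A protein identifier not in `members`.
#' @return Attachment score in `[0, 1)`.
#' @export
attach_score <- function(subnetwork, v, members) {
  sub <- check_subnetwork(subnetwork)
  members <- unique(as.character(members))
  if (length(members) < 1) {
    abort("`members` must be non-empty.", class = "dynppi_domain_error")
  }
  if (v %in% members) {
    abort("`v` must not be a member of the set.",
          class = "dynppi_domain_error")
  }
  touch <- (sub$protein_a == v & sub$protein_b %in% members) |
    (sub$protein_b == v & sub$protein_a %in% members)
  sum(sub$weight[touch]) / length(members)
}

#' Cluster score of an edge
#'
#' Seed-ranking score of an active edge: its weight scaled by the normalised
#' common-neighbourhood overlap `2 (|N_u ∩ N_v| + 1) / (|N_u| + |N_v|)`,
#' where neighbourhoods are taken in the active subnetwork (`scope =
#' "active"`, default) or optionally in the static network. Because the
#' common-neighbour set excludes `u` and `v` themselves, the topology factor
#' never exceeds 1, so the score is bounded by the edge weight (and hence is
#' always below 1 for dynamic-network weights).
#'
#' @inheritParams subgraph_density
#' @param u,v Endpoints of an edge with nonzero weight in the subnetwork.
#' @param static_network Optional static network; only used when
#'   `scope = "static"`.
#' @param scope `"active"` (default) or `"static"` neighbourhoods.
#' @return Cluster score in `(0, weight(u, v)]`.
#' @export
cluster_score <- function(subnetwork, u, v, static_network = NULL,
                          scope = c("active", "static")) {
  scope <- match.arg(scope)
  sub <- check_subnetwork(subnetwork)
  hit <- (sub$protein_a == pmin(u, v) & sub$protein_b == pmax(u, v))
  if (!any(hit) || sum(sub$weight[hit]) == 0) {
    abort("cluster_score is defined only for active (nonzero-weight) edges.",
          class = "dynppi_domain_error")
  }
  w <- sub$weight[which(hit)[1]]
  adj <- if (scope == "active") {
    build_adjacency(sub)
  } else {
    if (is.null(static_network)) {
      abort("`static_network` is required for scope = 'static'.",
            class = "dynppi_domain_error")
    }
    sn <- ppi_network(static_network)
    sn$weight <- 1
    build_adjacency(sn)
  }
  n_u <- names(adj[[u]])
  n_v <- names(adj[[v]])
  w * 2 * (length(intersect(n_u, n_v)) + 1) / (length(n_u) + length(n_v))
}

# Vectorised cluster scores for all edges of one subnetwork (internal fast
# path used by core detection; neighbourhoods in the active subnetwork).
edge_cluster_scores <- function(sub, adj = build_adjacency(sub)) {
  if (nrow(sub) == 0) {
    return(numeric(0))
  }
  nb <- lapply(adj, names)
  deg <- lengths(nb)
  vapply(seq_len(nrow(sub)), function(i) {
    u <- sub$protein_a[i]
    v <- sub$protein_b[i]
    common <- length(intersect(nb[[u]], nb[[v]]))
    sub$weight[i] * 2 * (common + 1) / (deg[[u]] + deg[[v]])
  }, numeric(1))
}
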