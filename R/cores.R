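# Core detection and attachment: the per-time-point clustering stage.
# Seeds are high-cluster-score edges; each seed greedily grows into a dense
# core; finished cores consume every seed they touch, so cores within one
# time point are pairwise node-disjoint. Attachment proteins are then added
# around each core by attachment score.

#' Detect protein-complex cores in one active subnetwork
#'
#' Every edge whose [cluster_score()] is at least `complex_thresh` becomes a
#' seed. Seeds are processed in descending score order (ties broken
#' lexicographically on the sorted endpoint pair). Each seed initialises a
#' core with its two endpoints, then repeatedly admits the
#' highest-[attach_score()] neighbour of the current core whose admission
#' keeps the core density at or above `complex_thresh` (scores are
#' recomputed after every admission; ties lexicographic). When a core is
#' finished, all remaining seeds sharing at least one protein with it are
#' discarded and its members are excluded from all later growth, so cores
#' are pairwise node-disjoint.
#'
#' @inheritParams subgraph_density
#' @param complex_thresh Seed/density threshold in `[0, 1]`.
#' @return List of character vectors (cores, in creation order).
#' @export
detect_cores <- function(subnetwork, complex_thresh) {
  if (complex_thresh < 0 || complex_thresh > 1) {
    abort("`complex_thresh` must be in [0, 1].", class = "dynppi_domain_error")
  }
  sub <- check_subnetwork(subnetwork)
  sub <- sub[sub$weight > 0, ]
  if (nrow(sub) == 0) {
    return(list())
  }
  adj <- build_adjacency(sub)
  scores <- edge_cluster_scores(sub, adj)
  seed_idx <- which(scores >= complex_thresh)
  if (length(seed_idx) == 0) {
    return(list())
  }
  pair_key <- paste(pmin(sub$protein_a, sub$protein_b),
                    pmax(sub$protein_a, sub$protein_b))
  ord <- seed_idx[order(-scores[seed_idx], pair_key[seed_idx])]
  seeds_a <- sub$protein_a[ord]
  seeds_b <- sub$protein_b[ord]
  alive <- rep(TRUE, length(ord))

  cores <- list()
  consumed <- character(0)
  repeat {
    nxt <- which(alive)
    if (length(nxt) == 0) break
    top <- nxt[1]
    core <- grow_core(c(seeds_a[top], seeds_b[top]), adj, complex_thresh,
                      exclude = consumed)
    cores[[length(cores) + 1]] <- sort(core)
    consumed <- c(consumed, core)
    alive <- alive & !(seeds_a %in% core | seeds_b %in% core)
  }
  cores
}

# Greedy expansion of a seed pair: admit neighbours of the growing core in
# descending attachment-score order while density stays >= complex_thresh.
# Proteins in `exclude` (members of earlier cores) are never admitted, which
# keeps cores within one time point pairwise node-disjoint.
grow_core <- function(core, adj, complex_thresh, exclude = character(0)) {
  in_core_sum <- intra_weight_sum(adj, core)
  repeat {
    nbs <- setdiff(unique(unlist(lapply(core, function(p) names(adj[[p]])),
                                 use.names = FALSE)), c(core, exclude))
    if (length(nbs) == 0) break
    link <- vapply(nbs, function(v) {
      nb <- adj[[v]]
      sum(nb[names(nb) %in% core])
    }, numeric(1))
    ord <- order(-link, nbs) # attach score = link / |core|; same order
    k <- length(core)
    admitted <- FALSE
    for (j in ord) {
      new_density <- 2 * (in_core_sum + link[j]) / ((k + 1) * k)
      if (new_density >= complex_thresh) {
        core <- c(core, nbs[j])
        in_core_sum <- in_core_sum + link[j]
        admitted <- TRUE
        break
      }
    }
    if (!admitted) break
  }
  core
}

#' Add attachment proteins around detected cores
#'
#' For each (node-disjoint) core, every subnetwork protein outside the core
#' whose [attach_score()] towards the core is positive and reaches
#' `attach_thresh` is added as an attachment (a protein with no active
#' interaction to the core is never attached, even at threshold 0). A protein may attach to several cores, so candidate
#' complexes from one time point may overlap; overlaps are resolved later by
#' [filter_overlaps()]. The recorded density is recomputed over the full
#' member set (core plus attachments).
#'
#' @inheritParams subgraph_density
#' @param cores List of character vectors as returned by [detect_cores()].
#' @param attach_thresh Attachment threshold in `[0, 1]`.
#' @param timepoint Optional time-point label stored with each candidate.
#' @return Tibble of candidate complexes: `timepoint`, `core`, `attachments`,
#'   `members` (list-columns), `size`, `density`.
#' @export
attach_to_cores <- function(subnetwork, cores, attach_thresh,
                            timepoint = NA_character_) {
  sub <- check_subnetwork(subnetwork)
  sub <- sub[sub$weight > 0, ]
  adj <- build_adjacency(sub)
  proteins <- names(adj)
  rows <- purrr::map(cores, function(core) {
    outside <- setdiff(proteins, core)
    link <- vapply(outside, function(v) {
      nb <- adj[[v]]
      sum(nb[names(nb) %in% core])
    }, numeric(1))
    # a protein with no active interaction to the core is never an
    # attachment, whatever the threshold
    attached <- outside[link > 0 & link / length(core) >= attach_thresh]
    members <- sort(c(core, attached))
    dens <- if (length(members) >= 2) {
      2 * intra_weight_sum(adj, members) /
        (length(members) * (length(members) - 1))
    } else {
      0
    }
    n_members <- length(members)
    tibble(timepoint = timepoint, core = list(sort(core)),
           attachments = list(sort(attached)), members = list(members),
           size = n_members, density = dens)
  })
  bind_rows(rows)
}

#' Predict candidate complexes from every active subnetwork
#'
#' Runs [detect_cores()] and [attach_to_cores()] on each time point of a
#' dynamic network in turn and pools the candidates, each tagged with its
#' originating time point. Fully deterministic: all orderings are by score
#' with lexicographic tie-breaks.
#'
#' @param dyn A `dynamic_network` from [build_dynamic_network()].
#' @param complex_thresh Seed/density threshold in `[0, 1]`; default 0.1.
#' @param attach_thresh Attachment threshold; defaults to `complex_thresh`.
#' @return Tibble of candidate complexes (see [attach_to_cores()]).
#' @export
predict_candidates <- function(dyn, complex_thresh = 0.1,
                               attach_thresh = complex_thresh) {
  df <- as_tibble(dyn)
  out <- purrr::map(timepoints(dyn), function(tp) {
    sub <- df[df$timepoint == tp, c("protein_a", "protein_b", "weight")]
    cores <- detect_cores(sub, complex_thresh)
    if (length(cores) == 0) {
      return(NULL)
    }
    attach_to_cores(sub, cores, attach_thresh, timepoint = tp)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(timepoint = character(0), core = list(),
                  attachments = list(), members = list(),
                  size = integer(0), density = numeric(0))
  }
  res
}
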