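# Post-processing of pooled candidates: greedy density-ranked selection that
# removes highly overlapping candidates.

#' Overlap degree between two protein sets
#'
#' Squared intersection size over the product of the set sizes — the same
#' functional form as the neighbourhood-affinity match score. 1 for
#' identical sets, 0 for disjoint sets.
#'
#' @param a,b Non-empty character vectors of protein identifiers.
#' @param method `"affinity"` (default, `|a∩b|^2 / (|a| |b|)`) or
#'   `"min"` (`|a∩b| / min(|a|, |b|)`).
#' @return Overlap degree in `[0, 1]`.
#' @export
overlap_degree <- function(a, b, method = c("affinity", "min")) {
  method <- match.arg(method)
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) {
    abort("Overlap degree needs non-empty sets.",
          class = "dynppi_domain_error")
  }
  inter <- length(intersect(a, b))
  if (method == "affinity") {
    inter^2 / (length(a) * length(b))
  } else {
    inter / min(length(a), length(b))
  }
}

#' Filter highly overlapping candidate complexes
#'
#' Greedy selection: the highest-density remaining candidate is kept (ties
#' broken towards the larger complex, then lexicographically on the sorted
#' member tuple) and every remaining candidate whose [overlap_degree()] with
#' it exceeds `overlap_thresh` (strictly) is removed; this repeats until no
#' candidates remain. Exact duplicates of a kept complex are always removed,
#' whatever the threshold. Densities from different time points are compared
#' directly, each computed in its own subnetwork.
#'
#' @param candidates Tibble with list-column `members` and column `density`
#'   (e.g. from [predict_candidates()]); `timepoint` is carried through when
#'   present.
#' @param overlap_thresh Removal threshold in `[0, 1]`; default `2/3`.
#' @param overlap_method Overlap measure, see [overlap_degree()].
#' @return A `complex_set` of the retained complexes.
#' @export
filter_overlaps <- function(candidates, overlap_thresh = 2 / 3,
                            overlap_method = c("affinity", "min")) {
  overlap_method <- match.arg(overlap_method)
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    return(complex_set(list()))
  }
  if (!all(c("members", "density") %in% names(candidates))) {
    abort("Candidates need `members` and `density` columns.",
          class = "dynppi_domain_error")
  }
  members <- lapply(candidates$members, function(m) sort(unique(m)))
  keys <- vapply(members, members_key, character(1))
  ord <- order(-candidates$density, -lengths(members), keys)

  kept <- integer(0)
  alive <- rep(TRUE, length(ord))
  for (pos in seq_along(ord)) {
    if (!alive[pos]) next
    i <- ord[pos]
    kept <- c(kept, i)
    alive[pos] <- FALSE
    rest <- which(alive)
    if (length(rest) == 0) break
    for (pos2 in rest) {
      j <- ord[pos2]
      ov <- overlap_degree(members[[i]], members[[j]],
                           method = overlap_method)
      if (ov > overlap_thresh || keys[j] == keys[i]) {
        alive[pos2] <- FALSE
      }
    }
  }
  tp <- if ("timepoint" %in% names(candidates)) {
    as.character(candidates$timepoint[kept])
  } else {
    NULL
  }
  complex_set(members[kept], timepoint = tp,
              density = candidates$density[kept])
}
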