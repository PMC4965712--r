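# Internal helpers shared across modules.

# Canonical unordered edge representation: protein_a < protein_b, no
# self-loops, no duplicates. Returns list(edges = tibble, n_self_loops).
normalize_edges <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.character(a)
  b <- as.character(b)
  self <- a == b
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  edges <- dplyr::distinct(tibble::tibble(protein_a = a2, protein_b = b2))
  edges <- dplyr::arrange(edges, .data$protein_a, .data$protein_b)
  list(edges = edges, n_self_loops = sum(self))
}

# Weighted adjacency list for one subnetwork: named list, one element per
# protein, each a named numeric vector of incident edge weights.
build_adjacency <- function(edges) {
  if (nrow(edges) == 0) {
    return(structure(list(), names = character(0)))
  }
  from <- c(edges$protein_a, edges$protein_b)
  to <- c(edges$protein_b, edges$protein_a)
  w <- rep(edges$weight, 2)
  split(stats::setNames(w, to), from)
}

# Sum of weights among all unordered pairs of `members` in the adjacency list.
intra_weight_sum <- function(adj, members) {
  total <- 0
  for (p in members) {
    nb <- adj[[p]]
    if (!is.null(nb)) {
      total <- total + sum(nb[names(nb) %in% members])
    }
  }
  total / 2
}

# Key used for lexicographic tie-breaking over protein sets.
members_key <- function(members) {
  paste(sort(members), collapse = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
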