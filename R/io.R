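# Readers/writers and tidy containers for the three standard inputs:
# PPI edge lists, expression matrices, and complex sets. All formats are
# plain UTF-8 text; lines starting with "#" are skipped by every reader.

read_text_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "dynppi_io_error")
  }
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

is_data_line <- function(lines) {
  !grepl("^\\s*(#|$)", lines)
}

# ---------------------------------------------------------------------------
# Static PPI network
# ---------------------------------------------------------------------------

#' Create a static PPI network from an edge table
#'
#' A static PPI network is stored as a tibble of unordered, deduplicated
#' protein pairs with `protein_a < protein_b` and no self-loops. All
#' downstream functions accept any data frame with two character columns of
#' interacting proteins.
#'
#' @param edges Data frame whose first two columns are interacting protein
#'   identifiers (extra columns are ignored).
#' @return A `ppi_network` tibble with columns `protein_a`, `protein_b`.
#' @examples
#' ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' @export
ppi_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("An edge table needs at least two columns.",
          class = "dynppi_io_error")
  }
  norm <- normalize_edges(edges[[1]], edges[[2]])
  if (norm$n_self_loops > 0) {
    inform(paste0("Dropped ", norm$n_self_loops, " self-loop(s)."))
  }
  new_ppi_network(norm$edges)
}

new_ppi_network <- function(edges) {
  structure(as_tibble(edges),
            class = c("ppi_network", class(as_tibble(edges))))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("# A static PPI network: ", length(network_proteins(x)), " proteins, ",
      nrow(x), " interactions\n", sep = "")
  NextMethod()
}

#' Proteins of a network
#'
#' @param network A `ppi_network` or any edge data frame.
#' @return Sorted character vector of protein identifiers with degree >= 1.
#' @export
network_proteins <- function(network) {
  sort(unique(c(as.character(network[[1]]), as.character(network[[2]]))))
}

#' Read a PPI edge list
#'
#' Parses a whitespace/tab-delimited edge list (two or more columns; extra
#' columns are ignored). Self-loops are dropped with a message, duplicate and
#' reversed edges are collapsed to a single undirected edge.
#'
#' @param path Path to the edge-list file.
#' @return A `ppi_network` tibble.
#' @export
read_edge_list <- function(path) {
  lines <- read_text_lines(path)
  keep <- is_data_line(lines)
  if (!any(keep)) {
    abort(paste0("Edge list is empty: ", path), class = "dynppi_io_error")
  }
  tokens <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(tokens) < 2)
  if (length(bad) > 0) {
    abort(paste0("Malformed edge list line ", which(keep)[bad[1]], " in ",
                 path, ": fewer than 2 fields."),
          class = "dynppi_io_error")
  }
  ppi_network(tibble(
    protein_a = vapply(tokens, `[[`, character(1), 1),
    protein_b = vapply(tokens, `[[`, character(1), 2)
  ))
}

#' Write a PPI edge list
#'
#' @param network Edge data frame (see [ppi_network()]).
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return The input, invisibly.
#' @export
write_edge_list <- function(network, path, header = NULL) {
  network <- ppi_network(network)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(network$protein_a, network$protein_b, sep = "\t"), con)
  invisible(network)
}

# ---------------------------------------------------------------------------
# Expression matrix
# ---------------------------------------------------------------------------

#' Create an expression matrix
#'
#' Time-course expression profiles are stored as a tibble whose first column
#' (`gene`) holds identifiers and whose remaining columns are ordered time
#' points. Column order is the authoritative temporal order. At least three
#' time points are required (the co-expression window spans three points).
#'
#' @param x Data frame with a gene identifier column first and one numeric
#'   column per time point, or a numeric matrix with rownames.
#' @return An `expression_matrix` tibble.
#' @export
as_expression_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort("Expression matrix needs gene rownames.",
            class = "dynppi_io_error")
    }
    x <- dplyr::bind_cols(tibble(gene = rownames(x)), as_tibble(x))
  }
  x <- as_tibble(x)
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  if (ncol(x) - 1 < 3) {
    abort("An expression matrix needs at least 3 time points.",
          class = "dynppi_io_error")
  }
  dup <- x$gene[duplicated(x$gene)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated gene row(s): ", paste(unique(dup), collapse = ", ")),
          class = "dynppi_io_error")
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("Expression values must all be finite numbers.",
          class = "dynppi_io_error")
  }
  structure(x, class = c("expression_matrix", class(as_tibble(x))))
}

# numeric matrix (genes x time points) view of an expression tibble
expr_values <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene
  storage.mode(m) <- "double"
  m
}

#' Read a time-course expression matrix
#'
#' Expects a TSV with a header row (first field a gene-column label, the rest
#' time-point labels) and one row per gene. Cells must be numeric; duplicate
#' gene rows are rejected.
#'
#' @param path Path to the TSV file.
#' @return An `expression_matrix` tibble.
#' @export
read_expression_matrix <- function(path) {
  lines <- read_text_lines(path)
  keep <- is_data_line(lines)
  if (sum(keep) < 2) {
    abort(paste0("Expression matrix is empty: ", path),
          class = "dynppi_io_error")
  }
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- rows[[1]]
  body <- rows[-1]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    abort(paste0("Ragged expression row ", which(widths != length(header))[1],
                 " in ", path), class = "dynppi_io_error")
  }
  genes <- vapply(body, `[[`, character(1), 1)
  n_tp <- length(header) - 1
  if (n_tp < 3) {
    abort("An expression matrix needs at least 3 time points.",
          class = "dynppi_io_error")
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_tp)
  for (j in seq_len(n_tp)) {
    cell <- vapply(body, `[[`, character(1), j + 1)
    num <- suppressWarnings(as.numeric(cell))
    if (any(is.na(num))) {
      i <- which(is.na(num))[1]
      abort(paste0("Non-numeric expression value at row ", i, " (gene ",
                   genes[i], "), column ", header[j + 1], "."),
            class = "dynppi_io_error")
    }
    vals[, j] <- num
  }
  colnames(vals) <- header[-1]
  as_expression_matrix(dplyr::bind_cols(tibble(gene = genes), as_tibble(vals)))
}

#' Write an expression matrix
#'
#' @param expr An `expression_matrix` (or compatible data frame).
#' @param path Output path.
#' @param header Optional comment lines.
#' @return The input, invisibly.
#' @export
write_expression_matrix <- function(expr, path, header = NULL) {
  expr <- as_expression_matrix(expr)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(expr), collapse = "\t"), con)
  vals <- expr_values(expr)
  body <- apply(format(vals, trim = TRUE, scientific = FALSE), 1, paste,
                collapse = "\t")
  writeLines(paste(expr$gene, body, sep = "\t"), con)
  invisible(expr)
}

#' Average expression over repeated cycles
#'
#' Time courses spanning several identical cycles (e.g. three cell cycles of
#' 12 samples each) are collapsed to one cycle by averaging homologous time
#' points: output column `j` is the mean of input columns `j`, `j + T/n`, ...
#'
#' @param expr An `expression_matrix`.
#' @param n_cycles Number of cycles; must divide the number of time points.
#' @return An `expression_matrix` with `T / n_cycles` columns, labelled as the
#'   first cycle (a plain tibble if fewer than three columns remain, since
#'   windowed correlation is then infeasible).
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 4, 6), nrow = 1,
#'             dimnames = list("g1", paste0("T", 1:6)))
#' collapse_cycles(as_expression_matrix(m), 2)
#' @export
collapse_cycles <- function(expr, n_cycles) {
  expr <- as_expression_matrix(expr)
  vals <- expr_values(expr)
  n_tp <- ncol(vals)
  if (n_cycles < 1 || n_tp %% n_cycles != 0) {
    abort(paste0("Number of time points (", n_tp,
                 ") is not divisible by n_cycles (", n_cycles, ")."),
          class = "dynppi_io_error")
  }
  per <- n_tp %/% n_cycles
  out <- matrix(0, nrow = nrow(vals), ncol = per,
                dimnames = list(rownames(vals), colnames(vals)[seq_len(per)]))
  for (c in seq_len(n_cycles)) {
    out <- out + vals[, (c - 1) * per + seq_len(per), drop = FALSE]
  }
  out <- out / n_cycles
  if (per >= 3) {
    as_expression_matrix(out)
  } else {
    # too few columns for windowed correlation; return a plain table
    dplyr::bind_cols(tibble(gene = rownames(out)), as_tibble(out))
  }
}

# ---------------------------------------------------------------------------
# Complex sets
# ---------------------------------------------------------------------------

#' Create a complex set
#'
#' A complex set is a tibble with one row per complex: `complex_id`,
#' `members` (list-column of protein identifier vectors), and optional
#' `timepoint` / `density` attributes carried by predictions.
#'
#' @param members List of character vectors (one per complex), or a
#'   `complex_set`-shaped data frame.
#' @param timepoint Optional character vector of originating time points.
#' @param density Optional numeric vector of subnetwork densities.
#' @return A `complex_set` tibble.
#' @export
complex_set <- function(members, timepoint = NULL, density = NULL) {
  if (is.data.frame(members)) {
    df <- members
    members <- df$members
    timepoint <- timepoint %||% df$timepoint
    density <- density %||% df$density
  }
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  n <- length(members)
  out <- tibble(
    complex_id = seq_len(n),
    members = members,
    timepoint = if (is.null(timepoint)) rep(NA_character_, n) else
      as.character(timepoint),
    density = if (is.null(density)) rep(NA_real_, n) else as.numeric(density)
  )
  structure(out, class = c("complex_set", class(out)))
}

#' @export
print.complex_set <- function(x, ...) {
  cat("# A complex set: ", nrow(x), " complexes, ",
      length(unique(unlist(x$members))), " proteins\n", sep = "")
  NextMethod()
}

#' Read a complex set
#'
#' One complex per line, whitespace-separated protein identifiers. A trailing
#' `#tp=<label> density=<value>` annotation (as written by
#' [write_complex_set()]) is parsed back into the `timepoint` and `density`
#' columns. Lines with fewer than two proteins are dropped with a message.
#'
#' @param path Path to the file.
#' @return A `complex_set` tibble.
#' @export
read_complex_set <- function(path) {
  lines <- read_text_lines(path)
  keep <- is_data_line(lines)
  if (!any(keep)) {
    warn(paste0("Complex set file is empty: ", path))
    return(complex_set(list()))
  }
  lines <- lines[keep]
  anno <- rep(NA_character_, length(lines))
  has_anno <- grepl("#", lines, fixed = TRUE)
  anno[has_anno] <- sub("^[^#]*#\\s*", "", lines[has_anno])
  body <- sub("\\s*#.*$", "", lines)
  members <- strsplit(trimws(body), "\\s+")
  members <- lapply(members, unique)
  sizes <- lengths(members)
  if (any(sizes < 2)) {
    inform(paste0("Dropped ", sum(sizes < 2),
                  " singleton complex line(s)."))
  }
  ok <- sizes >= 2
  tp <- ifelse(grepl("tp=", anno), sub(".*tp=(\\S+).*", "\\1", anno),
               NA_character_)
  dens <- suppressWarnings(as.numeric(
    ifelse(grepl("density=", anno), sub(".*density=(\\S+).*", "\\1", anno),
           NA_character_)))
  complex_set(members[ok], timepoint = tp[ok], density = dens[ok])
}

#' Write a complex set
#'
#' One complex per line, members sorted lexicographically; predictions carry
#' their time point and density as a trailing `#tp=... density=...`
#' annotation that [read_complex_set()] understands.
#'
#' @param complexes A `complex_set` (or compatible data frame).
#' @param path Output path.
#' @param header Optional comment lines.
#' @return The input, invisibly.
#' @export
write_complex_set <- function(complexes, path, header = NULL) {
  complexes <- complex_set(complexes)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (i in seq_len(nrow(complexes))) {
    line <- paste(sort(complexes$members[[i]]), collapse = " ")
    tp <- complexes$timepoint[i]
    dens <- complexes$density[i]
    if (!is.na(tp) || !is.na(dens)) {
      anno <- c(if (!is.na(tp)) paste0("tp=", tp),
                if (!is.na(dens)) paste0("density=", format(dens, digits = 6)))
      line <- paste(line, "#", paste(anno, collapse = " "))
    }
    writeLines(line, con)
  }
  invisible(complexes)
}
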