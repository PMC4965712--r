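# Run configuration shared by the pipeline functions and the command-line
# interface: defaults, optional YAML file, explicit overrides; precedence is
# overrides > file > defaults.

#' Assemble a run configuration
#'
#' Collects every pipeline threshold with its default (co-expression
#' threshold 0.5, complex threshold 0.1, attachment threshold defaulting to
#' the complex threshold, overlap threshold 2/3, match threshold 0.2,
#' minimum size 2), the window policy and the seed. Values from a YAML file
#' override the defaults; explicit arguments override both.
#'
#' @param file Optional path to a YAML key/value file.
#' @param ... Named overrides of individual settings.
#' @return A named list of class `dynppi_config`.
#' @export
dynppi_config <- function(file = NULL, ...) {
  defaults <- list(
    pre_thresh = 0.5,
    complex_thresh = 0.1,
    attach_thresh = NULL, # NULL = follow complex_thresh
    overlap_thresh = 2 / 3,
    na_thresh = 0.2,
    min_size = 2,
    window = "cyclic",
    constant_row_policy = "faithful",
    transform = "abs",
    overlap_method = "affinity",
    seed = 42
  )
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) {
      abort(paste0("Config file not found: ", file),
            class = "dynppi_io_error")
    }
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(defaults))
    if (length(unknown) > 0) {
      warn(paste0("Ignoring unknown config key(s): ",
                  paste(unknown, collapse = ", ")))
    }
    cfg[intersect(names(from_file), names(defaults))] <-
      from_file[intersect(names(from_file), names(defaults))]
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config setting(s): ",
                 paste(unknown, collapse = ", ")),
          class = "dynppi_domain_error")
  }
  cfg[names(overrides)] <- overrides
  for (key in c("pre_thresh", "complex_thresh", "overlap_thresh",
                "na_thresh")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("`", key, "` must be in [0, 1]."),
            class = "dynppi_domain_error")
    }
  }
  if (!is.null(cfg$attach_thresh) &&
      (cfg$attach_thresh < 0 || cfg$attach_thresh > 1)) {
    abort("`attach_thresh` must be in [0, 1].",
          class = "dynppi_domain_error")
  }
  structure(cfg, class = "dynppi_config")
}

#' @export
print.dynppi_config <- function(x, ...) {
  cat("dynppi run configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat("  ", format(k, width = 20), " ",
        if (is.null(v)) "(= complex_thresh)" else as.character(v), "\n",
        sep = "")
  }
  invisible(x)
}

#' Provenance stamp for output files
#'
#' Builds the comment lines (tool version, configuration hash, input file
#' checksums) that the command-line interface prepends to every output file.
#'
#' @param config A `dynppi_config`.
#' @param inputs Named character vector of input file paths.
#' @return Character vector of stamp lines (without the leading `#`).
#' @export
config_stamp <- function(config, inputs = character(0)) {
  lines <- c(
    paste0("dynppi version ", as.character(utils::packageVersion("dynppi"))),
    paste0("config hash ", rlang::hash(unclass(config)))
  )
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs) > 0) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, paste0("input ", names(inputs), " md5 ", sums))
  }
  lines
}
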