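#' Read and write pipeline tables
#'
#' All pipeline tables are comma-separated text with a header row, UTF-8
#' encoded, `"."` decimal mark. Writing uses a shortest round-trip decimal
#' representation, so a write/read cycle reproduces doubles exactly.
#'
#' @param x A tibble.
#' @param path File path.
#' @return `write_table_csv()` returns `path` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    stop("parse error in ", path, " at line(s) ",
         paste(unique(probs$row), collapse = ", "))
  }
  out
}

#' Write and read a run manifest
#'
#' The manifest is structured text (YAML) recording the master seed, derived
#' per-stage seeds, all ground-truth and schedule parameters actually used,
#' package version and output paths, so a run can be reproduced exactly from
#' the manifest alone.
#'
#' @param manifest Named list.
#' @param path File path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the named list.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}
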