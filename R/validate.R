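#' Validate pipeline tables against their schemas
#'
#' Checks each supplied table (or file path) against the schema of its kind:
#' required columns, controlled vocabularies (`experiment` in EX1-EX3,
#' `pool` in eelgrass/reference, `layer` in surface/bottom, `source` in
#' eelgrass/epiphytes), positivity of concentrations and detection limits,
#' and the 0-100 % range of elemental contents. Violations name the table,
#' row and column.
#'
#' @param tables Named list whose names identify the table kind (`sources`,
#'   `initial_leaves`, `decomposition`, `sediment`) and whose elements are
#'   tibbles or CSV file paths.
#' @return An object of class `validation_report`: tibble of violations
#'   (zero rows when everything passes) with columns `table`, `row`,
#'   `column`, `message`.
#' @export
validate_tables <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("`tables` must be a named list")
  }
  out <- list()
  for (kind in names(tables)) {
    tab <- tables[[kind]]
    if (is.character(tab)) {
      tab <- tryCatch(read_table_csv(tab), error = function(e) e)
      if (inherits(tab, "error")) {
        out[[kind]] <- violation(kind, NA_integer_, NA_character_,
                                 conditionMessage(tab))
        next
      }
    }
    checker <- switch(kind,
      sources = check_sources,
      initial_leaves = check_initial_leaves,
      decomposition = check_decomposition,
      sediment = check_sediment,
      stop("unknown table kind: ", kind))
    out[[kind]] <- checker(tab, kind)
  }
  v <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  v <- v %||% violation(character(), integer(), character(), character())
  structure(list(violations = tibble::as_tibble(v)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$violations) == 0L) {
    cat("All tables valid: zero violations.\n")
  } else {
    cat(nrow(x$violations), "violation(s):\n")
    print(x$violations)
  }
  invisible(x)
}

violation <- function(table, row, column, message) {
  tibble::tibble(table = table, row = row, column = column,
                 message = message)
}

need_cols <- function(tab, kind, cols) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    violation(kind, NA_integer_, miss, "required column missing")
  } else {
    NULL
  }
}

check_vocab <- function(tab, kind, column, allowed) {
  if (!column %in% names(tab)) return(NULL)
  bad <- which(!tab[[column]] %in% allowed)
  if (!length(bad)) return(NULL)
  violation(kind, bad, column,
            paste0("value not in {", paste(allowed, collapse = ", "), "}"))
}

check_range <- function(tab, kind, column, lo, hi, lo_open = FALSE) {
  if (!column %in% names(tab)) return(NULL)
  x <- tab[[column]]
  bad <- which(!is.finite(x) | (if (lo_open) x <= lo else x < lo) | x > hi)
  if (!length(bad)) return(NULL)
  violation(kind, bad, column,
            sprintf("value outside %s%g, %g]", if (lo_open) "(" else "[",
                    lo, hi))
}

check_positive <- function(tab, kind, column) {
  if (!column %in% names(tab)) return(NULL)
  x <- tab[[column]]
  bad <- which(!is.finite(x) | x <= 0)
  if (!length(bad)) return(NULL)
  violation(kind, bad, column, "value must be positive")
}

check_tracers <- function(tab, kind) {
  rbind(check_range(tab, kind, "c_content", 0, 100),
        check_range(tab, kind, "n_content", 0, 100),
        if ("d13c" %in% names(tab) && any(!is.finite(tab$d13c)))
          violation(kind, which(!is.finite(tab$d13c)), "d13c",
                    "delta value must be finite"),
        if ("d15n" %in% names(tab) && any(!is.finite(tab$d15n)))
          violation(kind, which(!is.finite(tab$d15n)), "d15n",
                    "delta value must be finite"))
}

check_sources <- function(tab, kind) {
  rbind(need_cols(tab, kind, c("source", "replicate")),
        check_vocab(tab, kind, "source", c("eelgrass", "epiphytes")),
        check_tracers(tab, kind))
}

check_initial_leaves <- function(tab, kind) {
  rbind(need_cols(tab, kind, "replicate"), check_tracers(tab, kind))
}

check_decomposition <- function(tab, kind) {
  v <- rbind(need_cols(tab, kind, c("experiment", "c_content")),
             check_vocab(tab, kind, "experiment", ZM_EXPERIMENTS),
             check_range(tab, kind, "c_content", 0, 100, lo_open = TRUE))
  for (m in intersect(ZM_METALS, names(tab))) {
    v <- rbind(v, check_positive(tab, kind, m),
               check_positive(tab, kind, paste0(m, "_limit")))
  }
  v
}

check_sediment <- function(tab, kind) {
  v <- rbind(need_cols(tab, kind, c("pool", "layer", "month", "d13c")),
             check_vocab(tab, kind, "pool", c("eelgrass", "reference")),
             check_vocab(tab, kind, "layer", c("surface", "bottom")))
  for (el in intersect(c("c", "n", ZM_METALS), names(tab))) {
    v <- rbind(v, check_positive(tab, kind, el))
  }
  v
}
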