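#' Read and write traces and tables as CSV
#'
#' Plain-CSV serialisation with full double precision (17 significant
#' digits, so values round-trip bitwise).  Column order is fixed and a
#' header row is always written.
#'
#' @param trace A `cell_trace` (or any data frame with `time`, `vm`, `h`).
#' @param path Output file.
#' @return `write_trace_csv()` and `write_table_csv()` return the input
#'   invisibly; `read_trace_csv()` returns a tibble.
#' @export
write_trace_csv <- function(trace, path) {
  write_table_csv(trace[, c("time", "vm", "h")], path)
  invisible(trace)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("cell_trace", class(out))
  out
}

#' @rdname write_trace_csv
#' @param table Any data frame.
#' @export
write_table_csv <- function(table, path) {
  header <- paste(names(table), collapse = ",")
  if (nrow(table) == 0L) {
    lines <- header
  } else {
    fmt <- vapply(table, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    }, character(nrow(table)))
    if (nrow(table) == 1L) fmt <- matrix(fmt, nrow = 1)
    lines <- c(header, apply(fmt, 1, paste, collapse = ","))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(table)
}
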