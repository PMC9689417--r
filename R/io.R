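# Plain-text I/O: numeric matrices in CSV/TSV (rows = time points), and
# JSON/CSV serialization of test results and power reports.

#' Read a series matrix from CSV/TSV
#'
#' Reads a rectangular numeric table with rows = time points and columns =
#' replicates.  The delimiter is sniffed from the first line (comma vs tab)
#' unless given; a header row is auto-detected (first row containing any
#' non-numeric cell).  Parse problems are reported with line numbers.
#'
#' @param path file path.
#' @param sep delimiter, `","` or `"\t"`; `NULL` (default) sniffs.
#' @param transpose if `TRUE` the file holds a q x n table and is
#'   transposed after reading.
#' @return n x q numeric matrix.
#' @export
read_series_matrix <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_invalid(sprintf("%s: empty file", path))
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  width <- lengths(cells)
  if (any(width != width[1]))
    stop_invalid(sprintf("%s: ragged rows at line(s) %s", path,
                         paste(which(width != width[1]), collapse = ", ")))
  is_num_row <- function(r) !anyNA(suppressWarnings(as.numeric(r)))
  start <- if (is_num_row(cells[[1]])) 1L else 2L
  body <- cells[start:length(cells)]
  vals <- suppressWarnings(lapply(body, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop_invalid(sprintf("%s: non-numeric cell(s) at line(s) %s", path,
                         paste(bad + start - 1L, collapse = ", ")))
  m <- do.call(rbind, vals)
  if (transpose) m <- t(m)
  if (nrow(m) < 3)
    stop_invalid(sprintf("%s: fewer than 3 time points (rows)", path))
  m
}

#' Serialize a test result or power report
#'
#' `"wc_test"`/`"wc_selfnorm"` objects are written as a flat JSON record
#' (numbers at full double precision); `"wc_power"` reports as JSON or CSV
#' (one row per grid cell).  [read_result()] round-trips the JSON form.
#'
#' @param x a `"wc_test"`, `"wc_selfnorm"`, or `"wc_power"`.
#' @param path output file.
#' @param format `"json"` or `"csv"` (csv only for power reports).
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "wc_power")) {
    if (format == "csv") utils::write.csv(x, path, row.names = FALSE)
    else jsonlite::write_json(as.list(as.data.frame(x)), path,
                              auto_unbox = FALSE, digits = NA)
    return(invisible(path))
  }
  if (format == "csv")
    stop_invalid("csv output is only supported for power reports")
  rec <- unclass(x)
  rec$path <- NULL                      # drop non-scalar internals
  rec$software_version <- as.character(utils::packageVersion("wcusum"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialized result record
#'
#' @param path JSON file written by [write_result()].
#' @return Named list.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
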