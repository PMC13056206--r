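#' Read a univariate series from CSV or plain text
#'
#' Accepts a single-column CSV (with or without header) or
#' whitespace-delimited plain text, one observation per line in time order.
#' A column can be selected by name or index for multi-column files. Rows
#' that do not parse as finite numbers are an error that names the
#' offending line numbers — silent coercion to NA would corrupt a
#' change-point analysis.
#'
#' @param path file path.
#' @param column column name or index (default: first column).
#' @return Numeric vector in file order.
#' @export
read_series <- function(path, column = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    stop("empty input file: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          blank.lines.skip = TRUE)
  if (is.character(column)) {
    if (!column %in% names(df)) {
      stop(sprintf("column '%s' not found (columns: %s)", column,
                   paste(names(df), collapse = ", ")), call. = FALSE)
    }
    raw <- df[[column]]
  } else {
    if (column < 1 || column > ncol(df)) {
      stop(sprintf("column index %d out of range (file has %d columns)",
                   column, ncol(df)), call. = FALSE)
    }
    raw <- df[[column]]
  }
  if (!length(raw)) stop("no observations in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    rows <- bad + as.integer(has_header)
    stop(sprintf("non-numeric or non-finite values at line%s %s of %s",
                 if (length(bad) > 1) "s" else "",
                 paste(utils::head(rows, 10L), collapse = ", "), path),
         call. = FALSE)
  }
  vals
}
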