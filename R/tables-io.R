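#' Write a result table
#'
#' Writes a tabular result to CSV or JSON (records orientation). Factors
#' (severity grades) are stored as their labels; round-trips through
#' [read_table()] are lossless at full double precision.
#'
#' @param rows A non-empty data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = NULL) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort("Refusing to write an empty table.")
  }
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) {
    "json"
  } else {
    "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  rows <- as.data.frame(lapply(rows, function(c) {
    if (is.factor(c)) as.character(c) else c
  }), stringsAsFactors = FALSE)
  if (format == "csv") {
    readr::write_csv(rows, path)
  } else {
    jsonlite::write_json(rows, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Read a result table
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return A tibble.
#' @export
read_table <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) {
    "json"
  } else {
    "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
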