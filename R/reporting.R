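# Result serialisation: CSV (header row, optional '#' comment header) and
# JSON (array of flat objects).  Numeric columns are written with 17
# significant digits so a write/read cycle is numerically exact.

#' Write results to CSV or JSON
#'
#' `records` may be a data frame or any package result object with an
#' `as.data.frame` method ([n_lognormal()] results, [estimate_power()]
#' results, [replicate_table()] output).  CSV files carry an optional
#' comment header (lines starting `#`) recording provenance; pass entries
#' via `header` and disable the timestamp line with `timestamp = FALSE`
#' when byte-identical output matters.
#'
#' @param records Data frame or coercible result object; must be non-empty.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param header Named character vector written as `# name: value` comment
#'   lines before the CSV header row (ignored for JSON).
#' @param timestamp Logical; add a `# written:` line to the CSV header.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @examples
#' res <- n_lognormal(group_spec(20, 5), group_spec(16, 5), design_spec())
#' f <- tempfile(fileext = ".csv")
#' write_results(res, f, timestamp = FALSE)
#' read_results(f)
#' @export
write_results <- function(records, path, format = c("csv", "json"),
                          header = NULL, timestamp = TRUE) {
  format <- match.arg(format)
  df <- as.data.frame(records)
  if (nrow(df) == 0L) ln_stop("no records to write")
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE)
    } else {
      con <- file(path, open = "wt")
      on.exit(close(con))
      if (timestamp)
        writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
      for (nm in names(header))
        writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
      out <- df
      num <- vapply(out, is.double, logical(1))
      out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
      utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
    }
    TRUE
  }, error = function(e) {
    ln_stop(sprintf("cannot write results to '%s': %s", path,
                    conditionMessage(e)),
            class = "lognsize_io_error")
  })
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path File produced by [write_results()].
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return A data frame.
#' @export
read_results <- function(path, format = NULL) {
  if (!file.exists(path))
    ln_stop(sprintf("no such file: '%s'", path), class = "lognsize_io_error")
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
}
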