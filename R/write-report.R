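#' Write a report to TSV or JSON
#'
#' Serialises any report tibble (or an object with a [tidy()] method) with a
#' deterministic field order and numeric values fixed to 3 decimals, so the
#' same report always produces byte-identical files.
#'
#' @param report A tibble, or an object with a `tidy()` method.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Decimal places for numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json"), digits = 3) {
  format <- match.arg(format)
  if (!is.data.frame(report)) report <- tidy(report)
  report <- report |>
    mutate(across(where(is.double), ~ round(.x, digits)))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("cannot write report: no such directory ", dir))
  if (format == "tsv") {
    # fixed-precision text so numeric columns round-trip deterministically
    out <- report |>
      mutate(across(where(is.double), ~ sprintf(paste0("%.", digits, "f"), .x)))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = digits, pretty = TRUE)
  }
  invisible(path)
}
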