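#' Read a treatment-record cohort from CSV
#'
#' Reads one treatment course per row. Values matching any of the configured
#' missing-value sentinels become `NA`; the printed tables in clinical
#' reports typically use an en dash, so the default sentinel set accepts
#' `""`, `"–"`, `"-"` and `"NA"`. Doses are kept in cGy exactly as
#' stored; no unit conversion is performed.
#'
#' Rows are returned in file order. Nothing is dropped silently: a missing
#' schema column raises an error naming the column, and a non-numeric value
#' in a mandatory prescription column raises an error carrying the offending
#' row indices.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [feature_schema()]; its fields must appear as columns.
#' @param na_sentinels Character vector of strings mapped to missing.
#'
#' @return A tibble with one row per record. A `record_id` column is
#'   generated from the row number when the file does not provide one.
#' @export
read_cohort <- function(path, schema = feature_schema(),
                        na_sentinels = c("", "–", "-", "NA")) {
  stopifnot(inherits(schema, "rx_schema"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  raw <- dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    ~ ifelse(trimws(.x) %in% na_sentinels, NA_character_, .x)
  ))

  needed <- c(schema$prescription_fields, schema$feature_fields, "technique")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rx_schema_error")
  }

  numeric_cols <- unique(c(
    schema$prescription_fields, schema$numeric_fields,
    intersect(c("total_dose", "accumulated_total_dose"), names(raw))
  ))
  mandatory_numeric <- schema$prescription_fields
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad) > 0L) {
      if (col %in% mandatory_numeric) {
        abort(sprintf("non-numeric value in column '%s' at row(s): %s",
                      col, paste(bad, collapse = ", ")),
              class = "rx_parse_error")
      }
      warn(sprintf("column '%s': unparseable value set to NA at row(s): %s",
                   col, paste(bad, collapse = ", ")))
      parsed[bad] <- NA_real_
    }
    raw[[col]] <- parsed
  }
  if ("fractions" %in% names(raw)) raw$fractions <- as.integer(raw$fractions)

  if (!"record_id" %in% names(raw)) {
    raw$record_id <- as.character(seq_len(nrow(raw)))
  }
  dplyr::relocate(as_tibble(raw), "record_id")
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()]: `NA` values are written as the first
#' configured sentinel so that a read/write round-trip preserves missing
#' markers.
#'
#' @param cohort A treatment-record tibble.
#' @param path Output path.
#' @param na Sentinel written for missing values (default empty string).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, na = "") {
  readr::write_csv(cohort, path, na = na)
  invisible(path)
}

#' Write a detection report
#'
#' Serializes detections as JSON lines, one object per record, in input
#' order. Each object carries the verdict, anomaly type, the scores R and F
#' with their thresholds, the historical prescription count and any
#' warnings. Numbers are written at full precision; `r_disp`, `f_disp`,
#' `t_rx_disp`, `t_f_disp` carry the 2-decimal display values used in
#' printed reports. An optional CSV mirror holds the same rows.
#'
#' @param detections A detection tibble from [detect_batch()] (possibly
#'   empty).
#' @param path Output path for the JSON-lines report.
#' @param csv_path Optional path for a CSV mirror.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path, csv_path = NULL) {
  disp <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
  out <- detections
  out$r_disp <- disp(out$r)
  out$t_rx_disp <- disp(out$t_rx)
  out$f_disp <- disp(out$f)
  out$t_f_disp <- disp(out$t_f)
  lines <- vapply(seq_len(nrow(out)), function(i) {
    row <- as.list(out[i, , drop = FALSE])
    row <- lapply(row, function(v) if (is.list(v)) v[[1]] else v)
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(csv_path)) {
    flat <- out
    flat$warnings <- vapply(out$warnings, function(w) paste(w, collapse = ";"),
                            character(1))
    readr::write_csv(flat, csv_path)
  }
  invisible(path)
}

#' Read a detection report written by [write_detections()]
#'
#' @param path Path to a JSON-lines report.
#' @return A detection tibble.
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_detections())
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    obj$warnings <- list(as.character(obj$warnings %||% character()))
    null_na <- function(v, as_fun) if (is.null(v)) as_fun(NA) else as_fun(v)
    tibble(
      record_id = as.character(obj$record_id),
      technique = null_na(obj$technique, as.character),
      verdict = null_na(obj$verdict, as.character),
      anomaly_type = null_na(obj$anomaly_type, as.character),
      r = null_na(obj$r, as.numeric),
      t_rx = null_na(obj$t_rx, as.numeric),
      f = null_na(obj$f, as.numeric),
      t_f = null_na(obj$t_f, as.numeric),
      counts = null_na(obj$counts, as.integer),
      warnings = obj$warnings
    )
  })
  dplyr::bind_rows(rows)
}

empty_detections <- function() {
  tibble(
    record_id = character(), technique = character(), verdict = character(),
    anomaly_type = character(), r = numeric(), t_rx = numeric(),
    f = numeric(), t_f = numeric(), counts = integer(), warnings = list()
  )
}
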