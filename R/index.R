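#' Build a per-technique historical index
#'
#' Fits everything detection needs against one technique's filtered
#' historical cohort: the prescription min-max scaler, the scaled
#' prescription pairs, the characteristic distances theta and tau, and the
#' exact-prescription occurrence counts. theta and tau are O(S^2) pairwise
#' means, so the index is built once and reused (see [write_index()]).
#'
#' @param cohort Treatment-record tibble for a single technique, S >= 2.
#' @param schema A [feature_schema()]; numeric ranges are (re)fitted here
#'   from the cohort.
#' @param technique Canonical technique label; defaults to the cohort's
#'   single technique value.
#' @return An object of class `rx_index` with elements `technique`,
#'   `records`, `schema`, `scaler`, `scaled_rx`, `theta`, `tau`,
#'   `rx_counts` and `s`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(size = 60, seed = 7))
#' idx <- build_index(cohort)
#' c(idx$theta, idx$tau)
build_index <- function(cohort, schema = feature_schema(), technique = NULL) {
  if (nrow(cohort) < 2L) abort("an index needs at least 2 records")
  technique <- technique %||% unique(cohort$technique)
  if (length(technique) != 1L) {
    abort("cohort spans multiple techniques; partition first")
  }
  if (!"record_id" %in% names(cohort)) {
    cohort$record_id <- as.character(seq_len(nrow(cohort)))
  }
  schema <- fit_schema(schema, cohort)
  scaler <- fit_rx_scaler(cohort, schema$prescription_fields)
  scaled <- scale_rx(scaler, cohort)
  ch <- characteristic_values(cohort, scaler, schema)
  keys <- rx_key(cohort$fractions, cohort$dose_per_fraction)
  counts <- table(keys)
  structure(
    list(
      technique = technique,
      records = as_tibble(cohort),
      schema = schema,
      scaler = scaler,
      scaled_rx = scaled,
      theta = ch$theta,
      tau = ch$tau,
      rx_counts = setNames(as.integer(counts), names(counts)),
      s = nrow(cohort)
    ),
    class = "rx_index"
  )
}

#' @export
print.rx_index <- function(x, ...) {
  cat("<rx_index>", x$technique, "\n")
  cat(sprintf("  S = %d records, %d distinct prescriptions\n",
              x$s, length(x$rx_counts)))
  cat(sprintf("  theta = %.4f  tau = %.4f\n", x$theta, x$tau))
  invisible(x)
}

#' Serialize a historical index to JSON
#'
#' Writes the full index — records, scaler limits, schema, theta, tau and
#' prescription counts — as a single JSON document, so detection can run
#' later without recomputing the O(S^2) pairwise statistics.
#'
#' @param index An `rx_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "rx_index"))
  payload <- list(
    technique = index$technique,
    s = index$s,
    theta = index$theta,
    tau = index$tau,
    scaler = list(fields = index$scaler$fields,
                  min = as.list(index$scaler$min),
                  max = as.list(index$scaler$max)),
    schema = list(prescription_fields = index$schema$prescription_fields,
                  feature_fields = index$schema$feature_fields,
                  numeric_fields = index$schema$numeric_fields,
                  numeric_ranges = as.list(index$schema$numeric_ranges)),
    rx_counts = as.list(index$rx_counts),
    records = index$records
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Restore a historical index written by [write_index()]
#'
#' @param path Path to the JSON artifact.
#' @return An `rx_index`.
#' @export
read_index <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  records <- as_tibble(p$records)
  if ("fractions" %in% names(records)) {
    records$fractions <- as.integer(records$fractions)
  }
  schema <- feature_schema(
    prescription_fields = p$schema$prescription_fields,
    feature_fields = p$schema$feature_fields,
    numeric_fields = p$schema$numeric_fields,
    numeric_ranges = unlist(p$schema$numeric_ranges)
  )
  fields <- p$scaler$fields
  mins <- unlist(p$scaler$min)[fields]
  maxs <- unlist(p$scaler$max)[fields]
  scaler <- structure(
    list(fields = fields, min = mins, max = maxs,
         degenerate = setNames(maxs == mins, fields)),
    class = "rx_scaler"
  )
  # the stored theta/tau are reused as-is: the point of the artifact is to
  # skip the O(S^2) pairwise recomputation
  structure(
    list(
      technique = p$technique,
      records = records,
      schema = schema,
      scaler = scaler,
      scaled_rx = scale_rx(scaler, records),
      theta = p$theta,
      tau = p$tau,
      rx_counts = setNames(as.integer(unlist(p$rx_counts)),
                           names(p$rx_counts)),
      s = as.integer(p$s)
    ),
    class = "rx_index"
  )
}
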