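#' Feature schema for treatment records
#'
#' Declares which columns form the prescription (entering the prescription
#' distance) and which form the clinical feature set (entering the Gower
#' feature distance), and which of the feature columns are numeric. The
#' default realizes the seven-feature layout used throughout: the
#' prescription pair (fractions, dose per fraction in cGy) plus age, beam
#' energy, treatment intent, ICD-10 diagnosis code and ICD-O morphology code.
#'
#' Numeric feature ranges are required for Gower normalization and are
#' learned from a historical cohort with [fit_schema()].
#'
#' @param prescription_fields Ordered character vector of prescription
#'   columns. Default `c("fractions", "dose_per_fraction")`.
#' @param feature_fields Ordered character vector of non-prescription columns
#'   entering the feature distance.
#' @param numeric_fields Subset of `feature_fields` treated numerically.
#' @param numeric_ranges Named numeric vector of ranges (max - min) for the
#'   numeric fields, or `NULL` before fitting.
#'
#' @return An object of class `rx_schema`.
#' @export
#' @examples
#' sc <- feature_schema()
#' sc$feature_fields
feature_schema <- function(prescription_fields = c("fractions", "dose_per_fraction"),
                           feature_fields = c("age", "energy", "intent", "icd10", "morphology"),
                           numeric_fields = "age",
                           numeric_ranges = NULL) {
  if (length(intersect(prescription_fields, feature_fields)) > 0L) {
    abort("prescription_fields and feature_fields must be disjoint")
  }
  if (!all(numeric_fields %in% feature_fields)) {
    abort("numeric_fields must be a subset of feature_fields")
  }
  structure(
    list(
      prescription_fields = prescription_fields,
      feature_fields = feature_fields,
      numeric_fields = numeric_fields,
      numeric_ranges = numeric_ranges
    ),
    class = "rx_schema"
  )
}

#' Fit a schema's numeric ranges from a historical cohort
#'
#' Stores, for every numeric feature field, the observed range used to
#' normalize that field's contribution to the Gower distance. Ranges come
#' from the historical cohort only; new records outside them simply
#' contribute more than one range unit.
#'
#' @param schema An [feature_schema()] object.
#' @param cohort A treatment-record data frame.
#' @return The schema with `numeric_ranges` filled in.
#' @export
fit_schema <- function(schema, cohort) {
  stopifnot(inherits(schema, "rx_schema"))
  ranges <- vapply(schema$numeric_fields, function(f) {
    v <- cohort[[f]]
    if (is.null(v) || all(is.na(v))) return(NA_real_)
    diff(range(v, na.rm = TRUE))
  }, numeric(1))
  bad <- names(ranges)[!is.na(ranges) & ranges <= 0]
  if (length(bad) > 0L) {
    warn(paste0("degenerate numeric range (max == min) for: ",
                paste(bad, collapse = ", ")))
  }
  schema$numeric_ranges <- ranges
  schema
}

#' @export
print.rx_schema <- function(x, ...) {
  cat("<rx_schema>\n")
  cat("  prescription:", paste(x$prescription_fields, collapse = ", "), "\n")
  cat("  features:    ", paste(x$feature_fields, collapse = ", "), "\n")
  cat("  numeric:     ", paste(x$numeric_fields, collapse = ", "), "\n")
  if (!is.null(x$numeric_ranges)) {
    cat("  ranges:      ",
        paste(sprintf("%s=%.3g", names(x$numeric_ranges), x$numeric_ranges),
              collapse = ", "), "\n")
  }
  invisible(x)
}
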