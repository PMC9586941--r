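# Synonym table collapsing free-text technique labels into canonical
# categories. Seeded with the alias spellings that occur in clinical
# treatment-record exports; matching is case-insensitive on the trimmed label.
technique_synonyms <- list(
  "3d" = c("3d", "3dcrt", "3d crt", "rao/lpo", "5 field conformal",
           "opposed laterals", "ap/pa"),
  imrt = c("imrt", "imrt ig", "imrt ig abc", "igvmat", "imrt vmat ig abc",
           "imrt tomo ig", "tomotherapy", "vmat"),
  sbrt = c("sbrt", "sbrt vmat ig", "igsbrt", "sbrt ig")
)

#' Normalize a technique label
#'
#' Collapses alternate spellings of delivery techniques into the canonical
#' categories `3d`, `imrt`, `sbrt`; anything unrecognized maps to `other`.
#' Total and idempotent: canonical labels map to themselves.
#'
#' @param raw Character vector of free-text technique labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_technique(c("ap/pa", "igvmat", "SBRT IG", "protons"))
normalize_technique <- function(raw) {
  lab <- tolower(trimws(as.character(raw)))
  out <- rep("other", length(lab))
  for (canon in names(technique_synonyms)) {
    out[lab %in% technique_synonyms[[canon]]] <- canon
  }
  out[is.na(raw)] <- "other"
  out
}

#' Cohort filtering rules
#'
#' Configuration for [filter_cohort()]. Each rule can be switched off;
#' parameters control the dose-mismatch tolerance and the diagnosis
#' inclusion list (ICD-10 prefixes for thoracic primaries: esophagus,
#' lung, heart/mediastinum, abnormal imaging, secondary lung).
#'
#' @param calibration Drop calibration/fake entries (zero total dose).
#' @param replan Drop re-plan courses and their initial plans, detected by a
#'   total vs accumulated dose mismatch beyond `dose_tol_cgy`.
#' @param cone_down Drop cone-down plans. Uses a `parent_plan_id` linkage
#'   column when the data provides one; otherwise cone-downs fall under the
#'   replan dose-mismatch heuristic.
#' @param technique Drop records whose canonical technique is not modelled
#'   (`3d`, `imrt`, `sbrt`).
#' @param diagnosis Drop records whose ICD-10 code matches none of the
#'   inclusion prefixes.
#' @param dose_tol_cgy Tolerance in cGy for the total/accumulated dose
#'   comparison; 1 cGy is the resolution of the stored doses.
#' @param icd10_include Character vector of accepted ICD-10 prefixes.
#' @param missing_policy `"keep"` (default) or `"drop"`: what to do when a
#'   field a filter needs is missing.
#' @return A list of class `rx_filter_rules`.
#' @export
filter_rules <- function(calibration = TRUE, replan = TRUE, cone_down = TRUE,
                         technique = TRUE, diagnosis = TRUE,
                         dose_tol_cgy = 1,
                         icd10_include = c("C15", "C34", "C38", "R91", "C78"),
                         missing_policy = c("keep", "drop")) {
  structure(
    list(calibration = calibration, replan = replan, cone_down = cone_down,
         technique = technique, diagnosis = diagnosis,
         dose_tol_cgy = dose_tol_cgy, icd10_include = icd10_include,
         missing_policy = match.arg(missing_policy)),
    class = "rx_filter_rules"
  )
}

#' Filter a cohort per the cleaning rules
#'
#' Partitions the input into records kept for modelling and records removed,
#' each removal tagged with a machine-readable reason. Reasons, applied in
#' order: `calibration` (zero total dose), `replan` (total vs accumulated
#' dose mismatch; when a `patient_id` column is present the whole course set
#' of an affected patient is removed, including the initial plan),
#' `cone_down` (a `parent_plan_id` linkage marks boost/cone-down plans),
#' `technique` (not one of the modelled techniques) and `diagnosis` (ICD-10
#' outside the inclusion list). The kept and removed sets partition the
#' input exactly.
#'
#' @param records Treatment-record tibble (canonical techniques).
#' @param rules A [filter_rules()] object.
#' @return A list with tibbles `kept` and `removed`; `removed` gains a
#'   `reason` column.
#' @export
filter_cohort <- function(records, rules = filter_rules()) {
  stopifnot(inherits(rules, "rx_filter_rules"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  miss_drop <- identical(rules$missing_policy, "drop")

  mark <- function(idx, why) {
    idx <- idx & is.na(reason)
    reason[idx] <<- why
  }

  if (isTRUE(rules$calibration) && "total_dose" %in% names(records)) {
    zero <- !is.na(records$total_dose) & records$total_dose == 0
    if (miss_drop) zero <- zero | is.na(records$total_dose)
    mark(zero, "calibration")
  }

  if (isTRUE(rules$cone_down) && "parent_plan_id" %in% names(records)) {
    mark(!is.na(records$parent_plan_id), "cone_down")
  }

  if (isTRUE(rules$replan) &&
      all(c("total_dose", "accumulated_total_dose") %in% names(records))) {
    mism <- !is.na(records$total_dose) & !is.na(records$accumulated_total_dose) &
      abs(records$total_dose - records$accumulated_total_dose) > rules$dose_tol_cgy
    if ("patient_id" %in% names(records)) {
      flagged_patients <- unique(records$patient_id[mism & !is.na(records$patient_id)])
      mism <- mism | (!is.na(records$patient_id) &
                        records$patient_id %in% flagged_patients)
    }
    mark(mism, "replan")
  }

  if (isTRUE(rules$technique)) {
    mark(!(records$technique %in% c("3d", "imrt", "sbrt")), "technique")
  }

  if (isTRUE(rules$diagnosis) && "icd10" %in% names(records)) {
    code <- toupper(trimws(records$icd10))
    ok <- rep(FALSE, n)
    for (p in rules$icd10_include) ok <- ok | startsWith(code, toupper(p))
    out_of_list <- !is.na(code) & !ok
    if (miss_drop) out_of_list <- out_of_list | is.na(code)
    mark(out_of_list, "diagnosis")
  }

  keep <- is.na(reason)
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = as_tibble(records[keep, , drop = FALSE]),
       removed = as_tibble(removed))
}

#' Split a cohort by technique
#'
#' Disjoint partition of the records into per-technique cohorts; downstream
#' models are fit separately per technique. A bucket for `other` is returned
#' but callers should not model it; a warning is emitted when a requested
#' technique has no records.
#'
#' @param records Treatment-record tibble with canonical techniques.
#' @param techniques Techniques to report (default the observed set).
#' @return Named list of tibbles keyed by technique.
#' @export
partition_by_technique <- function(records, techniques = NULL) {
  present <- unique(records$technique)
  techniques <- techniques %||% present
  empty <- setdiff(techniques, present)
  if (length(empty) > 0L) {
    warn(paste0("no records for technique(s): ", paste(empty, collapse = ", ")))
  }
  out <- lapply(union(techniques, present), function(t) {
    as_tibble(records[records$technique == t, , drop = FALSE])
  })
  setNames(out, union(techniques, present))
}

#' Fit the prescription min-max scaler
#'
#' Stores the historical minimum and maximum of each prescription field.
#' The transform maps `v` to `(v - min) / (max - min)`. It is fit on the
#' historical cohort only; a new record outside the historical range scales
#' outside `[0, 1]` — deliberately, since an out-of-range prescription is
#' exactly what should look distant. A degenerate field (max equal to min)
#' maps to the constant 0 with a recorded warning.
#'
#' @param historical Nonempty treatment-record tibble.
#' @param fields Prescription fields (default fractions and dose per
#'   fraction).
#' @return An object of class `rx_scaler`.
#' @export
fit_rx_scaler <- function(historical,
                          fields = c("fractions", "dose_per_fraction")) {
  if (nrow(historical) == 0L) abort("cannot fit a scaler on an empty cohort")
  lims <- lapply(fields, function(f) {
    v <- historical[[f]]
    if (is.null(v) || any(is.na(v))) {
      abort(sprintf("prescription field '%s' is missing or has NA values", f))
    }
    range(v)
  })
  lims <- do.call(rbind, lims)
  degenerate <- lims[, 2] == lims[, 1]
  if (any(degenerate)) {
    warn(paste0("degenerate prescription range for: ",
                paste(fields[degenerate], collapse = ", "),
                " (field scales to constant 0)"))
  }
  structure(
    list(fields = fields, min = setNames(lims[, 1], fields),
         max = setNames(lims[, 2], fields),
         degenerate = setNames(degenerate, fields)),
    class = "rx_scaler"
  )
}

#' Scale prescription fields of records
#'
#' Applies a fitted [fit_rx_scaler()] to one or more records; values outside
#' the historical range are not clipped.
#'
#' @param scaler An `rx_scaler`.
#' @param records Treatment-record tibble.
#' @return A numeric matrix, one row per record, one column per
#'   prescription field.
#' @export
scale_rx <- function(scaler, records) {
  stopifnot(inherits(scaler, "rx_scaler"))
  out <- vapply(scaler$fields, function(f) {
    v <- records[[f]]
    if (is.null(v) || any(is.na(v))) {
      abort(sprintf("prescription field '%s' is mandatory", f))
    }
    if (scaler$degenerate[[f]]) return(rep(0, length(v)))
    (as.numeric(v) - scaler$min[[f]]) / (scaler$max[[f]] - scaler$min[[f]])
  }, numeric(nrow(records)))
  matrix(out, nrow = nrow(records), dimnames = list(NULL, scaler$fields))
}
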