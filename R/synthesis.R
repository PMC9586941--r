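# Simulated anomalies: mutate a real record into a prescription-feature
# combination that verifiably never (or almost never) occurred in the
# historical cohort, giving a labelled positive class for threshold tuning.

# sample() on a length-1 numeric would sample 1:x; this never does
resample <- function(x, k = 1L, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}

new_sim_anomaly <- function(original, mutated, mutation, changed_fields,
                            rarity_evidence) {
  structure(
    list(original = as_tibble(original), mutated = as_tibble(mutated),
         mutation = mutation, changed_fields = changed_fields,
         rarity_evidence = rarity_evidence),
    class = "rx_sim_anomaly"
  )
}

new_rejection <- function(mutation, reason, diagnostics = NULL) {
  structure(list(mutation = mutation, reason = reason,
                 diagnostics = diagnostics),
            class = "rx_sim_rejection")
}

#' @export
print.rx_sim_anomaly <- function(x, ...) {
  cat("<simulated anomaly>", x$mutation, "\n")
  cat("  changed:", paste(x$changed_fields, collapse = ", "), "\n")
  cat("  rarity evidence:",
      paste(sprintf("%s=%d", names(x$rarity_evidence), x$rarity_evidence),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.rx_sim_rejection <- function(x, ...) {
  cat("<rejected mutation>", x$mutation, "-", x$reason, "\n")
  invisible(x)
}

#' Is a mutation result an accepted simulated anomaly?
#' @param x Result of a mutator.
#' @return `TRUE` for an accepted `rx_sim_anomaly`.
#' @export
is_sim_anomaly <- function(x) inherits(x, "rx_sim_anomaly")

#' @export
as_tibble.rx_sim_anomaly <- function(x, ...) {
  out <- x$mutated
  out$mutation <- x$mutation
  out$changed_fields <- paste(x$changed_fields, collapse = ";")
  out$truth <- 1L
  out
}

leading_digit_swap <- function(fractions, dose) {
  fs <- as.character(as.integer(fractions))
  ds <- as.character(as.integer(round(dose)))
  new_f <- paste0(substr(ds, 1, 1), substr(fs, 2, nchar(fs)))
  new_d <- paste0(substr(fs, 1, 1), substr(ds, 2, nchar(ds)))
  list(fractions = as.integer(new_f), dose = as.numeric(new_d))
}

#' Simulated anomaly by prescription digit switch
#'
#' Swaps the leading decimal digit of the fraction count with the leading
#' decimal digit of the dose per fraction (remaining digits retained), e.g.
#' 5 fx x 400 cGy becomes 4 fx x 500 cGy — same total dose, very different
#' radiobiology. The swap is rejected when it is a no-op (equal leading
#' digits) or when the resulting prescription is not rare in the historical
#' index. Applying the swap twice restores the original prescription.
#'
#' @param rec One-row treatment-record tibble.
#' @param index Historical [build_index()] used for rarity verification.
#' @param ceiling Maximum historical count the mutated prescription may
#'   have (default 0: never seen).
#' @return An `rx_sim_anomaly`, or an `rx_sim_rejection` (a typed outcome,
#'   not an error).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(size = 80, seed = 3))
#' idx <- build_index(cohort)
#' switch_rx_digits(cohort[1, ], idx)
#' }
switch_rx_digits <- function(rec, index, ceiling = 0L) {
  f <- rec$fractions[1]
  d <- rec$dose_per_fraction[1]
  if (is.na(f) || is.na(d)) abort("fractions and dose_per_fraction required")
  sw <- leading_digit_swap(f, d)
  if (sw$fractions == f && sw$dose == d) {
    return(new_rejection("rx_digit_switch", "no-op swap: equal leading digits"))
  }
  mutated <- rec
  mutated$fractions <- sw$fractions
  mutated$dose_per_fraction <- sw$dose
  if ("total_dose" %in% names(mutated)) {
    mutated$total_dose <- sw$fractions * sw$dose
  }
  if ("accumulated_total_dose" %in% names(mutated)) {
    mutated$accumulated_total_dose <- sw$fractions * sw$dose
  }
  ver <- verify_rarity(mutated, index, ceiling = ceiling,
                       changed_fields = c("fractions", "dose_per_fraction"))
  if (!ver$ok) {
    return(new_rejection("rx_digit_switch",
                         "mutated prescription is common in history",
                         ver$evidence))
  }
  new_sim_anomaly(rec, mutated, "rx_digit_switch",
                  c("fractions", "dose_per_fraction"), ver$evidence)
}

#' Simulated anomaly by feature mutation
#'
#' Keeps the prescription intact and redraws the chosen feature fields from
#' their global historical domains until, conditional on the record's exact
#' prescription, every new value is verified rare (historical co-occurrence
#' count at or below the ceiling) — e.g. an intent this prescription was
#' never delivered with, or an age band it never treated. For numeric
#' fields the co-occurrence count is taken within `age_tol` of the proposed
#' value.
#'
#' @param rec One-row treatment-record tibble whose prescription occurs in
#'   the index.
#' @param index Historical [build_index()].
#' @param fields Feature fields to mutate (default: two drawn at random
#'   from the schema's feature fields).
#' @param ceiling Rarity ceiling (default 0: never co-occurred).
#' @param age_tol Half-width in years of the numeric co-occurrence band.
#' @param max_draws Draw budget before giving up.
#' @return An `rx_sim_anomaly`, or an `rx_sim_rejection` with diagnostics
#'   when the budget is exhausted.
#' @export
mutate_features <- function(rec, index, fields = NULL, ceiling = 0L,
                            age_tol = 5, max_draws = 100L) {
  schema <- index$schema
  fields <- fields %||% sample(schema$feature_fields, 2L)
  bad <- setdiff(fields, schema$feature_fields)
  if (length(bad) > 0L) {
    abort(paste0("not feature fields: ", paste(bad, collapse = ", ")))
  }
  domains <- lapply(fields, function(f) {
    v <- index$records[[f]]
    unique(v[!is.na(v)])
  })
  names(domains) <- fields
  if (any(lengths(domains) == 0L)) {
    return(new_rejection("feature_mutation", "empty historical domain"))
  }
  last_evidence <- NULL
  for (k in seq_len(max_draws)) {
    mutated <- rec
    for (f in fields) {
      mutated[[f]] <- resample(domains[[f]])
    }
    changed <- fields[vapply(fields, function(f) {
      !identical(mutated[[f]][1], rec[[f]][1]) &&
        !(is.na(mutated[[f]][1]) && is.na(rec[[f]][1]))
    }, logical(1))]
    if (length(changed) == 0L) next
    ver <- verify_rarity(mutated, index, ceiling = ceiling,
                         changed_fields = changed, age_tol = age_tol)
    last_evidence <- ver$evidence
    if (ver$ok) {
      return(new_sim_anomaly(rec, mutated, "feature_mutation", changed,
                             ver$evidence))
    }
  }
  new_rejection("feature_mutation",
                sprintf("no rare combination found in %d draws", max_draws),
                last_evidence)
}

#' Simulated anomaly by technique switch
#'
#' Relabels the technique so the record is scored against another
#' technique's model, mismatching the whole feature set at once — e.g. a
#' 3D course whose 15 MeV beam energy rarely occurs among historical IMRT
#' cases. Accepted when at least one feature field is verified rare,
#' conditional on the prescription, in the target technique's cohort; the
#' rare fields (only) are recorded as rarity evidence.
#'
#' @param rec One-row treatment-record tibble.
#' @param target_index [build_index()] of the target technique (must differ
#'   from the record's technique).
#' @param ceiling Rarity ceiling (default 0).
#' @param age_tol Numeric co-occurrence band half-width, years.
#' @return An `rx_sim_anomaly` or `rx_sim_rejection`.
#' @export
switch_technique <- function(rec, target_index, ceiling = 0L, age_tol = 5) {
  target <- target_index$technique
  if (identical(rec$technique[1], target)) {
    abort("target technique equals the record's technique")
  }
  mutated <- rec
  mutated$technique <- target
  fields <- target_index$schema$feature_fields
  ver <- verify_rarity(mutated, target_index, ceiling = ceiling,
                       changed_fields = fields, age_tol = age_tol)
  rare <- ver$evidence[!is.na(ver$evidence) & ver$evidence <= ceiling]
  if (length(rare) == 0L) {
    return(new_rejection(
      "technique_switch",
      sprintf("every feature is common with this prescription in '%s'", target),
      ver$evidence))
  }
  new_sim_anomaly(rec, mutated, "technique_switch", "technique", rare)
}

#' Verify that a mutated record is historically rare
#'
#' For each changed field, counts the historical records that share the
#' mutated record's exact prescription AND that field's value (within
#' `age_tol` for numeric fields). For a prescription change the evidence is
#' the count of the new prescription itself. The verification passes when
#' every count is at or below the ceiling — the mutated combination never
#' occurred (ceiling 0) or occurred at most `ceiling` times.
#'
#' @param mutated One-row treatment-record tibble after mutation.
#' @param index Historical [build_index()].
#' @param ceiling Maximum allowed co-occurrence count.
#' @param changed_fields Fields whose values changed.
#' @param age_tol Numeric co-occurrence band half-width, years.
#' @return List with `ok` (logical) and `evidence` (named integer counts;
#'   `NA` for a field missing in the mutated record).
#' @export
verify_rarity <- function(mutated, index, ceiling = 0L, changed_fields,
                          age_tol = 5) {
  hist <- index$records
  rx_fields <- index$schema$prescription_fields
  evidence <- integer(0)

  if (any(changed_fields %in% rx_fields)) {
    evidence <- c(evidence,
                  prescription = prescription_count(mutated, index))
  }
  feat <- setdiff(changed_fields, rx_fields)
  if (length(feat) > 0L) {
    same_rx <- rx_key(hist$fractions, hist$dose_per_fraction) ==
      rx_key(mutated$fractions[1], mutated$dose_per_fraction[1])
    for (f in feat) {
      v <- mutated[[f]][1]
      if (is.na(v)) {
        evidence[f] <- NA_integer_
        next
      }
      hv <- hist[[f]][same_rx]
      if (f %in% index$schema$numeric_fields) {
        evidence[f] <- sum(!is.na(hv) & abs(as.numeric(hv) - as.numeric(v)) <= age_tol)
      } else {
        evidence[f] <- sum(!is.na(hv) & as.character(hv) == as.character(v))
      }
    }
  }
  known <- evidence[!is.na(evidence)]
  list(ok = length(evidence) > 0L && all(known <= ceiling), evidence = evidence)
}
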