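#' Model hyperparameters
#'
#' The four tunable parameters of the distance model: the neighbourhood
#' fractions mu and nu (m = round(mu * S), n = round(nu * S), both floored
#' at 1, rounding half away from zero) and the threshold multipliers a and
#' b (t_Rx = a * theta, t_F = b * tau). At training time mu and nu are
#' constrained to (0, 0.1], confining the neighbour pools to at most 10% of
#' the historical cohort; pass `validate = FALSE` to allow wider values at
#' inference.
#'
#' @param mu,nu Neighbourhood sizes as fractions of S.
#' @param a,b Nonnegative threshold multipliers.
#' @param validate Enforce the training-time box `0 < mu, nu <= 0.1`.
#' @return An object of class `rx_params`.
#' @export
model_params <- function(mu, nu, a, b, validate = TRUE) {
  stopifnot(is.numeric(mu), is.numeric(nu), is.numeric(a), is.numeric(b))
  if (a < 0 || b < 0) abort("a and b must be nonnegative")
  if (validate && (mu <= 0 || mu > 0.1 || nu <= 0 || nu > 0.1)) {
    abort("mu and nu must lie in (0, 0.1] at training time")
  }
  structure(list(mu = mu, nu = nu, a = a, b = b), class = "rx_params")
}

# round half away from zero, floored at 1 (round() rounds half to even)
neighbour_size <- function(frac, s) {
  max(1L, as.integer(floor(frac * s + 0.5)))
}

#' Decision thresholds from the characteristic distances
#'
#' t_Rx = a * theta and t_F = b * tau: the thresholds are patterned as
#' multiples of the cohort's mean pairwise distances, so the same a and b
#' transfer across cohorts of different scale.
#'
#' @param a,b Nonnegative multipliers.
#' @param theta,tau Characteristic distances from [build_index()] /
#'   [characteristic_values()].
#' @return Named list with `t_rx` and `t_f`.
#' @export
#' @examples
#' thresholds(a = 1.926, b = 0.465, theta = 0.141, tau = 0.503)
thresholds <- function(a, b, theta, tau) {
  stopifnot(a >= 0, b >= 0, theta >= 0, tau >= 0)
  list(t_rx = a * theta, t_f = b * tau)
}

# The two-inequality decision tree on precomputed scores; shared by the
# single-record path and the tuner's vectorized path so both cannot drift.
decide <- function(r, t_rx, f, t_f) {
  if (r > t_rx) return(list(verdict = "anomaly", anomaly_type = "type_I", f = NA_real_))
  if (f > t_f) return(list(verdict = "anomaly", anomaly_type = "type_II", f = f))
  list(verdict = "normal", anomaly_type = "none", f = f)
}

#' Score one record against a historical index
#'
#' Runs the two-threshold decision tree. The closest-m prescription
#' distance R is computed first; if R exceeds t_Rx the record is flagged as
#' a type I anomaly (rare prescription) and the feature distance is not
#' evaluated (reported as `NA`, not 0). Otherwise the closest-n feature
#' distance F is computed over the same-prescription group (padded from the
#' next-closest prescription groups when fewer than n share the
#' prescription) and compared with t_F; exceeding it flags a type II
#' anomaly (prescription-feature mismatch). Both comparisons are strict:
#' equality passes.
#'
#' A warning field is attached when fewer than n historical records share
#' the record's exact prescription; the verdict is still produced.
#'
#' @param i One-row treatment-record tibble.
#' @param index An [build_index()] for the record's technique.
#' @param params An [model_params()].
#' @param exclude_id Optional record ids excluded from the neighbour pools
#'   (in-sample scoring).
#' @return A one-row detection tibble: `record_id`, `technique`, `verdict`,
#'   `anomaly_type`, `r`, `t_rx`, `f`, `t_f`, `counts`, `warnings`.
#' @export
detect <- function(i, index, params, exclude_id = NULL) {
  stopifnot(inherits(index, "rx_index"), inherits(params, "rx_params"))
  if (!is.na(i$technique[1]) && i$technique[1] != index$technique) {
    abort(sprintf("record technique '%s' does not match index technique '%s'",
                  i$technique[1], index$technique),
          class = "rx_routing_error")
  }
  prof <- distance_profile(i, index, exclude_id = exclude_id)
  m <- neighbour_size(params$mu, prof$s)
  n <- neighbour_size(params$nu, prof$s)
  if (m > prof$s || n > prof$s) {
    abort(sprintf("neighbour pool smaller than m or n (S = %d)", prof$s))
  }
  th <- thresholds(params$a, params$b, index$theta, index$tau)
  d <- decide(prof$cum_r[[m]], th$t_rx, prof$cum_f[[n]], th$t_f)
  warnings <- character()
  if (prof$count < n) {
    warnings <- c(warnings, sprintf(
      "insufficient_same_prescription_history: %d of n = %d", prof$count, n))
  }
  tibble(
    record_id = as.character(i$record_id[1] %||% NA_character_),
    technique = index$technique,
    verdict = d$verdict,
    anomaly_type = d$anomaly_type,
    r = prof$cum_r[[m]],
    t_rx = th$t_rx,
    f = d$f,
    t_f = th$t_f,
    counts = prof$count,
    warnings = list(warnings)
  )
}

#' Score a batch of records, routed per technique
#'
#' Each record is scored against the index and parameters of its own
#' technique; output order equals input order. A record whose technique has
#' no index gets a routed-warning row with the verdict withheld (`NA`).
#'
#' @param records Treatment-record tibble.
#' @param indices Named list of [build_index()] objects keyed by technique.
#' @param params A single [model_params()] applied to every technique, or a
#'   named list keyed by technique.
#' @param exclude_self When `TRUE`, each record is excluded from its own
#'   neighbour pool by `record_id` (in-sample evaluation).
#' @return A detection tibble, one row per input record.
#' @export
detect_batch <- function(records, indices, params, exclude_self = FALSE) {
  if (inherits(indices, "rx_index")) {
    indices <- setNames(list(indices), indices$technique)
  }
  per_tech_params <- function(tech) {
    if (inherits(params, "rx_params")) params else params[[tech]]
  }
  rows <- lapply(seq_len(nrow(records)), function(k) {
    rec <- records[k, , drop = FALSE]
    tech <- rec$technique[1]
    if (is.na(tech) || is.null(indices[[tech]])) {
      return(tibble(
        record_id = as.character(rec$record_id[1] %||% NA_character_),
        technique = tech, verdict = NA_character_,
        anomaly_type = NA_character_, r = NA_real_, t_rx = NA_real_,
        f = NA_real_, t_f = NA_real_, counts = NA_integer_,
        warnings = list(sprintf("no_model_for_technique: %s", tech))
      ))
    }
    detect(rec, indices[[tech]], per_tech_params(tech),
           exclude_id = if (exclude_self) rec$record_id[1] else NULL)
  })
  if (length(rows) == 0L) return(empty_detections())
  dplyr::bind_rows(rows)
}
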