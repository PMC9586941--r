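#' Pairwise prescription distance
#'
#' Euclidean distance between the min-max scaled prescription pairs
#' (fractions, dose per fraction) of two records:
#' sqrt((f_i - f_j)^2 + (d_i - d_j)^2) on the scaled values. Symmetric and
#' zero exactly when the scaled pairs coincide.
#'
#' @param i,j One-row treatment-record tibbles.
#' @param scaler A fitted [fit_rx_scaler()].
#' @return A nonnegative number.
#' @export
rx_distance <- function(i, j, scaler) {
  xi <- scale_rx(scaler, i)
  xj <- scale_rx(scaler, j)
  sqrt(sum((xi - xj)^2))
}

# Vectorized Gower dissimilarity of one record against every row of a
# cohort. Numeric fields contribute |v_i - v_j| / range; categoricals
# contribute 0/1 on mismatch; fields missing in either record are dropped
# and the average renormalized over the available fields.
gower_to_cohort <- function(rec, cohort, schema) {
  stopifnot(inherits(schema, "rx_schema"))
  if (is.null(schema$numeric_ranges) && length(schema$numeric_fields) > 0L) {
    abort("schema numeric ranges not fitted; call fit_schema() first")
  }
  n <- nrow(cohort)
  num <- rep(0, n)
  den <- rep(0L, n)
  for (f in schema$feature_fields) {
    vi <- rec[[f]][1]
    vj <- cohort[[f]]
    if (f %in% schema$numeric_fields) {
      rng <- schema$numeric_ranges[[f]]
      avail <- !is.na(vi) & !is.na(vj) & !is.na(rng) & rng > 0
      contrib <- ifelse(avail, abs(as.numeric(vi) - as.numeric(vj)) / rng, 0)
    } else {
      avail <- !is.na(vi) & !is.na(vj)
      contrib <- ifelse(avail, as.numeric(as.character(vi) != as.character(vj)), 0)
    }
    num <- num + contrib
    den <- den + as.integer(avail)
  }
  out <- rep(NA_real_, n)
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Pairwise feature (Gower) distance
#'
#' Equal-weight Gower dissimilarity over the schema's non-prescription
#' feature fields. Numeric fields contribute the range-normalized absolute
#' difference, categorical fields 0 on match and 1 on mismatch; fields
#' missing in either record are excluded and the average renormalized over
#' the comparable fields. Lies in `[0, 1]` for in-range inputs.
#'
#' @param i,j One-row treatment-record tibbles.
#' @param schema A fitted [feature_schema()].
#' @return A number in `[0, 1]`.
#' @export
gower_distance <- function(i, j, schema) {
  d <- gower_to_cohort(i, j, schema)[1]
  if (is.na(d)) {
    abort("no comparable features: every feature field is missing in the pair")
  }
  d
}

# Distance profile of one record against an index: everything the decision
# tree can need, for every possible m and n, in one O(S log S) pass.
#   cum_r[m] = mean of the m smallest prescription distances = R(i, m)
#   cum_f[n] = mean Gower over the n records selected by the two-key sort
#              (prescription distance, then Gower, then record order) = F(i, n)
distance_profile <- function(rec, index, exclude_id = NULL) {
  cohort <- index$records
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(exclude_id)) keep <- !(cohort$record_id %in% exclude_id)
  scaled <- index$scaled_rx[keep, , drop = FALSE]
  cohort <- cohort[keep, , drop = FALSE]
  s <- nrow(cohort)
  if (s == 0L) abort("empty neighbour pool")

  x <- scale_rx(index$scaler, rec)
  d_rx <- sqrt(rowSums(sweep(scaled, 2, x[1, ])^2))
  g <- gower_to_cohort(rec, cohort, index$schema)
  ord <- order(d_rx, g, seq_len(s))
  list(
    s = s,
    cum_r = cumsum(sort(d_rx)) / seq_len(s),
    cum_f = cumsum(g[ord]) / seq_len(s),
    count = prescription_count(rec, index, exclude_id = exclude_id)
  )
}

#' Closest-m group prescription distance R
#'
#' Average of the `m` smallest pairwise prescription distances between the
#' record and the historical cohort. Ties at the selection boundary are
#' broken by record order, which cannot change the value since only the
#' distances enter the mean. Non-decreasing in `m`.
#'
#' @param i One-row treatment-record tibble.
#' @param index A [build_index()] object.
#' @param m Number of nearest prescriptions to average, `1 <= m <= S`.
#' @param exclude_id Optional record ids excluded from the neighbour pool
#'   (for in-sample scoring of a record that is itself in the index).
#' @return The score R, a nonnegative number.
#' @export
group_rx_distance <- function(i, index, m, exclude_id = NULL) {
  prof <- distance_profile(i, index, exclude_id = exclude_id)
  if (m < 1 || m > prof$s) {
    abort(sprintf("m = %s outside 1..S (S = %d)", format(m), prof$s))
  }
  prof$cum_r[[m]]
}

#' Closest-n group feature distance F
#'
#' Mean Gower distance over `n` historical records chosen by a two-key
#' sort: ascending prescription distance first, ascending Gower distance
#' second. All records sharing the new record's exact prescription are thus
#' considered first (their lowest Gower values taken); if fewer than `n`
#' share it, the selection pads from the next-closest prescription groups.
#'
#' @inheritParams group_rx_distance
#' @param n Number of neighbours to average, `1 <= n <= S`.
#' @return The score F, in `[0, 1]` for in-range inputs.
#' @export
group_feature_distance <- function(i, index, n, exclude_id = NULL) {
  prof <- distance_profile(i, index, exclude_id = exclude_id)
  if (n < 1 || n > prof$s) {
    abort(sprintf("n = %s outside 1..S (S = %d)", format(n), prof$s))
  }
  prof$cum_f[[n]]
}

#' Characteristic cohort distances theta and tau
#'
#' Mean pairwise prescription distance (theta) and mean pairwise feature
#' distance (tau) over all ordered pairs j != k of the cohort — the
#' 1/(S(S-1)) normalizer excludes self-pairs; by symmetry this equals the
#' mean over unordered pairs. These set the scale for the decision
#' thresholds.
#'
#' @param cohort Treatment-record tibble with at least two rows.
#' @param scaler A fitted [fit_rx_scaler()].
#' @param schema A fitted [feature_schema()].
#' @return A named list with `theta` and `tau`.
#' @export
characteristic_values <- function(cohort, scaler, schema) {
  s <- nrow(cohort)
  if (s < 2L) abort("characteristic values need at least 2 records")
  scaled <- scale_rx(scaler, cohort)
  theta <- mean(dist(scaled))

  num <- matrix(0, s, s)
  den <- matrix(0L, s, s)
  for (f in schema$feature_fields) {
    v <- cohort[[f]]
    if (f %in% schema$numeric_fields) {
      rng <- schema$numeric_ranges[[f]]
      if (is.na(rng) || rng <= 0) next
      x <- as.numeric(v)
      contrib <- abs(outer(x, x, "-")) / rng
      avail <- outer(!is.na(x), !is.na(x), "&")
    } else {
      x <- as.character(v)
      avail <- outer(!is.na(x), !is.na(x), "&")
      xx <- x
      xx[is.na(xx)] <- ""
      contrib <- 1 - outer(xx, xx, "==")
    }
    contrib[!avail] <- 0
    num <- num + contrib
    den <- den + avail
  }
  pair <- upper.tri(den)
  ok <- pair & den > 0
  if (any(pair & den == 0)) {
    warn("pairs with no comparable features excluded from tau")
  }
  tau <- mean(num[ok] / den[ok])
  list(theta = theta, tau = tau)
}

rx_key <- function(fractions, dose) {
  paste(as.integer(fractions), round(as.numeric(dose)), sep = "x")
}

#' Historical count of an exact prescription
#'
#' Number of historical records whose prescription matches the record's
#' exactly: same fraction count, same dose per fraction after rounding to
#' integer cGy.
#'
#' @inheritParams group_rx_distance
#' @return A nonnegative integer.
#' @export
prescription_count <- function(i, index, exclude_id = NULL) {
  key <- rx_key(i$fractions[1], i$dose_per_fraction[1])
  n <- unname(index$rx_counts[key])
  if (is.na(n)) n <- 0L
  if (!is.null(exclude_id)) {
    own <- index$records$record_id %in% exclude_id &
      rx_key(index$records$fractions, index$records$dose_per_fraction) == key
    n <- n - sum(own)
  }
  as.integer(n)
}
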