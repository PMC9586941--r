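# Independent brute-force oracles. These deliberately re-derive every
# quantity from the definitions with plain loops and sorts, sharing no code
# with the package's vectorized/cumulative implementations.

oracle_scale <- function(v, lo, hi) if (hi == lo) 0 else (v - lo) / (hi - lo)

oracle_rx_distance <- function(i, j, cohort) {
  fl <- range(cohort$fractions)
  dl <- range(cohort$dose_per_fraction)
  sqrt((oracle_scale(i$fractions, fl[1], fl[2]) -
          oracle_scale(j$fractions, fl[1], fl[2]))^2 +
       (oracle_scale(i$dose_per_fraction, dl[1], dl[2]) -
          oracle_scale(j$dose_per_fraction, dl[1], dl[2]))^2)
}

oracle_gower <- function(i, j, age_range) {
  num <- 0; den <- 0
  if (!is.na(i$age) && !is.na(j$age) && age_range > 0) {
    num <- num + abs(i$age - j$age) / age_range
    den <- den + 1
  }
  for (f in c("energy", "intent", "icd10", "morphology")) {
    vi <- i[[f]]; vj <- j[[f]]
    if (!is.na(vi) && !is.na(vj)) {
      num <- num + as.numeric(vi != vj)
      den <- den + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

oracle_R <- function(rec, cohort, m) {
  d <- vapply(seq_len(nrow(cohort)), function(k) {
    oracle_rx_distance(rec, cohort[k, ], cohort)
  }, numeric(1))
  mean(sort(d)[seq_len(m)])
}

oracle_F <- function(rec, cohort, n) {
  age_range <- diff(range(cohort$age, na.rm = TRUE))
  rho <- vapply(seq_len(nrow(cohort)), function(k) {
    oracle_rx_distance(rec, cohort[k, ], cohort)
  }, numeric(1))
  g <- vapply(seq_len(nrow(cohort)), function(k) {
    oracle_gower(rec, cohort[k, ], age_range)
  }, numeric(1))
  sel <- order(rho, g)[seq_len(n)]
  mean(g[sel])
}

oracle_theta_tau <- function(cohort) {
  s <- nrow(cohort)
  age_range <- diff(range(cohort$age, na.rm = TRUE))
  th <- 0; ta <- 0; n_ta <- 0L
  for (j in seq_len(s)) {
    for (k in seq_len(s)) {
      if (j == k) next
      th <- th + oracle_rx_distance(cohort[j, ], cohort[k, ], cohort)
      gg <- oracle_gower(cohort[j, ], cohort[k, ], age_range)
      if (!is.na(gg)) { ta <- ta + gg; n_ta <- n_ta + 1L }
    }
  }
  list(theta = th / (s * (s - 1)), tau = ta / n_ta)
}

oracle_count <- function(rec, cohort) {
  n <- 0L
  for (k in seq_len(nrow(cohort))) {
    if (cohort$fractions[k] == rec$fractions &&
        round(cohort$dose_per_fraction[k]) == round(rec$dose_per_fraction)) {
      n <- n + 1L
    }
  }
  n
}

# random mixed-type cohorts for property and oracle-equivalence tests;
# prescriptions drawn from a small pool so exact repeats occur
random_cohort <- function(s, seed) {
  set.seed(seed)
  rx_pool <- data.frame(
    fractions = c(5L, 10L, 15L, 25L, 30L, sample(1:41, 3)),
    dose = c(400, 300, 300, 180, 150, sample(seq(100, 2000, by = 10), 3))
  )
  pick <- sample.int(nrow(rx_pool), s, replace = TRUE)
  maybe_na <- function(x, p = 0.1) {
    x[runif(length(x)) < p] <- NA
    x
  }
  tibble::tibble(
    record_id = as.character(seq_len(s)),
    fractions = rx_pool$fractions[pick],
    dose_per_fraction = rx_pool$dose[pick],
    total_dose = rx_pool$fractions[pick] * rx_pool$dose[pick],
    accumulated_total_dose = rx_pool$fractions[pick] * rx_pool$dose[pick],
    technique = "3d",
    energy = maybe_na(sample(c("6", "10", "15", "mixed photon"), s, TRUE)),
    intent = maybe_na(sample(c("curative", "palliative"), s, TRUE)),
    icd10 = maybe_na(sample(c("C34.1", "C34.9", "C15.9", "C78.1"), s, TRUE)),
    morphology = maybe_na(sample(c("80463", "87203", "80413"), s, TRUE), 0.2),
    age = maybe_na(round(runif(s, 30, 90)), 0.05)
  )
}

random_record <- function(seed) {
  random_cohort(1L, seed)
}
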