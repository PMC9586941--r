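# Synthetic per-technique cohorts. Restricted clinical treatment records
# cannot be redistributed, so fixtures are drawn from a declarative spec
# that reproduces the statistical structure the detector relies on: a small
# catalog of prescriptions with very unequal frequencies, and feature
# distributions conditioned on the prescription (a prescription that is
# always curative, an energy that only one prescription uses, ...).

rtnorm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(qnorm(p, mean, sd), lo), hi)
}

default_catalogs <- list(
  "3d" = tibble(
    fractions = c(10L, 15L, 25L, 30L, 5L, 10L),
    dose_per_fraction = c(300, 300, 180, 150, 400, 250),
    weight = c(0.28, 0.18, 0.16, 0.14, 0.14, 0.10)
  ),
  imrt = tibble(
    fractions = c(25L, 30L, 10L, 15L, 15L, 10L),
    dose_per_fraction = c(180, 150, 300, 350, 400, 250),
    weight = c(0.25, 0.22, 0.18, 0.15, 0.12, 0.08)
  ),
  sbrt = tibble(
    fractions = c(5L, 4L, 5L),
    dose_per_fraction = c(1000, 1200, 400),
    weight = c(0.5, 0.3, 0.2)
  )
)

cond <- function(intent, energy, icd10, morphology, age) {
  list(intent = intent, energy = energy, icd10 = icd10,
       morphology = morphology, age = age)
}

# per-prescription conditional feature tables (probabilities) and a
# truncated-normal age model c(mean, sd, lo, hi) in years
default_feature_models <- list(
  "3d" = list(
    "10x300" = cond(c(palliative = 1),
                    c("15" = 0.9, "6" = 0.1),
                    c("C78.1" = 0.7, "C34.9" = 0.3),
                    c("80463" = 0.6, "80413" = 0.4), c(74, 8, 40, 95)),
    "15x300" = cond(c(palliative = 0.9, curative = 0.1),
                    c("6" = 0.8, "15" = 0.2),
                    c("C34.1" = 0.6, "C34.3" = 0.4),
                    c("80413" = 0.7, "80463" = 0.3), c(70, 9, 40, 92)),
    "25x180" = cond(c(curative = 1), c("6" = 1),
                    c("C15.9" = 0.6, "C15.6" = 0.4),
                    c("87203" = 0.8, "81403" = 0.2), c(62, 9, 35, 85)),
    "30x150" = cond(c(curative = 1), c("6" = 0.9, "10" = 0.1),
                    c("C34.1" = 0.5, "C34.3" = 0.5),
                    c("80413" = 0.7, "81403" = 0.3), c(60, 8, 35, 82)),
    "5x400" = cond(c(palliative = 1),
                   c("mixed photon" = 0.8, "15" = 0.2),
                   c("C34.9" = 0.8, "C78.1" = 0.2),
                   c("80463" = 1), c(76, 7, 50, 95)),
    "10x250" = cond(c(curative = 1), c("6" = 1), c("C34.1" = 1),
                    c("80413" = 1), c(63, 7, 40, 80))
  ),
  imrt = list(
    "25x180" = cond(c(curative = 1), c("6" = 1),
                    c("C15.9" = 0.6, "C15.6" = 0.4),
                    c("87203" = 0.8, "81403" = 0.2), c(63, 9, 35, 85)),
    "30x150" = cond(c(curative = 1), c("6" = 1),
                    c("C34.1" = 0.5, "C34.3" = 0.5),
                    c("80413" = 0.7, "81403" = 0.3), c(60, 8, 35, 82)),
    "10x300" = cond(c(palliative = 1), c("6" = 1),
                    c("C78.1" = 0.6, "C34.9" = 0.4),
                    c("80463" = 1), c(72, 8, 40, 95)),
    "15x350" = cond(c(curative = 0.7, palliative = 0.3), c("10" = 1),
                    c("C34.3" = 1), c("81403" = 1), c(66, 8, 40, 88)),
    "15x400" = cond(c(curative = 1), c("10" = 1),
                    c("C38.1" = 0.5, "C34.9" = 0.5),
                    c("87203" = 1), c(64, 9, 40, 86)),
    "10x250" = cond(c(curative = 1), c("6" = 1), c("C34.1" = 1),
                    c("80413" = 1), c(63, 7, 40, 80))
  ),
  sbrt = list(
    "5x1000" = cond(c(curative = 1),
                    c("6fff" = 0.7, "10fff" = 0.3),
                    c("R91.1" = 0.5, "C34.1" = 0.5),
                    c("80463" = 0.5, "80413" = 0.5), c(71, 9, 40, 92)),
    "4x1200" = cond(c(palliative = 0.5, curative = 0.5),
                    c("6" = 0.6, "6fff" = 0.4),
                    c("C34.3" = 0.5, "C34.1" = 0.5),
                    c("87203" = 0.7, "80463" = 0.3), c(55, 10, 30, 80)),
    "5x400" = cond(c(palliative = 1), c("6fff" = 1), c("C34.9" = 1),
                   c("80463" = 1), c(75, 8, 45, 95))
  )
)

default_missingness <- c(age = 0.01, energy = 0.05, intent = 0.02,
                         icd10 = 0.02, morphology = 0.2)

#' Specification of a synthetic per-technique cohort
#'
#' Declares the prescription catalog (with sampling weights), the
#' per-prescription conditional feature distributions, per-feature
#' missingness rates and the seed. Defaults provide realistic thoracic
#' cohorts for each technique, with strongly prescription-conditioned
#' features so that prescription-feature mismatches are well defined.
#'
#' @param technique Canonical technique (`3d`, `imrt`, `sbrt`).
#' @param size Number of records S (>= 2).
#' @param catalog Tibble with `fractions`, `dose_per_fraction`, `weight`;
#'   default per technique.
#' @param feature_model Named list keyed by prescription (`"5x400"`), each
#'   entry a list of probability tables for `intent`, `energy`, `icd10`,
#'   `morphology` plus an `age` vector `c(mean, sd, lo, hi)`.
#' @param missingness Named per-feature missingness rates.
#' @param seed Integer seed; the generated cohort is deterministic in it.
#' @return An object of class `rx_cohort_spec`.
#' @export
cohort_spec <- function(technique = "3d", size = 500L, catalog = NULL,
                        feature_model = NULL, missingness = NULL, seed = 1L) {
  if (!technique %in% names(default_catalogs)) {
    abort("technique: must be one of 3d, imrt, sbrt")
  }
  if (!is.numeric(size) || size < 2) abort("size: must be at least 2")
  catalog <- catalog %||% default_catalogs[[technique]]
  if (!all(c("fractions", "dose_per_fraction", "weight") %in% names(catalog))) {
    abort("catalog: needs fractions, dose_per_fraction, weight columns")
  }
  if (any(catalog$weight <= 0)) abort("catalog: weights must be positive")
  feature_model <- feature_model %||% default_feature_models[[technique]]
  keys <- rx_key(catalog$fractions, catalog$dose_per_fraction)
  missing_fm <- setdiff(keys, names(feature_model))
  if (length(missing_fm) > 0L) {
    abort(paste0("feature_model: no entry for prescription(s) ",
                 paste(missing_fm, collapse = ", ")))
  }
  for (key in keys) {
    fm <- feature_model[[key]]
    for (tab in c("intent", "energy", "icd10", "morphology")) {
      p <- fm[[tab]]
      if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        abort(sprintf("feature_model: table '%s' for %s must sum to 1",
                      tab, key))
      }
    }
    if (length(fm$age) != 4L || fm$age[2] <= 0) {
      abort(sprintf("feature_model: age for %s must be c(mean, sd, lo, hi)", key))
    }
  }
  missingness <- missingness %||% default_missingness
  structure(
    list(technique = technique, size = as.integer(size), catalog = catalog,
         feature_model = feature_model, missingness = missingness,
         seed = as.integer(seed)),
    class = "rx_cohort_spec"
  )
}

#' Generate a synthetic historical cohort
#'
#' Draws `spec$size` single-plan treatment courses: the prescription from
#' the weighted catalog, each clinical feature from that prescription's
#' conditional distribution, ages from a truncated normal, and missing
#' values per the configured rates. `total_dose` is fractions times dose
#' per fraction and the accumulated dose equals it (no re-plans), so the
#' output passes [filter_cohort()] untouched. Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @return A treatment-record tibble of `spec$size` rows.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec("sbrt", size = 100, seed = 42))
#' dplyr::count(cohort, fractions, dose_per_fraction)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rx_cohort_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)

  s <- spec$size
  cat_idx <- sample.int(nrow(spec$catalog), s, replace = TRUE,
                        prob = spec$catalog$weight)
  fractions <- spec$catalog$fractions[cat_idx]
  dose <- spec$catalog$dose_per_fraction[cat_idx]
  keys <- rx_key(fractions, dose)

  intent <- energy <- icd10 <- morphology <- rep(NA_character_, s)
  age <- rep(NA_real_, s)
  for (key in unique(keys)) {
    rows <- which(keys == key)
    fm <- spec$feature_model[[key]]
    pick <- function(tab) {
      names(tab)[sample.int(length(tab), length(rows), replace = TRUE,
                            prob = tab)]
    }
    intent[rows] <- pick(fm$intent)
    energy[rows] <- pick(fm$energy)
    icd10[rows] <- pick(fm$icd10)
    morphology[rows] <- pick(fm$morphology)
    age[rows] <- round(rtnorm(length(rows), fm$age[1], fm$age[2],
                              fm$age[3], fm$age[4]))
  }
  out <- tibble(
    record_id = sprintf("syn_%04d", seq_len(s)),
    fractions = as.integer(fractions),
    dose_per_fraction = dose,
    total_dose = fractions * dose,
    accumulated_total_dose = fractions * dose,
    technique = spec$technique,
    energy = energy, intent = intent, icd10 = icd10,
    morphology = morphology, age = age
  )
  for (f in names(spec$missingness)) {
    rate <- spec$missingness[[f]]
    if (rate > 0 && f %in% names(out)) {
      out[[f]][runif(s) < rate] <- NA
    }
  }
  out
}

#' Plant verified simulated anomalies and a disjoint normal holdout
#'
#' Assembles a labelled evaluation set from a synthetic (or real) cohort:
#' `k` source records are mutated into rarity-verified simulated anomalies
#' and `n_normals` further records become the holdout normal class. Both
#' the sources and the holdout are removed from the remaining historical
#' set, so the index built on `$historical` never sees the test data.
#' Rarity is verified against that historical set.
#'
#' @param cohort Treatment-record tibble.
#' @param k Number of simulated anomalies (>= 1).
#' @param mix Named weights over mutation families `rx_digit_switch`,
#'   `feature_mutation`, `technique_switch`; default an even split of the
#'   two within-technique families.
#' @param n_normals Holdout normal count (default `k`).
#' @param seed Integer seed.
#' @param ceiling Rarity ceiling passed to the mutators.
#' @param target_index Historical index of another technique, required only
#'   when `technique_switch` has positive weight.
#' @param max_attempts Overall mutation attempt budget.
#' @return A list with tibbles `anomalies` (with `truth = 1`, mutation
#'   provenance columns), `normals` (`truth = 0`) and `historical`, plus
#'   `index` built on the historical set.
#' @export
plant_anomalies <- function(cohort, k, mix = c(rx_digit_switch = 0.5,
                                               feature_mutation = 0.5),
                            n_normals = k, seed = 1L, ceiling = 0L,
                            target_index = NULL, max_attempts = 50L * k) {
  if (k < 1) abort("k must be at least 1")
  if (nrow(cohort) < k + n_normals + 2L) {
    abort("cohort too small for the requested anomaly and holdout counts")
  }
  mix <- mix[mix > 0]
  if ("technique_switch" %in% names(mix) && is.null(target_index)) {
    abort("technique_switch in the mix requires target_index")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  held <- resample(seq_len(nrow(cohort)), k + n_normals)
  sources <- cohort[held[seq_len(k)], , drop = FALSE]
  normals <- cohort[held[k + seq_len(n_normals)], , drop = FALSE]
  historical <- cohort[-held, , drop = FALSE]
  index <- build_index(historical)

  anomalies <- list()
  attempts <- 0L
  src_i <- 1L
  while (length(anomalies) < k && attempts < max_attempts) {
    attempts <- attempts + 1L
    rec <- sources[src_i, , drop = FALSE]
    family <- resample(names(mix), 1L)
    if (length(mix) == 1L) family <- names(mix)
    res <- switch(family,
      rx_digit_switch = switch_rx_digits(rec, index, ceiling = ceiling),
      feature_mutation = mutate_features(rec, index, ceiling = ceiling),
      technique_switch = switch_technique(rec, target_index, ceiling = ceiling)
    )
    if (is_sim_anomaly(res)) {
      row <- as_tibble(res)
      row$record_id <- sprintf("sa_%03d_%s", length(anomalies) + 1L,
                               rec$record_id[1])
      anomalies[[length(anomalies) + 1L]] <- row
      src_i <- src_i + 1L
    } else {
      # rejected: try the next source, cycling, under the shared budget
      src_i <- src_i %% k + 1L
    }
    if (src_i > k) src_i <- 1L
  }
  if (length(anomalies) < k) {
    abort(sprintf(
      "could not synthesize %d verified anomalies within %d attempts (got %d)",
      k, max_attempts, length(anomalies)))
  }
  normals$truth <- 0L
  list(
    anomalies = dplyr::bind_rows(anomalies),
    normals = as_tibble(normals),
    historical = as_tibble(historical),
    index = index
  )
}
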