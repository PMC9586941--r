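make_range_cohort <- function() {
  # spans fractions 1..41 and dose 100..2000 so the scaled ranges are known
  dplyr::bind_rows(rec(1, 100, id = "lo"), rec(41, 2000, id = "hi"))
}

test_that("pairwise prescription distance follows the scaled Euclidean formula", {
  sc <- fit_rx_scaler(make_range_cohort())
  expect_equal(rx_distance(rec(5, 400), rec(5, 400), sc), 0)
  expect_equal(rx_distance(rec(5, 400), rec(4, 500), sc),
               sqrt((1 / 40)^2 + (100 / 1900)^2))
  expect_equal(round(rx_distance(rec(5, 400), rec(4, 500), sc), 4), 0.0583)
  expect_equal(rx_distance(rec(1, 100), rec(41, 2000), sc), sqrt(2))
  # symmetry
  expect_equal(rx_distance(rec(4, 500), rec(5, 400), sc),
               rx_distance(rec(5, 400), rec(4, 500), sc))
  expect_error(rx_distance(rec(NA, 400), rec(5, 400), sc), "mandatory")
})

test_that("Gower distance handles mixed types and missing-field renormalization", {
  schema <- feature_schema(numeric_ranges = c(age = 90))
  a <- rec(5, 400, energy = "6", intent = "curative", icd10 = "C34.1",
           morphology = "80463", age = 60)
  expect_equal(gower_distance(a, a, schema), 0)

  b <- rec(5, 400, energy = "10", intent = "palliative", icd10 = "C15.9",
           morphology = "87203", age = 60)
  expect_equal(gower_distance(a, b, schema), 4 / 5) # ages equal, 4 mismatches

  c_ <- rec(5, 400, energy = "6", intent = "palliative", icd10 = "C34.1",
            morphology = "80463", age = 40)
  expect_equal(gower_distance(a, c_, schema), (20 / 90 + 1) / 5)

  # missing fields are excluded and the average renormalized
  d <- rec(5, 400, energy = NA, intent = "palliative", icd10 = "C34.1",
           morphology = NA, age = 60)
  expect_equal(gower_distance(a, d, schema), 1 / 3)

  all_na <- rec(5, 400)
  expect_error(gower_distance(all_na, all_na, schema), "no comparable")
})

test_that("group distances and counts match brute-force oracles on small cohorts", {
  for (seed in c(3, 14, 27)) {
    cohort <- random_cohort(25, seed = seed)
    idx <- build_index(cohort)
    probe <- random_record(seed + 1000)
    for (m in c(1L, 5L, 8L)) {
      expect_equal(group_rx_distance(probe, idx, m), oracle_R(probe, cohort, m))
      expect_equal(group_feature_distance(probe, idx, m),
                   oracle_F(probe, cohort, m))
    }
    expect_equal(prescription_count(probe, idx), oracle_count(probe, cohort))
  }
})

test_that("the two-key selection takes same-prescription records first", {
  # 12 records share the probe's prescription; with n = 10 the score is the
  # mean of the 10 lowest Gower distances inside that group
  same <- lapply(1:12, function(k) {
    rec(5, 400, energy = "6", intent = "curative", icd10 = "C34.1",
        morphology = "80463", age = 40 + 4 * k, id = paste0("s", k))
  })
  far <- lapply(1:8, function(k) {
    rec(30, 150, energy = "6", intent = "curative", icd10 = "C34.1",
        morphology = "80463", age = 40 + 4 * k, id = paste0("f", k))
  })
  cohort <- dplyr::bind_rows(c(same, far))
  idx <- build_index(cohort)
  probe <- rec(5, 400, energy = "6", intent = "curative", icd10 = "C34.1",
               morphology = "80463", age = 40)
  age_rng <- diff(range(cohort$age))
  gow <- abs((40 + 4 * (1:12)) - 40) / age_rng / 5
  expect_equal(group_feature_distance(probe, idx, 10), mean(sort(gow)[1:10]))
  # and with n beyond the group, padding comes from the next prescription group
  expect_equal(group_feature_distance(probe, idx, 15),
               oracle_F(probe, cohort, 15))
})

test_that("R is non-decreasing in m and F matches the oracle across n", {
  cohort <- random_cohort(30, seed = 77)
  idx <- build_index(cohort)
  probe <- random_record(78)
  rs <- vapply(1:30, function(m) group_rx_distance(probe, idx, m), numeric(1))
  expect_true(all(diff(rs) >= -1e-12))
  expect_error(group_rx_distance(probe, idx, 31), "outside")
  expect_error(group_feature_distance(probe, idx, 0), "outside")
})

test_that("characteristic values equal the ordered-pair means and permutation-invariant", {
  two_same <- dplyr::bind_rows(
    rec(5, 400, energy = "6", age = 60, id = "a"),
    rec(5, 400, energy = "6", age = 60, id = "b")
  )
  suppressWarnings({
    sc <- fit_rx_scaler(two_same)
    schema <- fit_schema(feature_schema(), two_same)
    ch <- characteristic_values(two_same, sc, schema)
  })
  expect_equal(ch$theta, 0)
  expect_equal(ch$tau, 0)

  two <- dplyr::bind_rows(
    rec(5, 400, energy = "6", age = 50, id = "a"),
    rec(10, 300, energy = "10", age = 70, id = "b")
  )
  sc2 <- fit_rx_scaler(two)
  schema2 <- fit_schema(feature_schema(), two)
  ch2 <- characteristic_values(two, sc2, schema2)
  expect_equal(ch2$theta, rx_distance(two[1, ], two[2, ], sc2))
  expect_equal(ch2$tau, gower_distance(two[1, ], two[2, ], schema2))

  cohort <- random_cohort(10, seed = 9)
  idx <- build_index(cohort)
  oc <- oracle_theta_tau(cohort)
  expect_equal(idx$theta, oc$theta)
  expect_equal(idx$tau, oc$tau)

  perm <- cohort[sample(1:10), ]
  idx_p <- build_index(perm)
  expect_equal(idx_p$theta, idx$theta)
  expect_equal(idx_p$tau, idx$tau)

  expect_error(characteristic_values(cohort[1, ], idx$scaler, idx$schema),
               "at least 2")
})

test_that("prescription counts use exact matching at 1 cGy resolution", {
  cohort <- random_cohort(40, seed = 12)
  idx <- build_index(cohort)
  expect_equal(prescription_count(rec(39, 1999.4), idx), 0L) # unseen
  sum_counts <- sum(idx$rx_counts)
  expect_equal(sum_counts, nrow(cohort))
  # rounding to integer cGy: 400.4 matches 400
  probe <- rec(cohort$fractions[1], cohort$dose_per_fraction[1] + 0.4)
  expect_equal(prescription_count(probe, idx),
               oracle_count(rec(cohort$fractions[1], cohort$dose_per_fraction[1]),
                            cohort))
})

test_that("in-sample scoring excludes the record's own entry from its pools", {
  cohort <- random_cohort(20, seed = 31)
  idx <- build_index(cohort)
  own <- cohort[4, ]
  rest <- cohort[-4, ]
  expect_equal(group_rx_distance(own, idx, 3, exclude_id = own$record_id),
               oracle_R(own, rest, 3))
  expect_equal(prescription_count(own, idx, exclude_id = own$record_id),
               oracle_count(own, rest))
})

test_that("an index survives the JSON round-trip without recomputation drift", {
  cohort <- random_cohort(30, seed = 55)
  idx <- build_index(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_index(idx, path)
  back <- read_index(path)
  expect_equal(back$theta, idx$theta)
  expect_equal(back$tau, idx$tau)
  expect_equal(back$rx_counts, idx$rx_counts)
  expect_equal(back$scaler$min, idx$scaler$min)
  probe <- random_record(56)
  expect_equal(group_feature_distance(probe, back, 7),
               group_feature_distance(probe, idx, 7))
})
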