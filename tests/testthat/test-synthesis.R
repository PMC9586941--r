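test_that("the leading-digit switch follows the digit-string rule", {
  cohort <- sbrt_facts_cohort()
  idx <- build_index(cohort)

  src <- rec(5, 400, technique = "sbrt", energy = "6fff", age = 76, id = "o")
  sa <- switch_rx_digits(src, idx)
  expect_true(is_sim_anomaly(sa))
  expect_equal(sa$mutated$fractions, 4L)
  expect_equal(sa$mutated$dose_per_fraction, 500)
  expect_equal(sa$mutated$total_dose, 2000) # total preserved by this swap

  # multi-digit quantities keep their trailing digits
  sa2 <- switch_rx_digits(rec(4, 1200, technique = "sbrt", id = "o2"), idx)
  expect_true(is_sim_anomaly(sa2))
  expect_equal(sa2$mutated$fractions, 1L)
  expect_equal(sa2$mutated$dose_per_fraction, 4200)

  # equal leading digits: a no-op, rejected as a typed outcome
  rej <- switch_rx_digits(rec(4, 400, technique = "sbrt", id = "o3"), idx)
  expect_false(is_sim_anomaly(rej))
  expect_s3_class(rej, "rx_sim_rejection")

  # a swap landing on a common prescription is rejected by rarity
  rej2 <- switch_rx_digits(rec(1, 5000, technique = "sbrt", id = "o4"), idx)
  expect_false(is_sim_anomaly(rej2)) # (1, 5000) -> (5, 1000): 40 occurrences
  expect_equal(unname(rej2$diagnostics["prescription"]), 40L)
})

test_that("the digit switch is an involution on accepted outputs", {
  cohort <- sbrt_facts_cohort()
  idx <- build_index(cohort)
  for (rx in list(c(5, 400), c(4, 1200), c(10, 300), c(25, 180))) {
    src <- rec(rx[1], rx[2], technique = "sbrt", id = "inv")
    sa <- switch_rx_digits(src, idx)
    if (is_sim_anomaly(sa)) {
      swap2 <- rxanomaly:::leading_digit_swap(sa$mutated$fractions,
                                              sa$mutated$dose_per_fraction)
      expect_equal(swap2$fractions, src$fractions)
      expect_equal(swap2$dose, src$dose_per_fraction)
    }
  }
})

test_that("feature mutation accepts only verified-rare conditional values", {
  cohort <- sbrt_facts_cohort()
  idx <- build_index(cohort)
  src <- idx$records[1, ] # 5 x 1000, curative

  set.seed(1)
  sa <- mutate_features(src, idx, fields = c("intent", "age"))
  expect_true(is_sim_anomaly(sa))
  for (f in sa$changed_fields) {
    expect_lte(sa$rarity_evidence[[f]], 0L)
  }
  # the drawn values come from the global historical domain
  if ("intent" %in% sa$changed_fields) {
    expect_true(sa$mutated$intent %in% cohort$intent)
  }

  # reproducible under a fixed seed
  set.seed(77)
  a <- mutate_features(src, idx, fields = c("icd10", "energy"))
  set.seed(77)
  b <- mutate_features(src, idx, fields = c("icd10", "energy"))
  expect_equal(a$mutated, b$mutated)

  # degenerate cohort where every domain value co-occurs: rejection with
  # diagnostics, not an error
  flat <- dplyr::bind_rows(lapply(1:10, function(k) {
    rec(5 + (k %% 2), 400, technique = "sbrt", energy = "6",
        intent = "curative", icd10 = "C34.1", morphology = "80463",
        age = 60, id = paste0("f", k))
  }))
  suppressWarnings(idx_flat <- build_index(flat))
  rej <- mutate_features(flat[1, ], idx_flat, fields = "intent",
                         max_draws = 20)
  expect_s3_class(rej, "rx_sim_rejection")
  expect_match(rej$reason, "draws")
})

test_that("technique switch verifies rarity against the target cohort", {
  imrt_idx <- build_index(imrt_facts_cohort())
  src <- rec(10, 300, technique = "3d", energy = "15", intent = "palliative",
             icd10 = "C78.1", age = 74, id = "d")
  sa <- switch_technique(src, imrt_idx)
  expect_true(is_sim_anomaly(sa))
  expect_equal(sa$mutated$technique, "imrt")
  # the 15 MV beam never occurs with this prescription among IMRT courses
  expect_equal(unname(sa$rarity_evidence["energy"]), 0L)

  expect_error(switch_technique(sa$mutated, imrt_idx), "equals")

  # a record matching the target cohort's patterns is rejected
  common <- rec(10, 300, technique = "3d", energy = "6",
                intent = "palliative", icd10 = "C78.1", morphology = "80463",
                age = 70, id = "c")
  rej <- switch_technique(common, imrt_idx)
  expect_s3_class(rej, "rx_sim_rejection")

  # the relabelled record routes to the target technique's model
  det <- detect_batch(sa$mutated, imrt_idx, model_params(0.05, 0.05, 1, 1))
  expect_equal(det$technique, "imrt")
})

test_that("verify_rarity counts conditional co-occurrences like a linear scan", {
  cohort <- sbrt_facts_cohort()
  idx <- build_index(cohort)

  # prescription mutation: evidence is the new prescription's own count
  mut <- rec(4, 1200, technique = "sbrt", id = "m")
  ver <- verify_rarity(mut, idx, ceiling = 0,
                       changed_fields = c("fractions", "dose_per_fraction"))
  expect_false(ver$ok) # 4 x 1200 occurs 30 times
  expect_equal(unname(ver$evidence["prescription"]), 30L)
  # seen-once prescriptions pass at ceiling 1
  once <- dplyr::bind_rows(cohort, rec(4, 500, technique = "sbrt",
                                       energy = "6", intent = "palliative",
                                       icd10 = "C34.1", age = 60, id = "once"))
  idx1 <- build_index(once)
  v1 <- verify_rarity(rec(4, 500, technique = "sbrt"), idx1, ceiling = 1,
                      changed_fields = "fractions")
  expect_true(v1$ok)
  expect_equal(unname(v1$evidence["prescription"]), 1L)

  # feature mutation: evidence is the same-prescription co-occurrence count
  mut2 <- rec(5, 1000, technique = "sbrt", intent = "palliative", age = 10)
  v2 <- verify_rarity(mut2, idx, ceiling = 0,
                      changed_fields = c("intent", "age"))
  expect_true(v2$ok)
  scan_intent <- sum(cohort$fractions == 5 & cohort$dose_per_fraction == 1000 &
                       cohort$intent == "palliative", na.rm = TRUE)
  expect_equal(unname(v2$evidence["intent"]), scan_intent)
  # numeric field: counted within the +/- 5 year band
  scan_age <- sum(cohort$fractions == 5 & cohort$dose_per_fraction == 1000 &
                    abs(cohort$age - 10) <= 5, na.rm = TRUE)
  expect_equal(unname(v2$evidence["age"]), scan_age)

  # a common intent fails verification
  v3 <- verify_rarity(rec(5, 1000, technique = "sbrt", intent = "curative"),
                      idx, ceiling = 0, changed_fields = "intent")
  expect_false(v3$ok)
})
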