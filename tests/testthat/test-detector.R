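test_that("thresholds scale the characteristic distances", {
  th <- thresholds(a = 1.926, b = 0.465, theta = 0.141, tau = 0.503)
  expect_equal(th$t_rx, 1.926 * 0.141)
  expect_equal(th$t_f, 0.465 * 0.503)
  expect_equal(thresholds(0, 1, 0.2, 0.5)$t_rx, 0)
})

test_that("model parameter box and neighbour-size rounding behave as specified", {
  expect_error(model_params(0.2, 0.05, 1, 1), "0.1")
  expect_error(model_params(0.05, 0, 1, 1), "0.1")
  expect_error(model_params(0.05, 0.05, -1, 1), "nonnegative")
  expect_s3_class(model_params(0.2, 0.5, 1, 1, validate = FALSE), "rx_params")
  # round half away from zero, floored at 1
  expect_equal(rxanomaly:::neighbour_size(0.005, 100), 1L)  # 0.5 -> 1
  expect_equal(rxanomaly:::neighbour_size(0.015, 100), 2L)  # 1.5 -> 2
  expect_equal(rxanomaly:::neighbour_size(0.025, 100), 3L)  # 2.5 -> 3
  expect_equal(rxanomaly:::neighbour_size(0.0001, 500), 1L) # floor at 1
})

test_that("the decision tree flags type I, type II and normal; equality passes", {
  decide <- rxanomaly:::decide
  d1 <- decide(0.00, 0.271566, 0.56, 0.233895)
  expect_equal(d1$anomaly_type, "type_II")
  d2 <- decide(0.00, 0.271566, 0.21, 0.233895)
  expect_equal(d2$anomaly_type, "none")
  d3 <- decide(0.13, 0.002, NA_real_, 0.233895)
  expect_equal(d3$anomaly_type, "type_I")
  expect_true(is.na(d3$f)) # F not evaluated on the type-I branch
  # strict inequality: equality is not a flag
  expect_equal(decide(0.27, 0.27, 0.1, 0.2)$verdict, "normal")
  expect_equal(decide(0.1, 0.27, 0.23, 0.23)$verdict, "normal")
})

test_that("detect attaches scores, counts and insufficient-history warnings", {
  cohort <- generate_cohort(cohort_spec("sbrt", size = 120, seed = 8))
  idx <- build_index(cohort)
  params <- model_params(0.05, 0.05, 1.5, 1.2)

  common <- cohort[which(cohort$fractions == 5 & cohort$dose_per_fraction == 1000)[1], ]
  d <- detect(common, idx, params, exclude_id = common$record_id)
  expect_equal(d$verdict, "normal")
  expect_equal(d$r, 0)
  expect_gt(d$counts, 0)
  # the detection carries everything needed to recompute its verdict
  expect_equal(d$verdict == "anomaly", d$r > d$t_rx || d$f > d$t_f)

  rare <- rec(39, 1990, technique = "sbrt", energy = "6fff",
              intent = "curative", icd10 = "C34.1", age = 70)
  d2 <- detect(rare, idx, params)
  expect_equal(d2$anomaly_type, "type_I")
  expect_true(is.na(d2$f))
  expect_equal(d2$counts, 0L)

  # seen-but-scarce prescription: verdict still produced, warning attached
  scarce_rx <- dplyr::count(cohort, fractions, dose_per_fraction)
  scarce_rx <- scarce_rx[which.min(scarce_rx$n), ]
  probe <- rec(scarce_rx$fractions, scarce_rx$dose_per_fraction,
               technique = "sbrt", energy = "6fff", intent = "palliative",
               icd10 = "C34.9", morphology = "80463", age = 75)
  big_n <- model_params(0.05, 0.1, 1.5, 1.2)
  d3 <- detect(probe, idx, big_n)
  n_used <- rxanomaly:::neighbour_size(0.1, idx$s)
  if (d3$counts < n_used) {
    expect_match(d3$warnings[[1]], "insufficient_same_prescription_history")
  }
  expect_false(is.na(d3$verdict))
})

test_that("technique routing is enforced", {
  cohort <- generate_cohort(cohort_spec("3d", size = 60, seed = 2))
  idx <- build_index(cohort)
  params <- model_params(0.05, 0.05, 1, 1)
  probe <- rec(5, 400, technique = "sbrt", energy = "6fff", age = 70)
  expect_error(detect(probe, idx, params), class = "rx_routing_error")
})

test_that("detect_batch routes per technique and preserves order", {
  c3 <- generate_cohort(cohort_spec("3d", size = 60, seed = 4))
  cs <- generate_cohort(cohort_spec("sbrt", size = 60, seed = 5))
  indices <- list("3d" = build_index(c3), sbrt = build_index(cs))
  params <- model_params(0.05, 0.05, 1, 1)

  expect_equal(nrow(detect_batch(c3[0, ], indices, params)), 0L)

  batch <- dplyr::bind_rows(cs[3, ], c3[7, ], rec(9, 275, "other", id = "uk"))
  out <- detect_batch(batch, indices, params)
  expect_equal(out$record_id, batch$record_id)
  expect_equal(out$technique[1:2], c("sbrt", "3d"))
  # cross-check against the single-record path
  expect_equal(out[1, ], detect(cs[3, ], indices$sbrt, params))
  expect_equal(out[2, ], detect(c3[7, ], indices$"3d", params))
  # unsupported technique: verdict withheld with a routing warning
  expect_true(is.na(out$verdict[3]))
  expect_match(out$warnings[[3]], "no_model_for_technique")
})

test_that("flagged sets shrink as a and b grow; embedded records never flag", {
  cohort <- generate_cohort(cohort_spec("imrt", size = 100, seed = 6))
  idx <- build_index(cohort)
  probes <- dplyr::bind_rows(lapply(1:15, function(k) {
    r <- random_record(600 + k)
    r$technique <- "imrt"
    r$record_id <- paste0("probe", k)
    r
  }))
  flagged <- function(a, b) {
    det <- detect_batch(probes, idx, model_params(0.03, 0.03, a, b))
    det$record_id[det$verdict == "anomaly"]
  }
  for (b in c(0.2, 0.6, 1.4)) {
    expect_true(all(flagged(1.0, b + 0.4) %in% flagged(1.0, b)))
  }
  type1 <- function(a) {
    det <- detect_batch(probes, idx, model_params(0.03, 0.03, a, 0.5))
    det$record_id[det$anomaly_type == "type_I"]
  }
  for (a in c(0.2, 0.8, 1.5)) {
    expect_true(all(type1(a + 0.5) %in% type1(a)))
  }

  # a record identical to many historical records is never flagged for a, b > 0
  dup <- cohort[which(cohort$fractions == 25)[1], ]
  clones <- dplyr::bind_rows(replicate(12, dup, simplify = FALSE))
  clones$record_id <- paste0("c", 1:12)
  idx2 <- build_index(dplyr::bind_rows(cohort, clones))
  for (ab in list(c(0.01, 0.01), c(0.5, 0.5), c(2, 2))) {
    d <- detect(dup, idx2, model_params(0.02, 0.02, ab[1], ab[2]),
                exclude_id = dup$record_id)
    expect_equal(d$verdict, "normal")
  }
})
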