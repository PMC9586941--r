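# Hand-built fixtures used across test files.

rec <- function(fractions, dose, technique = "3d", energy = NA, intent = NA,
                icd10 = NA, morphology = NA, age = NA, id = "x",
                total = fractions * dose, accumulated = total) {
  tibble::tibble(
    record_id = id, fractions = as.integer(fractions),
    dose_per_fraction = dose, total_dose = total,
    accumulated_total_dose = accumulated, technique = technique,
    energy = as.character(energy), intent = as.character(intent),
    icd10 = as.character(icd10), morphology = as.character(morphology),
    age = as.numeric(age)
  )
}

# Synthetic stand-in cohorts constructed to embody the documented
# co-occurrence facts behind the worked simulated-anomaly examples:
#  - SBRT: 5 fx x 1000 cGy is common, always curative intent, never given
#    to a pediatric patient; 4 fx x 1200 cGy is common, 6/6fff energies,
#    lung codes only (never C15 esophagus, never 10 MV).
#  - IMRT: 10 fx x 300 cGy is common, but never with a 15 MV beam.
sbrt_facts_cohort <- function() {
  n1 <- 40L; n2 <- 30L
  dplyr::bind_rows(
    tibble::tibble(
      record_id = sprintf("s1_%02d", seq_len(n1)),
      fractions = 5L, dose_per_fraction = 1000,
      total_dose = 5000, accumulated_total_dose = 5000,
      technique = "sbrt",
      energy = rep(c("6fff", "10fff"), length.out = n1),
      intent = "curative",
      icd10 = rep(c("R91.1", "C34.1"), length.out = n1),
      morphology = rep(c("80463", NA), length.out = n1),
      age = round(seq(45, 91, length.out = n1))
    ),
    tibble::tibble(
      record_id = sprintf("s2_%02d", seq_len(n2)),
      fractions = 4L, dose_per_fraction = 1200,
      total_dose = 4800, accumulated_total_dose = 4800,
      technique = "sbrt",
      energy = rep(c("6", "6fff"), length.out = n2),
      intent = rep(c("palliative", "curative"), length.out = n2),
      icd10 = rep(c("C34.3", "C34.1"), length.out = n2),
      morphology = "87203",
      age = round(seq(35, 80, length.out = n2))
    )
  )
}

imrt_facts_cohort <- function() {
  n <- 40L
  dplyr::bind_rows(
    tibble::tibble(
      record_id = sprintf("i_%02d", seq_len(n)),
      fractions = 10L, dose_per_fraction = 300,
      total_dose = 3000, accumulated_total_dose = 3000,
      technique = "imrt",
      energy = "6",
      intent = "palliative",
      icd10 = rep(c("C78.1", "C34.9"), length.out = n),
      morphology = "80463",
      age = round(seq(50, 90, length.out = n))
    ),
    tibble::tibble(
      record_id = sprintf("i2_%02d", 1:10),
      fractions = 25L, dose_per_fraction = 180,
      total_dose = 4500, accumulated_total_dose = 4500,
      technique = "imrt",
      energy = "6", intent = "curative",
      icd10 = "C15.9", morphology = "87203",
      age = round(seq(45, 75, length.out = 10))
    )
  )
}
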