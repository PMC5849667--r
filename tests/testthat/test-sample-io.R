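sample_io_cols <- function() {
  c("patient_id", "dbs_spot_a", "dbs_spot_a_valid", "dbs_spot_b",
    "dbs_spot_b_valid", "dbs_wb", "wb", "hematocrit", "dose_mg",
    "time_after_dose_h")
}

make_sample <- function(a = 10, a_ok = TRUE, b = 10.4, b_ok = TRUE,
                        hct = 0.35, dbs_wb = 10.2, wb = 9.5) {
  tibble::tibble(
    patient_id = "P1", dbs_spot_a = a, dbs_spot_a_valid = a_ok,
    dbs_spot_b = b, dbs_spot_b_valid = b_ok, dbs_wb = dbs_wb, wb = wb,
    hematocrit = hct, dose_mg = 10, time_after_dose_h = 23, flags = ""
  )
}

test_that("a written cohort reads back field-identically", {
  cohort <- generate_cohort(synthetic_config(seed = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(cohort, path)
  back <- read_samples(path)
  expect_equal(nrow(back), 20)
  for (col in setdiff(names(back), "flags")) {
    expect_equal(back[[col]], cohort[[col]], info = col)
  }
  expect_equal(nrow(rejections(back)), 0)
})

test_that("rows with impossible values are rejected, not dropped silently", {
  cohort <- generate_cohort(synthetic_config(seed = 4L))
  cohort$wb[7] <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(cohort, path)
  expect_warning(back <- read_samples(path), "rejected")
  expect_equal(nrow(back), 19)
  rej <- rejections(back)
  expect_equal(rej$patient_id, cohort$patient_id[7])
  expect_match(rej$reason, "non-positive concentration")
})

test_that("a missing mandatory column is a schema error", {
  cohort <- generate_cohort(synthetic_config(seed = 5L))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort[setdiff(sample_io_cols(), "hematocrit")], path)
  expect_error(read_samples(path), "hematocrit")
})

test_that("duplicate spots resolve by the stated rules", {
  both <- resolve_dbs(make_sample(10.0, TRUE, 10.4, TRUE))
  expect_equal(both$dbs, 10.2)
  expect_equal(both$flags, "")

  one <- resolve_dbs(make_sample(10.0, TRUE, 10.4, FALSE))
  expect_equal(one$dbs, 10.0)
  expect_match(one$flags, "dbs_single_spot")

  none <- resolve_dbs(make_sample(10.0, FALSE, 10.4, FALSE))
  expect_true(is.na(none$dbs))
  expect_match(none$flags, "dbs_excluded")

  # a missing concentration behaves like an invalid spot
  na_spot <- resolve_dbs(make_sample(NA, TRUE, 10.4, TRUE))
  expect_equal(na_spot$dbs, 10.4)
  expect_match(na_spot$flags, "dbs_single_spot")
})

test_that("spot resolution is invariant to the order of the duplicates", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- runif(1, 3, 33); b <- runif(1, 3, 33)
      a_ok <- runif(1) > 0.3; b_ok <- runif(1) > 0.3
    })
    fwd <- resolve_dbs(make_sample(a, a_ok, b, b_ok))
    rev <- resolve_dbs(make_sample(b, b_ok, a, a_ok))
    expect_equal(fwd$dbs, rev$dbs)
    expect_equal(fwd$flags, rev$flags)
  }
})

test_that("hematocrit flags follow the hard and caution thresholds", {
  expect_equal(flag_hematocrit(make_sample(hct = 0.35, a = 10, b = 10))$flags, "")
  expect_match(flag_hematocrit(make_sample(hct = 0.18))$flags, "hct_low")
  caution <- flag_hematocrit(make_sample(hct = 0.22, a = 25, b = 25))
  expect_match(caution$flags, "hct_high_conc")
  # low concentration at the same hematocrit stays unflagged
  expect_equal(flag_hematocrit(make_sample(hct = 0.22, a = 10, b = 10))$flags, "")
})

test_that("pairing uses only complete pairs and keeps labels aligned", {
  cohort <- generate_cohort(synthetic_config(seed = 6L, invalid_spot_rate = 0))
  pairs <- build_pairs(cohort)
  expect_setequal(unique(pairs$pair_name), c("DBS-WB", "DBSwb-WB", "DBS-DBSwb"))
  expect_true(all(table(pairs$pair_name) == 20))

  cohort$dbs_wb[3] <- NA
  pairs2 <- build_pairs(cohort)
  counts <- table(pairs2$pair_name)
  expect_equal(unname(counts[["DBS-WB"]]), 20)
  expect_equal(unname(counts[["DBSwb-WB"]]), 19)
  expect_equal(unname(counts[["DBS-DBSwb"]]), 19)
  expect_false(cohort$patient_id[3] %in%
                 pairs2$patient_id[pairs2$pair_name == "DBSwb-WB"])

  # x/y stay aligned with the source columns by patient label
  resolved <- resolve_dbs(cohort)
  p <- pairs2[pairs2$pair_name == "DBS-WB", ]
  expect_equal(p$x, resolved$dbs[match(p$patient_id, resolved$patient_id)])
  expect_equal(p$y, resolved$wb[match(p$patient_id, resolved$patient_id)])
})

test_that("pairing lengths match the generator's exclusion bookkeeping", {
  cfg <- synthetic_config(seed = 8L, n_patients = 200, invalid_spot_rate = 0.3)
  cohort <- resolve_dbs(generate_cohort(cfg))
  n_excluded <- sum(!cohort$dbs_spot_a_valid & !cohort$dbs_spot_b_valid)
  pairs <- build_pairs(cohort)
  counts <- table(pairs$pair_name)
  expect_equal(unname(counts[["DBS-WB"]]), 200 - n_excluded)
  expect_equal(unname(counts[["DBSwb-WB"]]), 200)
})

test_that("every input row is accounted for exactly once in the QC log", {
  cohort <- generate_cohort(synthetic_config(seed = 9L, n_patients = 80,
                                             invalid_spot_rate = 0.2))
  cohort$wb[5] <- -1
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(cohort, path)
  suppressWarnings(samples <- read_samples(path))
  samples <- flag_hematocrit(resolve_dbs(samples))
  log <- qc_log(samples)
  expect_equal(nrow(log), 80)
  expect_setequal(log$patient_id, cohort$patient_id)
  expect_true(all(log$action %in%
                    c("analyzed", "flagged", "excluded", "rejected")))
  expect_equal(sum(log$action == "rejected"), 1)
})
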