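test_that("a well-formed registry round-trips through csv identically", {
  reg <- simulate_cohort(ms_scenario(n_patients = 8, seed = 3L))
  dir <- withr::local_tempdir()
  paths <- write_registry(reg, dir)
  back <- read_registry(as.list(paths))
  for (nm in c("patients", "courses", "visits", "relapses", "treatments",
               "mri", "pregnancies")) {
    a <- reg[[nm]]; rownames(a) <- NULL
    b <- back[[nm]]; rownames(b) <- NULL
    expect_equal(a, b, info = nm)
  }
})

test_that("schema violations are reported with the missing column", {
  reg <- simulate_cohort(ms_scenario(n_patients = 3, seed = 4L))
  dir <- withr::local_tempdir()
  paths <- write_registry(reg, dir)
  vis <- utils::read.csv(paths[["visits"]])
  vis$edss <- NULL
  utils::write.csv(vis, paths[["visits"]], row.names = FALSE)
  expect_error(read_registry(as.list(paths)), "edss",
               class = "msmtrial_schema_error")
})

test_that("invalid EDSS values and close relapses trigger validation per policy", {
  pats <- data.frame(patient_id = "P1", sex = "female",
                     birth_date = d(-10000), ms_onset_date = d(-500),
                     stringsAsFactors = FALSE)
  bad_vis <- data.frame(patient_id = "P1", date = d(c(0, 100)),
                        edss = c(0.5, 2), stringsAsFactors = FALSE)
  expect_error(make_registry(pats, visits = bad_vis),
               "EDSS", class = "msmtrial_validation_error")

  rel <- data.frame(patient_id = "P1", date = d(c(0, 10)), stringsAsFactors = FALSE)
  ok_vis <- data.frame(patient_id = "P1", date = d(c(0, 100)), edss = c(2, 2),
                       stringsAsFactors = FALSE)
  expect_error(make_registry(pats, visits = ok_vis, relapses = rel,
                             relapse_policy = "strict"),
               "relapses", class = "msmtrial_validation_error")
  merged <- make_registry(pats, visits = ok_vis, relapses = rel,
                          relapse_policy = "merge")
  expect_equal(nrow(merged$relapses), 1L)
  expect_equal(merged$relapses$date, d(0))  # earlier onset kept
})

test_that("overlapping treatment episodes and SPMS reversion are rejected", {
  pats <- data.frame(patient_id = "P1", sex = "male", birth_date = d(-9000),
                     ms_onset_date = d(-100), stringsAsFactors = FALSE)
  trt <- data.frame(patient_id = "P1", dmt_name = "DMT",
                    start_date = d(c(0, 50)), stop_date = d(c(100, 200)),
                    stringsAsFactors = FALSE)
  expect_error(make_registry(pats, treatments = trt),
               "overlapping", class = "msmtrial_validation_error")

  crs <- data.frame(patient_id = "P1", phenotype = c("RRMS", "SPMS", "RRMS"),
                    start_date = d(c(-100, 100, 400)), stringsAsFactors = FALSE)
  expect_error(make_registry(pats, courses = crs),
               "SPMS", class = "msmtrial_validation_error")
})

test_that("eligibility filters apply the follow-up, score-count and gap rules", {
  # 0.8 years between first and last score -> excluded
  short <- one_patient("P1", edss = c(2, 2, 2, 2),
                       visit_days = c(0, 100, 200, 292))
  f <- filter_eligible(short, "relapsing")
  expect_equal(nrow(f$patients), 0L)
  log <- exclusion_log(f)
  expect_equal(log$reason_code, "followup_lt_1yr")

  # scores only at months 0, 1, 30: gap > 365 days
  gappy <- one_patient("P2", edss = c(2, 2, 2), visit_days = c(0, 30, 900))
  f <- filter_eligible(gappy, "relapsing")
  expect_equal(exclusion_log(f)$reason_code, "edss_gap_gt_1yr")

  # two scores only
  two <- one_patient("P3", edss = c(2, 3), visit_days = c(0, 400))
  expect_equal(exclusion_log(filter_eligible(two, "full"))$reason_code, "lt_3_edss")

  ok <- one_patient("P4", edss = rep(2, 5), visit_days = seq(0, 1200, by = 300))
  f <- filter_eligible(ok, "relapsing")
  expect_equal(nrow(f$patients), 1L)
  expect_equal(nrow(exclusion_log(f)), 0L)
  expect_equal(f$patients$baseline_date, d(0))
  expect_equal(f$patients$followup_end, d(1200))
})

test_that("relapsing cohort excludes progressive baselines and censors at SPMS conversion", {
  pats <- data.frame(patient_id = c("P1", "P2"), sex = "female",
                     birth_date = d(-12000), ms_onset_date = d(-1000),
                     stringsAsFactors = FALSE)
  crs <- data.frame(
    patient_id = c("P1", "P2", "P2"),
    phenotype = c("PPMS", "RRMS", "SPMS"),
    start_date = d(c(-1000, -1000, 1825)), stringsAsFactors = FALSE)
  vis <- data.frame(patient_id = rep(c("P1", "P2"), each = 11),
                    date = rep(d(seq(0, 3650, by = 365)), 2),
                    edss = 3, stringsAsFactors = FALSE)
  reg <- make_registry(pats, courses = crs, visits = vis)

  rel <- filter_eligible(reg, "relapsing")
  expect_equal(rel$patients$patient_id, "P2")
  expect_equal(exclusion_log(rel)$reason_code, "progressive_at_baseline")
  # RRMS -> SPMS at year 5 of 10: retained, censored at conversion
  expect_equal(rel$patients$censor_date, d(1825))

  full <- filter_eligible(reg, "full")
  expect_equal(nrow(full$patients), 2L)
  expect_true(all(is.na(full$patients$censor_date)))
})

test_that("eligibility filtering is idempotent and logs each exclusion once", {
  reg <- simulate_cohort(ms_scenario(n_patients = 60, seed = 9L))
  f1 <- filter_eligible(reg, "relapsing")
  f2 <- filter_eligible(f1, "relapsing")
  expect_equal(f2$patients$patient_id, f1$patients$patient_id)
  expect_equal(nrow(exclusion_log(f2)), 0L)
  log <- exclusion_log(f1)
  expect_equal(anyDuplicated(log$patient_id), 0L)
  expect_true(all(log$reason_code %in%
                    c("followup_lt_1yr", "lt_3_edss", "edss_gap_gt_1yr",
                      "missing_minimum_data", "progressive_at_baseline")))
})

test_that("patient_record extracts one subject's full history", {
  reg <- simulate_cohort(ms_scenario(n_patients = 5, seed = 10L))
  id <- reg$patients$patient_id[3]
  rec <- patient_record(reg, id)
  expect_true(all(rec$visits$patient_id == id))
  expect_equal(nrow(rec$patients), 1L)
  expect_error(patient_record(reg, "nope"), "unknown patient")
})
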