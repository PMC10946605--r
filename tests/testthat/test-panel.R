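test_that("the 15-treated-day rule classifies bins, with union arithmetic over episodes", {
  ep <- function(s, e) data.frame(start_date = d(s), stop_date = d(e))
  expect_equal(classify_treatment_status(d(0), d(183), ep(10, 30)), 1L)   # 20 days
  expect_equal(classify_treatment_status(d(0), d(183), ep(10, 24)), 0L)   # 14 days
  expect_equal(classify_treatment_status(d(0), d(183),                    # 8 + 8 days
                                         ep(c(0, 100), c(8, 108))), 1L)
  # open episode counts through the bin
  expect_equal(classify_treatment_status(d(0), d(183),
                                         data.frame(start_date = d(150),
                                                    stop_date = as.Date(NA))), 1L)
  expect_equal(classify_treatment_status(d(0), d(183), ep(numeric(0), numeric(0))), 0L)
})

test_that("carry-forward fills bins from the last recorded score and flags them", {
  bins <- data.frame(start_date = d(c(0, 183, 366)), end_date = d(c(183, 366, 549)))
  scores <- data.frame(date = d(c(10, 400)), edss = c(3, 4))
  out <- carry_forward_edss(bins, scores)
  expect_equal(out$edss, c(3, 3, 4))
  expect_equal(out$edss_carried, c(FALSE, TRUE, FALSE))
})

test_that("design A panels bin follow-up, flag outcomes, and censor at discontinuation", {
  # 3 years untreated -> 6 bins, all untreated
  reg <- filter_eligible(one_patient("P1", edss = rep(2, 7),
                                     visit_days = seq(0, 1098, by = 183)),
                         "relapsing")
  pan <- build_panel(reg, "A")
  expect_equal(nrow(pan), 6L)
  expect_equal(unique(pan$treated), 0L)
  expect_equal(pan$bin_index, 0:5)
  expect_equal(pan$end_day[6] - pan$start_day[1],
               sum(pan$end_day - pan$start_day))  # contiguous, conservative

  # DMT from day 100, stops during bin 4 (day 800): panel ends with bin 4
  reg <- filter_eligible(one_patient("P2", edss = rep(2, 8),
                                     visit_days = seq(0, 1400, by = 200),
                                     trt_start = 100, trt_stop = 800),
                         "relapsing")
  pan <- build_panel(reg, "A")
  expect_equal(max(pan$bin_index), 4L)
  expect_equal(pan$censor_reason[nrow(pan)], "treatment_discontinuation")
  expect_equal(pan$censored[nrow(pan)], 1L)
  expect_true(all(diff(pan$treated) >= 0))  # one-way transition
  expect_equal(pan$prev_treated, c(0L, pan$treated[-nrow(pan)]))

  # relapse bookkeeping: every relapse inside followed time lands in one bin
  reg <- filter_eligible(one_patient("P3", edss = rep(2, 7),
                                     visit_days = seq(0, 1098, by = 183),
                                     relapse_days = c(-100, 50, 90, 400)),
                         "relapsing")
  pan <- build_panel(reg, "A")
  expect_equal(sum(pan$relapses_in_bin), 3L)  # the pre-baseline one is out
  expect_equal(pan$relapse_outcome, as.integer(pan$relapses_in_bin >= 1))
  expect_equal(pan$arr_prior_12m[1], 1)       # the day -100 relapse
})

test_that("confirmed-event onsets map to exactly one bin", {
  reg <- filter_eligible(one_patient("P1", edss = c(2, 3, 3, 3, 3, 3),
                                     visit_days = c(0, 200, 500, 800, 1100, 1400)),
                         "relapsing")
  ev <- derive_events(reg)
  expect_equal(ev$onset_date, d(200))
  pan <- build_panel(reg, "A", ev)
  expect_equal(sum(pan$worsening_event), 1L)
  expect_equal(pan$bin_index[pan$worsening_event == 1], 1L)  # day 200 in bin 1
})

test_that("design B baselines at MS onset and marks pre-EDSS bins", {
  reg <- filter_eligible(one_patient("P1", edss = rep(3, 5),
                                     visit_days = seq(0, 1200, by = 300)),
                         "relapsing")
  pan <- build_panel(reg, "B")
  # onset is 730 days before the first visit: ~4 pre-EDSS bins
  expect_equal(pan$start_day[1], 0)
  expect_true(sum(pan$pre_edss) >= 3)
  expect_true(all(pan$pre_edss[pan$start_day >= 730] == 0))
  # pre-EDSS bins carry the first recorded score as a filled value
  expect_true(all(pan$edss == 3))
})

test_that("design C restarts the bin clock at each treatment transition", {
  reg <- filter_eligible(one_patient("P1", edss = rep(2, 8),
                                     visit_days = seq(0, 1400, by = 200),
                                     trt_start = 400, trt_stop = 1000),
                         "relapsing")
  pan <- build_panel(reg, "C")
  expect_equal(sort(unique(pan$segment)), 1:3)
  expect_equal(pan$bin_index[pan$segment == 2][1], 0L)
  expect_equal(pan$start_day[pan$segment == 2][1] -
                 pan$seg_start_day[pan$segment == 2][1], 0)
  # segment 2 covers the treated spell
  expect_true(all(pan$treated[pan$segment == 2] == 1))
  expect_true(all(pan$treated[pan$segment != 2] == 0))
})

test_that("short final bins are dropped and person-time is otherwise conserved", {
  # 1106 days of follow-up: 6 full bins + a 8-day remainder that is dropped
  reg <- filter_eligible(one_patient("P1", edss = rep(2, 7),
                                     visit_days = c(0, 200, 400, 600, 800, 1000, 1106)),
                         "relapsing")
  pan <- build_panel(reg, "A")
  expect_equal(nrow(pan), 6L)
  expect_equal(sum(pan$end_day - pan$start_day), 6 * 183)
})

test_that("panel covariates at bin start include MRI recency, pregnancy overlap and ages", {
  base <- one_patient("P1", edss = rep(2, 5), visit_days = seq(0, 1200, by = 300))
  mri <- data.frame(patient_id = "P1", date = d(c(-30, 700)),
                    activity = c("not_active", "active"), stringsAsFactors = FALSE)
  preg <- data.frame(patient_id = "P1", start_date = d(200), end_date = d(470),
                     stringsAsFactors = FALSE)
  reg <- make_registry(base$patients, base$courses, base$visits,
                       NULL, NULL, mri = mri, pregnancies = preg)
  pan <- build_panel(filter_eligible(reg, "relapsing"), "A")
  expect_equal(pan$mri_activity_12m[1], "not_active")      # day -30 assessment
  expect_equal(pan$mri_activity_12m[3], "not_assessed")    # bin start 366: -30 too old
  expect_equal(pan$mri_activity_12m[5], "active")          # day 700 within 365 of 732
  expect_equal(pan$pregnancy, c(0L, 1L, 1L, rep(0L, nrow(pan) - 3)))
  expect_equal(pan$age[1], (as.numeric(d(0)) - as.numeric(d(-30 * 365))) / 365)
  expect_equal(pan$ms_duration[1], 2)
})
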