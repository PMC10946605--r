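test_that("post-relapse EDSS cleaning uses a strict 30-day boundary", {
  vis <- data.frame(date = d(c(0, 110, 130, 250)), edss = c(2, 3, 3, 2))
  # relapse at day 100: the day-110 score (10 days after) is excluded,
  # the day-130 score (exactly 30 days after) is retained
  out <- clean_edss(vis, d(100))
  expect_equal(out$date, d(c(0, 130, 250)))
  # no relapses: unchanged
  expect_equal(clean_edss(vis, NULL), vis)
  # a relapse on the score's own day excludes it
  expect_equal(nrow(clean_edss(data.frame(date = d(5), edss = 2), d(5))), 0L)
})

test_that("required step depends on the reference score as in the confirmed-event definitions", {
  expect_equal(required_step(0, "worsening"), 1.5)
  expect_equal(required_step(6.0, "worsening"), 0.5)
  expect_equal(required_step(3.0, "worsening"), 1.0)
  expect_equal(required_step(5.5, "worsening"), 1.0)
  expect_equal(required_step(1.5, "improvement"), 1.5)
  expect_equal(required_step(6.5, "improvement"), 0.5)
  expect_equal(required_step(6.0, "improvement"), 1.0)
  expect_equal(required_step(4.0, "improvement"), 1.0)
  expect_error(required_step(0.5, "worsening"), class = "msmtrial_domain_error")
})

test_that("confirmed events require every score through the 12-month mark to hold", {
  # rise at day 180 sustained through day 560 -> one worsening
  ev <- detect_confirmed_events(data.frame(date = d(c(0, 180, 560)),
                                           edss = c(2, 3, 3)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "worsening")
  expect_equal(ev$onset_date, d(180))
  expect_equal(ev$reference_edss, 2)
  expect_equal(ev$confirmation_date, d(560))

  # confirmation window broken at day 300; the day-600 rise has no >=365-day
  # confirming score -> nothing by day 600
  ev <- detect_confirmed_events(data.frame(date = d(c(0, 180, 300, 600)),
                                           edss = c(2, 3, 2, 3)))
  expect_equal(nrow(ev), 0L)

  # constant trajectory and too-short trajectories yield nothing
  expect_equal(nrow(detect_confirmed_events(
    data.frame(date = d(seq(0, 900, 300)), edss = 4))), 0L)
  expect_equal(nrow(detect_confirmed_events(
    data.frame(date = d(0), edss = 4))), 0L)
})

test_that("roving references accumulate events while a fixed baseline measures from the first score", {
  traj <- data.frame(date = d(c(0, 200, 600, 800, 1300)),
                     edss = c(2, 3, 3, 4, 4))
  rov <- detect_confirmed_events(traj, "roving")
  expect_equal(rov$kind, c("worsening", "worsening"))
  expect_equal(rov$reference_edss, c(2, 3))
  fix <- detect_confirmed_events(traj, "fixed_baseline")
  expect_equal(fix$reference_edss, rep(2, nrow(fix)))

  # worsening then improvement back through the roving reference
  traj2 <- data.frame(date = d(c(0, 200, 600, 800, 1300)),
                      edss = c(3, 4, 4, 3, 3))
  rov2 <- detect_confirmed_events(traj2, "roving")
  expect_equal(rov2$kind, c("worsening", "improvement"))
})

test_that("detector matches the brute-force oracle on randomized trajectories", {
  set.seed(421)
  grid <- c(0, seq(1, 7, by = 0.5))
  for (rep in 1:400) {
    len <- sample(2:8, 1)
    days <- sort(sample(0:1500, len))
    values <- sample(grid, len, replace = TRUE)
    for (roving in c(TRUE, FALSE)) {
      got <- msmtrial:::detect_core(days, values, roving)
      want <- brute_force_events(days, values, roving)
      expect_equal(unname(got), unname(want),
                   info = paste("days", paste(days, collapse = ","),
                                "values", paste(values, collapse = ","),
                                "roving", roving))
    }
  }
})

test_that("event detection is translation invariant and monotone in available data", {
  set.seed(77)
  grid <- c(0, seq(1, 8, by = 0.5))
  for (rep in 1:200) {
    len <- sample(3:9, 1)
    days <- sort(sample(0:2000, len))
    values <- sample(grid, len, replace = TRUE)
    base <- msmtrial:::detect_core(days, values, TRUE)
    shifted <- msmtrial:::detect_core(days + 517, values, TRUE)
    expect_equal(shifted[, "onset"], base[, "onset"] + 517)
    expect_equal(shifted[, "confirmation"], base[, "confirmation"] + 517)
    # dropping the last score can only destroy events, never create new
    # earlier ones
    trimmed <- msmtrial:::detect_core(days[-len], values[-len], TRUE)
    if (nrow(trimmed)) {
      expect_true(nrow(base) >= nrow(trimmed))
      expect_equal(trimmed[, "onset"],
                   base[seq_len(nrow(trimmed)), "onset"])
    }
    # worsening and improvement never share an onset
    if (nrow(base) > 1) {
      expect_equal(anyDuplicated(base[, "onset"]), 0L)
    }
  }
})

test_that("annualized relapse rate counts the half-open window", {
  expect_equal(annualized_relapse_rate(d(c(10, 50)), d(0), d(183)),
               2 * 365 / 183)
  expect_equal(annualized_relapse_rate(d(numeric(0)), d(0), d(365)), 0)
  expect_equal(annualized_relapse_rate(d(c(0, 300, 600)), d(0), d(730)), 1.5)
  # boundary: a relapse on window_end is outside
  expect_equal(annualized_relapse_rate(d(365), d(0), d(365)), 0)
  expect_error(annualized_relapse_rate(d(1), d(10), d(10)),
               class = "msmtrial_domain_error")
})

test_that("derive_events combines cleaning and detection per patient", {
  reg <- one_patient("P1", edss = c(2, 3, 3, 3, 3),
                     visit_days = c(0, 180, 400, 560, 800),
                     relapse_days = 175)
  # day-180 score is 5 days after the relapse -> removed, so the first rise
  # seen is at day 400, confirmed at day 800
  ev <- derive_events(reg)
  expect_equal(ev$onset_date, d(400))
  expect_equal(ev$confirmation_date, d(800))
  # without the relapse the onset is at day 180
  reg2 <- one_patient("P1", edss = c(2, 3, 3, 3, 3),
                      visit_days = c(0, 180, 400, 560, 800))
  expect_equal(derive_events(reg2)$onset_date, d(180))
})
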