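fixture_analysis <- function(n = 400, seed = 61L, scenario = "protective",
                             cohort = "relapsing", design = "A") {
  sc <- default_scenarios(n)[[scenario]]
  sc$seed <- seed
  reg <- simulate_cohort(sc)
  coh <- filter_eligible(reg, cohort)
  pan <- build_panel(coh, design)
  list(panel = pan, weights = iptw(pan))
}

test_that("unit weights reproduce the unweighted Cox fit exactly", {
  fx <- fixture_analysis()
  covs <- c("prev_treated", "baseline_bin", "sex", "ms_duration_at_first_visit",
            "birth_year")
  w1 <- iptw(fx$panel, numerator_covs = covs, denominator_covs = covs)
  for (oc in c("relapse", "worsening")) {
    weighted <- fit_msm(fx$panel, w1, oc)
    naive <- fit_msm(fx$panel, NULL, oc)
    expect_equal(coef(weighted), coef(naive), tolerance = 1e-10)
  }
})

test_that("msm_fit objects expose the usual modelling methods", {
  fx <- fixture_analysis()
  f <- fit_msm(fx$panel, fx$weights, "relapse")
  expect_s3_class(f, "msm_fit")
  r <- as.data.frame(f)
  expect_equal(r$term, "Overall")
  expect_true(r$ci_lower <= r$hazard_ratio && r$hazard_ratio <= r$ci_upper)
  expect_true(r$n_events <= sum(fx$panel$relapse_outcome))
  expect_named(coef(f), "treated")
  ci <- confint(f)
  expect_equal(unname(exp(ci[1, ])), c(r$ci_lower, r$ci_upper), tolerance = 1e-8)
  expect_equal(dim(vcov(f)), c(1L, 1L))
  expect_length(residuals(f, type = "martingale"),
                f$fit$n)
  expect_output(print(f), "Overall")
  expect_output(summary(f), "stabilized weights")
  z <- check_ph(f)
  expect_true(is.numeric(z$table[, "p"]))
})

test_that("the pooled logistic cross-check agrees with the Cox fit up to odds-ratio inflation", {
  fx <- fixture_analysis(800, seed = 62L)
  cx <- log(fit_msm(fx$panel, fx$weights, "relapse")$result$hazard_ratio)
  pl <- log(fit_msm(fx$panel, fx$weights, "relapse",
                    estimator = "pooled_logistic")$result$hazard_ratio)
  # per-bin relapse probabilities are ~10-15%, so the discrete-time odds
  # ratio is noticeably farther from the null than the hazard ratio; the
  # estimators must agree in direction and order of magnitude
  expect_equal(sign(pl), sign(cx))
  expect_gt(abs(pl) / abs(cx), 0.7)
  expect_lt(abs(pl) / abs(cx), 1.7)
  # on the rarer worsening outcome the odds-ratio inflation shrinks, but a
  # few dozen events leave real Monte-Carlo play between the estimators
  cw <- log(fit_msm(fx$panel, fx$weights, "worsening")$result$hazard_ratio)
  pw <- log(fit_msm(fx$panel, fx$weights, "worsening",
                    estimator = "pooled_logistic")$result$hazard_ratio)
  expect_equal(sign(pw), sign(cw))
  expect_lt(abs(pw - cw), 0.5)
})

test_that("misaligned weights and empty outcomes raise typed errors", {
  fx <- fixture_analysis(120, seed = 63L)
  w <- fx$weights
  w$table <- w$table[-1, ]
  expect_error(fit_msm(fx$panel, w, "relapse"), "aligned",
               class = "msmtrial_domain_error")
  noev <- fx$panel[fx$panel$relapse_outcome == 0 & fx$panel$worsening_event == 0, ]
  class(noev) <- class(fx$panel)
  attr(noev, "design") <- "A"
  expect_error(fit_msm(noev, NULL, "relapse"), "no relapse events",
               class = "msmtrial_estimation_error")
})

test_that("interaction fitting enforces the modifier-excluded weight contract", {
  fx <- fixture_analysis(500, seed = 64L)
  expect_error(fit_interaction(fx$panel, fx$weights, "relapse", "edss"),
               "excluded", class = "msmtrial_domain_error")
  wE <- iptw(fx$panel, interacted_modifier = "edss")
  fi <- fit_interaction(fx$panel, wE, "relapse", "edss")
  expect_true("DMT x edss" %in% fi$result$term)
  wA <- iptw(fx$panel, interacted_modifier = "arr")
  expect_error(fit_interaction(fx$panel, wA, "relapse", "edss"),
               class = "msmtrial_domain_error")
  # constant modifier -> collinearity error
  pan1 <- fx$panel
  pan1$course <- "RRMS"
  wP <- iptw(pan1, interacted_modifier = "phenotype")
  expect_error(fit_interaction(pan1, wP, "relapse", "phenotype"),
               "constant", class = "msmtrial_estimation_error")
})

test_that("stratified models return one row per stratum and flag inestimable strata", {
  fx <- fixture_analysis(500, seed = 65L)
  wE <- iptw(fx$panel, interacted_modifier = "edss")
  fs <- fit_stratified(fx$panel, wE, "relapse", "edss")
  expect_s3_class(fs, "msm_strata")
  expect_equal(nrow(fs$result), length(unique(fs$result$stratum)))
  expect_true(all(fs$result$estimable | fs$result$n_events >= 0))
  expect_output(print(fs), "Stratified")
  # a phenotype stratifier on a relapsing-only cohort collapses to one stratum
  pan1 <- fx$panel
  pan1$course <- "RRMS"
  fs1 <- fit_stratified(pan1, fx$weights, "relapse", "phenotype")
  expect_equal(nrow(fs1$result), 1L)
  # custom cut points are honored
  fs2 <- fit_stratified(fx$panel, wE, "relapse", "edss", cut_points = c(2, 4))
  expect_equal(nrow(fs2$result), 3L)
  # plotting a strata object draws a forest without error
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(fs))
})

test_that("the three-way model needs both phenotype groups and labels its terms", {
  fxf <- fixture_analysis(900, seed = 66L, scenario = "phenotype_specific",
                          cohort = "full")
  f3 <- fit_three_way(fxf$panel, fxf$weights, "worsening")
  expect_true("DMT x phenotype x arr" %in% f3$result$term)
  rel_only <- fxf$panel[fxf$panel$course %in% c("CIS", "RRMS"), ]
  class(rel_only) <- class(fxf$panel)
  attr(rel_only, "design") <- "A"
  expect_error(fit_three_way(rel_only, NULL, "worsening"),
               class = "msmtrial_domain_error")
})

test_that("stratified fits on symmetric strata agree", {
  fx <- fixture_analysis(300, seed = 67L)
  pan <- fx$panel
  # duplicate the cohort into two identical artificial strata
  pan2 <- pan
  pan2$patient_id <- paste0(pan2$patient_id, "b")
  pan2$age <- pan2$age + 100
  both <- rbind(as.data.frame(pan), as.data.frame(pan2))
  class(both) <- class(pan)
  attr(both, "design") <- "A"
  fs <- fit_stratified(both, NULL, "relapse", "age", cut_points = 90)
  expect_equal(fs$result$hazard_ratio[1], fs$result$hazard_ratio[2],
               tolerance = 1e-8)
})
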