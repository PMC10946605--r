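# Synthetic MS registry generator. Emulates the longitudinal and causal
# structure the MSM analysis assumes: irregular visit schedules, EDSS
# random-walk trajectories with relapse-associated transient worsening,
# relapse processes with patient-level frailty and treatment effects,
# treatment initiation/discontinuation driven by recent relapses and EDSS
# (confounding by indication), CIS/RRMS -> SPMS transitions, MRI activity
# indicators, and pregnancy intervals -- with known ground-truth hazard
# ratios so every downstream stage can be checked by parameter recovery.

# Generator internals not exposed as scenario parameters; calibrated once to
# reproduce the descriptive features of large treated MS cohorts (~78% of
# 6-month bins treated, ~58% treated at the first EDSS visit, mean baseline
# EDSS ~2, annualized relapse rate ~0.3-0.5/yr). See the methods vignette.
GEN <- list(
  start_logit = -3.1,     # per-epoch treatment-initiation intercept
  init_logit = -1.0,      # baseline (first-visit) treatment intercept
  edss_ll = 0.08,         # log relapse intensity per EDSS step above 2
  p_up = 0.10,            # per-epoch prob of an upward latent EDSS step
  p_down = 0.06,          # per-epoch prob of a downward latent EDSS step
  prog_drift = 0.05,      # extra upward step prob in progressive phenotypes
  ppms_rel_lograte = log(0.25),  # relapse intensity multiplier in PPMS
  perm_step_prob = 0.2,   # prob a relapse leaves a permanent +0.5 EDSS step
  preg_prob = 0.012,      # per-epoch pregnancy start prob (female, age < 45)
  mri_int = -1.6, mri_rel = 1.3, mri_frailty = 0.7,  # MRI activity model
  # episode start/stop day jitter; stops are recorded <15 days into the
  # epoch whose intensity is already untreated, so the >=15-treated-day rule
  # classifies the stop bin consistently with the generative intensity
  start_jitter = 45, stop_jitter = 14
)

#' Define a synthetic-cohort scenario
#'
#' Collects the generative parameters of [simulate_cohort()]. True hazard
#' ratios are multiplicative treatment effects in the generator: the relapse
#' intensity is multiplied by `true_hr_relapse` while treated, and the
#' per-epoch probabilities of upward/downward latent EDSS steps are
#' multiplied by `true_hr_worsening` / `true_hr_improvement`.
#' `confounding_strength` is the log-odds increment of treatment initiation
#' per relapse in the past year and per EDSS step, which induces confounding
#' by indication.
#'
#' @param n_patients Number of patients (>= 0).
#' @param follow_up_years Named vector `c(mean=, min=)`: follow-up from the
#'   first EDSS visit is `min` plus a gamma-distributed excess with the given
#'   mean, capped at 20 years.
#' @param visit_interval_days Named vector `c(mean=, jitter=)`: EDSS visits
#'   occur at intervals uniform in `mean +/- jitter` days.
#' @param baseline_relapse_rate Untreated relapse intensity (events/year) at
#'   EDSS 2 for a patient with zero frailty.
#' @param true_hr_relapse,true_hr_worsening,true_hr_improvement Positive
#'   ground-truth treatment effects.
#' @param confounding_strength Nonnegative log-odds increment (see above);
#'   0 switches confounding by indication off.
#' @param discontinuation_prob_per_bin Per-epoch probability that a treated
#'   patient stops therapy.
#' @param spms_conversion_hazard Per-year hazard of RRMS -> SPMS conversion.
#' @param progressive_fraction Fraction of patients with a progressive
#'   phenotype (SPMS/PPMS/PRMS) already at MS onset.
#' @param effect_modifiers Optional list of effect-modification parameters:
#'   `edss_attenuation_loghr` (added to the treated log relapse-intensity per
#'   EDSS step, > 0 attenuates the effect at higher disability) and
#'   `progressive_hr_relapse` / `progressive_hr_worsening` (treatment effects
#'   that replace the global ones in progressive phenotypes).
#' @param frailty_sd SD of the patient-level normal frailty on the log
#'   relapse intensity (makes relapse history predictive of future relapses).
#' @param seed Integer seed; every call to [simulate_cohort()] with the same
#'   scenario is then byte-identical.
#' @param name Scenario label.
#' @return An object of class `ms_scenario`.
#' @export
ms_scenario <- function(n_patients = 1000,
                        follow_up_years = c(mean = 8.8, min = 1.5),
                        visit_interval_days = c(mean = 120, jitter = 60),
                        baseline_relapse_rate = 0.45,
                        true_hr_relapse = 1, true_hr_worsening = 1,
                        true_hr_improvement = 1,
                        confounding_strength = 0.4,
                        discontinuation_prob_per_bin = 0.04,
                        spms_conversion_hazard = 0.02,
                        progressive_fraction = 0.075,
                        effect_modifiers = NULL,
                        frailty_sd = 0.7, seed = NULL, name = "custom") {
  stopifnot(n_patients >= 0, baseline_relapse_rate >= 0,
            true_hr_relapse > 0, true_hr_worsening > 0, true_hr_improvement > 0,
            confounding_strength >= 0,
            discontinuation_prob_per_bin >= 0, discontinuation_prob_per_bin <= 1,
            spms_conversion_hazard >= 0,
            progressive_fraction >= 0, progressive_fraction <= 1,
            frailty_sd >= 0)
  em <- list(edss_attenuation_loghr = 0, progressive_hr_relapse = NULL,
             progressive_hr_worsening = NULL)
  if (!is.null(effect_modifiers)) {
    bad <- setdiff(names(effect_modifiers), names(em))
    if (length(bad)) stop_msm("msmtrial_domain_error", "unknown effect modifier '%s'", bad[1])
    em[names(effect_modifiers)] <- effect_modifiers
  }
  structure(list(
    n_patients = as.integer(n_patients), follow_up_years = follow_up_years,
    visit_interval_days = visit_interval_days,
    baseline_relapse_rate = baseline_relapse_rate,
    true_hr_relapse = true_hr_relapse, true_hr_worsening = true_hr_worsening,
    true_hr_improvement = true_hr_improvement,
    confounding_strength = confounding_strength,
    discontinuation_prob_per_bin = discontinuation_prob_per_bin,
    spms_conversion_hazard = spms_conversion_hazard,
    progressive_fraction = progressive_fraction,
    effect_modifiers = em, frailty_sd = frailty_sd, seed = seed, name = name
  ), class = "ms_scenario")
}

#' @export
print.ms_scenario <- function(x, ...) {
  cat(sprintf("<ms_scenario '%s'> n=%d, true HRs (relapse/worsening/improvement) = %.2f/%.2f/%.2f, confounding=%.2f\n",
              x$name, x$n_patients, x$true_hr_relapse, x$true_hr_worsening,
              x$true_hr_improvement, x$confounding_strength))
  invisible(x)
}

#' Reference simulation scenarios
#'
#' @param n_patients Cohort size applied to every scenario.
#' @return Named list of [ms_scenario()] objects:
#' \describe{
#'   \item{null}{all true HRs 1, confounding by indication on.}
#'   \item{protective}{relapse HR 0.5, worsening HR 0.55, improvement HR
#'     1.3, confounding on.}
#'   \item{no_confounding}{the protective effects with
#'     `confounding_strength = 0`.}
#'   \item{modified_by_edss}{the treatment effect on relapses attenuates by
#'     log-HR +0.35 per EDSS step (HR 0.40 at EDSS 0).}
#'   \item{phenotype_specific}{30% progressive phenotypes in whom treatment
#'     has no effect on worsening or relapses (effect confined to relapsing
#'     MS).}
#' }
#' @export
default_scenarios <- function(n_patients = 1000) {
  list(
    null = ms_scenario(n_patients, name = "null"),
    protective = ms_scenario(n_patients, true_hr_relapse = 0.5,
                             true_hr_worsening = 0.55, true_hr_improvement = 1.3,
                             name = "protective"),
    no_confounding = ms_scenario(n_patients, true_hr_relapse = 0.5,
                                 true_hr_worsening = 0.55, true_hr_improvement = 1.3,
                                 confounding_strength = 0, name = "no_confounding"),
    modified_by_edss = ms_scenario(n_patients, true_hr_relapse = 0.4,
                                   true_hr_worsening = 0.55, true_hr_improvement = 1.3,
                                   effect_modifiers = list(edss_attenuation_loghr = 0.35),
                                   name = "modified_by_edss"),
    phenotype_specific = ms_scenario(n_patients, true_hr_relapse = 0.5,
                                     true_hr_worsening = 0.55, true_hr_improvement = 1.3,
                                     progressive_fraction = 0.3,
                                     effect_modifiers = list(progressive_hr_relapse = 1,
                                                             progressive_hr_worsening = 1),
                                     name = "phenotype_specific")
  )
}

step_up_edss <- function(x) ifelse(x == 0, 1, pmin(10, x + 0.5))
step_down_edss <- function(x) ifelse(x <= 1, 0, x - 0.5)

# keep points >= `gap` apart, scanning left to right from `last`
thin_gaps <- function(ts, last = -Inf, gap = RELAPSE_MIN_GAP) {
  keep <- logical(length(ts))
  for (j in seq_along(ts)) {
    if (ts[j] - last >= gap) { keep[j] <- TRUE; last <- ts[j] }
  }
  ts[keep]
}

#' Simulate a synthetic registry cohort
#'
#' Generates an [ms_registry()] under the causal structure described in
#' [ms_scenario()]. Time advances in 183-day epochs from each patient's
#' first EDSS visit: each epoch, untreated patients may initiate therapy
#' with probability depending on relapses in the past year and current EDSS
#' (confounding by indication) and treated patients may discontinue;
#' relapses arise from a piecewise-constant intensity with lognormal
#' frailty; the latent EDSS takes bounded random-walk steps on the valid
#' grid whose up/down probabilities carry the treatment effects; relapses
#' add a transient +1.0 EDSS bump for 30-90 days (so post-relapse score
#' exclusion has observable effect) and occasionally a permanent +0.5 step.
#' Visits at jittered intervals observe the latent EDSS plus any bump.
#'
#' @param params An `ms_scenario`.
#' @param force_treatment `"natural"` follows the confounded assignment
#'   mechanism; `"always"` / `"never"` force the treated state for the whole
#'   record, giving the counterfactual cohorts used as a ground-truth oracle.
#' @return An `ms_registry` with attributes `ground_truth` (per-patient
#'   frailty, phenotype group, baseline treatment) and `scenario`.
#' @export
simulate_cohort <- function(params, force_treatment = c("natural", "always", "never")) {
  stopifnot(inherits(params, "ms_scenario"))
  force_treatment <- match.arg(force_treatment)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_patients
  empty_reg <- function() {
    chr <- character(0); dt <- as.Date(character(0)); num <- numeric(0)
    ms_registry(
      patients = data.frame(patient_id = chr, sex = chr, birth_date = dt, ms_onset_date = dt),
      courses = data.frame(patient_id = chr, phenotype = chr, start_date = dt),
      visits = data.frame(patient_id = chr, date = dt, edss = num),
      relapses = data.frame(patient_id = chr, date = dt),
      treatments = data.frame(patient_id = chr, dmt_name = chr, start_date = dt, stop_date = dt),
      mri = data.frame(patient_id = chr, date = dt, activity = chr),
      validate = FALSE)
  }
  if (n == 0) {
    out <- empty_reg()
    attr(out, "ground_truth") <- data.frame(patient_id = character(0), frailty = numeric(0),
                                            progressive = logical(0))
    attr(out, "scenario") <- params
    return(out)
  }

  em <- params$effect_modifiers
  cs <- params$confounding_strength
  log_hr_rel <- log(params$true_hr_relapse)
  att <- em$edss_attenuation_loghr

  ids <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(runif(n) < 0.71, "female", "male")
  age_onset <- pmin(pmax(rnorm(n, 30.6, 9.7), 15), 55)
  onset_date <- as.Date("1995-01-01") + floor(runif(n, 0, 17 * 365))
  dur0 <- pmin(pmax(round(rlnorm(n, log(2.77 * 365), 1.0)), 30), 25 * 365)
  fu_mean <- params$follow_up_years[["mean"]] * 365
  fu_min <- params$follow_up_years[["min"]] * 365
  fu_excess <- pmax(fu_mean - fu_min, 1)
  F_days <- pmin(fu_min + rgamma(n, shape = 1.4, scale = fu_excess / 1.4), 20 * 365)
  frailty <- rnorm(n, 0, params$frailty_sd)

  progressive <- runif(n) < params$progressive_fraction
  course0 <- ifelse(progressive,
                    sample(c("SPMS", "PPMS", "PRMS"), n, TRUE, prob = c(0.55, 0.38, 0.07)),
                    "CIS")
  edss0 <- pmin(round(rgamma(n, shape = 1.8, scale = 1.2) * 2) / 2, 9)
  edss0[edss0 == 0.5] <- 1
  edss0[progressive] <- pmin(edss0[progressive] + 2, 9)
  edss0 <- ifelse(edss0 > 0 & edss0 < 1, 1, edss0)

  code <- c(CIS = 1L, RRMS = 2L, SPMS = 3L, PPMS = 4L, PRMS = 5L)
  course_code <- code[course0]

  # treated log relapse-intensity increment given phenotype and EDSS
  trt_rel_log <- function(cc, ed) {
    base <- log_hr_rel + att * ed
    if (!is.null(em$progressive_hr_relapse)) {
      base <- ifelse(cc >= 3L, log(em$progressive_hr_relapse), base)
    }
    base
  }

  # --- pre-baseline relapses (the pre-baseline period is untreated:
  # therapy starts at or after the first EDSS visit) ---
  lam0 <- params$baseline_relapse_rate / 365 *
    exp(frailty + GEN$edss_ll * (edss0 - 2) +
          ifelse(course_code == 4L, GEN$ppms_rel_lograte, 0))
  npre <- rpois(n, lam0 * dur0)
  pre_rel <- vector("list", n)
  for (i in which(npre > 0)) {
    ts <- floor(sort(runif(npre[i], -dur0[i], 0)))
    pre_rel[[i]] <- thin_gaps(ts)
  }
  # CIS converts to RRMS at the first relapse
  first_pre <- vapply(pre_rel, function(x) if (length(x)) x[1] else NA_real_, numeric(1))
  cis_conv <- course_code == 1L & !is.na(first_pre)
  course_code[cis_conv] <- 2L

  # --- visit schedules (values are realized inside the epoch loop, so that
  # treatment decisions condition on exactly the observed scores) ---
  vi <- params$visit_interval_days
  lo <- max(vi[["mean"]] - vi[["jitter"]], 20); hi <- vi[["mean"]] + vi[["jitter"]]
  vis_days <- vector("list", n); vis_vals <- vector("list", n)
  for (i in seq_len(n)) {
    m <- ceiling(F_days[i] / lo) + 1L
    tv <- c(0, cumsum(floor(runif(m, lo, hi + 1))))
    tv <- unique(tv[tv <= F_days[i]])
    vis_days[[i]] <- tv
    vis_vals[[i]] <- rep(NA_real_, length(tv))
  }
  vptr <- rep(1L, n)

  # --- epoch loop over follow-up ---
  Kmax <- max(ceiling(F_days / BIN_DAYS))
  edss_hist <- matrix(NA_real_, n, Kmax)
  edss <- edss0
  last_rel <- vapply(pre_rel, function(x) if (length(x)) x[length(x)] else -Inf, numeric(1))
  rel_days_pat <- pre_rel
  bump_ends_pat <- lapply(pre_rel, function(x) x + 60)
  # last recorded observed EDSS: the covariate treatment decisions condition
  # on (clinicians see the chart value whether or not a relapse was recent);
  # the baseline visit realizes it before the first decision
  last_obs <- edss0
  preg_until <- rep(-Inf, n)
  age0 <- age_onset + dur0 / 365
  treated <- rep(FALSE, n); treated0 <- rep(FALSE, n)
  ep_start <- rep(NA_real_, n)

  # realize observed values for patient i's visits dated on/before `upto`:
  # latent state of the visit's epoch, +1.0 while inside a post-relapse bump
  # window; every recorded score updates the covariate fed to the
  # treatment-decision model
  observe <- function(i, upto) {
    vd <- vis_days[[i]]
    p <- vptr[i]
    while (p <= length(vd) && vd[p] <= upto) {
      day <- vd[p]
      e0 <- min(floor(day / BIN_DAYS) + 1L, Kmax)
      val <- edss_hist[i, e0]
      rts <- rel_days_pat[[i]]
      if (length(rts)) {
        li <- findInterval(day, rts)
        if (li > 0 && day <= bump_ends_pat[[i]][li]) val <- min(10, val + 1)
      }
      vis_vals[[i]][p] <<- val
      last_obs[i] <<- val
      p <- p + 1L
    }
    vptr[i] <<- p
  }

  rel_rec <- list(); ep_rec <- list(); course_rec <- list(); preg_rec <- list()
  hr_w_vec <- function(cc) {
    out <- rep(params$true_hr_worsening, length(cc))
    if (!is.null(em$progressive_hr_worsening)) {
      out[cc >= 3L] <- em$progressive_hr_worsening
    }
    out
  }

  for (k in seq_len(Kmax) - 1L) {
    d <- k * BIN_DAYS
    active <- d < F_days
    if (!any(active)) break
    len <- pmin(BIN_DAYS, F_days - d)
    edss_hist[, k + 1L] <- edss

    # observe visits due by the decision date; count relapses in the exact
    # 365-day window ending at the decision (the panel's arr_prior_12m)
    rel12 <- rep(0, n)
    for (i in which(active)) {
      observe(i, d)
      rts <- rel_days_pat[[i]]
      if (length(rts)) rel12[i] <- count_in(rts, d - 365, d)
    }

    # pregnancy
    can_preg <- active & sex == "female" & (age0 + d / 365) < 45 & d >= preg_until
    new_preg <- can_preg & runif(n) < GEN$preg_prob
    if (any(new_preg)) {
      preg_until[new_preg] <- d + 270
      preg_rec[[length(preg_rec) + 1L]] <-
        cbind(which(new_preg), d, d + 270)
    }

    # treatment decisions: the baseline (first-visit) decision has its own
    # intercept; initiation depends on relapses in the past year and the
    # last recorded EDSS (confounding by indication)
    if (force_treatment == "natural") {
      u <- runif(n)
      icpt <- if (k == 0L) GEN$init_logit else GEN$start_logit
      p_start <- plogis(icpt + cs * rel12 + cs * last_obs)
      starters <- active & !treated & u < p_start
      stoppers <- k > 0L & active & treated & u < params$discontinuation_prob_per_bin
      if (any(starters)) {
        treated[starters] <- TRUE
        ep_start[starters] <- d + floor(runif(sum(starters), 0, GEN$start_jitter))
      }
      if (k == 0L) treated0 <- starters
      if (any(stoppers)) {
        stops <- d + floor(runif(sum(stoppers), 0, GEN$stop_jitter))
        ep_rec[[length(ep_rec) + 1L]] <- cbind(which(stoppers), ep_start[stoppers], stops)
        treated[stoppers] <- FALSE
        ep_start[stoppers] <- NA_real_
      }
    } else if (force_treatment == "always" && k == 0L) {
      treated[] <- TRUE; treated0[] <- TRUE; ep_start[] <- 0
    }

    # relapses
    lam <- params$baseline_relapse_rate / 365 *
      exp(frailty + GEN$edss_ll * (edss - 2) +
            ifelse(course_code == 4L, GEN$ppms_rel_lograte, 0) +
            treated * trt_rel_log(course_code, edss))
    N <- rpois(n, lam * len * active)
    N <- pmin(N, 3L)
    for (i in which(N > 0L & active)) {
      ts <- floor(sort(d + runif(N[i]) * len[i]))
      ts <- thin_gaps(ts, last = last_rel[i])
      if (!length(ts)) next
      last_rel[i] <- ts[length(ts)]
      bump_end <- ts + runif(length(ts), 30, 90)
      rel_days_pat[[i]] <- c(rel_days_pat[[i]], ts)
      bump_ends_pat[[i]] <- c(bump_ends_pat[[i]], bump_end)
      rel_rec[[length(rel_rec) + 1L]] <- cbind(i, ts, bump_end)
      perm <- runif(length(ts)) < GEN$perm_step_prob
      if (any(perm)) {
        for (p in seq_len(sum(perm))) edss[i] <- step_up_edss(edss[i])
      }
      if (course_code[i] == 1L) {
        course_code[i] <- 2L
        course_rec[[length(course_rec) + 1L]] <- cbind(i, 2L, ts[1])
      }
    }

    # latent EDSS random walk (reflected at 0 and 10, valid steps only)
    p_up <- GEN$p_up * ifelse(treated, hr_w_vec(course_code), 1) +
      GEN$prog_drift * (course_code >= 3L)
    p_down <- pmin(GEN$p_down * ifelse(treated, params$true_hr_improvement, 1), 0.4)
    u2 <- runif(n)
    go_up <- active & u2 < p_up
    go_down <- active & u2 > 1 - p_down
    edss[go_up] <- step_up_edss(edss[go_up])
    edss[go_down] <- step_down_edss(edss[go_down])

    # SPMS conversion
    conv <- active & course_code == 2L &
      runif(n) < params$spms_conversion_hazard * len / 365
    if (any(conv)) {
      course_code[conv] <- 3L
      # conversion is recorded at the epoch end, after any same-epoch
      # relapse-driven CIS -> RRMS transition
      course_rec[[length(course_rec) + 1L]] <-
        cbind(which(conv), 3L, floor(d + len[conv]))
    }
  }
  if (any(treated)) {
    ep_rec[[length(ep_rec) + 1L]] <- cbind(which(treated), ep_start[treated], NA_real_)
  }
  # realize any visits after the last decision epoch
  for (i in seq_len(n)) observe(i, Inf)

  # --- MRI assessments (roughly yearly, activity tied to recent relapses) ---
  mri_pid <- vector("list", n); mri_day <- vector("list", n); mri_act <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- -floor(runif(1, 0, 120))
    while (tail(tm, 1) < F_days[i]) tm <- c(tm, tail(tm, 1) + floor(runif(1, 305, 426)))
    tm <- tm[tm <= F_days[i]]
    if (!length(tm)) next
    rts <- rel_days_pat[[i]]
    rel_recent <- if (length(rts)) {
      vapply(tm, function(t) any(rts > t - 365 & rts <= t), logical(1))
    } else rep(FALSE, length(tm))
    act <- runif(length(tm)) <
      plogis(GEN$mri_int + GEN$mri_rel * rel_recent + GEN$mri_frailty * frailty[i])
    mri_pid[[i]] <- rep(i, length(tm)); mri_day[[i]] <- tm
    mri_act[[i]] <- ifelse(act, "active", "not_active")
  }

  baseline_date <- onset_date + dur0
  to_date <- function(idx, day) baseline_date[idx] + day

  v_idx <- rep(seq_len(n), lengths(vis_days))
  visits <- data.frame(patient_id = ids[v_idx], date = to_date(v_idx, unlist(vis_days)),
                       edss = unlist(vis_vals), stringsAsFactors = FALSE)
  r_idx <- rep(seq_len(n), lengths(rel_days_pat))
  relapses <- data.frame(patient_id = ids[r_idx],
                         date = to_date(r_idx, unlist(rel_days_pat)),
                         stringsAsFactors = FALSE)
  ep_all <- if (length(ep_rec)) do.call(rbind, ep_rec) else matrix(numeric(0), ncol = 3)
  treatments <- data.frame(
    patient_id = ids[ep_all[, 1]], dmt_name = rep("DMT", nrow(ep_all)),
    start_date = to_date(ep_all[, 1], ep_all[, 2]),
    stop_date = to_date(ep_all[, 1], ep_all[, 3]), stringsAsFactors = FALSE)
  m_idx <- unlist(mri_pid)
  mri <- data.frame(patient_id = ids[m_idx],
                    date = to_date(m_idx, unlist(mri_day)),
                    activity = unlist(mri_act), stringsAsFactors = FALSE)
  pg_all <- if (length(preg_rec)) do.call(rbind, preg_rec) else matrix(numeric(0), ncol = 3)
  pregnancies <- data.frame(
    patient_id = ids[pg_all[, 1]],
    start_date = to_date(pg_all[, 1], pg_all[, 2]),
    end_date = to_date(pg_all[, 1], pg_all[, 3]), stringsAsFactors = FALSE)

  # course history: phenotype at onset plus recorded transitions
  courses <- data.frame(patient_id = ids, phenotype = course0,
                        start_date = onset_date, stringsAsFactors = FALSE)
  cis_rows <- which(cis_conv)
  if (length(cis_rows)) {
    courses <- rbind(courses, data.frame(
      patient_id = ids[cis_rows], phenotype = "RRMS",
      start_date = to_date(cis_rows, first_pre[cis_rows]), stringsAsFactors = FALSE))
  }
  cc_all <- if (length(course_rec)) do.call(rbind, course_rec) else
    matrix(numeric(0), ncol = 3)
  if (nrow(cc_all)) {
    courses <- rbind(courses, data.frame(
      patient_id = ids[cc_all[, 1]], phenotype = c("CIS", "RRMS", "SPMS")[cc_all[, 2]],
      start_date = to_date(cc_all[, 1], cc_all[, 3]), stringsAsFactors = FALSE))
  }

  patients <- data.frame(
    patient_id = ids, sex = sex,
    birth_date = onset_date - round(age_onset * 365.25),
    ms_onset_date = onset_date, stringsAsFactors = FALSE)

  out <- ms_registry(patients, courses, visits, relapses, treatments, mri,
                     pregnancies, validate = TRUE)
  attr(out, "ground_truth") <- data.frame(
    patient_id = ids, frailty = frailty, progressive = progressive,
    phenotype_onset = course0, treated_at_baseline = treated0,
    stringsAsFactors = FALSE)
  attr(out, "scenario") <- params
  out
}

#' Simulate registries from a scenario
#'
#' S3 [stats::simulate()] method for `ms_scenario`: draws `nsim` synthetic
#' registries (see [simulate_cohort()]).
#'
#' @param object An `ms_scenario`.
#' @param nsim Number of registries.
#' @param seed Optional seed overriding the scenario's own.
#' @param ... Passed to [simulate_cohort()] (e.g. `force_treatment`).
#' @return A single `ms_registry` if `nsim = 1`, else a list of them.
#' @export
simulate.ms_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seed <- seed
  if (nsim == 1) return(simulate_cohort(object, ...))
  out <- vector("list", nsim)
  base_seed <- object$seed %||% sample.int(1e6, 1)
  for (s in seq_len(nsim)) {
    object$seed <- base_seed + s - 1L
    out[[s]] <- simulate_cohort(object, ...)
  }
  out
}
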