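# Stabilized inverse-probability-of-treatment weights. The weight for
# patient i at bin j is the running product over k = 0..j of
#   P(A_k = a_k | A_{k-1}, S) / P(A_k = a_k | A_{k-1}, T_k, S),
# where S are the baseline stabilizing covariates (sex, MS duration at first
# visit, date of birth) and T_k the time-dependent covariates (age,
# pregnancy, treatment history, relapse history, MS duration, EDSS, MS
# course; onset date enters with date of birth to capture long-term changes
# in DMT availability). Both probabilities come from pooled logistic models
# of the treated state over all bins, conditioning on the previous state
# through the prev_treated covariate. When a treatment-by-modifier
# interaction is to be estimated downstream, that modifier is excluded from
# both models.

# baseline_bin is a function of time on study (first bin vs later bins);
# it enters both models so that the baseline treated state (prevalent
# users) and later initiation get their own intercepts
WEIGHT_NUMERATOR_DEFAULT <- c("prev_treated", "baseline_bin", "sex",
                              "ms_duration_at_first_visit", "birth_year")
WEIGHT_DENOMINATOR_DEFAULT <- c(WEIGHT_NUMERATOR_DEFAULT,
                                "age", "pregnancy", "prior_treated_fraction",
                                "arr_prior_12m", "arr_prior_24m", "ms_duration",
                                "edss", "course", "onset_year")

# map an interaction modifier to the weight-model covariates it removes
# map a model-matrix coefficient name back to its covariate (factor
# coefficients share the covariate's prefix; take the longest match)
coef_to_cov <- function(coef_name, covs) {
  hits <- covs[startsWith(coef_name, covs)]
  if (!length(hits)) return(coef_name)
  hits[which.max(nchar(hits))]
}

modifier_weight_drop <- function(modifier) {
  switch(modifier,
         edss = "edss",
         arr = c("arr_prior_12m", "arr_prior_24m"),
         age = "age",
         ms_duration = "ms_duration",
         phenotype = "course",
         mri_activity = character(0),   # MRI is not a weight-model covariate
         stop_msm("msmtrial_domain_error", "unknown modifier '%s'", modifier))
}

# covariate frame for the treatment models; the EDSS entering these models
# is the last recorded score on or before the bin start (pre-exposure)
weight_frame <- function(panel) {
  data.frame(
    A = panel$treated,
    prev_treated = panel$prev_treated,
    baseline_bin = as.integer(panel$bin_index == 0 & panel$segment == 1),
    sex = factor(panel$sex, levels = c("female", "male")),
    ms_duration_at_first_visit = panel$ms_duration_at_first_visit,
    birth_year = panel$birth_year,
    age = panel$age,
    pregnancy = panel$pregnancy,
    prior_treated_fraction = panel$prior_treated_fraction,
    arr_prior_12m = panel$arr_prior_12m,
    arr_prior_24m = panel$arr_prior_24m,
    ms_duration = panel$ms_duration,
    edss = panel$edss_prev,
    edss_missing = panel$pre_edss,
    course = factor(panel$course, levels = PHENOTYPES),
    onset_year = panel$onset_year
  )
}

# The pooled probability model conditions on the previous treated state
# A_{k-1} by stratification: one logistic fit among not-yet-treated bins
# (initiation) and one among previously treated bins (continuation). A
# stratum in which the observed state is constant -- e.g. continuation under
# design A, where treated patients stay treated until censoring -- gets the
# empirical constant probability, so its numerator/denominator ratio is
# exactly 1.
fit_one_probability_model <- function(frame, covs, optional = character(0)) {
  stratified <- "prev_treated" %in% covs
  covs2 <- setdiff(covs, "prev_treated")
  groups <- if (stratified) {
    list(initiation = frame$prev_treated == 0, continuation = frame$prev_treated == 1)
  } else list(pooled = rep(TRUE, nrow(frame)))
  fits <- list()
  for (g in names(groups)) {
    sub <- frame[groups[[g]], , drop = FALSE]
    if (!nrow(sub)) next
    if (length(unique(sub$A)) < 2) {
      fits[[g]] <- list(constant = mean(sub$A))
      next
    }
    dropped <- character(0)
    for (cv in covs2) {
      x <- sub[[cv]]
      const <- if (is.factor(x)) length(unique(as.integer(x))) < 2 else
        (max(x) - min(x)) < 1e-12
      if (const) dropped <- c(dropped, cv)
    }
    use <- setdiff(covs2, dropped)
    repeat {
      f <- if (length(use)) {
        as.formula(paste("A ~", paste(use, collapse = " + ")))
      } else A ~ 1
      dat <- droplevels(sub[c("A", use)])
      fit <- suppressWarnings(glm(f, family = binomial(), data = dat, model = FALSE))
      cf <- coef(fit)[-1]
      if (!anyNA(cf)) break
      # exactly collinear (aliased) covariate: age, MS duration, birth year
      # and onset year are linearly dependent by construction, so the last
      # of them to enter is removed and recorded
      alias_cov <- coef_to_cov(names(cf)[is.na(cf)][1], use)
      dropped <- c(dropped, alias_cov)
      use <- setdiff(use, alias_cov)
    }
    while (length(cf) && (!fit$converged || any(abs(cf) > 15))) {
      worst_cov <- coef_to_cov(names(cf)[which.max(abs(cf))], use)
      if (!worst_cov %in% optional) {
        stop_msm("msmtrial_estimation_error",
                 "treatment model shows (quasi-)separation on covariate '%s'", worst_cov)
      }
      # auto-added helper covariates (e.g. a sparse missing-EDSS indicator)
      # are dropped rather than fatal
      dropped <- c(dropped, worst_cov)
      use <- setdiff(use, worst_cov)
      f <- if (length(use)) {
        as.formula(paste("A ~", paste(use, collapse = " + ")))
      } else A ~ 1
      dat <- droplevels(sub[c("A", use)])
      fit <- suppressWarnings(glm(f, family = binomial(), data = dat, model = FALSE))
      cf <- coef(fit)[-1]
    }
    fits[[g]] <- list(fit = fit, covariates = use, dropped = dropped)
  }
  list(fits = fits, stratified = stratified, covariates = covs2)
}

predict_state_prob <- function(model, frame) {
  p <- rep(NA_real_, nrow(frame))
  groups <- if (model$stratified) {
    list(initiation = frame$prev_treated == 0, continuation = frame$prev_treated == 1)
  } else list(pooled = rep(TRUE, nrow(frame)))
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (!any(idx)) next
    m <- model$fits[[g]]
    if (is.null(m)) {
      stop_msm("msmtrial_domain_error",
               "panel contains a previous-state stratum absent at fitting time")
    }
    p[idx] <- if (!is.null(m$constant)) m$constant else
      predict(m$fit, newdata = frame[idx, , drop = FALSE], type = "response")
  }
  p
}

#' Fit the pooled treatment-probability models
#'
#' Fits the numerator (stabilizing) and denominator logistic models of the
#' per-bin treated state. With `interacted_modifier` set, the corresponding
#' covariates are removed from both models, since a variable whose
#' interaction with treatment is investigated in the outcome model must not
#' be balanced away by the weights. Covariates that are constant in the
#' panel are dropped and recorded. Fitted probabilities are later bounded
#' inside `prob_bounds`.
#'
#' @param panel An `ms_panel`.
#' @param numerator_covs,denominator_covs Covariate name vectors; defaults
#'   are the baseline stabilizing set and its union with the time-dependent
#'   set (see the package vignette).
#' @param interacted_modifier Optional modifier name (`"edss"`, `"arr"`,
#'   `"age"`, `"ms_duration"`, `"phenotype"`, `"mri_activity"`).
#' @param prob_bounds Length-2 floor/ceiling applied to the fitted
#'   probabilities of the observed state.
#' @return An object of class `ms_txmodels`.
#' @export
fit_treatment_models <- function(panel, numerator_covs = NULL,
                                 denominator_covs = NULL,
                                 interacted_modifier = NULL,
                                 prob_bounds = c(0.01, 0.99)) {
  stopifnot(inherits(panel, "ms_panel"))
  numerator_covs <- numerator_covs %||% WEIGHT_NUMERATOR_DEFAULT
  denominator_covs <- denominator_covs %||% WEIGHT_DENOMINATOR_DEFAULT
  if (!is.null(interacted_modifier)) {
    drop <- modifier_weight_drop(interacted_modifier)
    numerator_covs <- setdiff(numerator_covs, drop)
    denominator_covs <- setdiff(denominator_covs, drop)
  }
  frame <- weight_frame(panel)
  if ("edss" %in% denominator_covs && any(frame$edss_missing > 0)) {
    denominator_covs <- union(denominator_covs, "edss_missing")
  }
  bad <- setdiff(union(numerator_covs, denominator_covs), names(frame))
  if (length(bad)) {
    stop_msm("msmtrial_domain_error", "unknown weight-model covariate '%s'", bad[1])
  }
  if (length(unique(frame$A)) < 2) {
    stop_msm("msmtrial_estimation_error",
             "all bins share one treatment state; treatment models are inestimable")
  }
  # sparse indicator covariates may be inestimable (e.g. no initiation among
  # the few pregnant bins of a small cohort); they are dropped with a record
  # rather than aborting the analysis
  optional <- c("edss_missing", "pregnancy")
  num <- fit_one_probability_model(frame, numerator_covs, optional = optional)
  den <- fit_one_probability_model(frame, denominator_covs, optional = optional)
  structure(list(numerator = num, denominator = den,
                 interacted_modifier = interacted_modifier,
                 prob_bounds = prob_bounds),
            class = "ms_txmodels")
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' Evaluates both treatment models at the observed treated state of every
#' bin, bounds the probabilities inside the configured floor/ceiling, and
#' forms the cumulative product of numerator/denominator ratios within each
#' patient (within each at-risk segment under design C).
#'
#' @param panel The `ms_panel` the models were fitted on.
#' @param models An `ms_txmodels` from [fit_treatment_models()].
#' @return An object of class `ms_iptw` containing the per-bin weight table
#'   (`patient_id`, `segment`, `bin_index`, `p_num`, `p_den`, `w`,
#'   `w_truncated`) and distribution diagnostics.
#' @export
compute_stabilized_weights <- function(panel, models) {
  stopifnot(inherits(panel, "ms_panel"), inherits(models, "ms_txmodels"))
  frame <- weight_frame(panel)
  bounds <- models$prob_bounds
  obs_prob <- function(m) {
    p <- predict_state_prob(m, frame)
    p_obs <- ifelse(frame$A == 1, p, 1 - p)
    floored <- sum(p_obs < bounds[1] | p_obs > bounds[2])
    list(p = pmin(pmax(p_obs, bounds[1]), bounds[2]), floored = floored)
  }
  pn <- obs_prob(models$numerator)
  pd <- obs_prob(models$denominator)
  grp <- paste(panel$patient_id, panel$segment, sep = "\r")
  ratio <- pn$p / pd$p
  w <- exp(ave(log(ratio), grp, FUN = cumsum))
  tab <- data.frame(patient_id = panel$patient_id, segment = panel$segment,
                    bin_index = panel$bin_index, p_num = pn$p, p_den = pd$p,
                    w = w, w_truncated = w, stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    diagnostics = list(mean = mean(w), sd = sd(w), min = min(w), max = max(w),
                       n_floored_num = pn$floored, n_floored_den = pd$floored,
                       truncation = c(0, 1), truncation_bounds = range(w)),
    models = models, interacted_modifier = models$interacted_modifier
  ), class = "ms_iptw")
}

#' Winsorize stabilized weights at empirical quantiles
#'
#' @param weights An `ms_iptw`.
#' @param lower_q,upper_q Quantile probabilities, `0 <= lower_q < upper_q
#'   <= 1`; `(0, 1)` is the identity.
#' @return The `ms_iptw` with `w_truncated` winsorized and diagnostics
#'   updated.
#' @export
truncate_weights <- function(weights, lower_q = 0.01, upper_q = 0.99) {
  stopifnot(inherits(weights, "ms_iptw"),
            lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  w <- weights$table$w
  b <- unname(quantile(w, c(lower_q, upper_q), type = 7))
  weights$table$w_truncated <- pmin(pmax(w, b[1]), b[2])
  weights$diagnostics$truncation <- c(lower_q, upper_q)
  weights$diagnostics$truncation_bounds <- b
  weights
}

#' One-call stabilized weight estimation
#'
#' Convenience wrapper: [fit_treatment_models()], then
#' [compute_stabilized_weights()], then tail control. By default no
#' quantile winsorization is applied -- in calibration studies quantile
#' truncation of the upper tail removed exactly the correction the largest
#' weights carry and biased the null -- and instead a fixed upper cap
#' bounds the influence of rare extreme weights.
#'
#' @inheritParams fit_treatment_models
#' @param truncation Quantile pair for [truncate_weights()]; `c(0, 1)`
#'   (default) applies none.
#' @param weight_cap Absolute upper bound on the truncated weight
#'   (`Inf` disables).
#' @return An `ms_iptw`.
#' @export
iptw <- function(panel, numerator_covs = NULL, denominator_covs = NULL,
                 interacted_modifier = NULL, prob_bounds = c(0.01, 0.99),
                 truncation = c(0, 1), weight_cap = 20) {
  models <- fit_treatment_models(panel, numerator_covs, denominator_covs,
                                 interacted_modifier, prob_bounds)
  ws <- compute_stabilized_weights(panel, models)
  ws <- truncate_weights(ws, truncation[1], truncation[2])
  if (is.finite(weight_cap)) {
    ws$table$w_truncated <- pmin(ws$table$w_truncated, weight_cap)
    ws$diagnostics$weight_cap <- weight_cap
    ws$diagnostics$n_capped <- sum(ws$table$w > weight_cap)
  }
  ws
}

#' @export
print.ms_iptw <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<ms_iptw> %d bins; stabilized weights mean %.3f (sd %.3f), range [%.3f, %.3f]\n",
              nrow(x$table), d$mean, d$sd, d$min, d$max))
  if (!identical(unname(d$truncation), c(0, 1))) {
    cat(sprintf("  truncated at quantiles (%.3g, %.3g): [%.3f, %.3f]\n",
                d$truncation[1], d$truncation[2],
                d$truncation_bounds[1], d$truncation_bounds[2]))
  }
  if (!is.null(x$interacted_modifier)) {
    cat("  estimated with modifier '", x$interacted_modifier,
        "' excluded from both models\n", sep = "")
  }
  invisible(x)
}

#' Confounder balance at the treatment decision
#'
#' Standardized mean differences of covariates between the bins that adopt
#' each treatment state, computed where a treatment decision is actually at
#' play: within each previous-state stratum in which both states occur
#' (under design A, only initiation among not-yet-treated bins; under
#' designs B/C also discontinuation among treated bins). Comparing all
#' treated against all untreated bins pooled over follow-up would instead
#' mix in the causal effect of earlier treatment on later covariates (e.g.
#' suppressed relapse history) and the time trend of treatment prevalence,
#' neither of which is confounding. Weighted SMDs use the full stabilized
#' weight, whose current-bin ratio is what corrects the decision under
#' scrutiny; near-zero weighted SMDs indicate a well-specified treatment
#' model.
#'
#' @param panel An `ms_panel`.
#' @param weights Optional `ms_iptw` aligned with the panel.
#' @param covariates Numeric panel columns to balance-check.
#' @param use_truncated Use `w_truncated` instead of the untruncated
#'   stabilized weight (default `FALSE`: truncation deliberately sacrifices
#'   some confounding correction for variance, which this diagnostic should
#'   expose rather than absorb).
#' @return Data frame with `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
balance_table <- function(panel, weights = NULL,
                          covariates = c("arr_prior_12m", "arr_prior_24m",
                                         "edss", "age", "ms_duration"),
                          use_truncated = FALSE) {
  wv <- if (is.null(weights)) rep(1, nrow(panel)) else
    if (use_truncated) weights$table$w_truncated else weights$table$w
  strata <- list(panel$prev_treated == 0, panel$prev_treated == 1)
  strata <- Filter(function(s) length(unique(panel$treated[s])) == 2, strata)
  if (!length(strata)) {
    stop_msm("msmtrial_domain_error",
             "no previous-state stratum with both treatment states; balance is undefined")
  }
  one <- function(cv, w) {
    x <- panel[[cv]]
    num <- 0; den <- 0
    for (s in strata) {
      a <- s & panel$treated == 1; u <- s & panel$treated == 0
      sp <- sqrt((var(x[a]) + var(x[u])) / 2)
      num <- num + sum(s) * (weighted.mean(x[a], w[a]) - weighted.mean(x[u], w[u])) / sp
      den <- den + sum(s)
    }
    num / den
  }
  data.frame(
    covariate = covariates,
    smd_unweighted = vapply(covariates, one, numeric(1), w = rep(1, nrow(panel))),
    smd_weighted = vapply(covariates, one, numeric(1), w = wv),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
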