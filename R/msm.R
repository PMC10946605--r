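# Weighted Cox proportional-hazards models on the 6-month panels (MSM Cox
# models). The counting-process time axis is time since the design baseline
# (segment-local under design C). Relapses are recurrent per-bin events
# (Andersen-Gill); confirmed disability worsening/improvement are
# time-to-first-event within the at-risk segment. Observations are weighted
# by the truncated stabilized weights and variance is a robust sandwich
# estimator clustered on patient, which is required because the weights
# induce within-patient dependence.

OUTCOMES <- c("relapse", "worsening", "improvement")

# assemble the counting-process data set for one outcome
msm_data <- function(panel, weights, outcome) {
  outcome <- match.arg(outcome, OUTCOMES)
  if (is.null(weights)) {
    w <- rep(1, nrow(panel))
  } else {
    stopifnot(inherits(weights, "ms_iptw"))
    tab <- weights$table
    if (nrow(tab) != nrow(panel) ||
        !all(tab$patient_id == panel$patient_id &
               tab$segment == panel$segment &
               tab$bin_index == panel$bin_index)) {
      stop_msm("msmtrial_domain_error",
               "weights are not aligned with the panel on (patient_id, segment, bin_index)")
    }
    w <- tab$w_truncated
  }
  d <- as.data.frame(panel)
  d$.w <- w
  d$.ev <- switch(outcome, relapse = d$relapse_outcome,
                  worsening = d$worsening_event, improvement = d$improvement_event)
  if (outcome != "relapse") {
    # disability info requires recorded EDSS; drop design-B bins before the
    # first score, then censor each segment after its first confirmed event
    d <- d[d$pre_edss == 0, , drop = FALSE]
    grp <- paste(d$patient_id, d$segment, sep = "\r")
    prior <- ave(d$.ev, grp, FUN = function(x) c(0, cumsum(x)[-length(x)]))
    d <- d[prior == 0, , drop = FALSE]
  }
  d$.start <- d$start_day - d$seg_start_day
  d$.stop <- d$end_day - d$seg_start_day
  # event bins end at the event's actual date (at-risk time truncated
  # there); this keeps the binary-per-bin outcome while avoiding the
  # grouped-ties attenuation of stacking every event on a bin boundary
  evday <- switch(outcome, relapse = d$relapse_day,
                  worsening = d$worsening_day, improvement = d$improvement_day)
  hit <- d$.ev == 1 & !is.na(evday)
  d$.stop[hit] <- d$.start[hit] + pmax(evday[hit], 0.5)
  if (sum(d$.ev) == 0) {
    stop_msm("msmtrial_estimation_error", "no %s events in the analysis panel", outcome)
  }
  d
}

result_row <- function(outcome, term, est, se, design, n_patients, n_events,
                       stratum = NA_character_, estimable = TRUE) {
  z <- est / se
  data.frame(outcome = outcome, term = term,
             hazard_ratio = exp(est),
             ci_lower = exp(est - qnorm(0.975) * se),
             ci_upper = exp(est + qnorm(0.975) * se),
             p_value = 2 * pnorm(-abs(z)),
             n_patients = n_patients, n_events = n_events,
             design = design, stratum = stratum,
             estimable = estimable, stringsAsFactors = FALSE)
}

cox_terms <- function(d, rhs, design, outcome, label_map = identity) {
  f <- as.formula(paste("survival::Surv(.start, .stop, .ev) ~", rhs))
  fit <- survival::coxph(f, data = d, weights = d$.w, cluster = patient_id,
                         robust = TRUE, model = FALSE, x = FALSE, y = FALSE)
  est <- coef(fit)
  se <- sqrt(diag(fit$var))
  rows <- do.call(rbind, lapply(seq_along(est), function(j) {
    result_row(outcome, label_map(names(est)[j]), est[j], se[j], design,
               length(unique(d$patient_id)), sum(d$.ev))
  }))
  list(fit = fit, rows = rows)
}

new_msm_fit <- function(fit, rows, outcome, design, estimator, weights, call) {
  structure(list(fit = fit, result = rows, outcome = outcome, design = design,
                 estimator = estimator,
                 weight_diagnostics = if (!is.null(weights)) weights$diagnostics,
                 interacted_modifier = if (!is.null(weights)) weights$interacted_modifier,
                 call = call),
            class = "msm_fit")
}

#' Fit a marginal structural Cox model for one outcome
#'
#' Fits the weighted Cox model of the treated-vs-untreated hazard on the
#' panel's counting-process intervals. The relapse outcome is recurrent (a
#' patient can contribute several event bins); disability outcomes are time
#' to the first confirmed event within each at-risk segment, after which the
#' segment leaves that outcome's risk set. With `weights = NULL` the
#' unweighted ("naive") association is estimated, which is useful as the
#' confounded benchmark. A pooled discrete-time logistic estimator is
#' available as a cross-check; for rare per-interval events it approximates
#' the weighted partial likelihood.
#'
#' @param panel An `ms_panel`.
#' @param weights An `ms_iptw` aligned with the panel, or `NULL` for the
#'   unweighted fit.
#' @param outcome `"relapse"`, `"worsening"`, or `"improvement"`.
#' @param estimator `"cox"` (default) or `"pooled_logistic"`.
#' @return An object of class `msm_fit`; see [summary.msm_fit()]. The
#'   one-row result table carries the hazard ratio, robust 95% CI, p-value,
#'   and event/patient counts.
#' @export
fit_msm <- function(panel, weights = NULL, outcome = c("relapse", "worsening", "improvement"),
                    estimator = c("cox", "pooled_logistic")) {
  stopifnot(inherits(panel, "ms_panel"))
  outcome <- match.arg(outcome)
  estimator <- match.arg(estimator)
  design <- attr(panel, "design")
  d <- msm_data(panel, weights, outcome)
  if (estimator == "cox") {
    ct <- cox_terms(d, "treated", design, outcome,
                    label_map = function(x) "Overall")
    return(new_msm_fit(ct$fit, ct$rows, outcome, design, estimator, weights,
                       match.call()))
  }
  # pooled discrete-time logistic cross-check with cluster-robust variance
  fit <- glm(.ev ~ treated + offset(log((.stop - .start) / 365)),
             family = quasibinomial(), data = d, weights = d$.w)
  vc <- sandwich::vcovCL(fit, cluster = d$patient_id)
  est <- coef(fit)["treated"]; se <- sqrt(vc["treated", "treated"])
  rows <- result_row(outcome, "Overall", est, se, design,
                     length(unique(d$patient_id)), sum(d$.ev))
  out <- new_msm_fit(fit, rows, outcome, design, estimator, weights, match.call())
  out$robust_vcov <- vc
  out
}

# bin-level modifier column used by interaction/stratified/three-way models
modifier_column <- function(panel, modifier) {
  switch(modifier,
         edss = panel$edss,
         arr = panel$arr_prior_12m,
         age = panel$age,
         ms_duration = panel$ms_duration,
         mri_activity = factor(panel$mri_activity_12m,
                               levels = c("not_active", "active")),
         phenotype = factor(ifelse(panel$course %in% RELAPSING_PHENOTYPES,
                                   "relapsing", "progressive"),
                            levels = c("relapsing", "progressive")),
         stop_msm("msmtrial_domain_error", "unknown modifier '%s'", modifier))
}

#' Estimate a treatment-by-modifier interaction
#'
#' Adds the modifier's main effect and its product with the treated
#' indicator to the MSM Cox model. The supplied weights must have been
#' estimated with this modifier excluded from the weight models (the
#' `ms_iptw` records this); otherwise the weights would remove the very
#' association under study.
#'
#' EDSS and prior relapse-rate interactions are per step / per unit of
#' annualized relapse rate; MRI activity and phenotype are categorical (MRI
#' interaction uses only bins with an assessment in the past year).
#'
#' @inheritParams fit_msm
#' @param modifier One of `"edss"`, `"arr"`, `"age"`, `"ms_duration"`,
#'   `"mri_activity"`, `"phenotype"`.
#' @return An `msm_fit` whose result table contains the treated main effect
#'   and the interaction term(s).
#' @export
fit_interaction <- function(panel, weights, outcome, modifier) {
  stopifnot(inherits(panel, "ms_panel"), inherits(weights, "ms_iptw"))
  outcome <- match.arg(outcome, OUTCOMES)
  if (is.null(weights$interacted_modifier) ||
      !identical(weights$interacted_modifier, modifier)) {
    stop_msm("msmtrial_domain_error",
             "weights were not estimated with modifier '%s' excluded; refit them with interacted_modifier = '%s'",
             modifier, modifier)
  }
  d <- msm_data(panel, weights, outcome)
  mod <- modifier_column(d, modifier)
  if (modifier == "mri_activity") {
    keep <- !is.na(mod)
    d <- d[keep, , drop = FALSE]; mod <- mod[keep]
  }
  if (length(unique(as.vector(mod))) < 2) {
    stop_msm("msmtrial_estimation_error",
             "modifier '%s' is constant in the panel; interaction is collinear", modifier)
  }
  d$.mod <- mod
  lab <- function(x) {
    x <- gsub(".mod", modifier, x, fixed = TRUE)
    x <- gsub("treated", "DMT", x, fixed = TRUE)
    gsub(":", " x ", x, fixed = TRUE)
  }
  ct <- cox_terms(d, "treated * .mod", attr(panel, "design"), outcome,
                  label_map = lab)
  out <- new_msm_fit(ct$fit, ct$rows, outcome, attr(panel, "design"), "cox",
                     weights, match.call())
  out$modifier <- modifier
  out
}

#' Stratified marginal structural Cox models
#'
#' Estimates one treated-vs-untreated hazard ratio per stratum of a
#' modifier, each from the weighted Cox fit restricted to that stratum's
#' bins. Continuous stratifiers default to sample quartiles.
#'
#' @inheritParams fit_interaction
#' @param stratifier Modifier name (see [fit_interaction()]).
#' @param cut_points Optional interior cut points for a continuous
#'   stratifier (quartiles when `NULL`).
#' @return An object of class `msm_strata`: the per-stratum result table
#'   (strata with no events or a single treatment state are flagged
#'   `estimable = FALSE`, never dropped) plus the stratum fits.
#' @export
fit_stratified <- function(panel, weights, outcome, stratifier, cut_points = NULL) {
  stopifnot(inherits(panel, "ms_panel"))
  outcome <- match.arg(outcome, OUTCOMES)
  mod <- modifier_column(panel, stratifier)
  if (is.factor(mod)) {
    strata <- droplevels(mod)
  } else {
    cuts <- cut_points %||% unique(quantile(mod, c(0.25, 0.5, 0.75)))
    strata <- cut(mod, breaks = unique(c(-Inf, cuts, Inf)), right = FALSE)
  }
  levs <- levels(strata)
  rows <- vector("list", length(levs)); fits <- vector("list", length(levs))
  design <- attr(panel, "design")
  for (s in seq_along(levs)) {
    keep <- which(!is.na(strata) & strata == levs[s])
    sub <- panel[keep, , drop = FALSE]
    class(sub) <- class(panel)
    attr(sub, "design") <- design
    subw <- NULL
    if (!is.null(weights)) {
      subw <- weights
      subw$table <- weights$table[keep, , drop = FALSE]
    }
    res <- tryCatch({
      d <- msm_data(sub, subw, outcome)
      if (length(unique(d$treated)) < 2) {
        stop_msm("msmtrial_estimation_error", "single treatment state in stratum")
      }
      cox_terms(d, "treated", design, outcome, label_map = function(x) "DMT")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[s]] <- result_row(outcome, "DMT", NA_real_, NA_real_, design,
                              length(unique(sub$patient_id)),
                              sum(switch(outcome, relapse = sub$relapse_outcome,
                                         worsening = sub$worsening_event,
                                         improvement = sub$improvement_event)),
                              stratum = levs[s], estimable = FALSE)
    } else {
      rr <- res$rows; rr$stratum <- levs[s]
      rows[[s]] <- rr; fits[[s]] <- res$fit
    }
  }
  structure(list(result = do.call(rbind, rows), fits = fits,
                 stratifier = stratifier, outcome = outcome, design = design),
            class = "msm_strata")
}

#' Three-way DMT x phenotype x relapse-rate interaction
#'
#' On a full-cohort panel (relapsing and progressive phenotypes present),
#' fits the weighted Cox model with the treated indicator, phenotype group,
#' prior 12-month annualized relapse rate, all two-way products, and the
#' three-way product.
#'
#' @inheritParams fit_msm
#' @return An `msm_fit` whose result table contains all model terms; the
#'   three-way term is labelled `DMT x phenotype x arr`.
#' @export
fit_three_way <- function(panel, weights = NULL,
                          outcome = c("worsening", "relapse", "improvement")) {
  stopifnot(inherits(panel, "ms_panel"))
  outcome <- match.arg(outcome)
  phen <- modifier_column(panel, "phenotype")
  if (length(unique(phen[!is.na(phen)])) < 2) {
    stop_msm("msmtrial_domain_error",
             "both relapsing and progressive phenotypes are required for the three-way model")
  }
  d <- msm_data(panel, weights, outcome)
  d$.phen <- modifier_column(d, "phenotype")
  lab <- function(x) {
    x <- gsub(".phenprogressive", "phenotype", x, fixed = TRUE)
    x <- gsub("arr_prior_12m", "arr", x, fixed = TRUE)
    x <- gsub("treated", "DMT", x, fixed = TRUE)
    gsub(":", " x ", x, fixed = TRUE)
  }
  ct <- cox_terms(d, "treated * .phen * arr_prior_12m", attr(panel, "design"),
                  outcome, label_map = lab)
  new_msm_fit(ct$fit, ct$rows, outcome, attr(panel, "design"), "cox", weights,
              match.call())
}

#' Proportional-hazards diagnostic for an MSM fit
#'
#' Scaled Schoenfeld-residual trend test ([survival::cox.zph()]) surfacing
#' gross violations of proportional hazards (e.g. a time-varying true
#' treatment effect) instead of silently averaging over them.
#'
#' @param object An `msm_fit` estimated with the Cox estimator.
#' @param ... Passed to [survival::cox.zph()].
#' @return The `cox.zph` table.
#' @export
check_ph <- function(object, ...) {
  stopifnot(inherits(object, "msm_fit"))
  if (object$estimator != "cox") {
    stop_msm("msmtrial_domain_error", "PH diagnostics require the Cox estimator")
  }
  survival::cox.zph(object$fit, ...)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.msm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MSM %s model, outcome '%s', design %s\n",
              if (x$estimator == "cox") "Cox" else "pooled-logistic",
              x$outcome, x$design))
  r <- x$result
  for (j in seq_len(nrow(r))) {
    cat(sprintf("  %-38s HR %6.3f  (95%% CI %.3f-%.3f)  p=%.2g\n",
                r$term[j], r$hazard_ratio[j], r$ci_lower[j], r$ci_upper[j],
                r$p_value[j]))
  }
  cat(sprintf("  %d patients, %d events%s\n", r$n_patients[1], r$n_events[1],
              if (is.null(x$weight_diagnostics)) " (unweighted)" else ""))
  invisible(x)
}

#' Summarize an MSM fit
#'
#' @param object An `msm_fit`.
#' @param ... Unused.
#' @return The object, invisibly, after printing the result table and the
#'   stabilized-weight diagnostics.
#' @export
summary.msm_fit <- function(object, ...) {
  print(object)
  d <- object$weight_diagnostics
  if (!is.null(d)) {
    cat(sprintf("  stabilized weights: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
                d$mean, d$sd, d$min, d$max))
    if (!is.null(object$interacted_modifier)) {
      cat("  weight models excluded modifier '", object$interacted_modifier,
          "'\n", sep = "")
    }
  }
  invisible(object)
}

#' @export
coef.msm_fit <- function(object, ...) coef(object$fit)

#' @export
vcov.msm_fit <- function(object, ...) {
  if (object$estimator == "cox") object$fit$var else object$robust_vcov
}

#' @export
confint.msm_fit <- function(object, parm, level = 0.95, ...) {
  est <- coef(object$fit)
  se <- sqrt(diag(vcov(object)))
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.msm_fit <- function(object, ...) residuals(object$fit, ...)

#' @export
as.data.frame.msm_fit <- function(x, ...) x$result

#' @export
print.msm_strata <- function(x, digits = 3, ...) {
  cat(sprintf("Stratified MSM Cox models, outcome '%s', stratified by %s (design %s)\n",
              x$outcome, x$stratifier, x$design))
  r <- x$result
  for (j in seq_len(nrow(r))) {
    if (r$estimable[j]) {
      cat(sprintf("  %-22s HR %6.3f  (95%% CI %.3f-%.3f)  events=%d\n",
                  r$stratum[j], r$hazard_ratio[j], r$ci_lower[j], r$ci_upper[j],
                  r$n_events[j]))
    } else {
      cat(sprintf("  %-22s inestimable (events=%d)\n", r$stratum[j], r$n_events[j]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.msm_strata <- function(x, ...) x$result

#' Forest-style plot of stratified hazard ratios
#'
#' @param x An `msm_strata`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.msm_strata <- function(x, ...) {
  r <- x$result[x$result$estimable, , drop = FALSE]
  if (!nrow(r)) {
    stop_msm("msmtrial_domain_error", "no estimable strata to plot")
  }
  k <- nrow(r)
  xlim <- range(c(r$ci_lower, r$ci_upper, 1))
  graphics::plot(r$hazard_ratio, seq_len(k), log = "x", xlim = xlim,
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 19,
                 xlab = "Hazard ratio (treated vs untreated)", ylab = "",
                 main = sprintf("%s by %s", x$outcome, x$stratifier), ...)
  graphics::segments(r$ci_lower, seq_len(k), r$ci_upper, seq_len(k))
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = r$stratum, las = 1)
  invisible(x)
}
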