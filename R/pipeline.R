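# End-to-end orchestration: simulate or load a registry, apply eligibility,
# derive confirmed events, build the design panel, estimate weights (overall
# and per requested modifier, each time re-estimating with the modifier
# excluded), fit all models, and write the artifacts with a manifest.

#' Configure an end-to-end analysis
#'
#' @param scenario Name of a [default_scenarios()] scenario, an
#'   `ms_scenario`, or `NULL` when reading from files.
#' @param paths Named list of registry table paths (see [read_registry()]);
#'   used when `scenario` is `NULL`.
#' @param n_patients Cohort size for simulated scenarios.
#' @param cohort_kind `"relapsing"` or `"full"`.
#' @param design Emulation design `"A"`, `"B"`, or `"C"`.
#' @param outcomes Outcomes to fit.
#' @param modifiers Modifiers for interaction + stratified analyses (subset
#'   of `edss`, `arr`, `age`, `ms_duration`, `mri_activity`, `phenotype`).
#'   `phenotype` requires `cohort_kind = "full"`.
#' @param reference_policy Confirmed-event reference policy.
#' @param numerator_covs,denominator_covs,truncation Weight options (see
#'   [iptw()]).
#' @param seed Integer seed for simulated scenarios (required there).
#' @param output_dir Optional directory for the written artifacts.
#' @return An object of class `msm_config`.
#' @export
analysis_config <- function(scenario = "protective", paths = NULL,
                            n_patients = 1000,
                            cohort_kind = c("relapsing", "full"),
                            design = c("A", "B", "C"),
                            outcomes = c("relapse", "worsening", "improvement"),
                            modifiers = character(0),
                            reference_policy = c("roving", "fixed_baseline"),
                            numerator_covs = NULL, denominator_covs = NULL,
                            truncation = c(0.01, 0.99),
                            seed = 1L, output_dir = NULL) {
  cohort_kind <- match.arg(cohort_kind)
  design <- match.arg(design)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  reference_policy <- match.arg(reference_policy)
  known_mod <- c("edss", "arr", "age", "ms_duration", "mri_activity", "phenotype")
  bad <- setdiff(modifiers, known_mod)
  if (length(bad)) stop_msm("msmtrial_domain_error", "unknown modifier '%s'", bad[1])
  if ("phenotype" %in% modifiers && cohort_kind == "relapsing") {
    stop_msm("msmtrial_domain_error",
             "modifier 'phenotype' requires cohort_kind = 'full' (the relapsing cohort has a single phenotype group)")
  }
  if (is.null(scenario) && is.null(paths)) {
    stop_msm("msmtrial_domain_error", "either a scenario or registry paths must be given")
  }
  if (!is.null(scenario) && is.null(seed) && !inherits(scenario, "ms_scenario")) {
    stop_msm("msmtrial_domain_error", "a seed is required when simulating a scenario")
  }
  structure(list(scenario = scenario, paths = paths, n_patients = n_patients,
                 cohort_kind = cohort_kind, design = design, outcomes = outcomes,
                 modifiers = modifiers, reference_policy = reference_policy,
                 numerator_covs = numerator_covs, denominator_covs = denominator_covs,
                 truncation = truncation, seed = seed, output_dir = output_dir),
            class = "msm_config")
}

#' Run the full marginal-structural-model analysis
#'
#' Executes the pipeline stages in order with stage-level logging (patients
#' in/out, bins, events, weight diagnostics) and, when an output directory
#' is configured, writes the panel, weights, result table, exclusion log,
#' diagnostics, text forest report, and a manifest with content hashes.
#' Deterministic given the configuration and seed.
#'
#' @param config An [analysis_config()].
#' @return An object of class `msm_analysis`: list with `config`,
#'   `registry`, `panel`, `weights`, `results` (tidy table of all model
#'   rows), `fits`, `balance`, and `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "msm_config"))
  log <- character(0)
  note <- function(fmt, ...) {
    log[[length(log) + 1L]] <<- sprintf(fmt, ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_msm("msmtrial_pipeline_error", "stage '%s' failed: %s", name,
               conditionMessage(e))
    })
  }

  registry <- stage("input", {
    if (is.null(config$scenario)) {
      read_registry(config$paths)
    } else {
      sc <- config$scenario
      if (!inherits(sc, "ms_scenario")) {
        all_sc <- default_scenarios(config$n_patients)
        if (!sc %in% names(all_sc)) {
          stop_msm("msmtrial_domain_error", "unknown scenario '%s'", sc)
        }
        sc <- all_sc[[sc]]
      }
      sc$seed <- config$seed %||% sc$seed
      simulate_cohort(sc)
    }
  })
  note("input: %d patients", nrow(registry$patients))

  cohort <- stage("eligibility", filter_eligible(registry, config$cohort_kind))
  note("eligibility (%s cohort): %d retained, %d excluded", config$cohort_kind,
       nrow(cohort$patients), nrow(exclusion_log(cohort)))

  events <- stage("events", derive_events(cohort, config$reference_policy))
  note("events: %d worsening, %d improvement", sum(events$kind == "worsening"),
       sum(events$kind == "improvement"))

  panel <- stage("panel", build_panel(cohort, config$design, events))
  note("panel (design %s): %d bins, %.0f%% treated", config$design, nrow(panel),
       100 * mean(panel$treated))

  weights <- stage("weights", iptw(panel, config$numerator_covs,
                                   config$denominator_covs,
                                   truncation = config$truncation))
  dg <- weights$diagnostics
  note("weights: mean %.3f, sd %.3f, range [%.3f, %.3f]", dg$mean, dg$sd,
       dg$min, dg$max)

  fits <- list(); results <- list()
  for (oc in config$outcomes) {
    f <- stage(paste0("fit_", oc), fit_msm(panel, weights, oc))
    fits[[paste0("overall_", oc)]] <- f
    r <- f$result; r$modifier <- NA_character_; r$analysis <- "overall"
    results[[length(results) + 1L]] <- r
    note("fit %s: HR %.3f (%.3f-%.3f), %d events", oc, r$hazard_ratio[1],
         r$ci_lower[1], r$ci_upper[1], r$n_events[1])
  }
  for (mod in config$modifiers) {
    wmod <- stage(paste0("weights_", mod),
                  iptw(panel, config$numerator_covs, config$denominator_covs,
                       interacted_modifier = mod, truncation = config$truncation))
    for (oc in config$outcomes) {
      fi <- stage(paste0("interaction_", mod, "_", oc),
                  fit_interaction(panel, wmod, oc, mod))
      fits[[paste0("interaction_", mod, "_", oc)]] <- fi
      r <- fi$result; r$modifier <- mod; r$analysis <- "interaction"
      results[[length(results) + 1L]] <- r
      fs <- stage(paste0("strata_", mod, "_", oc),
                  fit_stratified(panel, wmod, oc, mod))
      fits[[paste0("strata_", mod, "_", oc)]] <- fs
      r <- fs$result; r$modifier <- mod; r$analysis <- "stratified"
      results[[length(results) + 1L]] <- r
    }
    note("modifier %s: interaction + strata fitted for %d outcome(s)", mod,
         length(config$outcomes))
  }
  results <- do.call(rbind, results)
  balance <- balance_table(panel, weights)

  out <- structure(list(config = config, registry = cohort, panel = panel,
                        weights = weights, results = results, fits = fits,
                        balance = balance, log = log),
                   class = "msm_analysis")
  if (!is.null(config$output_dir)) write_analysis(out, config$output_dir)
  out
}

write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    p
  }
  files <- c(
    wr(as.data.frame(analysis$panel), "panel.csv"),
    wr(analysis$weights$table, "weights.csv"),
    wr(analysis$results, "results.csv"),
    wr(exclusion_log(analysis$registry), "exclusions.csv"),
    wr(analysis$balance, "balance.csv")
  )
  dpath <- file.path(dir, "diagnostics.txt")
  dg <- analysis$weights$diagnostics
  writeLines(c(sprintf("weight_mean\t%.6f", dg$mean),
               sprintf("weight_sd\t%.6f", dg$sd),
               sprintf("weight_min\t%.6f", dg$min),
               sprintf("weight_max\t%.6f", dg$max),
               sprintf("truncation\t%g,%g", dg$truncation[1], dg$truncation[2]),
               analysis$log), dpath)
  rpath <- file.path(dir, "forest.txt")
  writeLines(report_forest(analysis$results), rpath)
  files <- c(files, dpath, rpath)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(files)
}

#' Plain-text forest-style report
#'
#' Groups overall, interaction, and stratum rows per outcome into an
#' aligned text report.
#'
#' @param results The tidy result table of an [run_analysis()] bundle.
#' @return Character vector of report lines.
#' @export
report_forest <- function(results) {
  lines <- character(0)
  for (oc in unique(results$outcome)) {
    lines <- c(lines, sprintf("== %s ==", oc))
    sub <- results[results$outcome == oc, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      mod <- if ("modifier" %in% names(sub) && !is.na(sub$modifier[j])) sub$modifier[j] else ""
      label <- if (!is.na(sub$stratum[j])) {
        sprintf("%s %s", mod, sub$stratum[j])
      } else sub$term[j]
      if (isTRUE(sub$estimable[j])) {
        bar <- {
          pos <- function(v) pmin(pmax(round(24 + 8 * v), 1), 48)
          lo <- pos(log(sub$ci_lower[j])); hi <- pos(log(sub$ci_upper[j]))
          b <- rep(" ", 48); b[lo:hi] <- "-"
          b[pos(0)] <- "|"
          b[pos(log(sub$hazard_ratio[j]))] <- "*"
          paste(b, collapse = "")
        }
        lines <- c(lines, sprintf("  %-34s %6.3f (%5.3f-%5.3f) %s",
                                  label, sub$hazard_ratio[j], sub$ci_lower[j],
                                  sub$ci_upper[j], bar))
      } else {
        lines <- c(lines, sprintf("  %-34s inestimable", label))
      }
    }
  }
  lines
}

#' @export
print.msm_analysis <- function(x, ...) {
  cat("<msm_analysis>\n")
  for (l in x$log) cat(" ", l, "\n")
  ov <- x$results[x$results$analysis == "overall", , drop = FALSE]
  if (nrow(ov)) {
    cat("  overall hazard ratios:\n")
    for (j in seq_len(nrow(ov))) {
      cat(sprintf("    %-12s %6.3f (95%% CI %.3f-%.3f)\n", ov$outcome[j],
                  ov$hazard_ratio[j], ov$ci_lower[j], ov$ci_upper[j]))
    }
  }
  invisible(x)
}
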