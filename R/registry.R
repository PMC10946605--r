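# Registry container, delimited-table readers/writers, validation, and the
# eligibility filters applied before any analysis.
#
# A registry is a list of long-format tables keyed by patient_id:
#   patients(patient_id, sex, birth_date, ms_onset_date)
#   courses(patient_id, phenotype, start_date)
#   visits(patient_id, date, edss)
#   relapses(patient_id, date)
#   treatments(patient_id, dmt_name, start_date, stop_date)  [stop may be NA = ongoing]
#   mri(patient_id, date, activity)
#   pregnancies(patient_id, start_date, end_date)             [optional]
# Dates are ISO-8601 in files and `Date` in memory.

REGISTRY_SCHEMA <- list(
  patients    = c("patient_id", "sex", "birth_date", "ms_onset_date"),
  courses     = c("patient_id", "phenotype", "start_date"),
  visits      = c("patient_id", "date", "edss"),
  relapses    = c("patient_id", "date"),
  treatments  = c("patient_id", "dmt_name", "start_date", "stop_date"),
  mri         = c("patient_id", "date", "activity"),
  pregnancies = c("patient_id", "start_date", "end_date")
)
REGISTRY_DATE_COLS <- list(
  patients = c("birth_date", "ms_onset_date"), courses = "start_date",
  visits = "date", relapses = "date", treatments = c("start_date", "stop_date"),
  mri = "date", pregnancies = c("start_date", "end_date")
)

#' Construct a validated MS registry from its component tables
#'
#' Bundles the long-format registry tables into an `ms_registry` object after
#' sorting each table by patient and date and enforcing the registry
#' invariants (valid EDSS steps, chronologically consistent courses with no
#' reversion from SPMS, non-overlapping treatment episodes, relapses >=30 days
#' apart).
#'
#' @param patients,courses,visits,relapses,treatments,mri,pregnancies
#'   Data frames following the registry schema (see Details in
#'   [read_registry()]). `pregnancies` may be `NULL`.
#' @param relapse_policy How to handle relapse pairs recorded <30 days apart:
#'   `"merge"` (default) keeps the earlier onset, `"strict"` raises a
#'   validation error.
#' @param validate Set to `FALSE` only for internally generated tables that
#'   are known to satisfy the invariants.
#' @return An object of class `ms_registry`: a named list of the seven tables.
#' @export
ms_registry <- function(patients, courses, visits, relapses, treatments, mri,
                        pregnancies = NULL, relapse_policy = c("merge", "strict"),
                        validate = TRUE) {
  relapse_policy <- match.arg(relapse_policy)
  if (is.null(pregnancies)) {
    pregnancies <- data.frame(patient_id = character(),
                              start_date = as.Date(character()),
                              end_date = as.Date(character()))
  }
  reg <- list(patients = patients, courses = courses, visits = visits,
              relapses = relapses, treatments = treatments, mri = mri,
              pregnancies = pregnancies)
  for (nm in names(reg)) {
    miss <- setdiff(REGISTRY_SCHEMA[[nm]], names(reg[[nm]]))
    if (length(miss)) {
      stop_msm("msmtrial_schema_error", "table '%s' is missing required column '%s'",
               nm, miss[1])
    }
    reg[[nm]] <- reg[[nm]][REGISTRY_SCHEMA[[nm]]]
  }
  ord <- function(df, col) df[order(df$patient_id, df[[col]]), , drop = FALSE]
  reg$patients <- reg$patients[order(reg$patients$patient_id), , drop = FALSE]
  reg$courses <- ord(reg$courses, "start_date")
  reg$visits <- ord(reg$visits, "date")
  reg$relapses <- ord(reg$relapses, "date")
  reg$treatments <- ord(reg$treatments, "start_date")
  reg$mri <- ord(reg$mri, "date")
  reg$pregnancies <- ord(reg$pregnancies, "start_date")
  rownames(reg$patients) <- NULL
  class(reg) <- "ms_registry"
  if (validate) reg <- validate_registry(reg, relapse_policy = relapse_policy)
  reg
}

#' Read a registry from delimited text tables
#'
#' Reads the comma-separated registry tables (header row, UTF-8, ISO-8601
#' dates), checks the schema, validates all registry invariants, and returns
#' one record per patient.
#'
#' @param paths Named list/vector of file paths; names must include
#'   `patients`, `courses`, `visits`, `relapses`, `treatments`, `mri`, and
#'   optionally `pregnancies`.
#' @inheritParams ms_registry
#' @return An `ms_registry` object.
#' @export
read_registry <- function(paths, relapse_policy = c("merge", "strict")) {
  relapse_policy <- match.arg(relapse_policy)
  need <- setdiff(names(REGISTRY_SCHEMA), "pregnancies")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    stop_msm("msmtrial_schema_error", "no path supplied for required table '%s'", miss[1])
  }
  tabs <- list()
  for (nm in intersect(names(REGISTRY_SCHEMA), names(paths))) {
    df <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE,
                          colClasses = "character")
    missc <- setdiff(REGISTRY_SCHEMA[[nm]], names(df))
    if (length(missc)) {
      stop_msm("msmtrial_schema_error", "table '%s' is missing required column '%s'",
               nm, missc[1])
    }
    for (dc in REGISTRY_DATE_COLS[[nm]]) {
      df[[dc]][!nzchar(df[[dc]])] <- NA
      df[[dc]] <- as.Date(df[[dc]])
    }
    if (nm == "visits") df$edss <- as.numeric(df$edss)
    tabs[[nm]] <- df
  }
  ms_registry(tabs$patients, tabs$courses, tabs$visits, tabs$relapses,
              tabs$treatments, tabs$mri, tabs$pregnancies,
              relapse_policy = relapse_policy)
}

#' Write a registry to delimited text tables
#'
#' Inverse of [read_registry()]: writes one CSV per table into `dir`.
#' Reading the written files back yields an identical registry (round trip).
#'
#' @param registry An `ms_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "ms_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(REGISTRY_SCHEMA)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(registry[[nm]], p, row.names = FALSE, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}

# Enforce all type invariants; merge or reject <30-day relapse pairs.
validate_registry <- function(reg, relapse_policy = "merge") {
  pat <- reg$patients
  if (anyDuplicated(pat$patient_id)) {
    stop_msm("msmtrial_validation_error", "duplicate patient_id '%s' in patients table",
             pat$patient_id[duplicated(pat$patient_id)][1])
  }
  bad <- which(!pat$sex %in% c("female", "male"))
  if (length(bad)) {
    stop_msm("msmtrial_validation_error", "patient %s: sex must be 'female' or 'male'",
             pat$patient_id[bad[1]])
  }
  bad <- which(!is.na(pat$birth_date) & !is.na(pat$ms_onset_date) &
                 pat$ms_onset_date < pat$birth_date)
  if (length(bad)) {
    stop_msm("msmtrial_validation_error", "patient %s: ms_onset_date precedes birth_date",
             pat$patient_id[bad[1]])
  }
  for (nm in setdiff(names(REGISTRY_SCHEMA), "patients")) {
    unknown <- setdiff(unique(reg[[nm]]$patient_id), pat$patient_id)
    if (length(unknown)) {
      stop_msm("msmtrial_validation_error", "table '%s' refers to unknown patient %s",
               nm, unknown[1])
    }
  }
  bad <- which(!is_valid_edss(reg$visits$edss))
  if (length(bad)) {
    stop_msm("msmtrial_validation_error",
             "patient %s: EDSS value %s is not a valid step (0 or half-steps from 1 to 10)",
             reg$visits$patient_id[bad[1]], format(reg$visits$edss[bad[1]]))
  }
  bad <- which(!reg$courses$phenotype %in% PHENOTYPES)
  if (length(bad)) {
    stop_msm("msmtrial_validation_error", "patient %s: unknown phenotype '%s'",
             reg$courses$patient_id[bad[1]], reg$courses$phenotype[bad[1]])
  }
  # course history: consecutive phenotypes differ; SPMS does not revert
  cr <- reg$courses
  if (nrow(cr) > 1) {
    same_pat <- cr$patient_id[-1] == cr$patient_id[-nrow(cr)]
    rep_ph <- same_pat & cr$phenotype[-1] == cr$phenotype[-nrow(cr)]
    if (any(rep_ph)) {
      stop_msm("msmtrial_validation_error",
               "patient %s: repeated phenotype '%s' in course history",
               cr$patient_id[-1][rep_ph][1], cr$phenotype[-1][rep_ph][1])
    }
    revert <- same_pat & cr$phenotype[-nrow(cr)] == "SPMS" & cr$phenotype[-1] != "SPMS"
    if (any(revert)) {
      stop_msm("msmtrial_validation_error",
               "patient %s: phenotype reverts after SPMS", cr$patient_id[-1][revert][1])
    }
  }
  # relapses >=30 days apart (merge keeps the earlier onset)
  rl <- reg$relapses
  if (nrow(rl) > 1) {
    repeat {
      close_pair <- rl$patient_id[-1] == rl$patient_id[-nrow(rl)] &
        as_day(rl$date[-1]) - as_day(rl$date[-nrow(rl)]) < RELAPSE_MIN_GAP
      if (!any(close_pair)) break
      if (relapse_policy == "strict") {
        stop_msm("msmtrial_validation_error",
                 "patient %s: relapses <%d days apart (policy 'strict')",
                 rl$patient_id[-1][close_pair][1], RELAPSE_MIN_GAP)
      }
      rl <- rl[-(which(close_pair) + 1L), , drop = FALSE]
      if (nrow(rl) < 2) break
    }
    reg$relapses <- rl
  }
  # non-overlapping treatment episodes (NA stop = ongoing)
  tr <- reg$treatments
  if (nrow(tr) > 1) {
    same_pat <- tr$patient_id[-1] == tr$patient_id[-nrow(tr)]
    prev_stop <- as_day(tr$stop_date[-nrow(tr)])
    overlap <- same_pat & (is.na(prev_stop) | as_day(tr$start_date[-1]) < prev_stop)
    if (any(overlap)) {
      stop_msm("msmtrial_validation_error",
               "patient %s: overlapping treatment episodes", tr$patient_id[-1][overlap][1])
    }
  }
  bad <- which(!reg$mri$activity %in% c("active", "not_active"))
  if (length(bad)) {
    stop_msm("msmtrial_validation_error", "patient %s: MRI activity must be 'active' or 'not_active'",
             reg$mri$patient_id[bad[1]])
  }
  reg
}

#' @export
print.ms_registry <- function(x, ...) {
  cat("<ms_registry> ", nrow(x$patients), " patients; ",
      nrow(x$visits), " EDSS visits; ", nrow(x$relapses), " relapses; ",
      nrow(x$treatments), " treatment episodes\n", sep = "")
  excl <- attr(x, "exclusions")
  if (!is.null(excl)) {
    cat("  eligibility-filtered (", attr(x, "cohort_kind") %||% "?", " cohort): ",
        nrow(excl), " patients excluded\n", sep = "")
  }
  invisible(x)
}

#' Extract one patient's complete longitudinal record
#'
#' @param registry An `ms_registry`.
#' @param patient_id A patient identifier present in the registry.
#' @return A list with the patient's row of `patients` plus the date-sorted
#'   slices of every event table.
#' @export
patient_record <- function(registry, patient_id) {
  stopifnot(inherits(registry, "ms_registry"))
  if (!patient_id %in% registry$patients$patient_id) {
    stop_msm("msmtrial_validation_error", "unknown patient %s", patient_id)
  }
  out <- lapply(registry, function(df) df[df$patient_id == patient_id, , drop = FALSE])
  class(out) <- "ms_patient_record"
  out
}

#' Apply the study eligibility filters
#'
#' Retains patients with: follow-up (first to last EDSS score) >= 1 year
#' (365 days), >= 3 EDSS scores, no inter-score gap > 365 days (the
#' "at least one score per year" rule, operationalized as a maximum-gap
#' rule), and a complete minimum dataset (sex, birth date, onset date, MS
#' course). Follow-up is trimmed to the span from the first to the last
#' recorded EDSS score. For the relapsing cohort, patients whose phenotype at
#' the first EDSS visit is progressive (SPMS/PPMS/PRMS) are excluded, and
#' patients converting to SPMS during follow-up have a censoring date
#' recorded at the conversion.
#'
#' @param registry An `ms_registry`.
#' @param cohort_kind `"relapsing"` (primary cohort) or `"full"` (all
#'   phenotypes, no SPMS censoring).
#' @return The filtered `ms_registry`. Its `patients` table gains
#'   `baseline_date`, `followup_end` and `censor_date` columns, and the
#'   exclusion log is available via [exclusion_log()]. An empty cohort is a
#'   valid result (no error).
#' @export
filter_eligible <- function(registry, cohort_kind = c("relapsing", "full")) {
  stopifnot(inherits(registry, "ms_registry"))
  cohort_kind <- match.arg(cohort_kind)
  pat <- registry$patients
  ids <- pat$patient_id
  n <- length(ids)
  reason <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)

  vis <- registry$visits
  vsplit <- split(as_day(vis$date), factor(vis$patient_id, levels = ids))
  nvis <- vapply(vsplit, length, integer(1))
  span <- vapply(vsplit, function(d) if (length(d) < 2) 0 else max(d) - min(d), numeric(1))
  maxgap <- vapply(vsplit, function(d) if (length(d) < 2) Inf else max(diff(d)), numeric(1))
  first_vis <- vapply(vsplit, function(d) if (length(d)) min(d) else NA_real_, numeric(1))
  last_vis <- vapply(vsplit, function(d) if (length(d)) max(d) else NA_real_, numeric(1))

  miss_min <- is.na(pat$sex) | is.na(pat$birth_date) | is.na(pat$ms_onset_date) |
    !ids %in% registry$courses$patient_id
  set_reason <- function(mask, code, det) {
    new <- mask & is.na(reason)
    reason[new] <<- code
    detail[new] <<- det[new]
  }
  set_reason(miss_min, "missing_minimum_data", rep("sex/birth/onset/course incomplete", n))
  set_reason(nvis < 3, "lt_3_edss", sprintf("%d EDSS scores recorded", nvis))
  set_reason(span < DAYS_PER_YEAR, "followup_lt_1yr",
             sprintf("%.2f years between first and last EDSS", span / DAYS_PER_YEAR))
  set_reason(is.finite(maxgap) & maxgap > DAYS_PER_YEAR, "edss_gap_gt_1yr",
             sprintf("longest gap between scores %.0f days", maxgap))

  # phenotype at baseline (latest course starting on/before the first EDSS visit,
  # falling back to the first recorded course)
  baseline_course <- rep(NA_character_, n)
  csplit <- split(registry$courses, factor(registry$courses$patient_id, levels = ids))
  spms_date <- rep(as.Date(NA), n)
  for (i in seq_len(n)) {
    cc <- csplit[[i]]
    if (!nrow(cc) || is.na(first_vis[i])) next
    at <- which(as_day(cc$start_date) <= first_vis[i])
    baseline_course[i] <- if (length(at)) cc$phenotype[max(at)] else cc$phenotype[1]
    sp <- which(cc$phenotype == "SPMS")
    if (length(sp)) spms_date[i] <- cc$start_date[sp[1]]
  }
  if (cohort_kind == "relapsing") {
    set_reason(!is.na(baseline_course) &
                 !baseline_course %in% RELAPSING_PHENOTYPES,
               "progressive_at_baseline",
               sprintf("phenotype %s at first EDSS visit", baseline_course))
  }

  keep <- is.na(reason)
  excl <- data.frame(patient_id = ids[!keep], reason_code = reason[!keep],
                     detail = detail[!keep], stringsAsFactors = FALSE)
  rownames(excl) <- NULL

  out <- registry
  kept_ids <- ids[keep]
  for (nm in names(REGISTRY_SCHEMA)) {
    out[[nm]] <- out[[nm]][out[[nm]]$patient_id %in% kept_ids, , drop = FALSE]
  }
  epoch <- as.Date("1970-01-01")
  out$patients$baseline_date <- epoch + first_vis[keep]
  out$patients$followup_end <- epoch + last_vis[keep]
  censor <- spms_date[keep]
  if (cohort_kind == "full") censor[] <- NA
  # SPMS censoring only matters when conversion falls inside trimmed follow-up
  censor[!is.na(censor) & as_day(censor) <= first_vis[keep]] <- NA
  out$patients$censor_date <- censor
  attr(out, "exclusions") <- excl
  attr(out, "cohort_kind") <- cohort_kind
  out
}

#' Retrieve the exclusion log of an eligibility-filtered registry
#'
#' @param registry A registry returned by [filter_eligible()].
#' @return Data frame with columns `patient_id`, `reason_code`, `detail`
#'   (one row per excluded patient).
#' @export
exclusion_log <- function(registry) {
  attr(registry, "exclusions") %||%
    data.frame(patient_id = character(), reason_code = character(),
               detail = character(), stringsAsFactors = FALSE)
}
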