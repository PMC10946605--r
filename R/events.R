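# EDSS cleaning, reference-dependent step thresholds, 12-month-confirmed
# worsening/improvement detection, and annualized relapse rates.

#' Remove EDSS scores recorded shortly after a relapse
#'
#' Scores obtained <30 days after a relapse onset reflect transient,
#' relapse-associated disability and are excluded before deriving confirmed
#' disability events. A score exactly 30 days after a relapse is retained.
#'
#' @param visits Data frame with columns `date` and `edss`, chronologically
#'   ordered.
#' @param relapse_dates Vector of relapse onset dates (may be empty).
#' @return The subset of `visits` whose dates are >=30 days after every
#'   preceding relapse, order preserved.
#' @export
clean_edss <- function(visits, relapse_dates = NULL) {
  stopifnot(all(c("date", "edss") %in% names(visits)))
  visits[clean_edss_keep(as_day(visits$date), sort(as_day(relapse_dates))), ,
         drop = FALSE]
}

clean_edss_keep <- function(vdays, rdays) {
  if (!length(rdays) || !length(vdays)) return(rep(TRUE, length(vdays)))
  idx <- findInterval(vdays, rdays)          # last relapse on/before each score
  idx == 0L | vdays - rdays[pmax(idx, 1L)] >= POST_RELAPSE_EXCL
}

#' Required EDSS change for a confirmed event
#'
#' The step threshold depends on the reference score: worsening requires an
#' increase of 1.0 step (1.5 if the reference is 0; 0.5 if the reference is
#' above 5.5); improvement requires a decrease of 1.0 step (1.5 if the
#' reference is at or below 1.5; 0.5 if the reference is above 6).
#'
#' @param reference_edss Valid EDSS step(s) the change is measured against.
#' @param kind `"worsening"` or `"improvement"`.
#' @return Numeric vector of required step sizes.
#' @export
required_step <- function(reference_edss, kind = c("worsening", "improvement")) {
  kind <- match.arg(kind)
  if (!all(is_valid_edss(reference_edss))) {
    stop_msm("msmtrial_domain_error", "reference_edss must be a valid EDSS step")
  }
  if (kind == "worsening") {
    ifelse(reference_edss == 0, 1.5, ifelse(reference_edss > 5.5, 0.5, 1.0))
  } else {
    ifelse(reference_edss <= 1.5, 1.5, ifelse(reference_edss > 6, 0.5, 1.0))
  }
}

.step_w <- function(ref) if (ref == 0) 1.5 else if (ref > 5.5) 0.5 else 1.0
.step_i <- function(ref) if (ref <= 1.5) 1.5 else if (ref > 6) 0.5 else 1.0

# Core detector on numeric day/value vectors. Returns a matrix with columns
# kind (1 = worsening, 2 = improvement), onset_day, reference, onset_value,
# confirmation_day. A candidate onset is the first score changing from the
# current reference by the required step; it is confirmed when a score >=365
# days later exists and every recorded score up to and including the first
# such score holds the same threshold. Under the roving policy the reference
# resets to the onset value after each confirmed event.
detect_core <- function(d, v, roving = TRUE) {
  n <- length(d)
  out <- vector("list", 0L)
  if (n >= 2) {
    ref <- v[1]
    for (i in 2:n) {
      vi <- v[i]
      kind <- 0L
      if (vi >= ref + .step_w(ref)) kind <- 1L
      else if (vi <= ref - .step_i(ref)) kind <- 2L
      if (kind == 0L) next
      j <- i + 1L
      lim <- d[i] + CONFIRM_DAYS
      while (j <= n && d[j] < lim) j <- j + 1L
      if (j > n) next                        # no score >=365 days after onset
      seg <- v[(i + 1L):j]
      ok <- if (kind == 1L) all(seg >= ref + .step_w(ref))
            else all(seg <= ref - .step_i(ref))
      if (!ok) next
      out[[length(out) + 1L]] <- c(kind, d[i], ref, vi, d[j])
      if (roving) ref <- vi
    }
  }
  if (!length(out)) {
    matrix(numeric(0), ncol = 5,
           dimnames = list(NULL, c("kind", "onset", "reference", "value", "confirmation")))
  } else {
    m <- do.call(rbind, out)
    colnames(m) <- c("kind", "onset", "reference", "value", "confirmation")
    m
  }
}

#' Detect 12-month-confirmed disability worsening and improvement
#'
#' Scans a cleaned EDSS trajectory chronologically. An event begins at the
#' first score that changes from the current reference score by at least the
#' [required_step()], and is confirmed when (a) a recorded score dated >=365
#' days after the onset exists and (b) every recorded score between the onset
#' and that confirming score (inclusive) also holds the threshold. Only
#' recorded scores participate; carried-forward values must never be passed
#' in. Under the default roving reference the reference resets to the onset
#' score after each confirmed event, so sequential events accumulate; under
#' `fixed_baseline` every event is measured against the first cleaned score.
#'
#' @param visits Data frame with columns `date` and `edss`: the cleaned,
#'   chronologically ordered trajectory (see [clean_edss()]).
#' @param reference_policy `"roving"` (default) or `"fixed_baseline"`.
#' @return Data frame with one row per confirmed event: `kind`,
#'   `onset_date`, `reference_edss`, `onset_edss`, `confirmation_date`.
#'   Fewer than two scores yield zero rows.
#' @export
detect_confirmed_events <- function(visits,
                                    reference_policy = c("roving", "fixed_baseline")) {
  reference_policy <- match.arg(reference_policy)
  stopifnot(all(c("date", "edss") %in% names(visits)))
  d <- as_day(visits$date)
  if (is.unsorted(d)) {
    stop_msm("msmtrial_domain_error", "visits must be chronologically ordered")
  }
  m <- detect_core(d, visits$edss, roving = reference_policy == "roving")
  is_date <- inherits(visits$date, "Date")
  back <- function(x) if (is_date) as.Date(x, origin = "1970-01-01") else x
  data.frame(
    kind = c("worsening", "improvement")[m[, "kind"]],
    onset_date = back(m[, "onset"]),
    reference_edss = m[, "reference"],
    onset_edss = m[, "value"],
    confirmation_date = back(m[, "confirmation"]),
    stringsAsFactors = FALSE
  )
}

#' Derive confirmed disability events for every patient in a registry
#'
#' Applies [clean_edss()] (using each patient's full relapse history) and
#' [detect_confirmed_events()] per patient.
#'
#' @param registry An `ms_registry`, typically after [filter_eligible()].
#' @inheritParams detect_confirmed_events
#' @return Data frame of confirmed events with a leading `patient_id` column.
#' @export
derive_events <- function(registry, reference_policy = c("roving", "fixed_baseline")) {
  stopifnot(inherits(registry, "ms_registry"))
  reference_policy <- match.arg(reference_policy)
  roving <- reference_policy == "roving"
  ids <- registry$patients$patient_id
  vis <- registry$visits
  vsp <- split(seq_len(nrow(vis)), factor(vis$patient_id, levels = ids))
  rel <- registry$relapses
  rsp <- split(as_day(rel$date), factor(rel$patient_id, levels = ids))
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- vsp[[i]]
    if (length(rows) < 2) next
    vd <- as_day(vis$date[rows]); vv <- vis$edss[rows]
    keep <- clean_edss_keep(vd, rsp[[i]])
    m <- detect_core(vd[keep], vv[keep], roving = roving)
    if (nrow(m)) res[[i]] <- cbind(i = i, m)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(patient_id = character(), kind = character(),
                      onset_date = as.Date(character()), reference_edss = numeric(),
                      onset_edss = numeric(), confirmation_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, res)
  data.frame(
    patient_id = ids[m[, "i"]],
    kind = c("worsening", "improvement")[m[, "kind"]],
    onset_date = as.Date(m[, "onset"], origin = "1970-01-01"),
    reference_edss = m[, "reference"],
    onset_edss = m[, "value"],
    confirmation_date = as.Date(m[, "confirmation"], origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
}

#' Annualized relapse rate over a window
#'
#' Counts relapse onsets in the half-open window `[window_start,
#' window_end)` and scales to events per 365-day year.
#'
#' @param relapse_dates Vector of relapse onset dates.
#' @param window_start,window_end Window bounds; `window_end` must be after
#'   `window_start`.
#' @return Events per year.
#' @export
annualized_relapse_rate <- function(relapse_dates, window_start, window_end) {
  len <- as_day(window_end) - as_day(window_start)
  if (is.na(len) || len <= 0) {
    stop_msm("msmtrial_domain_error", "window_end must be after window_start")
  }
  d <- as_day(relapse_dates)
  sum(d >= as_day(window_start) & d < as_day(window_end)) * DAYS_PER_YEAR / len
}
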