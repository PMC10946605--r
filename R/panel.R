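# Conversion of eligible patient records into 6-month (183-day) panel bins
# with treatment state, time-dependent covariates, and per-bin outcomes,
# under the three target-trial emulation designs:
#   A - baseline at the first EDSS visit; untreated -> treated transitions
#       allowed; follow-up censored at the first treatment discontinuation.
#   B - baseline at the MS onset date; free switching, no rebaselining.
#   C - baseline at the first EDSS visit; the bin clock restarts at every
#       change of treatment state (one at-risk segment per treated/untreated
#       spell).

#' Classify a bin's treatment status
#'
#' A bin is "treated" when the union of treatment-episode overlaps with the
#' bin totals at least 15 days; otherwise untreated. Open episodes (missing
#' stop date) are treated as ongoing.
#'
#' @param bin_start,bin_end Bin interval (half-open `[start, end)`), dates or
#'   day numbers.
#' @param episodes Data frame with `start_date` and `stop_date` columns
#'   (non-overlapping episodes; `stop_date` may be `NA`).
#' @return `1L` if treated, else `0L`.
#' @export
classify_treatment_status <- function(bin_start, bin_end, episodes) {
  s <- as_day(episodes$start_date)
  e <- as_day(episodes$stop_date); e[is.na(e)] <- Inf
  cov <- sum(pmax(0, pmin(e, as_day(bin_end)) - pmax(s, as_day(bin_start))))
  as.integer(cov >= MIN_TREATED_DAYS)
}

# vectorized over bins: total treated days per bin
treated_days_in_bins <- function(bstart, bend, es, ee) {
  out <- numeric(length(bstart))
  for (j in seq_along(es)) {
    out <- out + pmax(0, pmin(ee[j], bend) - pmax(es[j], bstart))
  }
  out
}

# merge episodes separated by <= EPISODE_MERGE_GAP days into treated periods
merge_periods <- function(es, ee) {
  if (!length(es)) return(list(start = numeric(0), stop = numeric(0)))
  ps <- es[1]; pe <- ee[1]; starts <- numeric(0); stops <- numeric(0)
  if (length(es) > 1) {
    for (j in 2:length(es)) {
      if (es[j] - pe <= EPISODE_MERGE_GAP) {
        pe <- max(pe, ee[j])
      } else {
        starts <- c(starts, ps); stops <- c(stops, pe)
        ps <- es[j]; pe <- ee[j]
      }
    }
  }
  list(start = c(starts, ps), stop = c(stops, pe))
}

#' Carry the last recorded EDSS score into bins without a record
#'
#' Each bin's `edss` becomes the last recorded (cleaned) score on or before
#' the bin end; bins without an in-bin record are flagged `edss_carried`.
#' Carried values are covariates only and must never feed confirmed-event
#' detection.
#'
#' @param bins Data frame with `start_date` and `end_date` columns.
#' @param recorded_scores Data frame with `date` and `edss`: the cleaned,
#'   recorded scores.
#' @return `bins` with `edss` and `edss_carried` columns added.
#' @export
carry_forward_edss <- function(bins, recorded_scores) {
  cd <- as_day(recorded_scores$date); cv <- recorded_scores$edss
  bs <- as_day(bins$start_date); be <- as_day(bins$end_date)
  idx <- findInterval(be - 0.5, cd)
  bins$edss <- ifelse(idx > 0, cv[pmax(idx, 1L)], NA_real_)
  inbin <- findInterval(be - 0.5, cd) > findInterval(bs - 0.5, cd)
  bins$edss_carried <- !inbin
  bins
}

panel_cols_chr <- c("patient_id", "course", "mri_activity_12m", "censor_reason", "sex")
panel_cols_num <- c("segment", "bin_index", "start_day", "end_day", "seg_start_day",
                    "treated", "prev_treated", "edss", "edss_carried", "edss_prev",
                    "pre_edss", "age", "ms_duration", "pregnancy", "relapses_in_bin",
                    "relapse_outcome", "arr_prior_12m", "arr_prior_24m",
                    "prior_treated_fraction", "worsening_event", "improvement_event",
                    "censored", "ms_duration_at_first_visit", "birth_year", "onset_year")

#' Build the 6-month panel for a cohort
#'
#' Converts each patient's record into a sequence of 183-day bins under the
#' chosen emulation design, attaching treatment state (>=15 treated days),
#' carried-forward cleaned EDSS, time-dependent covariates computed at bin
#' start (age, MS duration, annualized relapse rates over the prior 12/24
#' months, fraction of prior bins treated, MRI activity within the past 365
#' days, pregnancy overlap, phenotype), per-bin relapse counts/indicator,
#' and confirmed-event onset flags. The final partial bin is kept only when
#' at least 15 days long.
#'
#' @param registry An eligibility-filtered `ms_registry`
#'   (see [filter_eligible()]).
#' @param design `"A"`, `"B"`, or `"C"`.
#' @param events Confirmed events from [derive_events()]; derived on the fly
#'   when `NULL`.
#' @param reference_policy Passed to [derive_events()] when `events` is `NULL`.
#' @return A data frame of class `ms_panel`, one row per patient-bin, with
#'   attributes `design` and `cohort_kind`. `start_day`/`end_day` are days
#'   since the design baseline (segment-local origin under design C is given
#'   by `seg_start_day`).
#' @export
build_panel <- function(registry, design = c("A", "B", "C"), events = NULL,
                        reference_policy = c("roving", "fixed_baseline")) {
  stopifnot(inherits(registry, "ms_registry"))
  design <- match.arg(design)
  if (is.null(events)) events <- derive_events(registry, match.arg(reference_policy))
  pat <- registry$patients
  ids <- pat$patient_id
  n <- length(ids)
  fids <- factor(ids, levels = ids)
  vis <- registry$visits
  vsp <- split(seq_len(nrow(vis)), factor(vis$patient_id, levels = ids))
  rsp <- split(as_day(registry$relapses$date),
               factor(registry$relapses$patient_id, levels = ids))
  tsp <- split(registry$treatments[c("start_date", "stop_date")],
               factor(registry$treatments$patient_id, levels = ids))
  msp <- split(registry$mri[c("date", "activity")],
               factor(registry$mri$patient_id, levels = ids))
  psp <- split(registry$pregnancies[c("start_date", "end_date")],
               factor(registry$pregnancies$patient_id, levels = ids))
  csp <- split(registry$courses[c("phenotype", "start_date")],
               factor(registry$courses$patient_id, levels = ids))
  esp <- split(events, factor(events$patient_id, levels = ids))

  birth <- as_day(pat$birth_date); onset <- as_day(pat$ms_onset_date)
  censor <- if ("censor_date" %in% names(pat)) as_day(pat$censor_date) else
    rep(NA_real_, n)

  res <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- vsp[[i]]
    if (length(rows) < 1) next
    vd <- as_day(vis$date[rows]); vv <- vis$edss[rows]
    rel <- rsp[[i]]
    keep <- clean_edss_keep(vd, rel)
    cd <- vd[keep]; cvals <- vv[keep]
    if (!length(cd)) next
    fv <- vd[1]; lv <- vd[length(vd)]
    t0 <- if (design == "B") onset[i] else fv
    ep <- tsp[[i]]
    es <- as_day(ep$start_date); ee <- as_day(ep$stop_date); ee[is.na(ee)] <- Inf
    spms_c <- if (is.na(censor[i])) Inf else censor[i]
    per <- merge_periods(es, ee)
    disc <- Inf
    if (design == "A") {
      fin <- per$stop[is.finite(per$stop) & per$stop >= fv]
      if (length(fin)) disc <- min(fin)
    }
    end <- min(lv, spms_c, disc)
    if (end - t0 < MIN_BIN_DAYS) next
    reason <- if (end == disc) "treatment_discontinuation" else
      if (end == spms_c) "spms_conversion" else NA_character_

    if (design == "C") {
      cuts <- sort(unique(c(t0, end,
                            per$start[per$start > t0 & per$start < end],
                            per$stop[is.finite(per$stop) & per$stop > t0 & per$stop < end])))
      seg_s <- cuts[-length(cuts)]; seg_e <- cuts[-1]
      ok <- seg_e - seg_s >= MIN_BIN_DAYS
      seg_s <- seg_s[ok]; seg_e <- seg_e[ok]
    } else {
      seg_s <- t0; seg_e <- end
    }
    if (!length(seg_s)) next

    bstart <- numeric(0); bend <- numeric(0); seg_id <- integer(0)
    bin_idx <- integer(0); seg0 <- numeric(0)
    for (s in seq_along(seg_s)) {
      st <- seq(seg_s[s], seg_e[s] - 1, by = BIN_DAYS)
      en <- pmin(st + BIN_DAYS, seg_e[s])
      okb <- en - st >= MIN_BIN_DAYS
      st <- st[okb]; en <- en[okb]
      if (!length(st)) next
      bstart <- c(bstart, st); bend <- c(bend, en)
      seg_id <- c(seg_id, rep.int(s, length(st)))
      bin_idx <- c(bin_idx, seq_along(st) - 1L)
      seg0 <- c(seg0, rep.int(seg_s[s], length(st)))
    }
    nb <- length(bstart)
    if (!nb) next

    treated <- as.integer(treated_days_in_bins(bstart, bend, es, ee) >= MIN_TREATED_DAYS)
    if (design == "A" && any(diff(treated) < 0)) {
      # safety: enforce the one-way transition by truncating at the first
      # reversal (should be pre-empted by discontinuation censoring)
      cut <- which(diff(treated) < 0)[1]
      keep_b <- seq_len(cut)
      bstart <- bstart[keep_b]; bend <- bend[keep_b]; seg_id <- seg_id[keep_b]
      bin_idx <- bin_idx[keep_b]; seg0 <- seg0[keep_b]; treated <- treated[keep_b]
      nb <- cut; reason <- "treatment_discontinuation"
    }
    # the baseline treated state has no in-study previous state: prevalent
    # users at time 0 are weighted through the baseline covariates, not
    # conditioned away on their own pre-baseline exposure
    prev_treated <- c(0L, treated[-nb])[seq_len(nb)]
    ptf <- c(0, cumsum(treated)[-nb]) / pmax(seq_len(nb) - 1L, 1L)

    eidx <- findInterval(bend - 0.5, cd)
    edss <- ifelse(eidx > 0, cvals[pmax(eidx, 1L)], NA_real_)
    carried <- !(findInterval(bend - 0.5, cd) > findInterval(bstart - 0.5, cd))
    # pre-exposure EDSS for the treatment models: the last *recorded* score
    # on/before the bin start (clinicians act on the chart value whether or
    # not a relapse was recent); always defined from the baseline visit on
    pidx <- findInterval(bstart, vd)
    edss_prev <- ifelse(pidx > 0, vv[pmax(pidx, 1L)], NA_real_)
    pre_edss <- is.na(edss)
    edss[pre_edss] <- cvals[1]
    edss_prev[is.na(edss_prev)] <- vv[1]

    rel_in <- count_in(rel, bstart, bend)
    # day offset of the first in-bin relapse: the Cox models place the
    # bin's (binary) event at its actual date instead of the bin end
    ridx <- findInterval(bstart - 0.5, rel) + 1L
    rel_day <- ifelse(rel_in >= 1, rel[pmin(ridx, length(rel))] - bstart, NA_real_)
    arr12 <- count_in(rel, bstart - 365, bstart)
    arr24 <- count_in(rel, bstart - 730, bstart) / 2

    cc <- csp[[i]]
    cdy <- as_day(cc$start_date)
    cix <- findInterval(bstart, cdy)
    course <- cc$phenotype[pmax(cix, 1L)]

    mm <- msp[[i]]
    mri_act <- rep("not_assessed", nb)
    if (nrow(mm)) {
      md <- as_day(mm$date)
      mix <- findInterval(bstart, md)
      hasm <- mix > 0 & bstart - md[pmax(mix, 1L)] <= 365
      mri_act[hasm] <- mm$activity[mix[hasm]]
    }

    pg <- psp[[i]]
    preg <- rep(0L, nb)
    if (nrow(pg)) {
      ps <- as_day(pg$start_date); pe <- as_day(pg$end_date)
      for (j in seq_along(ps)) {
        preg[ps[j] < bend & pe[j] > bstart] <- 1L
      }
    }

    ev <- esp[[i]]
    wors <- rep(0L, nb); impr <- rep(0L, nb)
    wors_day <- rep(NA_real_, nb); impr_day <- rep(NA_real_, nb)
    if (nrow(ev)) {
      od <- as_day(ev$onset_date)
      bi <- findInterval(od, bstart)
      inb <- bi > 0 & od < bend[pmax(bi, 1L)]
      for (j in which(inb)) {
        if (ev$kind[j] == "worsening") {
          wors[bi[j]] <- 1L
          wors_day[bi[j]] <- od[j] - bstart[bi[j]]
        } else {
          impr[bi[j]] <- 1L
          impr_day[bi[j]] <- od[j] - bstart[bi[j]]
        }
      }
    }

    censored <- rep(0L, nb)
    if (!is.na(reason)) censored[nb] <- 1L

    res[[i]] <- list(
      i = rep.int(i, nb), segment = seg_id, bin_index = bin_idx,
      start_day = bstart - t0, end_day = bend - t0, seg_start_day = seg0 - t0,
      treated = treated, prev_treated = prev_treated,
      edss = edss, edss_carried = as.integer(carried), edss_prev = edss_prev,
      pre_edss = as.integer(pre_edss),
      age = (bstart - birth[i]) / 365, ms_duration = (bstart - onset[i]) / 365,
      course = course, pregnancy = preg,
      relapses_in_bin = rel_in, relapse_outcome = as.integer(rel_in >= 1),
      relapse_day = rel_day, worsening_day = wors_day, improvement_day = impr_day,
      arr_prior_12m = arr12, arr_prior_24m = arr24,
      prior_treated_fraction = ptf, mri_activity_12m = mri_act,
      worsening_event = wors, improvement_event = impr,
      censored = censored,
      censor_reason = c(rep(NA_character_, nb - 1L), reason),
      ms_duration_at_first_visit = rep.int((fv - onset[i]) / 365, nb),
      birth_year = rep.int(1970 + birth[i] / 365.25, nb),
      onset_year = rep.int(1970 + onset[i] / 365.25, nb),
      abs_start = bstart
    )
  }

  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    stop_msm("msmtrial_domain_error", "no panel rows could be built from this registry")
  }
  grab <- function(col) unlist(lapply(res, `[[`, col), use.names = FALSE)
  out <- data.frame(patient_id = ids[grab("i")], stringsAsFactors = FALSE)
  for (col in c("segment", "bin_index", "start_day", "end_day", "seg_start_day",
                "treated", "prev_treated", "edss", "edss_carried", "edss_prev",
                "pre_edss", "age", "ms_duration", "course", "pregnancy",
                "relapses_in_bin", "relapse_outcome", "relapse_day",
                "worsening_day", "improvement_day", "arr_prior_12m",
                "arr_prior_24m", "prior_treated_fraction", "mri_activity_12m",
                "worsening_event", "improvement_event", "censored",
                "censor_reason", "ms_duration_at_first_visit", "birth_year",
                "onset_year")) {
    out[[col]] <- grab(col)
  }
  out$sex <- pat$sex[grab("i")]
  out$start_date <- as.Date(grab("abs_start"), origin = "1970-01-01")
  out$end_date <- out$start_date + (out$end_day - out$start_day)
  class(out) <- c("ms_panel", "data.frame")
  attr(out, "design") <- design
  attr(out, "cohort_kind") <- attr(registry, "cohort_kind") %||% "full"
  out
}

#' @export
print.ms_panel <- function(x, ...) {
  cat(sprintf("<ms_panel design %s> %d bins, %d patients, %.0f%% treated bins, %d relapse bins, %d worsening / %d improvement onsets\n",
              attr(x, "design"), nrow(x), length(unique(x$patient_id)),
              100 * mean(x$treated), sum(x$relapse_outcome),
              sum(x$worsening_event), sum(x$improvement_event)))
  invisible(x)
}
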