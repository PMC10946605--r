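# Internal constants and small helpers shared across modules.
# All durations are handled in days: 1 year = 365 days, one panel bin = 183 days.

DAYS_PER_YEAR <- 365L
BIN_DAYS <- 183L
MIN_BIN_DAYS <- 15L          # shorter final bins are dropped (no near-zero risk intervals)
MIN_TREATED_DAYS <- 15L      # >=15 treated days in a bin classify it as "treated"
CONFIRM_DAYS <- 365L         # ">=12 months" confirmation window
RELAPSE_MIN_GAP <- 30L       # distinct relapses are >=30 days apart
POST_RELAPSE_EXCL <- 30L     # EDSS scores <30 days after a relapse are excluded
EPISODE_MERGE_GAP <- 30L     # treatment episodes <=30 days apart form one treated period

# Valid EDSS steps: 0, then half-steps from 1.0 to 10.0 (there is no 0.5).
EDSS_GRID <- c(0, seq(1, 10, by = 0.5))

PHENOTYPES <- c("CIS", "RRMS", "SPMS", "PPMS", "PRMS")
RELAPSING_PHENOTYPES <- c("CIS", "RRMS")

is_valid_edss <- function(x) {
  !is.na(x) & vapply(x, function(v) any(abs(v - EDSS_GRID) < 1e-8), logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msm <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "msmtrial_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

as_day <- function(x) as.numeric(x)  # Dates compare/subtract as numeric days

# count of sorted event days falling in [lo, hi)
count_in <- function(sorted_days, lo, hi) {
  findInterval(hi - 0.5, sorted_days) - findInterval(lo - 0.5, sorted_days)
}
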