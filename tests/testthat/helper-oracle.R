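# Independent brute-force checker for confirmed disability events: for each
# candidate onset it literally enumerates every later score as a potential
# confirming pair and verifies the sustained-threshold condition over all
# scores in between, instead of the production single-pass scan.

oracle_step <- function(ref, kind) {
  if (kind == "worsening") {
    if (ref == 0) 1.5 else if (ref > 5.5) 0.5 else 1.0
  } else {
    if (ref <= 1.5) 1.5 else if (ref > 6) 0.5 else 1.0
  }
}

brute_force_events <- function(days, values, roving = TRUE) {
  n <- length(days)
  res <- NULL
  if (n < 2) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("kind", "onset", "reference", "value",
                                          "confirmation"))))
  }
  ref <- values[1]
  for (i in 2:n) {
    hit <- 0L
    if (values[i] >= ref + oracle_step(ref, "worsening")) hit <- 1L
    if (values[i] <= ref - oracle_step(ref, "improvement")) hit <- 2L
    if (hit == 0L) next
    thr <- if (hit == 1L) ref + oracle_step(ref, "worsening") else
      ref - oracle_step(ref, "improvement")
    conf_days <- c()
    for (j in i:n) {
      if (days[j] - days[i] < 365) next
      seg <- values[i:j]
      sustained <- if (hit == 1L) all(seg >= thr) else all(seg <= thr)
      if (sustained) conf_days <- c(conf_days, days[j])
    }
    if (length(conf_days)) {
      res <- rbind(res, c(hit, days[i], ref, values[i], min(conf_days)))
      if (roving) ref <- values[i]
    }
  }
  if (is.null(res)) {
    res <- matrix(numeric(0), ncol = 5)
  }
  colnames(res) <- c("kind", "onset", "reference", "value", "confirmation")
  res
}
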