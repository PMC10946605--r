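# Small in-code registry fixtures.

d <- function(x) as.Date("2010-01-01") + x

# one-call builder: each argument is a data.frame or NULL
make_registry <- function(patients, courses = NULL, visits = NULL,
                          relapses = NULL, treatments = NULL, mri = NULL,
                          pregnancies = NULL, ...) {
  empty <- function(cols, dates) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    for (dc in dates) df[[dc]] <- as.Date(character(0))
    df
  }
  ms_registry(
    patients = patients,
    courses = courses %||% data.frame(
      patient_id = patients$patient_id, phenotype = "RRMS",
      start_date = patients$ms_onset_date, stringsAsFactors = FALSE),
    visits = visits %||% empty(c("patient_id", "date", "edss"), "date"),
    relapses = relapses %||% empty(c("patient_id", "date"), "date"),
    treatments = treatments %||% empty(
      c("patient_id", "dmt_name", "start_date", "stop_date"),
      c("start_date", "stop_date")),
    mri = mri %||% empty(c("patient_id", "date", "activity"), "date"),
    pregnancies = pregnancies,
    ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a single patient with a regular visit schedule
one_patient <- function(id = "P1", edss = c(2, 2, 2, 2, 2, 2),
                        visit_days = seq(0, by = 183, length.out = length(edss)),
                        relapse_days = numeric(0),
                        trt_start = NULL, trt_stop = NULL,
                        phenotype = "RRMS", sex = "female") {
  patients <- data.frame(patient_id = id, sex = sex, birth_date = d(-30 * 365),
                         ms_onset_date = d(-730), stringsAsFactors = FALSE)
  courses <- data.frame(patient_id = id, phenotype = phenotype,
                        start_date = d(-730), stringsAsFactors = FALSE)
  visits <- data.frame(patient_id = id, date = d(visit_days), edss = edss,
                       stringsAsFactors = FALSE)
  relapses <- if (length(relapse_days)) {
    data.frame(patient_id = id, date = d(relapse_days), stringsAsFactors = FALSE)
  } else NULL
  treatments <- if (!is.null(trt_start)) {
    data.frame(patient_id = id, dmt_name = "DMT", start_date = d(trt_start),
               stop_date = if (is.null(trt_stop)) as.Date(NA) else d(trt_stop),
               stringsAsFactors = FALSE)
  } else NULL
  make_registry(patients, courses, visits, relapses, treatments)
}
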