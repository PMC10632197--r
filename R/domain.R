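# Domain types shared by the screening engine, statistics, simulator and I/O:
# timestamped observation events, patient records with a brain-death reference
# outcome, and the engine configuration.

# Observation kinds and their value domains. Values are stored canonically as
# character strings so one events table can hold every kind; numeric kinds are
# converted on demand.
.kind_domains <- list(
  RASS            = list(type = "integer", min = -5, max = 4),
  GCS             = list(type = "integer", min = 3, max = 15),
  PLR_LEFT        = list(type = "enum", levels = c("present", "absent", "not_assessable")),
  PLR_RIGHT       = list(type = "enum", levels = c("present", "absent", "not_assessable")),
  VENT_CONTROLLED = list(type = "boolean"),
  SPONT_BREATHING = list(type = "boolean"),
  ICP             = list(type = "numeric", min = 0, max = Inf),
  CPP             = list(type = "numeric", min = 0, max = Inf),
  SODIUM          = list(type = "numeric", min = 0, max = Inf, exclusive_min = TRUE),
  CPR             = list(type = "boolean")
)

#' Observation kinds understood by the screening engine
#'
#' @return Character vector of the recognised observation kinds: sedation
#'   score (RASS), coma score (GCS), per-eye pupillary light reflex, controlled
#'   ventilation and spontaneous-breathing status, intracranial and cerebral
#'   perfusion pressure (mmHg), serum sodium (mmol/L), and cardiopulmonary
#'   resuscitation events.
#' @export
observation_kinds <- function() names(.kind_domains)

# Canonical character encoding for a value of a given kind. Returns NA_character_
# for values that do not belong to the kind's domain.
encode_value <- function(kind, value) {
  dom <- .kind_domains[[kind]]
  if (is.null(dom)) stop("unknown observation kind: ", kind)
  v <- value
  switch(dom$type,
    integer = {
      n <- suppressWarnings(as.numeric(v))
      ifelse(!is.na(n) & n == round(n) & n >= dom$min & n <= dom$max,
             as.character(as.integer(round(n))), NA_character_)
    },
    numeric = {
      n <- suppressWarnings(as.numeric(v))
      lo_ok <- if (isTRUE(dom$exclusive_min)) n > dom$min else n >= dom$min
      ifelse(!is.na(n) & lo_ok & n <= dom$max, format(n, digits = 10), NA_character_)
    },
    enum = ifelse(as.character(v) %in% dom$levels, as.character(v), NA_character_),
    boolean = {
      ch <- tolower(as.character(v))
      ifelse(ch %in% c("true", "1"), "true",
             ifelse(ch %in% c("false", "0"), "false", NA_character_))
    }
  )
}

value_ok <- function(kind, value) !is.na(encode_value(kind, value))

#' Build a table of observation events
#'
#' Assembles timestamped clinical observations into the canonical events
#' `data.frame` used throughout the package, sorted by (patient_id, time,
#' kind). Values are stored as character strings in a kind-dependent
#' encoding; out-of-domain values are rejected.
#'
#' @param patient_id Character vector of patient identifiers.
#' @param time Timestamps (POSIXct or ISO-8601 strings, minute resolution).
#' @param kind Observation kind, see [observation_kinds()].
#' @param value Observed values (numeric, logical or character as fits the kind).
#' @return A `data.frame` with columns `patient_id`, `time`, `kind`, `value`.
#' @examples
#' observation_events("P1", "2020-02-01T06:00", "RASS", -5)
#' @export
observation_events <- function(patient_id = character(), time = character(),
                               kind = character(), value = character()) {
  df <- data.frame(patient_id = as.character(patient_id),
                   time = parse_time(time),
                   kind = as.character(kind),
                   value = rep(NA_character_, length(patient_id)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad_kind <- !df$kind %in% names(.kind_domains)
    if (any(bad_kind))
      stop("unknown observation kind(s): ", paste(unique(df$kind[bad_kind]), collapse = ", "))
    for (k in unique(df$kind)) {
      i <- df$kind == k
      df$value[i] <- encode_value(k, value[i])
    }
    if (anyNA(df$value)) {
      j <- which(is.na(df$value))[1]
      stop("value out of domain for kind ", df$kind[j], ": ", as.character(value[j]))
    }
    df <- df[order(df$patient_id, df$time, df$kind), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Reference outcome of a patient admission
#'
#' The study's reference standard reduced to an outcome label: whether brain
#' death was eventually confirmed by guideline-based determination, and when.
#'
#' @param brain_death_confirmed Logical.
#' @param determination_time Timestamp of the formal determination; required
#'   exactly when `brain_death_confirmed` is `TRUE`.
#' @param died_in_icu,organ_donation Logical descriptors.
#' @return An object of class `reference_outcome`.
#' @export
reference_outcome <- function(brain_death_confirmed = FALSE,
                              determination_time = NULL,
                              died_in_icu = FALSE,
                              organ_donation = FALSE) {
  out <- list(
    brain_death_confirmed = isTRUE(brain_death_confirmed),
    determination_time = if (!is.null(determination_time)) parse_time(determination_time),
    died_in_icu = isTRUE(died_in_icu),
    organ_donation = isTRUE(organ_donation)
  )
  structure(out, class = "reference_outcome")
}

#' A patient admission with its event stream and reference outcome
#'
#' @param patient_id Identifier.
#' @param age Age in years (adults only, >= 18).
#' @param sex `"female"` or `"male"`.
#' @param admission_time,discharge_time Admission window timestamps.
#' @param events Events table from [observation_events()] (this patient only).
#' @param outcome A [reference_outcome()].
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, age, sex,
                           admission_time, discharge_time,
                           events = observation_events(),
                           outcome = reference_outcome()) {
  rec <- structure(list(
    patient_id = as.character(patient_id),
    age = as.numeric(age),
    sex = as.character(sex),
    admission_time = parse_time(admission_time),
    discharge_time = parse_time(discharge_time),
    events = events,
    outcome = outcome
  ), class = "patient_record")
  rec
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %s, age %.0f, %s to %s, %d events, brain death: %s>\n",
              x$patient_id, x$sex, x$age,
              format_time(x$admission_time), format_time(x$discharge_time),
              nrow(x$events),
              if (x$outcome$brain_death_confirmed) "confirmed" else "no"))
  invisible(x)
}

#' Validate a patient record against the domain invariants
#'
#' Checks type and range invariants (value domains per observation kind, the
#' admission window, adult age, outcome consistency) and reports every
#' violation found. The validator reports and never throws.
#'
#' @param record A [patient_record()].
#' @return Character vector of human-readable violations; empty when valid.
#' @examples
#' r <- patient_record("P1", 70, "female", "2020-02-01T00:00", "2020-02-05T00:00")
#' validate_record(r)  # character(0)
#' @export
validate_record <- function(record) {
  v <- character()
  say <- function(...) v[[length(v) + 1L]] <<- sprintf(...)
  if (!inherits(record, "patient_record")) return("not a patient_record")
  if (!is_scalar_number(record$age) || record$age < 18)
    say("age: must be a number >= 18 (adult cohort), got %s", format(record$age))
  if (!record$sex %in% c("female", "male"))
    say("sex: must be 'female' or 'male', got '%s'", record$sex)
  if (!record$admission_time < record$discharge_time)
    say("admission window: admission_time must precede discharge_time")
  ev <- record$events
  if (nrow(ev)) {
    if (!all(ev$patient_id == record$patient_id))
      say("events: patient_id mismatch with record")
    out_of_window <- ev$time < record$admission_time | ev$time > record$discharge_time
    for (i in which(out_of_window))
      say("events[%d]: time %s outside admission window", i, format_time(ev$time[i]))
    for (i in seq_len(nrow(ev))) {
      if (!ev$kind[i] %in% names(.kind_domains)) {
        say("events[%d]: unknown kind '%s'", i, ev$kind[i])
      } else if (!value_ok(ev$kind[i], ev$value[i])) {
        dom <- .kind_domains[[ev$kind[i]]]
        rule <- switch(dom$type,
          integer = sprintf("integer in [%g, %g]", dom$min, dom$max),
          numeric = sprintf("number %s %g", if (isTRUE(dom$exclusive_min)) ">" else ">=", dom$min),
          enum = paste("one of", paste(dom$levels, collapse = "/")),
          boolean = "true/false")
        say("events[%d]: %s value '%s' violates domain (%s)",
            i, ev$kind[i], ev$value[i], rule)
      }
    }
    if (is.unsorted(order(ev$patient_id, ev$time, ev$kind)))
      say("events: not sorted by (patient_id, time, kind)")
  }
  oc <- record$outcome
  if (oc$brain_death_confirmed && is.null(oc$determination_time))
    say("outcome: determination_time required when brain death is confirmed")
  if (!oc$brain_death_confirmed && !is.null(oc$determination_time))
    say("outcome: determination_time present without confirmed brain death")
  if (!is.null(oc$determination_time) &&
      (oc$determination_time < record$admission_time ||
       oc$determination_time > record$discharge_time))
    say("outcome: determination_time outside admission window")
  v
}

#' Screening engine configuration
#'
#' Parameters of the cyclic screening rule. Defaults encode a 12-hour cycle
#' anchored at 06:00 and 18:00 wall-clock time, coma defined as RASS -4/-5 or
#' GCS 3-6, and strict thresholds for the ancillary flags (intracranial
#' pressure above 50 mmHg, cerebral perfusion pressure below 20 mmHg, serum
#' sodium above 160 mmol/L or a swing of more than 10 mmol/L within 24 h).
#' A charted value counts at a tick only while fresh: within 12 h for the
#' neuro observations (one screening cycle) and 24 h for pressures, sodium
#' and ventilation status; resuscitation events are cumulative.
#'
#' @param cadence_hours Screening cycle length in hours.
#' @param tick_anchors Wall-clock anchor times (`"HH:MM"`) of the cycle.
#' @param staleness_hours Named vector of per-kind maximum observation age in
#'   hours; `Inf` means never expires.
#' @param icp_threshold,cpp_threshold Pressure thresholds, mmHg.
#' @param sodium_abs_threshold Absolute sodium threshold, mmol/L.
#' @param sodium_delta_threshold Sodium 24-h change threshold, mmol/L.
#' @param sodium_window_hours Trailing window for the sodium change, hours.
#' @param coma_rass RASS values counting as coma.
#' @param coma_gcs_max Largest GCS value counting as coma.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(cadence_hours = 12,
                          tick_anchors = c("06:00", "18:00"),
                          staleness_hours = c(RASS = 12, GCS = 12,
                                              PLR_LEFT = 12, PLR_RIGHT = 12,
                                              VENT_CONTROLLED = 24, SPONT_BREATHING = 24,
                                              ICP = 24, CPP = 24, SODIUM = 24,
                                              CPR = Inf),
                          icp_threshold = 50,
                          cpp_threshold = 20,
                          sodium_abs_threshold = 160,
                          sodium_delta_threshold = 10,
                          sodium_window_hours = 24,
                          coma_rass = c(-4, -5),
                          coma_gcs_max = 6) {
  stopifnot(is_scalar_number(cadence_hours), cadence_hours > 0,
            icp_threshold > 0, cpp_threshold > 0,
            sodium_abs_threshold > 0, sodium_delta_threshold > 0,
            sodium_window_hours > 0,
            coma_gcs_max >= 3, coma_gcs_max <= 15)
  if (!all(grepl("^[0-2][0-9]:[0-5][0-9]$", tick_anchors)))
    stop("tick_anchors must be 'HH:MM' strings")
  full <- formals(engine_config)$staleness_hours
  full <- eval(full)
  full[names(staleness_hours)] <- staleness_hours
  structure(list(
    cadence_hours = cadence_hours,
    tick_anchors = tick_anchors,
    staleness_hours = full,
    icp_threshold = icp_threshold,
    cpp_threshold = cpp_threshold,
    sodium_abs_threshold = sodium_abs_threshold,
    sodium_delta_threshold = sodium_delta_threshold,
    sodium_window_hours = sodium_window_hours,
    coma_rass = coma_rass,
    coma_gcs_max = coma_gcs_max
  ), class = "engine_config")
}
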