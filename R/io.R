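# File formats: JSONL event streams (one observation per line, versioned
# schema header), CSV patient/outcome tables, JSONL notification logs and the
# structured metrics JSON. Timestamps are ISO-8601 at minute resolution.

.events_schema <- "bdscreen/events-1"
.notifications_schema <- "bdscreen/notifications-1"

#' Write an event stream to JSONL
#'
#' One observation per line (`patient_id`, `time`, `kind`, `value`), preceded
#' by a versioned schema header line. Numeric kinds are written as JSON
#' numbers, boolean kinds as JSON booleans.
#'
#' @param events Events table from [observation_events()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(list(schema = .events_schema), auto_unbox = TRUE), con)
  if (nrow(events)) {
    typed <- .typed_values(events$kind, events$value)
    lines <- vapply(seq_len(nrow(events)), function(i) {
      jsonlite::toJSON(list(patient_id = events$patient_id[i],
                            time = format_time(events$time[i]),
                            kind = events$kind[i],
                            value = typed[[i]]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

.typed_values <- function(kind, value) {
  lapply(seq_along(kind), function(i) {
    dom <- .kind_domains[[kind[i]]]
    switch(dom$type,
           integer = as.integer(value[i]),
           numeric = as.numeric(value[i]),
           boolean = identical(value[i], "true"),
           value[i])
  })
}

#' Read an event stream from JSONL
#'
#' Counterpart of [write_events_jsonl()]. Malformed lines and out-of-domain
#' values are reported with their line number.
#'
#' @param path Input file.
#' @return Events table.
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty event file: ", path)
    return(observation_events())
  }
  start <- 1L
  first <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e)
    stop(path, ":1: malformed JSON: ", conditionMessage(e)))
  if (!is.null(first$schema)) start <- 2L
  if (start > length(lines)) {
    warning("empty event file (header only): ", path)
    return(observation_events())
  }
  rows <- lapply(seq(start, length(lines)), function(i) {
    o <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop(path, ":", i, ": malformed JSON: ", conditionMessage(e)))
    for (f in c("patient_id", "time", "kind", "value"))
      if (is.null(o[[f]])) stop(path, ":", i, ": missing field '", f, "'")
    o
  })
  df <- data.frame(patient_id = vapply(rows, function(o) as.character(o$patient_id), ""),
                   time = vapply(rows, function(o) as.character(o$time), ""),
                   kind = vapply(rows, function(o) as.character(o$kind), ""),
                   value = vapply(rows, function(o) as.character(o$value), ""),
                   line = seq(start, length(lines)),
                   stringsAsFactors = FALSE)
  .events_from_raw(df, path)
}

.events_from_raw <- function(df, path) {
  bad_kind <- !df$kind %in% names(.kind_domains)
  if (any(bad_kind)) {
    i <- which(bad_kind)[1]
    stop(path, ":", df$line[i], ": unknown observation kind '", df$kind[i], "'")
  }
  enc <- df$value
  for (k in unique(df$kind)) {
    sel <- df$kind == k
    enc[sel] <- encode_value(k, df$value[sel])
  }
  if (anyNA(enc)) {
    i <- which(is.na(enc))[1]
    dom <- .kind_domains[[df$kind[i]]]
    rule <- switch(dom$type,
                   integer = sprintf("integer in [%g, %g]", dom$min, dom$max),
                   numeric = sprintf("number %s %g",
                                     if (isTRUE(dom$exclusive_min)) ">" else ">=", dom$min),
                   enum = paste("one of", paste(dom$levels, collapse = "/")),
                   boolean = "true/false")
    stop(path, ":", df$line[i], ": ", df$kind[i], " value '", df$value[i],
         "' violates domain (", rule, ")")
  }
  observation_events(df$patient_id, df$time, df$kind, df$value)
}

#' Write / read an event stream as CSV
#'
#' Flat `patient_id,time,kind,value` table with the same validation as the
#' JSONL reader.
#'
#' @param events Events table.
#' @param path File path.
#' @return `path` invisibly (writer); events table (reader).
#' @export
write_events_csv <- function(events, path) {
  out <- events
  out$time <- format_time(out$time)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(df)) {
    warning("empty event file: ", path)
    return(observation_events())
  }
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  .events_from_raw(df, path)
}

#' Write / read the cohort patient table as CSV
#'
#' Columns: `patient_id`, `age`, `sex`, `admission_time`, `discharge_time`.
#'
#' @param records List of [patient_record()]s (writer).
#' @param path File path.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_patients_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id, age = r$age, sex = r$sex,
               admission_time = format_time(r$admission_time),
               discharge_time = format_time(r$discharge_time),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patients_csv
#' @export
read_patients_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the reference-outcome table as CSV
#'
#' Columns: `patient_id`, `brain_death` (0/1), optional `determination_time`,
#' and any covariate columns (e.g. `ventilated`, `analgosedation`).
#'
#' @param outcomes Outcomes data frame.
#' @param path File path.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_outcomes_csv <- function(outcomes, path) {
  out <- outcomes
  out$brain_death <- as.integer(as.logical(out$brain_death))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$brain_death <- as.logical(as.integer(df$brain_death))
  for (col in c("ventilated", "analgosedation", "died_in_icu", "organ_donation"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a simulated cohort to a directory
#'
#' Writes `events.jsonl` (or `.csv`), `patients.csv`, `outcomes.csv`,
#' `truth.csv` and a `metadata.json` recording the seed and generative
#' configuration.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"jsonl"` or `"csv"` for the event stream.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  events <- do.call(rbind, lapply(cohort$records, `[[`, "events"))
  if (is.null(events)) events <- observation_events()
  if (format == "jsonl") write_events_jsonl(events, file.path(dir, "events.jsonl"))
  else write_events_csv(events, file.path(dir, "events.csv"))
  write_patients_csv(cohort$records, file.path(dir, "patients.csv"))
  write_outcomes_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
  truth <- cohort$truth
  truth$first_designed_tick <- ifelse(is.na(truth$first_designed_tick), "",
                                      format_time(truth$first_designed_tick))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(schema = "bdscreen/cohort-1",
                            seed = cohort$seed,
                            n_patients = length(cohort$records)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a cohort from event, patient and outcome files
#'
#' Assembles validated [patient_record()]s from an event stream plus the
#' patient and outcome tables; records failing [validate_record()] are
#' rejected with their violations listed.
#'
#' @param events_path Event stream (JSONL or CSV).
#' @param patients_path Patient table CSV.
#' @param outcomes_path Outcomes CSV (optional; outcomes default to
#'   no-brain-death when absent).
#' @param format Event-stream format, inferred from the extension by default.
#' @return List of validated [patient_record()]s with the outcomes attached.
#' @export
read_cohort <- function(events_path, patients_path, outcomes_path = NULL,
                        format = NULL) {
  format <- format %||% if (grepl("\\.csv$", events_path)) "csv" else "jsonl"
  events <- if (format == "csv") read_events_csv(events_path)
            else read_events_jsonl(events_path)
  patients <- read_patients_csv(patients_path)
  outcomes <- if (!is.null(outcomes_path)) read_outcomes_csv(outcomes_path)
  ev_split <- split(events, events$patient_id)
  records <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    oc <- reference_outcome()
    if (!is.null(outcomes)) {
      j <- match(as.character(p$patient_id), outcomes$patient_id)
      if (!is.na(j)) {
        det <- outcomes$determination_time[j]
        oc <- reference_outcome(
          brain_death_confirmed = isTRUE(outcomes$brain_death[j]),
          determination_time = if (!is.na(det) && nzchar(det)) det,
          died_in_icu = isTRUE(outcomes$died_in_icu[j]),
          organ_donation = isTRUE(outcomes$organ_donation[j]))
      }
    }
    ev <- ev_split[[as.character(p$patient_id)]] %||% observation_events()
    rownames(ev) <- NULL
    patient_record(p$patient_id, p$age, p$sex,
                   p$admission_time, p$discharge_time,
                   events = ev, outcome = oc)
  })
  bad <- lapply(records, validate_record)
  nbad <- vapply(bad, length, integer(1))
  if (any(nbad > 0)) {
    i <- which(nbad > 0)[1]
    stop("invalid record for patient ", records[[i]]$patient_id, ":\n  ",
         paste(bad[[i]], collapse = "\n  "))
  }
  records
}

#' Write / read a notification log as JSONL
#'
#' One notification per line with a versioned schema header; timestamps
#' ISO-8601.
#'
#' @param log A `notification_log`.
#' @param path File path.
#' @return `path` invisibly (writer); `notification_log` (reader).
#' @export
write_notifications_jsonl <- function(log, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(list(schema = .notifications_schema),
                              auto_unbox = TRUE), con)
  if (nrow(log)) {
    lines <- vapply(seq_len(nrow(log)), function(i) {
      jsonlite::toJSON(list(
        patient_id = log$patient_id[i],
        tick_time = format_time(log$tick_time[i]),
        is_repeat = log$is_repeat[i],
        age = log$age[i], sex = log$sex[i],
        flags = list(vent_no_spont_breathing = log$vent_no_spont_breathing[i],
                     icp_above_50 = log$icp_above_50[i],
                     cpp_below_20 = log$cpp_below_20[i],
                     sodium_above_160 = log$sodium_above_160[i],
                     sodium_delta_gt_10 = log$sodium_delta_gt_10[i],
                     cpr_any = log$cpr_any[i])), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_notifications_jsonl
#' @export
read_notifications_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && !is.null(jsonlite::fromJSON(lines[1])$schema))
    lines <- lines[-1]
  if (!length(lines)) return(.empty_log())
  rows <- lapply(lines, jsonlite::fromJSON)
  log <- do.call(rbind, lapply(rows, function(o)
    data.frame(patient_id = o$patient_id, tick_time = parse_time(o$tick_time),
               is_repeat = o$is_repeat, age = o$age, sex = o$sex,
               vent_no_spont_breathing = o$flags$vent_no_spont_breathing,
               icp_above_50 = o$flags$icp_above_50,
               cpp_below_20 = o$flags$cpp_below_20,
               sodium_above_160 = o$flags$sodium_above_160,
               sodium_delta_gt_10 = o$flags$sodium_delta_gt_10,
               cpr_any = o$flags$cpr_any,
               stringsAsFactors = FALSE)))
  class(log) <- c("notification_log", "data.frame")
  log
}

#' Write an accuracy report as structured JSON
#'
#' Every metric carries its point estimate, bounds, interval method and the
#' numerator/denominator it was computed from, so downstream consumers can
#' re-derive the estimates; the confusion matrix and class sizes ride along.
#'
#' @param report An `accuracy_report` from [diagnostic_metrics()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  est <- function(e) list(point = e$point, lower = e$lower, upper = e$upper,
                          method = e$method, confidence = e$confidence,
                          numerator = e$x, denominator = e$n)
  jsonlite::write_json(list(
    schema = "bdscreen/metrics-1",
    matrix = list(tp = report$matrix$tp, fp = report$matrix$fp,
                  fn = report$matrix$fn, tn = report$matrix$tn),
    n1 = report$n1, n0 = report$n0, prevalence = report$prevalence,
    ci_method = report$ci_method, confidence = report$confidence,
    metrics = list(sensitivity = est(report$sensitivity),
                   specificity = est(report$specificity),
                   ppv = est(report$ppv),
                   npv = est(report$npv),
                   accuracy = est(report$accuracy))
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
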