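# The cyclic screening engine: evaluates the positivity rule (coma AND
# bilaterally absent pupillary light reflexes) at fixed wall-clock ticks over
# each patient's event stream and emits the notification log.

#' Most recent observation of a kind at a time point
#'
#' Returns the value of the most recent event of `kind` charted at or before
#' `t` and no older than `max_staleness_hours`; `NULL` when nothing fresh is
#' documented. Stale or missing observations never contribute to the rule.
#'
#' @param events Events table (one patient), sorted by time.
#' @param kind One of [observation_kinds()].
#' @param t Tick time.
#' @param max_staleness_hours Maximum age in hours (`Inf` = never expires).
#' @return Character value in canonical encoding, or `NULL`.
#' @export
latest_value <- function(events, kind, t, max_staleness_hours = 12) {
  if (!kind %in% names(.kind_domains))
    stop("unknown observation kind: ", kind, " (programming error)")
  e <- events[events$kind == kind, , drop = FALSE]
  if (!nrow(e)) return(NULL)
  t <- parse_time(t)
  age <- as.numeric(t) - as.numeric(e$time)
  ok <- age >= 0 & age <= hours(max_staleness_hours)
  if (!any(ok)) return(NULL)
  e$value[max(which(ok))]
}

.latest_num <- function(events, kind, t, stal) {
  v <- latest_value(events, kind, t, stal)
  if (is.null(v)) NULL else as.numeric(v)
}

#' Evaluate the coma criterion at a tick
#'
#' Coma is met when the freshest RASS is -4 or -5, or the freshest GCS is in
#' 3-6. Absent (undocumented or stale) scores never trigger.
#'
#' @param events Events table for one patient.
#' @param t Tick time.
#' @param config An [engine_config()].
#' @return List with `met` (logical) and `source` (`"RASS"`, `"GCS"`,
#'   `"both"` or `"none"`).
#' @export
evaluate_coma_criterion <- function(events, t, config = engine_config()) {
  rass <- .latest_num(events, "RASS", t, config$staleness_hours[["RASS"]])
  gcs <- .latest_num(events, "GCS", t, config$staleness_hours[["GCS"]])
  by_rass <- !is.null(rass) && rass %in% config$coma_rass
  by_gcs <- !is.null(gcs) && gcs <= config$coma_gcs_max
  list(met = by_rass || by_gcs,
       source = if (by_rass && by_gcs) "both"
                else if (by_rass) "RASS"
                else if (by_gcs) "GCS"
                else "none")
}

#' Evaluate the pupillary criterion at a tick
#'
#' Met only when both eyes have a fresh, explicitly documented *absent* light
#' reflex. A `not_assessable` or undocumented pupil on either side fails the
#' criterion: screening must not fire on missing data.
#'
#' @inheritParams evaluate_coma_criterion
#' @return Logical.
#' @export
evaluate_pupil_criterion <- function(events, t, config = engine_config()) {
  l <- latest_value(events, "PLR_LEFT", t, config$staleness_hours[["PLR_LEFT"]])
  r <- latest_value(events, "PLR_RIGHT", t, config$staleness_hours[["PLR_RIGHT"]])
  identical(l, "absent") && identical(r, "absent")
}

#' Ancillary clinical flags reported with a notification
#'
#' Computes the optional notification content from events at or before the
#' tick (no lookahead): controlled ventilation without spontaneous breathing,
#' intracranial pressure strictly above 50 mmHg, cerebral perfusion pressure
#' strictly below 20 mmHg, serum sodium strictly above 160 mmol/L, a sodium
#' swing (max minus min, needing at least two values) greater than 10 mmol/L
#' in the trailing 24 h, and any resuscitation at or before the tick.
#'
#' @inheritParams evaluate_coma_criterion
#' @return Named logical vector of the six flags.
#' @export
compute_optional_flags <- function(events, t, config = engine_config()) {
  t <- parse_time(t)
  st <- config$staleness_hours
  vent <- latest_value(events, "VENT_CONTROLLED", t, st[["VENT_CONTROLLED"]])
  spont <- latest_value(events, "SPONT_BREATHING", t, st[["SPONT_BREATHING"]])
  icp <- .latest_num(events, "ICP", t, st[["ICP"]])
  cpp <- .latest_num(events, "CPP", t, st[["CPP"]])
  na_now <- .latest_num(events, "SODIUM", t, st[["SODIUM"]])
  na_ev <- events[events$kind == "SODIUM", , drop = FALSE]
  in_win <- na_ev$time > t - hours(config$sodium_window_hours) & na_ev$time <= t
  na_win <- as.numeric(na_ev$value[in_win])
  cpr <- events[events$kind == "CPR", , drop = FALSE]
  c(
    vent_no_spont_breathing = identical(vent, "true") && identical(spont, "false"),
    icp_above_50 = !is.null(icp) && icp > config$icp_threshold,
    cpp_below_20 = !is.null(cpp) && cpp < config$cpp_threshold,
    sodium_above_160 = !is.null(na_now) && na_now > config$sodium_abs_threshold,
    sodium_delta_gt_10 = length(na_win) >= 2 &&
      (max(na_win) - min(na_win)) > config$sodium_delta_threshold,
    cpr_any = any(cpr$time <= t & cpr$value == "true")
  )
}

#' Evaluate the full screening rule at one tick
#'
#' @param record A validated [patient_record()].
#' @param t Tick time.
#' @param config An [engine_config()].
#' @return List of class `tick_result`: `patient_id`, `tick_time`,
#'   `coma_met`, `coma_source`, `plr_met`, `positive` (coma AND pupils), and
#'   the optional `flags`.
#' @export
evaluate_tick <- function(record, t, config = engine_config()) {
  t <- parse_time(t)
  coma <- evaluate_coma_criterion(record$events, t, config)
  plr <- evaluate_pupil_criterion(record$events, t, config)
  structure(list(
    patient_id = record$patient_id,
    tick_time = t,
    coma_met = coma$met,
    coma_source = coma$source,
    plr_met = plr,
    positive = coma$met && plr,
    flags = compute_optional_flags(record$events, t, config)
  ), class = "tick_result")
}

#' Screening tick times for an admission window
#'
#' All configured wall-clock anchor times strictly after `from` and at or
#' before `to`.
#'
#' @param from,to Window bounds (admission; discharge or determination).
#' @param config An [engine_config()].
#' @return POSIXct vector, sorted.
#' @export
tick_schedule <- function(from, to, config = engine_config()) {
  from <- parse_time(from); to <- parse_time(to)
  if (to < from) return(from[0])
  days <- seq(as.Date(from, tz = .tz) - 1, as.Date(to, tz = .tz) + 1, by = "day")
  anchor_sec <- vapply(strsplit(config$tick_anchors, ":"), function(p)
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60, numeric(1))
  ticks <- as.POSIXct(outer(as.numeric(as.POSIXct(as.character(days), tz = .tz)),
                            anchor_sec, `+`),
                      origin = "1970-01-01", tz = .tz)
  ticks <- sort(ticks[ticks > from & ticks <= to])
  ticks
}

# Vectorised latest-value lookup used by the screening loop: for sorted event
# times `et` (numeric seconds) return, per tick, the index of the freshest
# event within `stal` hours, or NA.
.latest_idx <- function(et, ticks_num, stal) {
  if (!length(et)) return(rep(NA_integer_, length(ticks_num)))
  idx <- findInterval(ticks_num, et)
  age_ok <- idx >= 1L & (ticks_num - et[pmax(idx, 1L)]) <= hours(stal)
  ifelse(age_ok, idx, NA_integer_)
}

# Screen one patient; returns a data.frame of positive ticks with flags.
.screen_one <- function(record, config) {
  end <- record$discharge_time
  oc <- record$outcome
  if (oc$brain_death_confirmed && !is.null(oc$determination_time))
    end <- min(end, oc$determination_time)
  ticks <- tick_schedule(record$admission_time, end, config)
  if (!length(ticks)) return(NULL)
  tn <- as.numeric(ticks)
  ev <- record$events
  st <- config$staleness_hours
  by_kind <- split(seq_len(nrow(ev)), ev$kind)
  look <- function(kind) {
    i <- by_kind[[kind]]
    if (is.null(i)) return(rep(NA_character_, length(tn)))
    idx <- .latest_idx(as.numeric(ev$time[i]), tn, st[[kind]])
    ev$value[i][idx]
  }
  rass <- suppressWarnings(as.numeric(look("RASS")))
  gcs <- suppressWarnings(as.numeric(look("GCS")))
  coma <- (!is.na(rass) & rass %in% config$coma_rass) |
          (!is.na(gcs) & gcs <= config$coma_gcs_max)
  plr <- !is.na(look("PLR_LEFT")) & look("PLR_LEFT") == "absent" &
         !is.na(look("PLR_RIGHT")) & look("PLR_RIGHT") == "absent"
  pos <- which(coma & plr)
  if (!length(pos)) return(NULL)
  flags <- t(vapply(ticks[pos],
                    function(t) compute_optional_flags(ev, t, config),
                    logical(6)))
  data.frame(patient_id = record$patient_id,
             tick_time = ticks[pos],
             is_repeat = seq_along(pos) > 1L,
             age = record$age,
             sex = record$sex,
             flags,
             stringsAsFactors = FALSE)
}

.empty_log <- function() {
  structure(data.frame(patient_id = character(), tick_time = parse_time(character()),
                       is_repeat = logical(), age = numeric(), sex = character(),
                       vent_no_spont_breathing = logical(), icp_above_50 = logical(),
                       cpp_below_20 = logical(), sodium_above_160 = logical(),
                       sodium_delta_gt_10 = logical(), cpr_any = logical(),
                       stringsAsFactors = FALSE),
            class = c("notification_log", "data.frame"))
}

#' Run the cyclic screening over a cohort
#'
#' Evaluates the positivity rule at every scheduled tick of every patient and
#' emits one notification per positive tick. Ticks run strictly after
#' admission and stop at discharge, or at brain-death determination when
#' confirmed, so post-mortem charting cannot generate alerts. The first
#' notification of a patient has `is_repeat = FALSE`; all later ones are
#' repeats. The log is deterministic and sorted by (tick_time, patient_id).
#'
#' @param records A list of validated [patient_record()]s (or a single one).
#' @param config An [engine_config()].
#' @return A `notification_log` data frame: `patient_id`, `tick_time`,
#'   `is_repeat`, demographic snapshot (`age`, `sex`) and the six optional
#'   clinical flags.
#' @export
run_screening <- function(records, config = engine_config()) {
  if (inherits(records, "patient_record")) records <- list(records)
  ids <- vapply(records, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) {
      recs <- records[ids == d]
      win <- t(vapply(recs, function(r)
        as.numeric(c(r$admission_time, r$discharge_time)), numeric(2)))
      win <- win[order(win[, 1]), , drop = FALSE]
      if (any(win[-1, 1] < win[-nrow(win), 2]))
        stop("overlapping admission windows for patient_id ", d)
    }
    stop("duplicate patient_id in cohort: ", paste(dup, collapse = ", "),
         " (one record per patient admission)")
  }
  parts <- lapply(records, .screen_one, config = config)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(.empty_log())
  log <- do.call(rbind, parts)
  log <- log[order(log$tick_time, log$patient_id), , drop = FALSE]
  rownames(log) <- NULL
  class(log) <- c("notification_log", "data.frame")
  log
}

#' Summarise a notification log
#'
#' Per-patient and cohort-level bookkeeping of the notification stream:
#' first-notification times, counts, repeats, and inter-notification gaps.
#'
#' @param log A `notification_log` from [run_screening()].
#' @return An object of class `notification_summary` with elements
#'   `per_patient` (data frame: `patient_id`, `first_time`, `n_notifications`,
#'   `n_repeats`, `median_gap_hours`) and `cohort` (list: screen-positive
#'   patient count, total and repeat notification counts, and
#'   median/IQR/mean/sd of per-patient counts and of gaps in hours).
#' @export
summarize_notifications <- function(log) {
  split_pt <- split(log, log$patient_id)
  per <- do.call(rbind, lapply(split_pt, function(d) {
    tt <- sort(d$tick_time)
    gaps <- if (length(tt) > 1) as.numeric(diff(tt), units = "hours") else numeric()
    data.frame(patient_id = d$patient_id[1],
               first_time = tt[1],
               n_notifications = length(tt),
               n_repeats = length(tt) - 1L,
               median_gap_hours = if (length(gaps)) stats::median(gaps) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  all_gaps <- unlist(lapply(split_pt, function(d) {
    tt <- sort(d$tick_time)
    if (length(tt) > 1) as.numeric(diff(tt), units = "hours") else numeric()
  }), use.names = FALSE)
  five <- function(x) {
    if (!length(x)) return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                                mean = NA_real_, sd = NA_real_))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3], mean = mean(x), sd = stats::sd(x))
  }
  if (is.null(per)) {
    per <- data.frame(patient_id = character(), first_time = parse_time(character()),
                      n_notifications = integer(), n_repeats = integer(),
                      median_gap_hours = numeric(), stringsAsFactors = FALSE)
  } else {
    per <- per[order(per$first_time, per$patient_id), , drop = FALSE]
    rownames(per) <- NULL
  }
  structure(list(
    per_patient = per,
    cohort = list(
      n_screen_positive = nrow(per),
      n_notifications = nrow(log),
      n_repeats = sum(log$is_repeat),
      n_repeat_detected = sum(per$n_notifications > 1),
      notifications_per_patient = five(per$n_notifications),
      gap_hours = five(all_gaps)
    )
  ), class = "notification_summary")
}

#' @export
print.notification_summary <- function(x, ...) {
  co <- x$cohort
  cat(sprintf("Screening summary: %d screen-positive patients, %d notifications (%d repeats)\n",
              co$n_screen_positive, co$n_notifications, co$n_repeats))
  np <- co$notifications_per_patient
  if (!is.na(np$median))
    cat(sprintf("  notifications/patient: median %.1f (IQR %.0f-%.0f), mean %.1f +/- %.1f\n",
                np$median, np$q1, np$q3, np$mean, np$sd))
  g <- co$gap_hours
  if (!is.na(g$median))
    cat(sprintf("  inter-notification gap: median %.1f h (IQR %.1f-%.1f), mean %.1f +/- %.1f\n",
                g$median, g$q1, g$q3, g$mean, g$sd))
  invisible(x)
}
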