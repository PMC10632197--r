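# Synthetic neurocritical-care cohort generator. Emulates the statistical
# structure the screening evaluation assumes -- low brain-death prevalence,
# sedation-driven transient false-positive screening patterns, sub-12-hour
# charting cadence -- so the engine and the accuracy statistics can be
# exercised end-to-end without patient data. Everything here is synthetic.

#' Simulation configuration
#'
#' Generative parameters of the synthetic cohort. Defaults encode the study
#' conditions of a 414-patient neurocritical-care cohort: ~1.9% brain-death
#' prevalence, a 46/406 rate of transient false-positive screening patterns
#' among non-brain-death patients (34/54 of screen-positives detected
#' repeatedly), age 70.8 +/- 14.8 years (>= 18), 45.9% female, ICU stay
#' 9.1 +/- 8.6 days (>= 1), a 3.6 +/- 3.2 day (>= 0.5) course from screening
#' onset to brain-death determination, 4-hourly observation charting, the
#' admission-diagnosis mix of such a cohort, and sedation/ventilation
#' covariate rates by designed class (89.1% sedation among false positives
#' vs 56.7% among true negatives; 49/54 of positives ventilated).
#'
#' @param n_patients Cohort size.
#' @param prevalence_bd Probability a patient progresses to brain death.
#' @param p_false_positive_pattern Probability a non-brain-death patient
#'   exhibits a transient screening-positive episode.
#' @param p_repeat_given_positive Probability a false-positive pattern spans
#'   more than one screening tick.
#' @param bd_delay_mean_days,bd_delay_sd_days,bd_delay_min_days Truncated
#'   normal model for the onset-to-determination delay (days).
#' @param los_mean_days,los_sd_days,los_min_days Truncated normal ICU length
#'   of stay (days).
#' @param age_mean,age_sd,age_min Truncated normal age (years).
#' @param p_female Probability of female sex.
#' @param charting_interval_hours Nominal observation charting interval
#'   (jittered +/- 1 h per charting round).
#' @param diagnosis_mix Named admission-diagnosis weights.
#' @param p_sedation_given_fp,p_sedation_given_tn,p_sedation_given_bd
#'   Analgosedation covariate rates by designed class.
#' @param p_vent_given_positive,p_vent_given_negative Controlled-ventilation
#'   rates for designed screen-positives vs the rest.
#' @param p_icp_flag,p_cpp_flag,p_sodium_abs_flag,p_sodium_delta_flag,p_cpr_flag
#'   Rates of the ancillary notification flags among designed positives.
#' @param p_icp_monitored Fraction of non-flagged patients with invasive
#'   pressure monitoring charted.
#' @param fn_pattern Enable the stress mode that plants short flickering
#'   episodes between ticks in brain-death patients (designed false
#'   negatives). Off by default.
#' @param p_fn_pattern Probability of the flicker pattern when enabled.
#' @param origin Calendar start of the admission window (admissions spread
#'   over one year).
#' @param seed Optional integer seed; recorded in outputs.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 414,
                              prevalence_bd = 0.019,
                              p_false_positive_pattern = 46 / 406,
                              p_repeat_given_positive = 34 / 54,
                              bd_delay_mean_days = 3.6,
                              bd_delay_sd_days = 3.2,
                              bd_delay_min_days = 0.5,
                              los_mean_days = 9.1,
                              los_sd_days = 8.6,
                              los_min_days = 1,
                              age_mean = 70.8,
                              age_sd = 14.8,
                              age_min = 18,
                              p_female = 0.459,
                              charting_interval_hours = 4,
                              diagnosis_mix = c(ischemic_stroke = 0.701,
                                                intracerebral_hemorrhage = 0.128,
                                                seizure = 0.082,
                                                meningoencephalitis = 0.031,
                                                other = 0.058),
                              p_sedation_given_fp = 0.891,
                              p_sedation_given_tn = 0.567,
                              p_sedation_given_bd = 7 / 8,
                              p_vent_given_positive = 49 / 54,
                              p_vent_given_negative = 125 / 360,
                              p_icp_flag = 6 / 54,
                              p_cpp_flag = 4 / 54,
                              p_sodium_abs_flag = 7 / 54,
                              p_sodium_delta_flag = 25 / 54,
                              p_cpr_flag = 6 / 54,
                              p_icp_monitored = 0.25,
                              fn_pattern = FALSE,
                              p_fn_pattern = 0.05,
                              origin = "2020-02-01",
                              seed = NULL) {
  cfg <- as.list(environment())
  probs <- cfg[grepl("^p_|^prevalence", names(cfg))]
  stopifnot(all(unlist(probs) >= 0), all(unlist(probs) <= 1),
            n_patients >= 0, n_patients == round(n_patients),
            charting_interval_hours > 0,
            abs(sum(diagnosis_mix) - 1) < 1e-6)
  structure(cfg, class = "simulation_config")
}

# Truncated-normal draws by rejection; vectorised.
rtrunc_norm <- function(n, mean, sd, min) {
  out <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out < min
    if (!any(bad)) return(out)
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, min)
}

# Build the charting stream for one patient as numeric-second vectors, then
# assemble one events frame. Episodes are [start, end] windows during which
# the neuro observations chart persistent coma with bilaterally absent
# pupils; baseline neuro charts inside an episode are dropped so the override
# is unambiguous.
.build_events <- function(pid, adm, dis, cfg, sedated, ventilated,
                          icp_monitored, episodes, flags, flag_window) {
  step <- hours(cfg$charting_interval_hours)
  grid <- seq(adm, dis, by = step)
  jit <- stats::runif(length(grid), -hours(1), hours(1))
  ct <- pmin(pmax(grid + jit, adm), dis)
  in_episode <- rep(FALSE, length(ct))
  for (ep in episodes) in_episode <- in_episode | (ct >= ep[1] & ct <= ep[2])
  base <- ct[!in_episode]
  nb <- length(base)
  t <- c(); k <- c(); v <- c()
  add <- function(time, kind, value) {
    t <<- c(t, time); k <<- c(k, rep(kind, length(time))); v <<- c(v, as.character(value))
  }
  # baseline neuro charting: sedated patients can be comatose by score, but
  # pupils always react, so the combined rule never fires at baseline
  if (nb) {
    add(base, "RASS", if (sedated) sample(c(-5, -4, -3, -2), nb, TRUE)
                      else sample(-1:1, nb, TRUE))
    add(base, "GCS", if (sedated) sample(3:8, nb, TRUE) else sample(9:15, nb, TRUE))
    add(base, "PLR_LEFT", rep("present", nb))
    add(base, "PLR_RIGHT", rep("present", nb))
  }
  # episode charting: persistent coma with bilaterally absent reflexes
  for (ep in episodes) {
    et <- unique(c(seq(ep[1], ep[2], by = step), ep[2]))
    add(et, "RASS", rep(-5, length(et)))
    add(et, "GCS", rep(3, length(et)))
    add(et, "PLR_LEFT", rep("absent", length(et)))
    add(et, "PLR_RIGHT", rep("absent", length(et)))
  }
  # ventilation status, charted every round
  add(ct, "VENT_CONTROLLED", rep(if (ventilated) "true" else "false", length(ct)))
  add(ct, "SPONT_BREATHING", rep(if (ventilated) "false" else "true", length(ct)))
  # pressures when monitored; flagged extremes only inside the flag window
  if (icp_monitored || flags[["icp"]] || flags[["cpp"]]) {
    pt <- ct
    in_fw <- !is.null(flag_window) & pt >= (flag_window[1] %||% Inf) & pt <= (flag_window[2] %||% -Inf)
    icp_v <- stats::runif(length(pt), 8, 20)
    cpp_v <- stats::runif(length(pt), 60, 90)
    if (flags[["icp"]]) icp_v[in_fw] <- stats::runif(sum(in_fw), 52, 75)
    if (flags[["cpp"]]) cpp_v[in_fw] <- stats::runif(sum(in_fw), 5, 18)
    add(pt, "ICP", round(icp_v, 1))
    add(pt, "CPP", round(cpp_v, 1))
  }
  # serum sodium roughly every second charting round
  na_t <- ct[seq(1, length(ct), by = 2)]
  na_v <- round(stats::runif(length(na_t), 135, 144), 1)
  if (!is.null(flag_window)) {
    if (flags[["sodium_abs"]]) {
      sel <- na_t >= flag_window[1] & na_t <= flag_window[2]
      na_v[sel] <- round(stats::runif(sum(sel), 161, 168), 1)
    }
    if (flags[["sodium_delta"]]) {
      # a >10 mmol/L swing within the 24 h before the first flagged tick
      add(flag_window[1] - hours(20), "SODIUM", round(stats::runif(1, 136, 139), 1))
      add(flag_window[1] - hours(2), "SODIUM", round(stats::runif(1, 151, 155), 1))
    }
  }
  add(na_t, "SODIUM", na_v)
  if (flags[["cpr"]]) add(adm, "CPR", "true")
  keep <- t >= adm & t <= dis
  tt <- round_minute(as.POSIXct(t[keep], origin = "1970-01-01", tz = .tz))
  observation_events(rep(pid, sum(keep)), tt, k[keep], v[keep])
}

.no_flags <- c(icp = FALSE, cpp = FALSE, sodium_abs = FALSE,
               sodium_delta = FALSE, cpr = FALSE)

#' Simulate one synthetic patient record
#'
#' Draws a designed class (brain death / transient false-positive pattern /
#' true negative, or a forced one) and synthesises a charting stream that
#' realises it: brain-death patients transition to persistent coma with
#' bilaterally absent pupils from a random onset until determination;
#' false-positive-pattern patients exhibit sedation-flagged transient
#' episodes covering one or more screening ticks; all other patients never
#' satisfy both rule criteria at once. Uses the current RNG state (seed the
#' stream via [simulate_cohort()] or `set.seed()`).
#'
#' @param config A [simulation_config()].
#' @param patient_id Identifier for the record.
#' @param force_outcome Optional: `"brain_death"`, `"false_positive"`,
#'   `"true_negative"` or `"fn_flicker"` (short sub-tick flicker, a designed
#'   false negative for stress testing).
#' @param econf The [engine_config()] whose tick grid the designed episodes
#'   target.
#' @return List with `record` (a [patient_record()]) and `truth` (one-row
#'   data frame: designed class, covariates, designed tick count and first
#'   designed tick).
#' @export
simulate_patient <- function(config = simulation_config(), patient_id = "P0001",
                             force_outcome = NULL, econf = engine_config()) {
  cfg <- config
  class_ <- force_outcome %||% {
    u <- stats::runif(1)
    if (u < cfg$prevalence_bd) "brain_death"
    else if (cfg$fn_pattern && u < cfg$prevalence_bd + cfg$p_fn_pattern) "fn_flicker"
    else if (stats::runif(1) < cfg$p_false_positive_pattern) "false_positive"
    else "true_negative"
  }
  age <- rtrunc_norm(1, cfg$age_mean, cfg$age_sd, cfg$age_min)
  sex <- if (stats::runif(1) < cfg$p_female) "female" else "male"
  diagnosis <- sample(names(cfg$diagnosis_mix), 1, prob = cfg$diagnosis_mix)
  origin_num <- as.numeric(parse_time(cfg$origin))
  adm <- round((origin_num + stats::runif(1, 0, 365 * 86400)) / 60) * 60
  is_pos_design <- class_ %in% c("brain_death", "false_positive")
  sedated <- stats::runif(1) < switch(class_,
    brain_death = cfg$p_sedation_given_bd,
    fn_flicker = cfg$p_sedation_given_bd,
    false_positive = cfg$p_sedation_given_fp,
    true_negative = cfg$p_sedation_given_tn)
  ventilated <- stats::runif(1) <
    if (is_pos_design) cfg$p_vent_given_positive else cfg$p_vent_given_negative
  flags <- .no_flags
  if (is_pos_design) {
    flags <- c(icp = stats::runif(1) < cfg$p_icp_flag,
               cpp = stats::runif(1) < cfg$p_cpp_flag,
               sodium_abs = stats::runif(1) < cfg$p_sodium_abs_flag,
               sodium_delta = stats::runif(1) < cfg$p_sodium_delta_flag,
               cpr = stats::runif(1) < cfg$p_cpr_flag)
  }
  icp_monitored <- stats::runif(1) < cfg$p_icp_monitored
  outcome <- reference_outcome()
  episodes <- list()
  flag_window <- NULL
  designed_ticks <- parse_time(character())

  anchors_in <- function(a, b) {  # anchor ticks in (a, b], numeric seconds
    tk <- tick_schedule(as.POSIXct(a, origin = "1970-01-01", tz = .tz),
                        as.POSIXct(b, origin = "1970-01-01", tz = .tz), econf)
    as.numeric(tk)
  }

  if (class_ == "brain_death") {
    for (attempt in 1:50) {
      delay <- rtrunc_norm(1, cfg$bd_delay_mean_days, cfg$bd_delay_sd_days,
                           cfg$bd_delay_min_days) * 86400
      los <- rtrunc_norm(1, cfg$los_mean_days, cfg$los_sd_days, cfg$los_min_days) * 86400
      if (los > delay + hours(18)) break
      if (attempt == 50) stop("could not draw a stay long enough for the designed course")
    }
    dis <- adm + round(los / 60) * 60
    onset <- adm + stats::runif(1, hours(2), los - delay - hours(2))
    onset <- round(onset / 60) * 60
    determination <- round((onset + delay) / 60) * 60
    episodes <- list(c(onset, determination))
    flag_window <- c(onset, determination)
    designed_num <- anchors_in(onset, determination)
    outcome <- reference_outcome(TRUE,
                                 as.POSIXct(determination, origin = "1970-01-01", tz = .tz),
                                 died_in_icu = TRUE,
                                 organ_donation = stats::runif(1) < 7 / 8)
  } else if (class_ == "false_positive") {
    los <- rtrunc_norm(1, cfg$los_mean_days, cfg$los_sd_days, cfg$los_min_days) * 86400
    dis <- adm + round(los / 60) * 60
    avail <- anchors_in(adm, dis)
    k <- if (stats::runif(1) < cfg$p_repeat_given_positive)
      2 + stats::rnbinom(1, size = 2, mu = 3.5) else 1
    k <- max(1L, min(k, length(avail)))
    start_i <- sample.int(length(avail) - k + 1L, 1)
    run <- avail[start_i:(start_i + k - 1L)]
    ep_start <- max(run[1] - stats::runif(1, hours(2), hours(6)), adm + 60)
    episodes <- list(c(ep_start, run[k]))
    flag_window <- c(ep_start, run[k])
    designed_num <- run
  } else if (class_ == "fn_flicker") {
    # brain death whose coma/pupil findings are only charted in a short
    # window between ticks: designed to be missed by 12-hourly screening
    los <- max(rtrunc_norm(1, cfg$los_mean_days, cfg$los_sd_days, cfg$los_min_days),
               2) * 86400
    dis <- adm + round(los / 60) * 60
    avail <- anchors_in(adm, dis - hours(13))
    a <- avail[sample.int(length(avail), 1)]
    episodes <- list(c(a + hours(3), a + hours(5)))
    designed_num <- numeric()
    outcome <- reference_outcome(TRUE,
                                 as.POSIXct(a + hours(5), origin = "1970-01-01", tz = .tz),
                                 died_in_icu = TRUE)
  } else {
    los <- rtrunc_norm(1, cfg$los_mean_days, cfg$los_sd_days, cfg$los_min_days) * 86400
    dis <- adm + round(los / 60) * 60
    designed_num <- numeric()
  }

  ev <- .build_events(patient_id, adm, dis, cfg, sedated, ventilated,
                      icp_monitored, episodes, flags, flag_window)
  rec <- patient_record(patient_id, age, sex,
                        as.POSIXct(adm, origin = "1970-01-01", tz = .tz),
                        as.POSIXct(dis, origin = "1970-01-01", tz = .tz),
                        events = ev, outcome = outcome)
  truth <- data.frame(
    patient_id = patient_id,
    designed_class = class_,
    diagnosis = diagnosis,
    analgosedation = sedated,
    ventilated = ventilated,
    n_designed_ticks = length(designed_num),
    first_designed_tick = if (length(designed_num))
      as.POSIXct(min(designed_num), origin = "1970-01-01", tz = .tz)
    else as.POSIXct(NA, tz = .tz),
    stringsAsFactors = FALSE
  )
  list(record = rec, truth = truth)
}

#' Simulate a synthetic cohort
#'
#' Draws `n_patients` independent records plus the outcomes table and a truth
#' log recording each patient's designed class, so engine output can be
#' scored against the design. Fully reproducible under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param econf The [engine_config()] whose tick grid designed episodes target.
#' @return List with `records` (list of [patient_record()]), `outcomes`
#'   (data frame: `patient_id`, `brain_death`, `determination_time`,
#'   `died_in_icu`, `organ_donation`, `ventilated`, `analgosedation`) and
#'   `truth` (design log from [simulate_patient()]).
#' @export
simulate_cohort <- function(config = simulation_config(), econf = engine_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  sims <- lapply(seq_len(n), function(i)
    simulate_patient(config, sprintf("P%05d", i), econf = econf))
  records <- lapply(sims, `[[`, "record")
  truth <- do.call(rbind, lapply(sims, `[[`, "truth")) %||%
    data.frame(patient_id = character(), designed_class = character(),
               diagnosis = character(), analgosedation = logical(),
               ventilated = logical(), n_designed_ticks = integer(),
               first_designed_tick = parse_time(character()),
               stringsAsFactors = FALSE)
  outcomes <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id,
               brain_death = r$outcome$brain_death_confirmed,
               determination_time = if (!is.null(r$outcome$determination_time))
                 format_time(r$outcome$determination_time) else NA_character_,
               died_in_icu = r$outcome$died_in_icu,
               organ_donation = r$outcome$organ_donation,
               stringsAsFactors = FALSE)
  })) %||% data.frame(patient_id = character(), brain_death = logical(),
                      determination_time = character(), died_in_icu = logical(),
                      organ_donation = logical(), stringsAsFactors = FALSE)
  if (nrow(outcomes)) {
    outcomes$ventilated <- truth$ventilated
    outcomes$analgosedation <- truth$analgosedation
  } else {
    outcomes$ventilated <- logical()
    outcomes$analgosedation <- logical()
  }
  list(records = records, outcomes = outcomes, truth = truth,
       seed = config$seed)
}

#' Score engine output against the simulation design
#'
#' Parameter-recovery harness: compares what the engine found on a simulated
#' cohort with what the generator designed. Designed persistent positives
#' (brain death and false-positive patterns) must all be detected; empirical
#' specificity, prevalence and the repeat fraction must lie within
#' Monte-Carlo tolerance (3 binomial sigma) of the configured generative
#' rates.
#'
#' @param log Engine `notification_log` for the simulated cohort.
#' @param truth Truth log from [simulate_cohort()].
#' @param config The [simulation_config()] used.
#' @return Object of class `calibration_check`: data frame `checks`
#'   (`check`, `observed`, `expected`, `tolerance`, `ok`) and overall `ok`.
#' @export
calibration_check <- function(log, truth, config = simulation_config()) {
  pos_ids <- unique(log$patient_id)
  counts <- table(log$patient_id)
  is_pos <- truth$patient_id %in% pos_ids
  designed_pos <- truth$designed_class %in% c("brain_death", "false_positive")
  bd <- truth$designed_class %in% c("brain_death", "fn_flicker")
  n_nonbd <- sum(!bd)
  rows <- list()
  add <- function(check, observed, expected, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, observed = observed, expected = expected,
      tolerance = tolerance, ok = abs(observed - expected) <= tolerance,
      stringsAsFactors = FALSE)
  }
  binom_tol <- function(p, n) if (n > 0) 3 * sqrt(p * (1 - p) / n) else Inf
  # every designed persistent positive yields at least one notification
  if (any(designed_pos))
    add("designed_positive_detected",
        mean(is_pos[designed_pos]), 1.0, 0)
  if (any(truth$designed_class == "brain_death"))
    add("engine_sensitivity_on_designed_bd",
        mean(is_pos[truth$designed_class == "brain_death"]), 1.0, 0)
  if (n_nonbd > 0) {
    p_fp <- config$p_false_positive_pattern
    add("specificity", mean(!is_pos[!bd]), 1 - p_fp, binom_tol(p_fp, n_nonbd))
  }
  if (nrow(truth) > 0)
    add("prevalence", mean(bd), config$prevalence_bd +
          if (config$fn_pattern) config$p_fn_pattern else 0,
        binom_tol(config$prevalence_bd, nrow(truth)))
  if (length(pos_ids) > 0) {
    rep_frac <- mean(counts[pos_ids] > 1)
    add("repeat_fraction_given_positive", rep_frac,
        config$p_repeat_given_positive,
        binom_tol(config$p_repeat_given_positive, length(pos_ids)))
  }
  checks <- do.call(rbind, rows)
  structure(list(checks = checks, ok = all(checks$ok)),
            class = "calibration_check")
}

#' @export
print.calibration_check <- function(x, ...) {
  cat(sprintf("Calibration check: %s\n", if (x$ok) "PASS" else "DEVIATION"))
  df <- x$checks
  df$observed <- signif(df$observed, 4)
  df$expected <- signif(df$expected, 4)
  df$tolerance <- signif(df$tolerance, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
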