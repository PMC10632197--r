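cfg <- engine_config()

test_that("latest_value respects recency and staleness", {
  t <- parse_iso(iso(2, "06:00"))
  e <- bind_events(ev("P1", iso(2, "05:00"), "RASS", -5),
                   ev("P1", iso(2, "04:00"), "RASS", 0))
  expect_identical(latest_value(e, "RASS", t, 12), "-5")        # most recent wins
  expect_identical(latest_value(e, "RASS", parse_iso(iso(2, "17:00")), 12), "-5")
  expect_null(latest_value(e, "RASS", parse_iso(iso(2, "17:01")), 12))  # expired
  # the 05:00 observation is in the future at 04:59; the 04:00 one stands
  expect_identical(latest_value(e, "RASS", parse_iso(iso(2, "04:59")), 12), "0")
  expect_null(latest_value(e, "RASS", parse_iso(iso(2, "03:59")), 12))  # all future
  expect_null(latest_value(e, "GCS", t, 12))
  expect_error(latest_value(e, "PULSE", t, 12), "unknown observation kind")
})

test_that("coma criterion fires on deep sedation score or low coma scale, not on absence", {
  t <- parse_iso(iso(2, "06:00"))
  at <- function(kinds, values) {
    e <- do.call(bind_events, Map(function(k, v) ev("P1", iso(2, "05:00"), k, v),
                                  kinds, values))
    evaluate_coma_criterion(e, t, cfg)
  }
  expect_identical(at("RASS", -5), list(met = TRUE, source = "RASS"))
  expect_identical(at("RASS", -4), list(met = TRUE, source = "RASS"))
  expect_identical(at(c("RASS", "GCS"), c(-3, 6)), list(met = TRUE, source = "GCS"))
  expect_identical(at(c("RASS", "GCS"), c(-5, 3)), list(met = TRUE, source = "both"))
  expect_identical(at(c("RASS", "GCS"), c(0, 7)), list(met = FALSE, source = "none"))
  expect_identical(at("GCS", 15), list(met = FALSE, source = "none"))
  # nothing documented never triggers
  expect_identical(evaluate_coma_criterion(observation_events(), t, cfg),
                   list(met = FALSE, source = "none"))
})

test_that("pupil criterion requires explicit bilateral absence", {
  t <- parse_iso(iso(2, "06:00"))
  plr <- function(left, right = NULL) {
    e <- ev("P1", iso(2, "05:00"), "PLR_LEFT", left)
    if (!is.null(right))
      e <- bind_events(e, ev("P1", iso(2, "05:00"), "PLR_RIGHT", right))
    evaluate_pupil_criterion(e, t, cfg)
  }
  expect_true(plr("absent", "absent"))
  expect_false(plr("absent", "present"))
  expect_false(plr("absent"))                       # one side undocumented
  expect_false(plr("absent", "not_assessable"))     # not assessable is not absence
  expect_false(evaluate_pupil_criterion(observation_events(), t, cfg))
})

test_that("optional flags follow the strict thresholds and trailing windows", {
  t <- parse_iso(iso(2, "06:00"))
  # sodium 150 twenty hours back, 162 one hour back: both sodium flags fire
  e <- bind_events(ev("P1", iso(1, "10:00"), "SODIUM", 150),
                   ev("P1", iso(2, "05:00"), "SODIUM", 162))
  f <- compute_optional_flags(e, t, cfg)
  expect_true(f[["sodium_above_160"]])
  expect_true(f[["sodium_delta_gt_10"]])

  # a single value in the window can never flag a change
  f1 <- compute_optional_flags(ev("P1", iso(2, "05:00"), "SODIUM", 162), t, cfg)
  expect_true(f1[["sodium_above_160"]])
  expect_false(f1[["sodium_delta_gt_10"]])

  # boundary strictness: exactly 50 mmHg ICP / 20 mmHg CPP / 160 mmol/L do not flag
  f2 <- compute_optional_flags(
    bind_events(ev("P1", iso(2, "05:00"), "ICP", 50),
                ev("P1", iso(2, "05:00"), "CPP", 20),
                ev("P1", iso(2, "05:00"), "SODIUM", 160)), t, cfg)
  expect_false(any(f2[c("icp_above_50", "cpp_below_20", "sodium_above_160")]))
  f3 <- compute_optional_flags(
    bind_events(ev("P1", iso(2, "05:00"), "ICP", 50.5),
                ev("P1", iso(2, "05:00"), "CPP", 19.5)), t, cfg)
  expect_true(f3[["icp_above_50"]])
  expect_true(f3[["cpp_below_20"]])

  # ventilation without spontaneous breathing needs both channels documented
  f4 <- compute_optional_flags(ev("P1", iso(2, "05:00"), "VENT_CONTROLLED", TRUE), t, cfg)
  expect_false(f4[["vent_no_spont_breathing"]])
  f5 <- compute_optional_flags(
    bind_events(ev("P1", iso(2, "05:00"), "VENT_CONTROLLED", TRUE),
                ev("P1", iso(2, "05:00"), "SPONT_BREATHING", FALSE)), t, cfg)
  expect_true(f5[["vent_no_spont_breathing"]])

  # resuscitation is cumulative: an admission-time event still flags days later
  f6 <- compute_optional_flags(ev("P1", iso(1, "10:00"), "CPR", TRUE), t, cfg)
  expect_true(f6[["cpr_any"]])
})

test_that("screening enumerates the 12-hour ticks of a persistent positive", {
  rec <- persistent_positive_record()
  log <- run_screening(list(rec))
  # rule met day 2 06:00 through day 4 06:00: five anchor ticks
  expect_equal(nrow(log), 5)
  expect_equal(format(log$tick_time, "%d %H:%M", tz = "UTC"),
               c("02 06:00", "02 18:00", "03 06:00", "03 18:00", "04 06:00"))
  expect_identical(log$is_repeat, c(FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("screening bookkeeping: negatives, single positives, repeats, ordering", {
  quiet <- make_record(normal_chart("P2", iso(1, "12:00"), iso(4, "00:00")), pid = "P2")
  expect_equal(nrow(run_screening(list(quiet))), 0)

  # rule met at exactly one tick
  once <- make_record(bind_events(
    normal_chart("P3", iso(1, "12:00"), iso(2, "02:00")),
    coma_chart("P3", iso(2, "05:00"), iso(2, "06:00")),
    normal_chart("P3", iso(2, "08:00"), iso(4, "00:00"))), pid = "P3")
  log1 <- run_screening(list(once))
  expect_equal(nrow(log1), 1)
  expect_false(log1$is_repeat)

  log <- run_screening(list(persistent_positive_record("P1"), once, quiet))
  expect_identical(log, log[order(log$tick_time, log$patient_id), ])
  # one non-repeat per screen-positive patient, and it is the earliest
  for (pid in unique(log$patient_id)) {
    d <- log[log$patient_id == pid, ]
    expect_equal(sum(!d$is_repeat), 1)
    expect_false(d$is_repeat[which.min(d$tick_time)])
  }
})

test_that("ticks stop at brain-death determination", {
  rec <- persistent_positive_record()
  rec$outcome <- reference_outcome(TRUE, iso(3, "09:00"), died_in_icu = TRUE)
  log <- run_screening(list(rec))
  expect_true(all(log$tick_time <= parse_iso(iso(3, "09:00"))))
  expect_equal(nrow(log), 3)  # day 2 06:00/18:00, day 3 06:00
})

test_that("duplicate and overlapping admissions are rejected", {
  a <- persistent_positive_record("PX")
  b <- make_record(normal_chart("PX", iso(3, "00:00"), iso(6, "00:00")),
                   pid = "PX", adm = iso(3, "00:00"), dis = iso(6, "00:00"))
  expect_error(run_screening(list(a, b)), "overlapping admission windows")
  c2 <- make_record(normal_chart("PX", iso(10, "00:00"), iso(12, "00:00")),
                    pid = "PX", adm = iso(10, "00:00"), dis = iso(12, "00:00"))
  expect_error(run_screening(list(a, c2)), "duplicate patient_id")
})

test_that("no lookahead: events after a tick never change its result", {
  rec <- persistent_positive_record()
  t <- parse_iso(iso(2, "18:00"))
  before <- evaluate_tick(rec, t, cfg)
  perturbed <- rec
  perturbed$events <- bind_events(
    rec$events,
    ev("P1", iso(2, "18:01"), "RASS", 0),
    ev("P1", iso(2, "18:01"), "PLR_LEFT", "present"),
    ev("P1", iso(3, "02:00"), "SODIUM", 170),
    ev("P1", iso(3, "02:00"), "CPR", TRUE))
  after <- evaluate_tick(perturbed, t, cfg)
  expect_identical(before, after)
})

test_that("rule is monotone in the coma criterion", {
  # deepening sedation at tick time can never turn a positive tick negative
  set.seed(202)
  for (i in 1:20) {
    times <- parse_iso(iso(1, "12:00")) + sort(sample(0:(72 * 60), 30)) * 60
    kinds <- sample(c("RASS", "GCS", "PLR_LEFT", "PLR_RIGHT"), 30, TRUE)
    vals <- vapply(kinds, function(k) switch(k,
      RASS = as.character(sample(-5:0, 1)),
      GCS = as.character(sample(3:15, 1)),
      sample(c("present", "absent", "not_assessable"), 1)), "")
    rec <- make_record(observation_events(rep("P1", 30), times, kinds, vals),
                       adm = iso(1, "10:00"), dis = iso(5, "00:00"))
    t <- parse_iso(iso(3, "06:00"))
    base <- evaluate_tick(rec, t, cfg)
    rec2 <- rec
    rec2$events <- bind_events(rec$events, ev("P1", iso(3, "06:00"), "RASS", -5))
    deeper <- evaluate_tick(rec2, t, cfg)
    if (base$positive) expect_true(deeper$positive)
    expect_true(deeper$coma_met)
  }
})

test_that("engine agrees with a brute-force per-tick oracle", {
  # the oracle walks the schedule calling the scalar rule primitives; the
  # engine uses its vectorised path -- the two must agree tick for tick
  set.seed(77)
  sims <- lapply(1:12, function(i)
    simulate_patient(simulation_config(), sprintf("S%02d", i),
                     force_outcome = sample(c("brain_death", "false_positive",
                                              "true_negative"), 1)))
  records <- lapply(sims, `[[`, "record")
  log <- run_screening(records, cfg)
  for (rec in records) {
    end <- rec$discharge_time
    if (rec$outcome$brain_death_confirmed)
      end <- min(end, rec$outcome$determination_time)
    ticks <- tick_schedule(rec$admission_time, end, cfg)
    oracle_pos <- ticks[vapply(ticks, function(t) {
      coma <- evaluate_coma_criterion(rec$events, t, cfg)
      coma$met && evaluate_pupil_criterion(rec$events, t, cfg)
    }, logical(1))]
    engine_pos <- log$tick_time[log$patient_id == rec$patient_id]
    expect_equal(as.numeric(engine_pos), as.numeric(oracle_pos),
                 info = rec$patient_id)
  }
})

test_that("notification summary arithmetic", {
  log <- run_screening(list(persistent_positive_record("P1")))
  s <- summarize_notifications(log)
  expect_equal(s$cohort$n_screen_positive, 1)
  expect_equal(s$cohort$n_notifications, 5)
  expect_equal(s$cohort$n_repeats, 4)
  expect_equal(s$per_patient$n_notifications, 5)
  expect_equal(s$per_patient$median_gap_hours, 12)
  expect_equal(s$cohort$gap_hours$mean, 12)

  empty <- summarize_notifications(run_screening(list(
    make_record(normal_chart("P9", iso(1, "12:00"), iso(3, "00:00")), pid = "P9"))))
  expect_equal(empty$cohort$n_screen_positive, 0)
  expect_equal(empty$cohort$n_notifications, 0)
  expect_true(is.na(empty$cohort$gap_hours$median))
})
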