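# Fixture builders: small hand-constructed patient records used across the
# engine and I/O tests. All times are ISO strings at minute resolution.

iso <- function(day, hm) sprintf("2020-02-%02dT%s", day, hm)

# events for one patient charted at given times; value vectors recycled
ev <- function(pid, times, kind, values) {
  observation_events(rep(pid, length(times)), times, rep(kind, length(times)),
                     rep(values, length.out = length(times)))
}

bind_events <- function(...) {
  out <- do.call(rbind, list(...))
  out <- out[order(out$patient_id, out$time, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

make_record <- function(events, pid = "P1", adm = iso(1, "10:00"),
                        dis = iso(5, "00:00"), age = 70, sex = "female",
                        outcome = reference_outcome()) {
  patient_record(pid, age, sex, adm, dis, events = events, outcome = outcome)
}

# coma + bilaterally absent pupils charted every 4 h over [from, to]
coma_chart <- function(pid, from, to, step_hours = 4) {
  times <- seq(parse_iso(from), parse_iso(to), by = step_hours * 3600)
  bind_events(ev(pid, times, "RASS", -5),
              ev(pid, times, "GCS", 3),
              ev(pid, times, "PLR_LEFT", "absent"),
              ev(pid, times, "PLR_RIGHT", "absent"))
}

# unremarkable charting (awake, reactive pupils) every 4 h over [from, to]
normal_chart <- function(pid, from, to, step_hours = 4) {
  times <- seq(parse_iso(from), parse_iso(to), by = step_hours * 3600)
  bind_events(ev(pid, times, "RASS", 0),
              ev(pid, times, "GCS", 14),
              ev(pid, times, "PLR_LEFT", "present"),
              ev(pid, times, "PLR_RIGHT", "present"))
}

parse_iso <- function(x) as.POSIXct(x, tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M", "%Y-%m-%d"))

# the worked tick-enumeration case: admitted day 1 10:00, rule continuously
# met from day 2 06:00 through day 4 06:00, discharged day 4 12:00
persistent_positive_record <- function(pid = "P1") {
  events <- bind_events(
    normal_chart(pid, iso(1, "10:00"), iso(2, "02:00")),
    coma_chart(pid, iso(2, "05:00"), iso(4, "06:00"))
  )
  make_record(events, pid = pid, adm = iso(1, "10:00"), dis = iso(4, "12:00"))
}
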