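# Independent brute-force oracles, deliberately naive: written against the
# stated measurement rules, not against the package implementation.

TZ <- "UTC"
D0 <- as.Date("2023-02-01")

at_min <- function(mins, date = D0) {
  as.POSIXct(paste(format(date), "00:00:00"), tz = TZ) + mins * 60
}

# count of intervals intersecting each half-open bin [b, b + w), looping
# over every interval x bin pair; zero-length intervals occupy the bin
# containing their instant
oracle_n_active <- function(intervals, bin_starts, bin_width) {
  vapply(bin_starts, function(b) {
    be <- as.numeric(b) + bin_width * 60
    b <- as.numeric(b)
    s <- as.numeric(intervals$start)
    e <- as.numeric(intervals$end)
    sum((s < be & e > b) | (s == e & s >= b & s < be))
  }, numeric(1))
}

# sum of successive gaps <= threshold, elementwise loop
oracle_ehr_time <- function(ts_secs, threshold_min = 5) {
  ts <- sort(ts_secs)
  if (length(ts) < 2) return(0)
  tot <- 0
  for (i in 2:length(ts)) {
    g <- ts[i] - ts[i - 1]
    if (g <= threshold_min * 60) tot <- tot + g
  }
  tot / 60
}

# drop patient-less events, count adjacent differing-patient pairs within
# the threshold
oracle_switches <- function(ts_secs, pids, threshold_min = 5) {
  keep <- !is.na(pids)
  ts <- ts_secs[keep][order(ts_secs[keep])]
  p <- pids[keep][order(ts_secs[keep])]
  if (length(p) < 2) return(0L)
  n <- 0L
  for (i in 2:length(p)) {
    if (p[i] != p[i - 1] && (ts[i] - ts[i - 1]) <= threshold_min * 60) n <- n + 1L
  }
  n
}

random_intervals <- function(n, p_zero = 0.2) {
  s <- runif(n, 0, 86000)
  d <- ifelse(runif(n) < p_zero, 0, runif(n, 0, 14400))
  tibble::tibble(
    clinician_id = "CX", conversation_id = sprintf("cv%03d", seq_len(n)),
    date = D0,
    start = as.POSIXct(paste(format(D0), "00:00:00"), tz = TZ) + round(s),
    end = as.POSIXct(paste(format(D0), "00:00:00"), tz = TZ) + round(pmin(s + d, 86399))
  )
}

mk_audit <- function(mins, types = "chart_access", pids = NA_character_,
                     contexts = NA_character_, clinician = "C1", date = D0) {
  n <- length(mins)
  tibble::tibble(
    clinician_id = clinician,
    timestamp = at_min(mins, date),
    action_type = rep_len(types, n),
    patient_id = rep_len(pids, n),
    login_context = rep_len(contexts, n)
  )
}

mk_messages <- function(mins, conv = "cv1", clinician = "C1", date = D0) {
  tibble::tibble(
    conversation_id = rep_len(conv, length(mins)),
    clinician_id = clinician,
    direction = rep_len(c("sent", "read"), length(mins)),
    timestamp = at_min(mins, date)
  )
}

empty_messages <- function(clinician = "C1") {
  tibble::tibble(conversation_id = character(), clinician_id = character(),
                 direction = character(),
                 timestamp = as.POSIXct(character(), tz = TZ))
}

# one analyzable day: login + note + order + a message
ok_day_audit <- function(clinician = "C1", date = D0, context = "ICU") {
  mk_audit(c(540, 541, 542, 543, 544), # 09:00 onward, 1-minute gaps
           types = c("login", "note_sign", "order", "chart_access", "chart_access"),
           pids = c(NA, "P1", "P1", "P2", "P2"),
           contexts = c(context, NA, NA, NA, NA),
           clinician = clinician, date = date)
}

ok_day_messages <- function(clinician = "C1", date = D0) {
  mk_messages(c(600, 605), conv = paste0(clinician, "-cv"), clinician = clinician,
              date = date)
}

simple_roster <- function(ids = "C1", role = "attending", age = 40, sex = "female") {
  tibble::tibble(clinician_id = ids, role = rep_len(role, length(ids)),
                 age = rep_len(age, length(ids)), sex = rep_len(sex, length(ids)))
}
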