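ACTION_TYPES <- c("note_sign", "order", "login", "chart_access", "other")

validate_audit_events <- function(events) {
  assert_cols(events, c("clinician_id", "timestamp", "action_type"), "audit log table")
  if (!inherits(events$timestamp, "POSIXct")) {
    stop("audit timestamps must be POSIXct; use read_audit_log() to parse raw files",
         call. = FALSE)
  }
  invisible(events)
}

filter_day <- function(events, date) {
  if (is.null(date)) return(events)
  target_day <- as.Date(date)
  events[event_date(events$timestamp) == target_day, , drop = FALSE]
}

#' Total EHR time from an audit-log stream
#'
#' Active EHR time for a clinician-day is the sum of the time intervals
#' between successive audit-log actions, excluding intervals exceeding the
#' inactivity threshold (default 5 minutes), which are treated as periods
#' away from the EHR. A gap exactly equal to the threshold is counted; the
#' trailing action contributes no imputed duration. Zero or one action gives
#' 0 minutes.
#'
#' @param events Audit-log events for one clinician (tibble with
#'   `clinician_id`, `timestamp`, `action_type`, optional `patient_id`,
#'   `login_context`). Sorted defensively; ties keep input order.
#' @param date Optional calendar day filter.
#' @param inactivity_threshold Threshold in minutes (default 5).
#' @return EHR time in minutes (double).
#' @examples
#' d0 <- as.POSIXct("2023-02-01 08:00:00", tz = "UTC")
#' ev <- tibble::tibble(clinician_id = "C1", timestamp = d0 + c(0, 2, 4, 10, 11) * 60,
#'                      action_type = "chart_access")
#' ehr_time(ev) # gaps 2,2,6,1 -> 6 excluded -> 5 minutes
#' @export
ehr_time <- function(events, date = NULL, inactivity_threshold = 5) {
  validate_audit_events(events)
  ev <- filter_day(events, date)
  if (nrow(ev) < 2) return(0)
  ts <- sort(as.numeric(ev$timestamp), method = "radix")
  gaps <- pmax(diff(ts), 0)
  sum(gaps[gaps <= inactivity_threshold * 60]) / 60
}

#' Patient-chart switches from an audit-log stream
#'
#' A switch is a transition between two successive patient-attached actions
#' (actions carrying a `patient_id`; patient-less actions are skipped when
#' forming pairs and do not reset the clock) whose patient ids differ,
#' unless the time between the two actions exceeds the inactivity threshold.
#'
#' @inheritParams ehr_time
#' @return Integer count of switches.
#' @export
patient_switches <- function(events, date = NULL, inactivity_threshold = 5) {
  validate_audit_events(events)
  ev <- filter_day(events, date)
  if (!"patient_id" %in% names(ev)) return(0L)
  ev <- ev[!is.na(ev$patient_id) & ev$patient_id != "", , drop = FALSE]
  if (nrow(ev) < 2) return(0L)
  o <- order(as.numeric(ev$timestamp), method = "radix")
  ts <- as.numeric(ev$timestamp)[o]
  pid <- ev$patient_id[o]
  gaps <- pmax(diff(ts), 0)
  sum(pid[-1] != pid[-length(pid)] & gaps <= inactivity_threshold * 60)
}

#' Daily patient load
#'
#' Operationalized as the number of distinct patients whose charts the
#' clinician touched that day (distinct non-missing patient ids in the
#' audit log).
#'
#' @inheritParams ehr_time
#' @return Integer count of distinct patients.
#' @export
patient_load <- function(events, date = NULL) {
  validate_audit_events(events)
  ev <- filter_day(events, date)
  if (!"patient_id" %in% names(ev)) return(0L)
  pid <- ev$patient_id
  length(unique(pid[!is.na(pid) & pid != ""]))
}

#' Outcome summary for one clinician-day
#'
#' @inheritParams ehr_time
#' @param date Calendar day to summarise (required).
#' @return One-row tibble: `clinician_id`, `date`, `ehr_time`, `n_switches`,
#'   `patient_load`.
#' @export
outcome_summary <- function(events, date, inactivity_threshold = 5) {
  validate_audit_events(events)
  date <- as.Date(date)
  cl <- if (nrow(events)) unique(events$clinician_id) else NA_character_
  if (length(cl) > 1) stop("outcome_summary() expects one clinician", call. = FALSE)
  tibble::tibble(
    clinician_id = cl, date = date,
    ehr_time = ehr_time(events, date, inactivity_threshold),
    n_switches = as.integer(patient_switches(events, date, inactivity_threshold)),
    patient_load = as.integer(patient_load(events, date))
  )
}

# per clinician-day audit summary used by build_cohort(); also extracts the
# fields needed by the inclusion and service-assignment rules
summarise_audit <- function(audit_log, inactivity_threshold = 5) {
  validate_audit_events(audit_log)
  if (nrow(audit_log) == 0) {
    return(tibble::tibble(clinician_id = character(), date = as.Date(character()),
                          ehr_time = double(), n_switches = integer(),
                          patient_load = integer(), n_notes = integer(),
                          n_orders = integer(), n_logins = integer(),
                          first_login = as.POSIXct(character(), tz = .TZ),
                          service = character()))
  }
  ev <- dplyr::mutate(audit_log, date = event_date(.data$timestamp))
  key <- paste(ev$clinician_id, ev$date)
  pieces <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    g <- ev[idx, ]
    logins <- g[g$action_type == "login", , drop = FALSE]
    tibble::tibble(
      clinician_id = g$clinician_id[1],
      date = g$date[1],
      ehr_time = ehr_time(g, inactivity_threshold = inactivity_threshold),
      n_switches = as.integer(patient_switches(g, inactivity_threshold = inactivity_threshold)),
      patient_load = as.integer(patient_load(g)),
      n_notes = sum(g$action_type == "note_sign"),
      n_orders = sum(g$action_type == "order"),
      n_logins = nrow(logins),
      first_login = if (nrow(logins)) min(logins$timestamp) else
        as.POSIXct(NA, tz = .TZ),
      service = if (nrow(logins)) assign_service(logins) else NA_character_
    )
  })
  dplyr::bind_rows(pieces) |> dplyr::arrange(.data$clinician_id, .data$date)
}
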