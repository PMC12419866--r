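EXCLUSION_REASONS <- c("none", "no_note", "no_order", "no_message",
                       "no_login", "night_shift", "missing_demographics")

#' Night-shift rule for a clinician-day
#'
#' A clinician-day counts as a night shift when the first EHR login of the
#' day occurs strictly before 5 AM or strictly after 5 PM local time. A
#' first login at exactly 17:00:00 is a day shift.
#'
#' @param first_login POSIXct first login of the day (vectorized).
#' @return Logical.
#' @export
is_night_shift <- function(first_login) {
  s <- secs_of_day(first_login)
  s < 5 * 3600 | s > 17 * 3600
}

#' Daily clinical-service assignment from login contexts
#'
#' The service a clinician worked on a given day is proxied by the modal
#' login context of that day; ties are broken in favour of the context whose
#' first login of the day occurred earliest.
#'
#' @param login_events Audit-log rows of that clinician-day with
#'   `action_type == "login"` and a `login_context` column.
#' @return Service identifier (character), or `NA` when no login carries a
#'   context.
#' @export
assign_service <- function(login_events) {
  lc <- login_events$login_context
  ok <- !is.na(lc) & lc != ""
  if (!any(ok)) return(NA_character_)
  lc <- lc[ok]
  ts <- as.numeric(login_events$timestamp)[ok]
  o <- order(ts, method = "radix")
  lc <- lc[o]
  freq <- table(lc)
  first_seen <- match(names(freq), lc)
  names(freq)[order(-as.integer(freq), first_seen)][1]
}

#' Inclusion status of a clinician-day
#'
#' A clinician-day is analyzable when, on that day, the clinician signed at
#' least one patient note, placed at least one order, and sent or read at
#' least one secure message; the day was not a night shift; and the
#' clinician's age and sex are known. Failing days receive the first failing
#' rule (fixed precedence: note, order, message, login presence, night
#' shift, demographics) as their single exclusion reason. A day with
#' activity but no login at all cannot be classified for shift or service
#' and is excluded with the distinct reason `no_login`.
#'
#' @param n_notes,n_orders,n_messages,n_logins Daily activity counts
#'   (vectorized).
#' @param first_login POSIXct first login (NA when `n_logins == 0`).
#' @param has_demographics Logical; age and sex both known.
#' @return Factor of exclusion reasons with levels `r toString(EXCLUSION_REASONS)`;
#'   `"none"` means included.
#' @export
inclusion_status <- function(n_notes, n_orders, n_messages, n_logins,
                             first_login, has_demographics) {
  night <- !is.na(first_login) & is_night_shift(first_login)
  reason <- ifelse(n_notes < 1, "no_note",
            ifelse(n_orders < 1, "no_order",
            ifelse(n_messages < 1, "no_message",
            ifelse(n_logins < 1, "no_login",
            ifelse(night, "night_shift",
            ifelse(!has_demographics, "missing_demographics", "none"))))))
  factor(reason, levels = EXCLUSION_REASONS)
}

#' Assemble the analyzable clinician-day cohort
#'
#' Joins the three source tables, computes messaging exposure and EHR
#' outcomes per clinician-day, applies the inclusion rules, and assigns the
#' daily clinical service. Every clinician-date with any message or audit
#' activity yields one row; the exclusion accounting (counts per reason) is
#' attached as the `"exclusions"` attribute and retrievable with
#' [exclusion_report()]. Clinicians appearing in the event streams but
#' absent from the roster are excluded as `missing_demographics` with a
#' warning.
#'
#' @param messages Message-event table (see [read_messages()]).
#' @param audit_log Audit-log table (see [read_audit_log()]).
#' @param roster Clinician roster with `clinician_id`, `role`, `age`, `sex`.
#' @param bin_width Concurrency bin width in minutes (1, 2 or 5).
#' @param inactivity_threshold Inactivity threshold in minutes for the EHR
#'   outcomes (default 5).
#' @return Tibble with one row per candidate clinician-day: identifiers,
#'   demographics, `service`, `included`, `exclusion_reason`, `exposure`,
#'   and all messaging/EHR metrics.
#' @export
build_cohort <- function(messages, audit_log, roster, bin_width = 1,
                         inactivity_threshold = 5) {
  assert_cols(roster, c("clinician_id", "role", "age", "sex"), "roster")
  msg <- summarise_messaging(messages, bin_width)
  aud <- summarise_audit(audit_log, inactivity_threshold)
  days <- dplyr::full_join(msg, aud, by = c("clinician_id", "date"))
  if (nrow(days) == 0) {
    out <- tibble::tibble()
    attr(out, "exclusions") <- list(total = 0L, included = 0L,
                                    by_reason = integer(0))
    return(out)
  }
  days <- days |>
    dplyr::mutate(
      msg_volume = dplyr::coalesce(.data$msg_volume, 0L),
      total_msg_time = dplyr::coalesce(.data$total_msg_time, 0),
      pct_concurrent_time = dplyr::coalesce(.data$pct_concurrent_time, 0),
      max_concurrent = dplyr::coalesce(.data$max_concurrent, 0L),
      category = dplyr::coalesce(.data$category, categorize_exposure(0L)),
      ehr_time = dplyr::coalesce(.data$ehr_time, 0),
      n_switches = dplyr::coalesce(.data$n_switches, 0L),
      patient_load = dplyr::coalesce(.data$patient_load, 0L),
      n_notes = dplyr::coalesce(.data$n_notes, 0L),
      n_orders = dplyr::coalesce(.data$n_orders, 0L),
      n_logins = dplyr::coalesce(.data$n_logins, 0L)
    )
  unknown <- setdiff(unique(days$clinician_id), roster$clinician_id)
  if (length(unknown)) {
    warning(sprintf("%d clinician(s) in event streams but not in roster; their days are excluded (missing_demographics): %s",
                    length(unknown), paste(head(unknown, 5), collapse = ", ")),
            call. = FALSE)
  }
  days <- dplyr::left_join(days, roster, by = "clinician_id")
  days <- days |>
    dplyr::mutate(
      has_demographics = !is.na(.data$role) & !is.na(.data$age) & !is.na(.data$sex),
      exclusion_reason = inclusion_status(.data$n_notes, .data$n_orders,
                                          .data$msg_volume, .data$n_logins,
                                          .data$first_login, .data$has_demographics),
      included = .data$exclusion_reason == "none",
      exposure = .data$category
    ) |>
    dplyr::arrange(.data$clinician_id, .data$date)
  by_reason <- table(days$exclusion_reason[!days$included])
  attr(days, "exclusions") <- list(
    total = nrow(days),
    included = sum(days$included),
    by_reason = setNames(as.integer(by_reason), names(by_reason))
  )
  days
}

#' Exclusion accounting of a cohort
#'
#' @param cohort Output of [build_cohort()].
#' @return List with `total` candidate clinician-days, `included` count, and
#'   `by_reason` counts. These always satisfy
#'   `included + sum(by_reason) == total`.
#' @export
exclusion_report <- function(cohort) {
  rep <- attr(cohort, "exclusions")
  if (is.null(rep)) stop("cohort has no exclusion accounting attribute", call. = FALSE)
  rep
}
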