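#' Exposure categories for conversational multitasking
#'
#' Ordered levels of the daily exposure: no concurrent conversations, a
#' maximum of 2, 3, or 4 or more simultaneously active conversations.
#'
#' @format Character vector of the four level names.
#' @export
EXPOSURE_LEVELS <- c("NONE", "TWO", "THREE", "FOUR_PLUS")

validate_message_events <- function(events) {
  assert_cols(events, c("conversation_id", "clinician_id", "direction", "timestamp"),
              "message table")
  bad <- !events$direction %in% c("sent", "read")
  if (any(bad)) {
    stop(sprintf("invalid message direction at row(s) %s (must be 'sent' or 'read')",
                 paste(head(which(bad), 5), collapse = ", ")), call. = FALSE)
  }
  if (!inherits(events$timestamp, "POSIXct")) {
    stop("message timestamps must be POSIXct; use read_messages() to parse raw files",
         call. = FALSE)
  }
  invisible(events)
}

#' Active-conversation intervals for each clinician-day
#'
#' A conversation is considered active from the first to the last of the
#' clinician's message activities (sent or read) within that conversation on
#' a given calendar day. Conversations spanning midnight are clipped to
#' calendar days: each day gets its own interval bounded by that day's
#' events. A conversation with a single activity on a day yields a
#' zero-length interval.
#'
#' @param events Tibble of message events with columns `conversation_id`,
#'   `clinician_id`, `direction` (`"sent"`/`"read"`), `timestamp` (POSIXct).
#'   May contain several clinicians and days.
#' @param date Optional `Date` (or string); if given, only events on that
#'   calendar day are used.
#' @return Tibble with one row per (clinician, conversation, day):
#'   `clinician_id`, `conversation_id`, `date`, `start`, `end`.
#' @examples
#' ev <- fig_timeline_events()
#' conversation_intervals(ev)
#' @export
conversation_intervals <- function(events, date = NULL) {
  validate_message_events(events)
  if (nrow(events) == 0) {
    return(tibble::tibble(clinician_id = character(), conversation_id = character(),
                          date = as.Date(character()),
                          start = as.POSIXct(character(), tz = .TZ),
                          end = as.POSIXct(character(), tz = .TZ)))
  }
  ev <- dplyr::mutate(events, date = event_date(.data$timestamp))
  if (!is.null(date)) {
    target_day <- as.Date(date)
    ev <- dplyr::filter(ev, .data$date == target_day)
  }
  ev |>
    dplyr::group_by(.data$clinician_id, .data$conversation_id, .data$date) |>
    dplyr::summarise(start = min(.data$timestamp), end = max(.data$timestamp),
                     .groups = "drop") |>
    dplyr::arrange(.data$clinician_id, .data$date, .data$start, .data$conversation_id)
}

#' Per-bin concurrency trace for one clinician-day
#'
#' Tiles the span of the day's active intervals with half-open bins
#' `[t, t + w)` aligned to midnight and counts, per bin, the number of
#' active conversations. An interval `[start, end)` intersects a bin when
#' `start < bin_end` and `end > bin_start`; a zero-length interval (single
#' message activity) is active in the single bin containing its timestamp.
#' Following the field convention that a lone open conversation is not
#' multitasking, the reported `concurrency` is `n_active` when at least two
#' conversations are active and 0 otherwise; `n_active` itself is kept for
#' exposure categorization.
#'
#' @param intervals Output of [conversation_intervals()] restricted to one
#'   clinician and one day.
#' @param bin_width Bin width in minutes; one of 1 (primary), 2 or 5
#'   (sensitivity analyses).
#' @return Tibble with columns `bin_start` (POSIXct), `n_active`,
#'   `concurrency`, and attributes `clinician_id`, `date`, `bin_width`.
#' @examples
#' iv <- conversation_intervals(fig_timeline_events())
#' tr <- concurrency_trace(iv)
#' max_concurrent(tr)
#' @export
concurrency_trace <- function(intervals, bin_width = 1) {
  if (!bin_width %in% c(1, 2, 5)) {
    stop("bin_width must be 1, 2 or 5 minutes", call. = FALSE)
  }
  empty <- tibble::tibble(bin_start = as.POSIXct(character(), tz = .TZ),
                          n_active = integer(), concurrency = integer())
  attr(empty, "bin_width") <- bin_width
  if (nrow(intervals) == 0) return(empty)
  if (length(unique(intervals$clinician_id)) > 1 || length(unique(intervals$date)) > 1) {
    stop("concurrency_trace() expects intervals from a single clinician-day",
         call. = FALSE)
  }
  w <- bin_width * 60
  d0 <- day_start(intervals$date[1])
  s <- as.numeric(intervals$start) - as.numeric(d0)
  e <- as.numeric(intervals$end) - as.numeric(d0)
  k1 <- floor(s / w)
  k2 <- ifelse(e > s, ceiling(e / w) - 1, k1)  # half-open end; point = its own bin
  k2 <- pmax(k1, k2)
  kmin <- min(k1); kmax <- max(k2)
  nb <- kmax - kmin + 1
  delta <- integer(nb + 1)
  i1 <- k1 - kmin + 1; i2 <- k2 - kmin + 2
  for (j in seq_along(i1)) {
    delta[i1[j]] <- delta[i1[j]] + 1L
    delta[i2[j]] <- delta[i2[j]] - 1L
  }
  n_active <- cumsum(delta[seq_len(nb)])
  out <- tibble::tibble(
    bin_start = d0 + (kmin:kmax) * w,
    n_active = as.integer(n_active),
    concurrency = as.integer(ifelse(n_active >= 2, n_active, 0L))
  )
  attr(out, "clinician_id") <- intervals$clinician_id[1]
  attr(out, "date") <- intervals$date[1]
  attr(out, "bin_width") <- bin_width
  out
}

#' Maximum number of simultaneously active conversations in a trace
#'
#' @param trace Output of [concurrency_trace()].
#' @return Integer; 0 for an empty trace. Note this is the raw count of
#'   active conversations (a lone active conversation gives 1), so that a
#'   maximum of 2 means two genuinely simultaneous threads.
#' @export
max_concurrent <- function(trace) {
  if (nrow(trace) == 0) return(0L)
  max(trace$n_active)
}

#' Categorize a day's maximum concurrency into the exposure groups
#'
#' Days whose conversations never overlap (maximum 0 or 1 active) are the
#' reference `NONE` group; otherwise the day is classed by its maximum as
#' `TWO`, `THREE`, or `FOUR_PLUS` (>= 4).
#'
#' @param max_concurrent Non-negative integer (vectorized).
#' @return Factor with levels [EXPOSURE_LEVELS].
#' @export
categorize_exposure <- function(max_concurrent) {
  stopifnot(all(max_concurrent >= 0))
  lab <- ifelse(max_concurrent <= 1, "NONE",
         ifelse(max_concurrent == 2, "TWO",
         ifelse(max_concurrent == 3, "THREE", "FOUR_PLUS")))
  factor(lab, levels = EXPOSURE_LEVELS)
}

# exact measure (minutes) of the set where >= k intervals overlap;
# zero-length intervals have measure zero and are ignored here
coverage_minutes <- function(start, end, k = 1) {
  keep <- as.numeric(end) > as.numeric(start)
  if (!any(keep)) return(0)
  t <- c(as.numeric(start[keep]), as.numeric(end[keep]))
  d <- c(rep(1L, sum(keep)), rep(-1L, sum(keep)))
  o <- order(t, d)  # half-open intervals: ends apply before coincident starts
  t <- t[o]; d <- d[o]
  cov <- cumsum(d)
  dt <- diff(t)
  sum(dt[cov[-length(cov)] >= k]) / 60
}

#' Messaging summary for one clinician-day
#'
#' Computes the day's message volume (sent + read activities), total
#' messaging time (measure of the union of active-conversation intervals,
#' in minutes), the percentage of messaging time spent with two or more
#' conversations simultaneously active, the day's maximum concurrency, and
#' the exposure category.
#'
#' @param events Message events for a single clinician (other days are
#'   ignored after day-clipping).
#' @param date Calendar day to summarise.
#' @param bin_width Trace bin width in minutes (1, 2 or 5); affects
#'   `max_concurrent` and `category`, not the exact time measures.
#' @return One-row tibble: `clinician_id`, `date`, `msg_volume`,
#'   `total_msg_time`, `pct_concurrent_time`, `max_concurrent`, `category`.
#' @examples
#' messaging_summary(fig_timeline_events(), as.Date("2023-02-01"))
#' @export
messaging_summary <- function(events, date, bin_width = 1) {
  validate_message_events(events)
  date <- as.Date(date)
  if (nrow(events)) {
    cl <- unique(events$clinician_id)
    if (length(cl) > 1) stop("messaging_summary() expects one clinician", call. = FALSE)
  } else cl <- NA_character_
  iv <- conversation_intervals(events, date)
  n_events <- if (nrow(events)) sum(event_date(events$timestamp) == date) else 0L
  messaging_summary_core(iv, cl, date, n_events, bin_width)
}

messaging_summary_core <- function(iv, clinician_id, date, n_events, bin_width) {
  if (nrow(iv) == 0) {
    return(tibble::tibble(clinician_id = clinician_id, date = date,
                          msg_volume = 0L, total_msg_time = 0,
                          pct_concurrent_time = 0, max_concurrent = 0L,
                          category = categorize_exposure(0L)))
  }
  tr <- concurrency_trace(iv, bin_width)
  total <- coverage_minutes(iv$start, iv$end, 1)
  conc <- coverage_minutes(iv$start, iv$end, 2)
  tibble::tibble(
    clinician_id = clinician_id,
    date = date,
    msg_volume = as.integer(n_events),
    total_msg_time = total,
    pct_concurrent_time = if (total > 0) 100 * conc / total else 0,
    max_concurrent = max_concurrent(tr),
    category = categorize_exposure(max_concurrent(tr))
  )
}

# vectorized over all clinician-days present in a message table
summarise_messaging <- function(messages, bin_width = 1) {
  validate_message_events(messages)
  iv <- conversation_intervals(messages)
  if (nrow(iv) == 0) {
    return(tibble::tibble(clinician_id = character(), date = as.Date(character()),
                          msg_volume = integer(), total_msg_time = double(),
                          pct_concurrent_time = double(), max_concurrent = integer(),
                          category = categorize_exposure(integer())))
  }
  counts <- messages |>
    dplyr::mutate(date = event_date(.data$timestamp)) |>
    dplyr::count(.data$clinician_id, .data$date, name = "msg_volume")
  key <- paste(iv$clinician_id, iv$date)
  pieces <- lapply(split(seq_len(nrow(iv)), key), function(idx) {
    g <- iv[idx, ]
    n <- counts$msg_volume[counts$clinician_id == g$clinician_id[1] &
                             counts$date == g$date[1]]
    messaging_summary_core(g, g$clinician_id[1], g$date[1], n, bin_width)
  })
  dplyr::bind_rows(pieces) |> dplyr::arrange(.data$clinician_id, .data$date)
}

#' Worked-example messaging timeline
#'
#' Message events reproducing the canonical three-conversation illustration
#' of the concurrency measurement: conversation 1 active 8:30-11:00,
#' conversation 2 active 8:40-10:30, conversation 3 active 9:30-11:30. The
#' resulting per-minute trace is 0 concurrent until 8:40, 2 until 9:30, 3
#' until 10:30, 2 until 11:00, and 0 thereafter, for a daily maximum of 3.
#'
#' @param date Calendar day on which to place the events.
#' @param clinician_id Clinician identifier to stamp on the events.
#' @return Message-event tibble suitable for [conversation_intervals()].
#' @export
fig_timeline_events <- function(date = as.Date("2023-02-01"), clinician_id = "C001") {
  at <- function(hm) day_start(date) + (as.numeric(substr(hm, 1, 2)) * 3600 +
                                          as.numeric(substr(hm, 4, 5)) * 60)
  tibble::tibble(
    conversation_id = rep(c("conv1", "conv2", "conv3"), each = 2),
    clinician_id = clinician_id,
    direction = rep(c("sent", "read"), 3),
    timestamp = c(at("08:30"), at("11:00"), at("08:40"), at("10:30"),
                  at("09:30"), at("11:30"))
  )
}
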