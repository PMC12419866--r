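# Delimited-table interfaces. All three tables are comma-separated with a
# header row; timestamps are ISO 8601, timezone-naive local time; empty
# fields encode missingness.

parse_timestamps <- function(x, what) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = .TZ)
  present <- !is.na(x) & x != ""
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(present & is.na(out))
    if (!length(idx)) break
    p <- as.POSIXct(strptime(x[idx], fmt, tz = .TZ), tz = .TZ)
    out[idx[!is.na(p)]] <- p[!is.na(p)]
  }
  bad <- which(present & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: unparseable timestamp at row(s) %s (first offending value: '%s')",
                 what, paste(head(bad, 5), collapse = ", "), x[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Read secure-messaging metadata
#'
#' Expected columns: `conversation_id`, `clinician_id`, `direction`
#' (`sent`/`read`), `timestamp` (ISO 8601, local time).
#'
#' @param path Path to `messages.csv`.
#' @return Validated message-event tibble.
#' @export
read_messages <- function(path) {
  if (!file.exists(path)) stop(sprintf("message file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  assert_cols(df, c("conversation_id", "clinician_id", "direction", "timestamp"),
              basename(path))
  df$timestamp <- parse_timestamps(df$timestamp, basename(path))
  validate_message_events(df)
  df
}

#' Read an EHR audit log
#'
#' Expected columns: `clinician_id`, `timestamp`, `action_type` (one of
#' `note_sign`, `order`, `login`, `chart_access`, `other`), `patient_id`
#' (optional per row), `login_context` (present on login rows).
#'
#' @param path Path to `audit_log.csv`.
#' @return Validated audit-log tibble.
#' @export
read_audit_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("audit log file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  assert_cols(df, c("clinician_id", "timestamp", "action_type"), basename(path))
  df$timestamp <- parse_timestamps(df$timestamp, basename(path))
  if (!"patient_id" %in% names(df)) df$patient_id <- NA_character_
  if (!"login_context" %in% names(df)) df$login_context <- NA_character_
  bad <- !df$action_type %in% ACTION_TYPES
  if (any(bad)) {
    stop(sprintf("%s: unknown action_type at row(s) %s", basename(path),
                 paste(head(which(bad), 5), collapse = ", ")), call. = FALSE)
  }
  validate_audit_events(df)
  df
}

#' Read a clinician roster
#'
#' Expected columns: `clinician_id`, `role` (`attending`/`APP`/`trainee`),
#' `age` (years; empty when unknown), `sex` (`female`/`male`; empty when
#' unknown). Missing demographics are kept as `NA`, never imputed.
#'
#' @param path Path to `roster.csv`.
#' @return Roster tibble.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop(sprintf("roster file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  assert_cols(df, c("clinician_id", "role", "age", "sex"), basename(path))
  if (anyDuplicated(df$clinician_id)) {
    stop(sprintf("%s: duplicated clinician_id", basename(path)), call. = FALSE)
  }
  df$age <- suppressWarnings(as.numeric(df$age))
  df$sex[!is.na(df$sex) & df$sex == ""] <- NA_character_
  df
}

#' Write a simulated study to disk
#'
#' Writes `messages.csv`, `audit_log.csv`, `roster.csv` (and `truth.csv`
#' with the planted ground truth) into a directory, in the schemas read back
#' by [read_messages()], [read_audit_log()] and [read_roster()]. Output is
#' byte-identical for identical simulations.
#'
#' @param sim Output of [simulate_study()] (event level).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "convoload_sim"))
  if (is.null(sim$messages)) {
    stop("write_sim_data() needs an event-level simulation", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S")
  paths <- c(messages = file.path(dir, "messages.csv"),
             audit_log = file.path(dir, "audit_log.csv"),
             roster = file.path(dir, "roster.csv"),
             truth = file.path(dir, "truth.csv"))
  msg <- dplyr::mutate(sim$messages, timestamp = fmt(.data$timestamp))
  aud <- dplyr::mutate(sim$audit_log, timestamp = fmt(.data$timestamp))
  readr::write_csv(msg, paths["messages"], na = "", progress = FALSE)
  readr::write_csv(aud, paths["audit_log"], na = "", progress = FALSE)
  readr::write_csv(sim$roster, paths["roster"], na = "", progress = FALSE)
  readr::write_csv(sim$truth, paths["truth"], na = "", progress = FALSE)
  invisible(paths)
}
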