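# Internal time helpers. All instants are timezone-naive local time,
# represented as POSIXct in UTC so that arithmetic never crosses DST.

.TZ <- "UTC"

as_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate_free(x))
  out <- as.POSIXct(x, tz = .TZ,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

# force POSIXct into the package timezone without changing the clock reading
lubridate_free <- function(x) {
  if (identical(attr(x, "tzone"), .TZ)) return(x)
  as.POSIXct(format(x, tz = if (is.null(attr(x, "tzone"))) "" else attr(x, "tzone")),
             tz = .TZ)
}

event_date <- function(ts) as.Date(ts, tz = .TZ)

day_start <- function(date) {
  d <- as.Date(date)
  out <- as.POSIXct(rep(NA_real_, length(d)), origin = "1970-01-01", tz = .TZ)
  ok <- !is.na(d)
  if (any(ok)) out[ok] <- as.POSIXct(paste0(format(d[ok]), " 00:00:00"), tz = .TZ)
  out
}

# seconds since local midnight
secs_of_day <- function(ts) {
  as.numeric(ts) - as.numeric(day_start(event_date(ts)))
}

instant_at <- function(date, secs) day_start(date) + secs

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
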