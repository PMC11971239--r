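# Clock-time helpers. All analysis time is timezone-naive local clock time,
# carried as POSIXct in UTC so that arithmetic never crosses DST boundaries
# and "midnight to midnight" is a plain 86400-s window.

#' Parse clock time
#'
#' Converts character timestamps (or numbers of seconds since the epoch) to
#' the package's internal clock-time representation: `POSIXct` in UTC,
#' interpreted as local wall-clock time.
#'
#' @param x Character vector of timestamps, `POSIXct`, or numeric seconds.
#' @param format Format string passed to [base::as.POSIXct()] for character
#'   input. The default accepts `"2024-03-04 08:00:00"` and ISO-8601 with a
#'   `T` separator.
#' @return A `POSIXct` vector in UTC.
#' @export
clock_time <- function(x, format = NULL) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  if (is.null(format)) {
    out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
    d_only <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    out[d_only] <- as.POSIXct(x[d_only], tz = "UTC", format = "%Y-%m-%d")
  } else {
    out <- as.POSIXct(x, tz = "UTC", format = format)
  }
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp(s), e.g. ", x[which(is.na(out))[1L]],
         call. = FALSE)
  }
  out
}

# Floor a POSIXct to the start of its local day.
floor_day <- function(t) {
  clock_time(floor(as.numeric(t) / 86400) * 86400)
}

# Floor a POSIXct to a grid of `by` seconds anchored at midnight.
floor_grid <- function(t, by = 60) {
  clock_time(floor(as.numeric(t) / by) * by)
}

# First grid point at or after t.
ceil_grid <- function(t, by = 60) {
  clock_time(ceiling(as.numeric(t) / by) * by)
}

# Format for deterministic CSV output.
iso_stamp <- function(t) {
  format(clock_time(t), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# seconds-of-day for a POSIXct
sec_of_day <- function(t) {
  as.numeric(t) %% 86400
}
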