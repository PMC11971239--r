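#' Dominant activity class per epoch
#'
#' Labels each 60-s behaviour epoch with the class holding the most
#' seconds. Ties are broken by a fixed priority favouring rarer, more
#' specific classes: stepping > cycling > upright > seated_transport >
#' sedentary > secondary_lying > primary_lying > non_wear.
#'
#' @param table A `behaviour_epochs` data frame.
#' @return Data frame: `epoch_start`, `label` (factor over the classes).
#' @export
label_dominant <- function(table) {
  pri <- class_priority()
  m <- as.matrix(as.data.frame(table)[, pri])
  win <- pri[max.col(m, ties.method = "first")]
  data.frame(epoch_start = table$epoch_start,
             label = factor(win, levels = behaviour_classes()))
}

#' Extract stepping bouts
#'
#' Reconstructs continuous stepping bouts from the minute-epoch table: a
#' bout is a maximal run of grid-consecutive epochs each holding at least
#' `min_epoch_stepping_s` seconds of stepping, its duration the summed
#' stepping seconds of the run (minute epochs cannot represent exact
#' continuity, hence the per-epoch threshold). In `event_stream` mode an
#' already bout-level record is validated and passed through unchanged.
#'
#' @param table A `behaviour_epochs` data frame (`epoch_reconstruction`
#'   mode) or a data frame of bouts with `start` and `duration` seconds
#'   (`event_stream` mode).
#' @param mode `"epoch_reconstruction"` or `"event_stream"`.
#' @param min_epoch_stepping_s Seconds of stepping a 60-s epoch needs to
#'   join a bout (default 55).
#' @return Data frame of bouts: `start`, `end`, `duration` (s), `source`.
#' @export
extract_stepping_bouts <- function(table, mode = "epoch_reconstruction",
                                   min_epoch_stepping_s = 55) {
  if (!mode %in% c("epoch_reconstruction", "event_stream")) {
    stop("config error: unknown mode '", mode, "'", call. = FALSE)
  }
  if (mode == "event_stream") {
    stopifnot(all(c("start", "duration") %in% names(table)))
    out <- data.frame(start = clock_time(table$start),
                      duration = as.numeric(table$duration))
    out$end <- out$start + out$duration
    if (any(out$duration <= 0)) {
      stop("integrity error: non-positive bout duration", call. = FALSE)
    }
    o <- order(as.numeric(out$start))
    out <- out[o, ]
    if (nrow(out) > 1L &&
        any(as.numeric(out$start[-1L]) < as.numeric(out$end[-nrow(out)]))) {
      stop("integrity error: overlapping bouts", call. = FALSE)
    }
    out$source <- "event_stream"
    rownames(out) <- NULL
    return(out[, c("start", "end", "duration", "source")])
  }
  tt <- as.numeric(table$epoch_start)
  keep <- table$stepping >= min_epoch_stepping_s
  if (!any(keep)) {
    return(data.frame(start = clock_time(numeric(0)),
                      end = clock_time(numeric(0)),
                      duration = numeric(0), source = character(0)))
  }
  # runs of kept epochs that are also consecutive on the 60-s grid
  ki <- which(keep)
  new_run <- c(TRUE, diff(ki) != 1L | diff(tt[ki]) != 60)
  run_id <- cumsum(new_run)
  start <- tapply(tt[ki], run_id, min)
  dur <- tapply(table$stepping[ki], run_id, sum)
  data.frame(start = clock_time(as.numeric(start)),
             end = clock_time(as.numeric(start) + as.numeric(dur)),
             duration = as.numeric(dur),
             source = "epoch_reconstruction")
}

#' Detect environment-transition events from stepping bouts
#'
#' A stepping bout marks a transition between environments (home and
#' community) when it is continuously longer than `long_s` seconds, or —
#' when a heading series is available — when some sub-segment of at least
#' `straight_s` seconds is walked in a straight line (cumulative absolute
#' heading change at most `straight_max_turn_deg`). Straight walking of
#' that length is very unlikely inside a constrained home environment. One
#' event per qualifying bout, stamped at the bout start.
#'
#' @param bouts Data frame of bouts from [extract_stepping_bouts()].
#' @param long_s Duration threshold in seconds (transition if strictly
#'   exceeded; default 60).
#' @param straight_s Straight-line duration threshold in seconds (default
#'   25).
#' @param straight_max_turn_deg Maximum cumulative absolute heading change
#'   (degrees) for a segment to count as straight (default 30).
#' @param heading Optional data frame `time`, `heading_deg` sampled during
#'   walking.
#' @return Data frame of events: `time` (bout start), `rule` (factor
#'   long_bout/straight_line).
#' @export
detect_transitions <- function(bouts, long_s = 60, straight_s = 25,
                               straight_max_turn_deg = 30, heading = NULL) {
  n <- nrow(bouts)
  time <- numeric(0)
  rule <- character(0)
  ht <- if (!is.null(heading)) as.numeric(clock_time(heading$time))
  for (i in seq_len(n)) {
    if (bouts$duration[i] > long_s) {
      time <- c(time, as.numeric(bouts$start[i]))
      rule <- c(rule, "long_bout")
    } else if (!is.null(heading)) {
      s <- as.numeric(bouts$start[i]); e <- as.numeric(bouts$end[i])
      sel <- which(ht >= s & ht <= e)
      if (length(sel) >= 2L &&
          straight_span(ht[sel], heading$heading_deg[sel],
                        straight_max_turn_deg) >= straight_s) {
        time <- c(time, s)
        rule <- c(rule, "straight_line")
      }
    }
  }
  data.frame(time = clock_time(time),
             rule = factor(rule, levels = c("long_bout", "straight_line")))
}

# Longest time span (s) over which the summed absolute heading change stays
# within max_turn. Two-pointer over the cumulative turn, which is monotone.
straight_span <- function(t, h, max_turn) {
  dh <- diff(h)
  dh <- (dh + 180) %% 360 - 180      # wrap to (-180, 180]
  cum <- c(0, cumsum(abs(dh)))
  best <- 0
  lo <- 1L
  for (hi in seq_along(cum)) {
    while (cum[hi] - cum[lo] > max_turn) lo <- lo + 1L
    best <- max(best, t[hi] - t[lo])
  }
  best
}

#' Detect sleep periods from dominant labels
#'
#' Sleep periods are maximal runs of epochs dominated by `primary_lying`,
#' allowing interruptions (other classes or missing epochs) of at most
#' `interruption_tol_min` minutes, with a total duration of at least
#' `min_sleep_hours`. The period overlapping the nightly anchor window is
#' each day's main sleep, used to anchor the home/away state machine.
#'
#' @param labels Data frame from [label_dominant()].
#' @param min_sleep_hours Minimum period duration in hours (default 3).
#' @param interruption_tol_min Minutes of non-lying interruption merged
#'   into a period (default 15).
#' @return Data frame of periods: `start`, `end`, `duration_h`.
#' @export
detect_sleep <- function(labels, min_sleep_hours = 3,
                         interruption_tol_min = 15) {
  if (nrow(labels) == 0L) {
    return(data.frame(start = clock_time(numeric(0)),
                      end = clock_time(numeric(0)), duration_h = numeric(0)))
  }
  tt <- as.numeric(labels$epoch_start)
  grid <- seq(tt[1L], tt[length(tt)], by = 60)
  lying <- rep(FALSE, length(grid))
  lying[match(tt, grid)] <- labels$label == "primary_lying"
  r <- rle(lying)
  # merge short non-lying runs sandwiched between lying runs
  if (length(r$lengths) > 2L) {
    for (i in 2:(length(r$lengths) - 1L)) {
      if (!r$values[i] && r$lengths[i] <= interruption_tol_min) {
        r$values[i] <- TRUE
      }
    }
  }
  lying2 <- inverse.rle(r)
  r2 <- rle(lying2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values & r2$lengths >= min_sleep_hours * 60
  data.frame(
    start = clock_time(grid[starts[keep]]),
    end = clock_time(grid[ends[keep]] + 60),
    duration_h = r2$lengths[keep] / 60)
}

#' Classify each day's time into at-home and away-from-home
#'
#' Sleep-anchored classification of community participation: after each
#' main sleep the participant is at home; the first transition event after
#' sleep marks leaving home and the final transition before the next sleep
#' marks returning. Between those anchors every transition toggles the
#' home/away state (the minimal extension consistent with multiple daily
#' excursions); with an odd transition count the final away interval closes
#' at the returning anchor. `anchors_only` mode instead reports the span
#' from first to last transition as the day's away ("active") hours.
#'
#' Days are midnight to midnight; away intervals are clipped to the day.
#' Only days with more than `min_observed_hours` of monitor data (non-
#' missing, non-non_wear epochs) are flagged valid for group summaries.
#'
#' @param transitions Data frame from [detect_transitions()].
#' @param sleep Data frame from [detect_sleep()].
#' @param table The `behaviour_epochs` table (for observed hours).
#' @param mode `"toggle"` (default) or `"anchors_only"`.
#' @param min_observed_hours Valid-day threshold in hours (default 20,
#'   strict inequality).
#' @return Data frame, one row per day: `date`, `away_hours`,
#'   `observed_hours`, `valid`, `n_transitions`, `anchored`, plus a
#'   list-column `away_intervals` of two-column start/end matrices
#'   (numeric seconds).
#' @export
classify_home_away <- function(transitions, sleep, table, mode = "toggle",
                               min_observed_hours = 20) {
  mode <- match.arg(mode, c("toggle", "anchors_only"))
  tt <- as.numeric(table$epoch_start)
  days <- sort(unique(floor(tt / 86400) * 86400))
  ev <- sort(as.numeric(transitions$time))
  sl_s <- as.numeric(sleep$start)
  sl_e <- as.numeric(sleep$end)
  res <- lapply(days, function(d0) {
    d1 <- d0 + 86400
    # wake anchor: latest sleep end in the day's morning half
    wk <- sl_e[sl_e >= d0 & sl_e <= d0 + 14 * 3600]
    # bed anchor: first sleep start from afternoon up to early next day
    bd <- sl_s[sl_s >= d0 + 14 * 3600 & sl_s <= d1 + 4 * 3600]
    anchored <- length(wk) > 0L && length(bd) > 0L
    in_day <- tt >= d0 & tt < d1
    observed <- sum(60 - table$non_wear[in_day]) / 3600
    away <- matrix(numeric(0), ncol = 2)
    if (anchored) {
      wake <- max(wk)
      bed <- min(bd)
      e <- ev[ev >= wake & ev <= bed]
      if (length(e) >= 2L) {
        if (mode == "anchors_only") {
          away <- matrix(c(e[1L], e[length(e)]), ncol = 2)
        } else {
          k <- length(e) %/% 2L
          away <- cbind(e[2L * seq_len(k) - 1L], e[2L * seq_len(k)])
        }
      }
      if (nrow(away)) {
        away[, 1L] <- pmax(away[, 1L], d0)
        away[, 2L] <- pmin(away[, 2L], d1)
        away <- away[away[, 2L] > away[, 1L], , drop = FALSE]
      }
    }
    data.frame(
      date = as.Date(clock_time(d0)),
      away_hours = sum(away[, 2L] - away[, 1L]) / 3600,
      observed_hours = observed,
      valid = observed > min_observed_hours,
      n_transitions = sum(ev >= d0 & ev < d1),
      anchored = anchored,
      away_intervals = I(list(away)))
  })
  do.call(rbind, res)
}
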