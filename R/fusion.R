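#' Align the wrist and thigh streams on one clock
#'
#' Shifts the thigh behaviour table by the supplied clock offset (thigh
#' clock minus wrist clock, in seconds), snaps it onto the wrist epoch
#' grid, and computes the span of simultaneous coverage. The offset comes
#' from configuration (the monitors' clocks are assessed externally);
#' [estimate_clock_offset()] offers an advisory estimate that is never
#' silently applied.
#'
#' @param wear A `wear_mask` from [detect_wear()].
#' @param behaviour A `behaviour_epochs` table.
#' @param offset Seconds by which the thigh clock leads the wrist clock.
#' @return An `aligned_streams` list: `wear`, `behaviour` (shifted and
#'   snapped), `applied_offset`, `overlap` (start/end `POSIXct`).
#' @export
align_streams <- function(wear, behaviour, offset = 0) {
  b <- behaviour
  shifted <- as.numeric(b$epoch_start) - offset
  b$epoch_start <- clock_time(round(shifted / 60) * 60)
  ws <- as.numeric(wear$epoch_start)
  bs <- as.numeric(b$epoch_start)
  lo <- max(min(ws), min(bs))
  hi <- min(max(ws) + 60, max(bs) + 60)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("alignment error: streams have no simultaneous coverage",
         call. = FALSE)
  }
  structure(list(wear = wear, behaviour = b, applied_offset = offset,
                 overlap = clock_time(c(lo, hi))),
            class = "aligned_streams")
}

#' Advisory clock-offset estimate
#'
#' Cross-correlates the wrist vector magnitude with thigh steps per minute
#' over integer-minute lags and reports the lag maximising the correlation.
#' Advisory only: the estimate is returned, never applied.
#'
#' @param series A `count_epochs` data frame.
#' @param behaviour A `behaviour_epochs` table.
#' @param max_lag_min Largest lag searched, in minutes (default 10).
#' @return List: `offset_s` (estimated thigh-minus-wrist offset, seconds),
#'   `correlation` at that lag.
#' @export
estimate_clock_offset <- function(series, behaviour, max_lag_min = 10) {
  ws <- as.numeric(series$epoch_start)
  bs <- as.numeric(behaviour$epoch_start)
  lags <- seq(-max_lag_min, max_lag_min) * 60
  best <- c(lag = 0, cor = -Inf)
  for (lag in lags) {
    common <- intersect(ws, bs - lag)
    if (length(common) < 10L) next
    v <- series$vm[match(common, ws)]
    st <- behaviour$steps[match(common + lag, bs)]
    if (stats::sd(v) == 0 || stats::sd(st) == 0) next
    r <- stats::cor(v, st)
    if (r > best["cor"]) best <- c(lag = lag, cor = r)
  }
  list(offset_s = unname(best["lag"]), correlation = unname(best["cor"]))
}

#' Stepping in the 30-minute windows around don/doff events
#'
#' For each donning and doffing event, counts the 60-s behaviour epochs in
#' which the participant was stepping within the window before
#' (`[t - 30 min, t)`) and after (`(t, t + 30 min]`) the event. A window is
#' flagged incomplete — and later excluded from group means — when any of
#' its epochs is missing or monitor non-wear, or when an adjacent event
#' falls inside it.
#'
#' @param aligned An `aligned_streams` object from [align_streams()].
#' @param events Data frame of events from [extract_events()].
#' @param window_min Window length in minutes (default 30).
#' @param epoch_rule `"any_stepping"` (stepping seconds > 0, default) or
#'   `"dominant_stepping"` (stepping is the dominant class).
#' @return Data frame, one row per event: `time`, `kind`,
#'   `pre_stepping_min`, `post_stepping_min`, `complete`.
#' @export
stepping_around_events <- function(aligned, events, window_min = 30,
                                   epoch_rule = "any_stepping") {
  epoch_rule <- match.arg(epoch_rule, c("any_stepping", "dominant_stepping"))
  b <- aligned$behaviour
  bt <- as.numeric(b$epoch_start)
  stepping <- if (epoch_rule == "any_stepping") {
    b$stepping > 0
  } else {
    label_dominant(b)$label == "stepping"
  }
  nonwear <- b$non_wear >= 30
  et <- as.numeric(events$time)
  w <- window_min * 60
  n_ep <- as.integer(window_min)
  out <- lapply(seq_along(et), function(i) {
    t <- et[i]
    pre_idx <- match(seq(t - w, t - 60, by = 60), bt)
    post_idx <- match(seq(t, t + w - 60, by = 60), bt)
    pre_ok <- !is.na(pre_idx)
    post_ok <- !is.na(post_idx)
    neighbour <- any(abs(et[-i] - t) < w)
    complete <- all(pre_ok) && all(post_ok) &&
      !any(nonwear[pre_idx[pre_ok]]) && !any(nonwear[post_idx[post_ok]]) &&
      !neighbour &&
      t - w >= as.numeric(aligned$overlap[1L]) &&
      t + w <= as.numeric(aligned$overlap[2L])
    data.frame(time = clock_time(t), kind = events$kind[i],
               pre_stepping_min = sum(stepping[pre_idx[pre_ok]]),
               post_stepping_min = sum(stepping[post_idx[post_ok]]),
               complete = complete)
  })
  if (!length(out)) {
    return(data.frame(time = clock_time(numeric(0)),
                      kind = factor(character(0), c("don", "doff")),
                      pre_stepping_min = numeric(0),
                      post_stepping_min = numeric(0), complete = logical(0)))
  }
  do.call(rbind, out)
}

#' Group-level pre/post stepping summary
#'
#' Averages the pre- and post-event stepping minutes per participant
#' group, monitoring phase and event kind, using complete windows only.
#' Group-phase cells without events are reported as missing (`NA`), never
#' zero.
#'
#' @param stats Named list (by participant id) of data frames from
#'   [stepping_around_events()], or a single data frame with a
#'   `participant_id` column.
#' @param groups Named character vector mapping participant id to group
#'   (e.g. `"previous_user"`, `"new_user"`).
#' @param phases Named character vector mapping participant id to
#'   monitoring phase (e.g. `"T0"`, `"T1"`, `"T2"`), or a single phase
#'   label applied to all.
#' @return List with `summary` (per group x phase x kind: mean pre/post
#'   minutes, event and participant counts) and `participants`
#'   (per-participant means).
#' @export
aggregate_group <- function(stats, groups, phases = "T1") {
  if (is.data.frame(stats)) {
    stopifnot("participant_id" %in% names(stats))
    df <- stats
  } else {
    df <- do.call(rbind, lapply(names(stats), function(id) {
      s <- stats[[id]]
      if (nrow(s)) s$participant_id <- id
      else s$participant_id <- character(0)
      s
    }))
  }
  df$group <- unname(groups[df$participant_id])
  df$phase <- if (length(phases) == 1L && is.null(names(phases))) {
    phases
  } else {
    unname(phases[df$participant_id])
  }
  used <- df[df$complete, , drop = FALSE]
  per_part <- if (nrow(used)) {
    aggregate(cbind(pre_stepping_min, post_stepping_min) ~
                participant_id + group + phase + kind,
              data = used, FUN = mean)
  } else {
    data.frame(participant_id = character(0), group = character(0),
               phase = character(0), kind = character(0),
               pre_stepping_min = numeric(0), post_stepping_min = numeric(0))
  }
  cells <- expand.grid(group = sort(unique(stats::na.omit(unname(groups)))),
                       phase = sort(unique(df$phase)),
                       kind = c("don", "doff"),
                       stringsAsFactors = FALSE)
  summ <- cells
  summ$mean_pre_stepping_min <- NA_real_
  summ$mean_post_stepping_min <- NA_real_
  summ$n_events <- 0L
  summ$n_participants <- 0L
  if (nrow(used)) {
    for (i in seq_len(nrow(summ))) {
      sel <- used$group == summ$group[i] & used$phase == summ$phase[i] &
        used$kind == summ$kind[i]
      if (any(sel)) {
        summ$mean_pre_stepping_min[i] <- mean(used$pre_stepping_min[sel])
        summ$mean_post_stepping_min[i] <- mean(used$post_stepping_min[sel])
        summ$n_events[i] <- sum(sel)
        summ$n_participants[i] <- length(unique(used$participant_id[sel]))
      }
    }
  }
  list(summary = summ, participants = per_part)
}
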