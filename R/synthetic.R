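# Synthetic free-living cohort generator. Produces ground-truth daily
# schedules (sleep, home/away excursions bounded by transition walks,
# prosthesis wear intervals, stepping bouts) and renders them as raw wrist
# signal and thigh behaviour epochs, so the whole pipeline is testable
# against known truth. The wrist renderer works at the signal level so the
# count-emulation stage is exercised, never bypassed.

#' Synthetic cohort configuration
#'
#' Defaults describe a small free-living cohort of upper-limb prosthesis
#' users: one main nightly sleep, one or two away-from-home excursions per
#' day bounded by >60-s transition walks, prosthesis donning tied to
#' departure, and group-phase daily wear-hour targets that loosely imitate
#' previous users (stable, ~11 h/day) versus new users (low shortly after
#' fitting, rising months later). These are configuration, not field-data
#' truth.
#'
#' @param n_participants Cohort size (default 8).
#' @param n_days Monitored days per participant (default 7).
#' @param seed Master seed; every random draw derives from it.
#' @param start_date First monitored day (local midnight anchor).
#' @param phase Monitoring phase label: `"T0"`, `"T1"` or `"T2"`.
#' @param group_mix Fraction of participants who are previous prosthesis
#'   users (listed first; default 0.5).
#' @param wear_hours_mean Named list (`previous_user`, `new_user`) of
#'   per-phase daily wear-hour means.
#' @param wear_hours_sd Between-day SD of the daily wear-hour target.
#' @param don_at_departure_prob Probability that an excursion is bracketed
#'   by a don within 10 min before departure and a doff within 30 min
#'   after return (default 1).
#' @param excursions_per_day Integer range (min, max) of daily excursions.
#' @param excursion_duration_h Range of excursion durations in hours.
#' @param depart_lead_min Range of don-to-departure lead, minutes (< 10).
#' @param return_doff_lag_min Range of return-to-doff lag, minutes (< 30).
#' @param sleep_start,sleep_end Nominal bed and wake clock times.
#' @param sleep_jitter_sd_min SD of nightly jitter on both, minutes.
#' @param transition_walk_s Range of boundary transition-walk durations,
#'   seconds (at least 225, so that minute epochs always reconstruct a
#'   bout longer than 60 s whatever the walk's phase on the epoch grid).
#' @param home_bouts_per_h,away_bouts_per_h Short stepping-bout rates at
#'   home / away (bouts per waking hour).
#' @param home_bout_s,away_bout_s Ranges of short-bout durations, seconds
#'   (kept below 55 s so they can never register as transitions).
#' @param cadence_spm Range of stepping cadence, steps per minute.
#' @param noise_sd_g Wrist sensor noise SD in g (sub-dead-band).
#' @param burst_amp_g Amplitude of worn-period movement bursts in g (must
#'   exceed the count dead-band after band-pass filtering).
#' @param burst_period_min Minutes between movement bursts while worn
#'   (below half the non-wear run threshold, so worn time is never
#'   misread as non-wear).
#' @param burst_dur_s Movement-burst duration, seconds.
#' @param min_wear_gap_min Minimum doffed gap between wear intervals,
#'   minutes (at or above the detector's run threshold so intended
#'   non-wear is always detectable).
#' @param tail_hours Hours of recording rendered past the last analysis
#'   day's midnight (default 10), so the final night's sleep is fully
#'   observed and can anchor the last day's home/away classification —
#'   mirroring field deployments where monitors are collected the morning
#'   after the final day.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 8, n_days = 7, seed = 20259,
                          start_date = "2024-03-04", phase = "T1",
                          group_mix = 0.5,
                          wear_hours_mean = list(
                            previous_user = c(T0 = 10.6, T1 = 11.0, T2 = 13.6),
                            new_user = c(T0 = 0, T1 = 4.5, T2 = 9.4)),
                          wear_hours_sd = 1.5,
                          don_at_departure_prob = 1,
                          excursions_per_day = c(1, 2),
                          excursion_duration_h = c(1.5, 4),
                          depart_lead_min = c(2, 8),
                          return_doff_lag_min = c(5, 25),
                          sleep_start = "22:00", sleep_end = "06:30",
                          sleep_jitter_sd_min = 30,
                          transition_walk_s = c(240, 360),
                          home_bouts_per_h = 2, home_bout_s = c(15, 40),
                          away_bouts_per_h = 6, away_bout_s = c(20, 50),
                          cadence_spm = c(90, 115),
                          noise_sd_g = 0.003, burst_amp_g = 0.5,
                          burst_period_min = 15, burst_dur_s = 60,
                          min_wear_gap_min = 70, tail_hours = 10) {
  cfg <- as.list(environment())
  phase <- match.arg(phase, c("T0", "T1", "T2"))
  if (don_at_departure_prob < 0 || don_at_departure_prob > 1) {
    stop("generation error: don_at_departure_prob must be in [0, 1]",
         call. = FALSE)
  }
  pos <- c("n_participants", "n_days", "wear_hours_sd", "home_bouts_per_h",
           "away_bouts_per_h", "noise_sd_g", "burst_amp_g",
           "burst_period_min", "burst_dur_s", "min_wear_gap_min")
  for (p in pos) {
    if (any(cfg[[p]] < 0)) stop("generation error: ", p, " must be >= 0",
                                call. = FALSE)
  }
  if (min(transition_walk_s) < 225) {
    # a walk of D s starting at any phase keeps at least D - 110 s inside
    # full >=55-s epochs, so D >= 225 guarantees a reconstructed bout > 60 s
    stop("generation error: transition walks must be at least 225 s so ",
         "minute epochs always reconstruct a bout longer than 60 s",
         call. = FALSE)
  }
  if (max(home_bout_s) >= 55 || max(away_bout_s) >= 55) {
    stop("generation error: short bouts must stay below 55 s", call. = FALSE)
  }
  if (max(depart_lead_min) > 10 || max(return_doff_lag_min) > 30) {
    stop("generation error: don lead must be <= 10 min and doff lag <= 30 min",
         call. = FALSE)
  }
  waking_h <- (hm_sec(sleep_start) - hm_sec(sleep_end)) / 3600
  if (max(unlist(wear_hours_mean)) > waking_h + 1) {
    stop("generation error: wear-hour target exceeds the waking span",
         call. = FALSE)
  }
  if (max(excursions_per_day) * max(excursion_duration_h) > waking_h - 2) {
    stop("generation error: excursions exceed the waking span", call. = FALSE)
  }
  cfg$phase <- phase
  structure(cfg, class = "cohort_config")
}

hm_sec <- function(hm) {
  p <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1L]])
  p[1L] * 3600 + p[2L] * 60
}

runif_int <- function(n, range) {
  round(runif(n, range[1L], range[2L]))
}

#' Simulate ground-truth schedules for a cohort
#'
#' Draws, per participant and day: the main sleep period, one or more
#' home/away excursions each bounded by a qualifying transition walk,
#' prosthesis wear intervals (excursion-linked with probability
#' `don_at_departure_prob`, topped up with at-home wear blocks towards the
#' group-phase daily target), and short sub-transition stepping bouts at
#' home and away. All schedules are reproducible from the seed and
#' validated against the generator's structural invariants.
#'
#' @param config A [cohort_config()].
#' @return A `truth_cohort`: list with `config`, `groups` (named vector)
#'   and `schedules`, one `truth_schedule` per participant (fields:
#'   `participant_id`, `group`, `phase`, `start`, `n_days`, `days`,
#'   `sleep`, `excursions`, `wear`, `bouts`, `seed`).
#' @export
simulate_truth <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed %% .Machine$integer.max)
  n <- config$n_participants
  n_prev <- round(n * config$group_mix)
  groups <- stats::setNames(
    c(rep("previous_user", n_prev), rep("new_user", n - n_prev)),
    sprintf("P%d", seq_len(n)))
  pseeds <- sample.int(.Machine$integer.max - 1L, n)
  schedules <- lapply(seq_len(n), function(i) {
    simulate_participant(sprintf("P%d", i), groups[[i]], pseeds[i], config)
  })
  names(schedules) <- names(groups)
  out <- structure(list(config = config, groups = groups,
                        schedules = schedules),
                   class = "truth_cohort")
  for (s in schedules) validate_truth(s, config)
  out
}

simulate_participant <- function(id, group, pseed, config) {
  set.seed(pseed)
  t0 <- as.numeric(clock_time(config$start_date))
  nd <- config$n_days
  jit <- config$sleep_jitter_sd_min * 60
  day0 <- t0 + (seq_len(nd + 1L) - 1L) * 86400
  wake <- round(pmin(pmax(
    day0 + hm_sec(config$sleep_end) + rnorm(nd + 1L, 0, jit),
    day0 + 4 * 3600), day0 + 10 * 3600))
  bed0 <- t0 + (seq_len(nd) - 1L) * 86400
  bed <- round(pmin(pmax(bed0 + hm_sec(config$sleep_start) + rnorm(nd, 0, jit),
                         bed0 + 19 * 3600), bed0 + 23.5 * 3600))
  # the final sleep runs into the rendered morning tail
  end_obs <- t0 + nd * 86400 + config$tail_hours * 3600
  sleep <- data.frame(
    start = c(t0, bed),
    end = c(wake[seq_len(nd)], min(wake[nd + 1L], end_obs)))
  wake <- wake[seq_len(nd)]
  target_h <- config$wear_hours_mean[[group]][[config$phase]]
  gap_req <- config$min_wear_gap_min * 60 +
    (max(config$depart_lead_min) + max(config$return_doff_lag_min)) * 60 + 600
  exc <- list(); wear <- list(); bouts <- list(); targets <- numeric(nd)
  for (d in seq_len(nd)) {
    win_lo <- wake[d] + 1800
    win_hi <- bed[d] - 2700
    k <- sample(seq(config$excursions_per_day[1L],
                    config$excursions_per_day[2L]), 1L)
    repeat {
      dur <- round(runif(k, config$excursion_duration_h[1L],
                         config$excursion_duration_h[2L]) * 3600)
      need <- sum(dur) + (k - 1L) * gap_req
      if (need <= win_hi - win_lo || k == 0L) break
      k <- k - 1L
    }
    departs <- returns <- numeric(0)
    if (k > 0L) {
      slack <- (win_hi - win_lo) - sum(dur) - (k - 1L) * gap_req
      g <- diff(c(0, sort(runif(k)), 1)) * slack
      pos <- win_lo
      for (j in seq_len(k)) {
        dep <- round(pos + g[j])
        departs <- c(departs, dep)
        returns <- c(returns, dep + dur[j])
        pos <- dep + dur[j] + gap_req
      }
    }
    day_exc <- data.frame(day = rep(d, k), depart = departs, return = returns)
    exc[[d]] <- day_exc
    # transition walks bounding each excursion
    if (k > 0L) {
      wd1 <- runif_int(k, config$transition_walk_s)
      wd2 <- runif_int(k, config$transition_walk_s)
      bouts[[length(bouts) + 1L]] <- data.frame(
        start = c(departs, returns), duration = c(wd1, wd2),
        context = rep(c("depart_walk", "return_walk"), each = k))
    }
    # wear intervals
    W <- if (target_h <= 0) 0 else {
      max(0, round(rnorm(1L, target_h, config$wear_hours_sd) * 3600))
    }
    targets[d] <- W / 3600
    day_wear <- matrix(numeric(0), ncol = 2L)
    if (W > 0) {
      linked <- if (k > 0L) {
        runif(k) < config$don_at_departure_prob
      } else logical(0)
      if (any(linked)) {
        don <- departs[linked] - runif_int(sum(linked),
                                           config$depart_lead_min) * 60
        doff <- returns[linked] + runif_int(sum(linked),
                                            config$return_doff_lag_min) * 60
        day_wear <- merge_intervals(cbind(don, doff),
                                    config$min_wear_gap_min * 60)
      }
      base <- sum(day_wear[, 2L] - day_wear[, 1L])
      remaining <- W - base
      if (remaining >= 1200) {
        buffer <- config$min_wear_gap_min * 60 + 120
        blocked <- day_wear
        if (k > 0L) {
          blocked <- rbind(blocked,
                           cbind(departs - 600, returns + 1800))
        }
        free <- free_windows(wake[d], bed[d], blocked, buffer)
        free <- free[order(free[, 2L] - free[, 1L], decreasing = TRUE), ,
                     drop = FALSE]
        for (f in seq_len(min(2L, nrow(free)))) {
          if (remaining < 1200) break
          len <- min(remaining, free[f, 2L] - free[f, 1L])
          if (len < 1200) next
          day_wear <- rbind(day_wear, c(free[f, 1L], free[f, 1L] + len))
          remaining <- remaining - len
        }
        day_wear <- day_wear[order(day_wear[, 1L]), , drop = FALSE]
      }
    }
    if (nrow(day_wear)) {
      wear[[length(wear) + 1L]] <-
        data.frame(don = day_wear[, 1L], doff = day_wear[, 2L])
    }
    # short stepping bouts, kept clear of walks and of each other
    walk_iv <- if (k > 0L) {
      wmax <- max(config$transition_walk_s)
      cbind(c(departs, returns) - 240,
            c(departs, returns) + wmax + 240)
    } else matrix(numeric(0), ncol = 2L)
    away_iv <- if (k > 0L) cbind(departs, returns) else
      matrix(numeric(0), ncol = 2L)
    home_iv <- free_windows(wake[d] + 120, bed[d] - 120,
                            rbind(away_iv, walk_iv), 0)
    away_in <- free_windows(wake[d], bed[d],
                            rbind(complement_iv(away_iv, wake[d], bed[d]),
                                  walk_iv), 0)
    bouts[[length(bouts) + 1L]] <-
      short_bouts(home_iv, config$home_bouts_per_h, config$home_bout_s,
                  "home")
    bouts[[length(bouts) + 1L]] <-
      short_bouts(away_in, config$away_bouts_per_h, config$away_bout_s,
                  "away")
  }
  exc <- do.call(rbind, exc)
  wear <- if (length(wear)) do.call(rbind, wear) else
    data.frame(don = numeric(0), doff = numeric(0))
  bouts <- do.call(rbind, bouts[lengths(bouts) > 0])
  if (is.null(bouts)) {
    bouts <- data.frame(start = numeric(0), duration = numeric(0),
                        context = character(0))
  }
  bouts <- bouts[order(bouts$start), ]
  rownames(bouts) <- NULL
  bouts$cadence <- round(runif(nrow(bouts), config$cadence_spm[1L],
                               config$cadence_spm[2L]))
  structure(
    list(participant_id = id, group = group, phase = config$phase,
         start = t0, n_days = nd,
         days = data.frame(day = seq_len(nd), wake = wake, bed = bed,
                           wear_target_h = targets),
         sleep = sleep, excursions = exc, wear = wear, bouts = bouts,
         seed = pseed),
    class = "truth_schedule")
}

# merge intervals closer than gap (or overlapping); m is a 2-col matrix
merge_intervals <- function(m, gap = 0) {
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] - out[nrow(out), 2L] < gap) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

# windows of [lo, hi] at least `buffer` away from every blocked interval
free_windows <- function(lo, hi, blocked, buffer) {
  if (hi <= lo) return(matrix(numeric(0), ncol = 2L))
  if (!nrow(blocked)) return(matrix(c(lo, hi), ncol = 2L))
  b <- merge_intervals(cbind(blocked[, 1L] - buffer, blocked[, 2L] + buffer))
  complement_iv(b, lo, hi)
}

complement_iv <- function(iv, lo, hi) {
  if (!nrow(iv)) return(matrix(c(lo, hi), ncol = 2L))
  iv <- merge_intervals(iv[order(iv[, 1L]), , drop = FALSE])
  edges <- c(lo, t(iv), hi)
  starts <- edges[seq(1L, length(edges), by = 2L)]
  ends <- edges[seq(2L, length(edges), by = 2L)]
  keep <- ends - starts > 0
  cbind(starts[keep], ends[keep])
}

# short (< 55 s) stepping bouts inside the given windows, starts >= 150 s
# apart so no two bouts can load the same or adjacent minute epochs
short_bouts <- function(windows, per_h, dur_range, context) {
  out <- list()
  for (w in seq_len(nrow(windows))) {
    len <- windows[w, 2L] - windows[w, 1L]
    if (len < 300) next
    n <- stats::rpois(1L, len / 3600 * per_h)
    if (n == 0L) next
    starts <- sort(round(runif(n, windows[w, 1L], windows[w, 2L] - 60)))
    keep <- c(TRUE, diff(starts) >= 150)
    starts <- starts[keep]
    out[[w]] <- data.frame(start = starts,
                           duration = runif_int(length(starts), dur_range),
                           context = context)
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), duration = numeric(0),
                      context = character(0)))
  }
  do.call(rbind, out)
}

# structural invariants of a generated schedule; violations are generator
# bugs, surfaced as generation errors
validate_truth <- function(s, config) {
  chk <- function(ok, msg) if (!ok) stop("generation error: ", msg,
                                         call. = FALSE)
  cols <- list(sleep = c("start", "end"),
               excursions = c("depart", "return"),
               wear = c("don", "doff"))
  for (nm in names(cols)) {
    iv <- s[[nm]]
    if (nrow(iv) > 1L) {
      a <- iv[[cols[[nm]][1L]]]; b <- iv[[cols[[nm]][2L]]]
      o <- order(a)
      chk(all(a[o][-1L] >= b[o][-length(b)]), paste(nm, "intervals overlap"))
    }
  }
  if (nrow(s$excursions)) {
    for (i in seq_len(nrow(s$excursions))) {
      dep <- s$excursions$depart[i]; ret <- s$excursions$return[i]
      chk(any(s$bouts$start == dep & s$bouts$duration >= 225),
          "departure not bounded by a qualifying walk")
      chk(any(s$bouts$start == ret & s$bouts$duration >= 225),
          "return not bounded by a qualifying walk")
    }
  }
  if (nrow(s$wear) > 1L) {
    gaps <- s$wear$don[-1L] - s$wear$doff[-nrow(s$wear)]
    chk(all(gaps >= config$min_wear_gap_min * 60),
        "doffed gap shorter than the non-wear run threshold")
  }
  invisible(TRUE)
}

#' @export
print.truth_schedule <- function(x, ...) {
  cat(sprintf(
    "<truth_schedule> %s (%s, %s): %d days, %d excursions, %d wear intervals, %d stepping bouts\n",
    x$participant_id, x$group, x$phase, x$n_days, nrow(x$excursions),
    nrow(x$wear), nrow(x$bouts)))
  invisible(x)
}

#' @export
print.truth_cohort <- function(x, ...) {
  cat(sprintf("<truth_cohort> %d participants x %d days (phase %s, seed %d)\n",
              x$config$n_participants, x$config$n_days, x$config$phase,
              x$config$seed))
  invisible(x)
}

#' Render the wrist signal of a truth schedule
#'
#' Generates the 50 Hz tri-axial wrist recording implied by a schedule:
#' while doffed, a fixed gravity orientation plus sub-dead-band sensor
#' noise (so emulated counts are exactly zero); while worn, a different
#' orientation, noise, and gait-band (1-3 Hz) movement bursts at the don
#' and doff boundaries, periodically in between, and during stepping bouts
#' — oscillations that survive the count band-pass filter and register
#' counts. Reproducible from the schedule's seed.
#'
#' @param truth A `truth_schedule`.
#' @param config The [cohort_config()] used to generate it.
#' @param days Integer vector of consecutive day numbers to render
#'   (default: all days).
#' @param rate Output sampling rate in Hz (default 50).
#' @return A [raw_triaxial()] recording covering the requested days.
#' @export
render_wrist <- function(truth, config, days = NULL, rate = 50) {
  if (is.null(days)) days <- seq_len(truth$n_days)
  stopifnot(all(diff(days) == 1L), all(days >= 1L),
            all(days <= truth$n_days))
  day_len <- rep(86400, length(days))
  if (days[length(days)] == truth$n_days && config$tail_hours > 0) {
    days <- c(days, truth$n_days + 1L)
    day_len <- c(day_len, config$tail_hours * 3600)
  }
  blocks <- lapply(seq_along(days), function(k) {
    d <- days[k]
    set.seed((truth$seed + d * 131L) %% .Machine$integer.max)
    d0 <- truth$start + (d - 1L) * 86400
    n <- as.integer(day_len[k] * rate)
    tt <- (seq_len(n) - 1L) / rate
    x <- rnorm(n, 0, config$noise_sd_g)
    y <- rnorm(n, 0, config$noise_sd_g)
    z <- rnorm(n, 1, config$noise_sd_g)
    wear <- clip_iv(as.matrix(truth$wear), d0, d0 + day_len[k])
    if (nrow(wear)) {
      for (i in seq_len(nrow(wear))) {
        idx <- iv_index(wear[i, 1L], wear[i, 2L], d0, rate, n)
        # worn orientation differs from the resting pose
        x[idx] <- x[idx] + 0.71
        z[idx] <- z[idx] - 0.29
      }
      bursts <- wear_bursts(truth, wear, config)
      for (i in seq_len(nrow(bursts))) {
        idx <- iv_index(bursts[i, 1L], bursts[i, 2L], d0, rate, n)
        if (!length(idx)) next
        ph <- runif(2L, 0, 2 * pi)
        amp <- config$burst_amp_g
        x[idx] <- x[idx] + amp * sin(2 * pi * 1.8 * tt[idx] + ph[1L])
        y[idx] <- y[idx] + 0.6 * amp * sin(2 * pi * 1.2 * tt[idx] + ph[2L])
      }
    }
    cbind(x, y, z)
  })
  samples <- do.call(rbind, blocks)
  raw_triaxial(truth$start + (days[1L] - 1L) * 86400, rate, samples,
               device_range = 16, participant_id = truth$participant_id,
               body_site = "prosthetic_wrist")
}

clip_iv <- function(iv, lo, hi) {
  if (!nrow(iv)) return(iv)
  a <- pmax(iv[, 1L], lo); b <- pmin(iv[, 2L], hi)
  keep <- b > a
  cbind(a[keep], b[keep])
}

iv_index <- function(a, b, d0, rate, n) {
  i0 <- max(1L, floor((a - d0) * rate) + 1L)
  i1 <- min(n, ceiling((b - d0) * rate))
  if (i1 < i0) integer(0) else i0:i1
}

# movement-burst windows within worn time: boundary bursts at don/doff,
# periodic bursts in between, and arm swing during stepping bouts
wear_bursts <- function(truth, wear, config) {
  out <- list()
  bd <- config$burst_dur_s
  for (i in seq_len(nrow(wear))) {
    don <- wear[i, 1L]; doff <- wear[i, 2L]
    b <- rbind(c(don, min(don + bd, doff)),
               c(max(doff - bd, don), doff))
    period <- config$burst_period_min * 60
    mids <- seq(don + period, doff - 60, by = period)
    if (length(mids)) b <- rbind(b, cbind(mids, pmin(mids + bd, doff)))
    out[[i]] <- b
  }
  b <- do.call(rbind, out)
  if (nrow(truth$bouts)) {
    sb <- clip_iv(cbind(truth$bouts$start,
                        truth$bouts$start + truth$bouts$duration),
                  -Inf, Inf)
    worn_b <- list()
    for (i in seq_len(nrow(wear))) {
      worn_b[[i]] <- clip_iv(sb, wear[i, 1L], wear[i, 2L])
    }
    b <- rbind(b, do.call(rbind, worn_b))
  }
  b
}

#' Render the thigh behaviour epoch table of a truth schedule
#'
#' Produces the per-minute thigh epoch table implied by a schedule: sleep
#' time is primary lying, stepping bouts are stepping with steps at the
#' bout cadence, remaining away time is upright and remaining at-home
#' waking time sedentary. Every row's class seconds sum to exactly 60.
#'
#' @inheritParams render_wrist
#' @return A `behaviour_epochs` table covering the requested days.
#' @export
render_thigh <- function(truth, config, days = NULL) {
  if (is.null(days)) days <- seq_len(truth$n_days)
  stopifnot(all(diff(days) == 1L), all(days >= 1L),
            all(days <= truth$n_days))
  cls <- behaviour_classes()
  day_len <- rep(86400L, length(days))
  if (days[length(days)] == truth$n_days && config$tail_hours > 0) {
    days <- c(days, truth$n_days + 1L)
    day_len <- c(day_len, as.integer(config$tail_hours * 3600))
  }
  blocks <- lapply(seq_along(days), function(k) {
    d <- days[k]
    d0 <- truth$start + (d - 1L) * 86400
    n_sec <- day_len[k]
    n_ep <- n_sec %/% 60L
    sec <- rep(match("sedentary", cls), n_sec)
    paint <- function(iv, class) {
      iv <- clip_iv(iv, d0, d0 + n_sec)
      for (i in seq_len(nrow(iv))) {
        sec[(iv[i, 1L] - d0 + 1L):(iv[i, 2L] - d0)] <<- match(class, cls)
      }
    }
    paint(as.matrix(truth$excursions[, c("depart", "return")]), "upright")
    paint(as.matrix(truth$sleep), "primary_lying")
    steps_sec <- numeric(n_sec)
    if (nrow(truth$bouts)) {
      biv <- cbind(truth$bouts$start, truth$bouts$start + truth$bouts$duration)
      for (i in seq_len(nrow(biv))) {
        civ <- clip_iv(biv[i, , drop = FALSE], d0, d0 + n_sec)
        if (!nrow(civ)) next
        idx <- (civ[1L, 1L] - d0 + 1L):(civ[1L, 2L] - d0)
        sec[idx] <- match("stepping", cls)
        steps_sec[idx] <- truth$bouts$cadence[i] / 60
      }
    }
    ep <- rep(seq_len(n_ep), each = 60L)
    m <- vapply(seq_along(cls), function(ci) {
      as.numeric(rowsum(as.numeric(sec == ci), ep, reorder = FALSE))
    }, numeric(n_ep))
    colnames(m) <- cls
    steps <- round(as.numeric(rowsum(steps_sec, ep, reorder = FALSE)))
    steps[m[, "stepping"] == 0] <- 0
    df <- data.frame(epoch_start = clock_time(d0 + (seq_len(n_ep) - 1L) * 60))
    df <- cbind(df, as.data.frame(m))
    df$steps <- steps
    df
  })
  behaviour_epochs(do.call(rbind, blocks))
}
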