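#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a ground-truth cohort, renders each participant's wrist
#' signal and thigh epoch table, and runs every analysis stage: count
#' emulation, wear detection, don/doff events, daily wear summary,
#' stepping bouts, transitions, sleep, home/away classification, stream
#' alignment, event-window stepping, and the group summary. Rendering and
#' count emulation proceed day by day so memory stays bounded.
#'
#' @param config A [cohort_config()].
#' @param cparams A [count_params()].
#' @param nwparams A [nonwear_params()].
#' @param offset_s Thigh-minus-wrist clock offset passed to
#'   [align_streams()] (default 0; the renderers share one clock).
#' @return A `cohort_results` list: `truth`, `participants` (per id:
#'   `mask`, `events`, `wear_daily`, `thigh`, `bouts`, `transitions`,
#'   `sleep`, `participation`, `window_stats`), and pooled tables
#'   `wear_daily`, `participation`, `window_stats`, plus `group_summary`.
#' @export
run_cohort_pipeline <- function(config = cohort_config(),
                                cparams = count_params(),
                                nwparams = nonwear_params(),
                                offset_s = 0) {
  truth <- simulate_truth(config)
  parts <- lapply(truth$schedules, function(s) {
    counts <- do.call(rbind, lapply(seq_len(s$n_days), function(d) {
      emulate_counts(render_wrist(s, config, days = d), cparams)
    }))
    class(counts) <- c("count_epochs", "data.frame")
    attr(counts, "epoch_length") <- cparams$epoch_length
    mask <- detect_wear(counts, nwparams)
    events <- extract_events(mask)
    wear_daily <- daily_wear_summary(mask)
    thigh <- render_thigh(s, config)
    labels <- label_dominant(thigh)
    bouts <- extract_stepping_bouts(thigh)
    transitions <- detect_transitions(bouts)
    sleep <- detect_sleep(labels)
    participation <- classify_home_away(transitions, sleep, thigh)
    aligned <- align_streams(mask, thigh, offset = offset_s)
    window_stats <- stepping_around_events(aligned, events)
    list(mask = mask, events = events, wear_daily = wear_daily,
         thigh = thigh, bouts = bouts, transitions = transitions,
         sleep = sleep, participation = participation,
         window_stats = window_stats)
  })
  pool <- function(field) {
    do.call(rbind, lapply(names(parts), function(id) {
      df <- parts[[id]][[field]]
      if (nrow(df)) df$participant_id <- id else df$participant_id <- character(0)
      df
    }))
  }
  agg <- aggregate_group(
    stats::setNames(lapply(parts, `[[`, "window_stats"), names(parts)),
    truth$groups, phases = config$phase)
  structure(
    list(truth = truth, participants = parts,
         wear_daily = pool("wear_daily"),
         participation = pool("participation"),
         window_stats = pool("window_stats"),
         group_summary = agg$summary,
         participant_summary = agg$participants),
    class = "cohort_results")
}

#' Compare pipeline estimates against the generating truth
#'
#' Scores a [run_cohort_pipeline()] result against its own truth
#' schedules: daily wear-hour error, don/doff event matching within a
#' tolerance, daily away-hour error and away-interval Jaccard overlap, and
#' the group mean post-don versus post-doff stepping contrast.
#'
#' @param results A `cohort_results` object.
#' @param event_tol_s Event match tolerance in seconds (default 120).
#' @return List of cohort-level metrics: `wear_mae_h`, `wear_max_err_h`,
#'   `event_match_rate`, `n_events_truth`, `away_mae_h`, `away_max_err_h`,
#'   `mean_jaccard`, `mean_post_don`, `mean_post_doff`, `mean_pre_don`,
#'   `mean_pre_doff`, and per-day tables `wear_days`, `away_days`.
#' @export
evaluate_recovery <- function(results, event_tol_s = 120) {
  truth <- results$truth
  wear_rows <- list(); away_rows <- list()
  matched <- 0L; total_truth <- 0L
  for (id in names(truth$schedules)) {
    s <- truth$schedules[[id]]
    p <- results$participants[[id]]
    for (d in seq_len(s$n_days)) {
      d0 <- s$start + (d - 1L) * 86400
      date <- as.Date(clock_time(d0))
      wiv <- clip_iv(as.matrix(s$wear), d0, d0 + 86400)
      truth_wear <- sum(wiv[, 2L] - wiv[, 1L]) / 3600
      est <- p$wear_daily$wear_hours[p$wear_daily$date == date]
      wear_rows[[length(wear_rows) + 1L]] <- data.frame(
        participant_id = id, date = date, truth_h = truth_wear,
        est_h = if (length(est)) est else 0)
      eiv <- clip_iv(as.matrix(s$excursions[, c("depart", "return")]),
                     d0, d0 + 86400)
      truth_away <- sum(eiv[, 2L] - eiv[, 1L]) / 3600
      pr <- p$participation[p$participation$date == date, ]
      est_away <- if (nrow(pr)) pr$away_hours[1L] else 0
      est_iv <- if (nrow(pr)) pr$away_intervals[[1L]] else
        matrix(numeric(0), ncol = 2L)
      away_rows[[length(away_rows) + 1L]] <- data.frame(
        participant_id = id, date = date, truth_h = truth_away,
        est_h = est_away,
        jaccard = interval_jaccard(eiv, est_iv))
    }
    # event matching: one-to-one greedy match by kind within tolerance
    tr_ev <- rbind(
      data.frame(time = s$wear$don, kind = "don"),
      data.frame(time = s$wear$doff, kind = "doff"))
    total_truth <- total_truth + nrow(tr_ev)
    est_ev <- data.frame(time = as.numeric(p$events$time),
                         kind = as.character(p$events$kind))
    for (k in c("don", "doff")) {
      tt <- sort(tr_ev$time[tr_ev$kind == k])
      ee <- sort(est_ev$time[est_ev$kind == k])
      for (t in tt) {
        if (!length(ee)) break
        j <- which.min(abs(ee - t))
        if (abs(ee[j] - t) <= event_tol_s) {
          matched <- matched + 1L
          ee <- ee[-j]
        }
      }
    }
  }
  wear_days <- do.call(rbind, wear_rows)
  away_days <- do.call(rbind, away_rows)
  gs <- results$group_summary
  wmean <- function(col) {
    ok <- gs$n_events > 0
    if (!any(ok)) return(NA_real_)
    sum(gs[[col]][ok] * gs$n_events[ok]) / sum(gs$n_events[ok])
  }
  don <- gs$kind == "don"; doff <- gs$kind == "doff"
  mean_for <- function(col, sel) {
    ok <- sel & gs$n_events > 0
    if (!any(ok)) return(NA_real_)
    sum(gs[[col]][ok] * gs$n_events[ok]) / sum(gs$n_events[ok])
  }
  list(
    wear_mae_h = mean(abs(wear_days$est_h - wear_days$truth_h)),
    wear_max_err_h = max(abs(wear_days$est_h - wear_days$truth_h)),
    event_match_rate = matched / max(1L, total_truth),
    n_events_truth = total_truth,
    away_mae_h = mean(abs(away_days$est_h - away_days$truth_h)),
    away_max_err_h = max(abs(away_days$est_h - away_days$truth_h)),
    mean_jaccard = mean(away_days$jaccard[away_days$truth_h > 0]),
    mean_post_don = mean_for("mean_post_stepping_min", don),
    mean_post_doff = mean_for("mean_post_stepping_min", doff),
    mean_pre_don = mean_for("mean_pre_stepping_min", don),
    mean_pre_doff = mean_for("mean_pre_stepping_min", doff),
    wear_days = wear_days, away_days = away_days)
}

# Jaccard overlap of two interval sets (2-col matrices, numeric seconds)
interval_jaccard <- function(a, b) {
  if (!nrow(a) && !nrow(b)) return(1)
  if (!nrow(a) || !nrow(b)) return(0)
  inter <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      inter <- inter + max(0, min(a[i, 2L], b[j, 2L]) -
                             max(a[i, 1L], b[j, 1L]))
    }
  }
  la <- sum(a[, 2L] - a[, 1L])
  lb <- sum(b[, 2L] - b[, 1L])
  inter / (la + lb - inter)
}
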