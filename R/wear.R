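#' Non-wear detection parameters
#'
#' Parameters of the run-length non-wear algorithm applied to epoch vector
#' magnitudes. A maximal run of epochs at or below `zero_threshold` lasting
#' at least `min_nonwear_run` minutes is classified as doffed; within a
#' candidate run, up to `spike_tolerance_epochs` isolated (non-adjacent)
#' epochs with `vm <= spike_max_vm` are absorbed.
#'
#' @param zero_threshold Counts; epochs with `vm` at or below this are
#'   "still" (default 0).
#' @param min_nonwear_run Minutes; minimum still-run length to call
#'   non-wear (default 60).
#' @param spike_tolerance_epochs Maximum number of absorbed spike epochs
#'   per run (default 2).
#' @param spike_max_vm Counts; ceiling for an absorbable spike epoch
#'   (default 50).
#' @return An object of class `nonwear_params`.
#' @export
nonwear_params <- function(zero_threshold = 0, min_nonwear_run = 60,
                           spike_tolerance_epochs = 2, spike_max_vm = 50) {
  if (min_nonwear_run < 1) {
    stop("config error: min_nonwear_run must be >= 1", call. = FALSE)
  }
  if (spike_tolerance_epochs < 0) {
    stop("config error: spike_tolerance_epochs must be >= 0", call. = FALSE)
  }
  if (spike_max_vm < zero_threshold) {
    stop("config error: spike_max_vm must be >= zero_threshold",
         call. = FALSE)
  }
  structure(list(zero_threshold = zero_threshold,
                 min_nonwear_run = min_nonwear_run,
                 spike_tolerance_epochs = spike_tolerance_epochs,
                 spike_max_vm = spike_max_vm),
            class = "nonwear_params")
}

# Mark doffed epochs in one gap-free vm segment, union semantics: an epoch
# is doffed iff it lies inside some interval that (i) starts and ends on
# still epochs, (ii) contains only still epochs plus at most K isolated
# spike epochs (vm <= spike_max_vm), and (iii) spans >= min_run epochs.
# Implemented over chains of still-runs separated by single spike epochs.
nonwear_segment <- function(vm, params) {
  n <- length(vm)
  doffed <- logical(n)
  if (n == 0L) return(doffed)
  still <- vm <= params$zero_threshold
  spike <- !still & vm <= params$spike_max_vm
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zi <- which(r$values)            # indices of still-runs in the rle
  if (!length(zi)) return(doffed)
  # chain id: consecutive still-runs joined when separated by exactly one
  # spike epoch
  K <- params$spike_tolerance_epochs
  min_run <- params$min_nonwear_run
  m <- length(zi)
  joined <- logical(m)             # joined[i]: run i connected to run i-1
  if (m > 1L) {
    for (i in 2:m) {
      gap_start <- ends[zi[i - 1L]] + 1L
      gap_end <- starts[zi[i]] - 1L
      joined[i] <- (gap_end == gap_start) && spike[gap_start]
    }
  }
  chain <- cumsum(!joined)
  for (cid in unique(chain)) {
    runs <- zi[chain == cid]
    L <- r$lengths[runs]
    k <- length(runs)
    for (a in seq_len(k)) {
      for (b in a:min(k, a + K)) {
        span <- sum(L[a:b]) + (b - a)      # stills + absorbed spikes
        if (span >= min_run) {
          doffed[starts[runs[a]]:ends[runs[b]]] <- TRUE
        }
      }
    }
  }
  doffed
}

#' Detect prosthesis wear from epoch counts
#'
#' Classifies each 60-s epoch of a count series as `worn`, `doffed` or
#' `no_data` using the run-length non-wear algorithm: long runs of
#' (near-)zero vector magnitude are non-wear of the sensor, which for a
#' prosthesis-mounted sensor is taken as non-wear of the prosthesis. Gaps
#' in the epoch grid become `no_data` and break runs.
#'
#' @param series A `count_epochs` data frame (vm populated), e.g. from
#'   [emulate_counts()].
#' @param params A [nonwear_params()] object.
#' @return A `wear_mask` data frame: `epoch_start`, `state` (factor
#'   worn/doffed/no_data) on the gap-free 60-s grid spanning the series.
#' @export
detect_wear <- function(series, params = nonwear_params()) {
  stopifnot(inherits(params, "nonwear_params"))
  if (!"vm" %in% names(series)) {
    stop("vm not populated; run vector_magnitude() first", call. = FALSE)
  }
  el <- attr(series, "epoch_length")
  if (is.null(el)) el <- 60
  if (nrow(series) == 0L) {
    out <- data.frame(epoch_start = clock_time(numeric(0)),
                      state = factor(character(0),
                                     levels = c("worn", "doffed", "no_data")))
    class(out) <- c("wear_mask", "data.frame")
    attr(out, "epoch_length") <- el
    return(out)
  }
  tt <- as.numeric(series$epoch_start)
  grid <- seq(tt[1L], tt[length(tt)], by = el)
  state <- rep("no_data", length(grid))
  pos <- match(tt, grid)
  present <- !is.na(pos)
  vm_grid <- rep(NA_real_, length(grid))
  vm_grid[pos[present]] <- series$vm[present]
  obs <- !is.na(vm_grid)
  state[obs] <- "worn"
  seg <- rle(obs)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  for (i in which(seg$values)) {
    idx <- seg_start[i]:seg_end[i]
    doff <- nonwear_segment(vm_grid[idx], params)
    state[idx][doff] <- "doffed"
  }
  out <- data.frame(
    epoch_start = clock_time(grid),
    state = factor(state, levels = c("worn", "doffed", "no_data")))
  class(out) <- c("wear_mask", "data.frame")
  attr(out, "epoch_length") <- el
  out
}

#' Extract donning and doffing events from a wear mask
#'
#' A don is a doffed-to-worn transition, a doff a worn-to-doffed
#' transition, stamped at the first epoch of the new state. Transitions
#' into or out of `no_data` (recording boundaries, gaps) generate no
#' events, so the fusion windows never attach behaviour to artefactual
#' boundaries.
#'
#' @param mask A `wear_mask` from [detect_wear()].
#' @return A data frame of events: `time` (epoch boundary), `kind`
#'   (factor don/doff), ordered by time.
#' @export
extract_events <- function(mask) {
  s <- as.character(mask$state)
  n <- length(s)
  ev_time <- numeric(0)
  ev_kind <- character(0)
  if (n > 1L) {
    prev <- s[-n]
    cur <- s[-1L]
    don <- prev == "doffed" & cur == "worn"
    doff <- prev == "worn" & cur == "doffed"
    ev_time <- as.numeric(mask$epoch_start[-1L])[don | doff]
    ev_kind <- ifelse(don[don | doff], "don", "doff")
    o <- order(ev_time)
    ev_time <- ev_time[o]
    ev_kind <- ev_kind[o]
  }
  data.frame(time = clock_time(ev_time),
             kind = factor(ev_kind, levels = c("don", "doff")))
}

#' Daily prosthesis wear summary
#'
#' Hours worn per local calendar day (midnight to midnight), with the
#' observed hours (worn + doffed, i.e. non-missing) reported alongside for
#' valid-day filtering. A day's wear hours are always reported; downstream
#' group averaging applies the observed-hours filter.
#'
#' @param mask A `wear_mask` from [detect_wear()].
#' @param min_observed_hours Hours of observed data a day needs to be
#'   flagged valid (default 20, mirroring the thigh-stream rule).
#' @return Data frame: `date`, `wear_hours`, `observed_hours`, `valid`.
#' @export
daily_wear_summary <- function(mask, min_observed_hours = 20) {
  el <- attr(mask, "epoch_length")
  if (is.null(el)) el <- 60
  day <- floor_day(mask$epoch_start)
  worn <- mask$state == "worn"
  obs <- mask$state != "no_data"
  agg <- aggregate(cbind(wear = worn, obs = obs),
                   by = list(date = as.Date(day)), FUN = sum)
  data.frame(date = agg$date,
             wear_hours = agg$wear * el / 3600,
             observed_hours = agg$obs * el / 3600,
             valid = agg$obs * el / 3600 > min_observed_hours)
}
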