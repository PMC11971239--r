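# Legacy activity-count emulation: the published conversion from raw
# accelerometry to ActiGraph-equivalent counts. Constants below are the
# reference method's versioned table; they are not tuning knobs.

# 21-coefficient IIR approximating the legacy device's analog band-pass
# (~0.25-2.5 Hz at 30 Hz sampling), plus its published gain.
count_bandpass <- function() {
  list(
    b = c(0.049109, -0.12284, 0.14356, -0.11269, 0.053804,
          -0.02023, 0.0063778, 0.018513, -0.038154, 0.048727,
          -0.052577, 0.047847, -0.046015, 0.036283, -0.012977,
          -0.0046262, 0.012835, -0.0093762, 0.0034485, -0.00080972,
          -0.00019623),
    a = c(1, -4.1637, 7.5712, -7.9805, 5.385, -2.4636, 0.89238,
          0.06361, -1.3481, 2.4734, -2.9257, 2.9298, -2.7816, 2.4777,
          -1.6847, 0.46483, 0.46565, -0.67312, 0.4162, -0.13832,
          0.019852),
    gain = 0.965
  )
}

#' Activity-count emulation parameters
#'
#' Parameter set for the raw-acceleration to legacy-activity-count
#' conversion. The defaults are the published reference values: resample to
#' 30 Hz, band-pass filter, decimate to 10 Hz, rectify, saturate at 2.13 g,
#' zero below the 0.068 g dead-band, quantize at the 0.0164 g ADC step, and
#' accumulate into epochs.
#'
#' @param intermediate_rate Hz of the filter stage (default 30).
#' @param accumulation_rate Hz of the post-filter accumulation stage
#'   (default 10; must divide `intermediate_rate`).
#' @param dead_band g; rectified filtered values below this count as zero.
#' @param saturation g; rectified filtered values are clipped here.
#' @param adc_resolution g per quantization step.
#' @param band_pass Filter coefficient set `list(b, a, gain)`; defaults to
#'   the reference table.
#' @param epoch_length Epoch length in seconds (default 60).
#' @return An object of class `count_params`.
#' @export
count_params <- function(intermediate_rate = 30, accumulation_rate = 10,
                         dead_band = 0.068, saturation = 2.13,
                         adc_resolution = 0.0164,
                         band_pass = count_bandpass(),
                         epoch_length = 60) {
  if (dead_band >= saturation) {
    stop("config error: dead_band must be below saturation", call. = FALSE)
  }
  if (intermediate_rate %% accumulation_rate != 0) {
    stop("config error: accumulation_rate must divide intermediate_rate",
         call. = FALSE)
  }
  structure(
    list(intermediate_rate = intermediate_rate,
         accumulation_rate = accumulation_rate,
         dead_band = dead_band, saturation = saturation,
         adc_resolution = adc_resolution, band_pass = band_pass,
         epoch_length = epoch_length),
    class = "count_params")
}

# IIR filtering with steady-state initial conditions at x0: past inputs are
# taken as x0 and past outputs as its steady-state response, so a constant
# signal produces its (sub-dead-band) DC response with no start-up
# transient. MA part via convolution filter, AR part via recursive filter.
bandpass_filter <- function(x, bp) {
  b <- bp$b * bp$gain
  a <- bp$a
  nb <- length(b)
  x0 <- x[1L]
  y0 <- x0 * sum(b) / sum(a)
  xp <- c(rep(x0, nb - 1L), x)
  ma <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  ma <- ma[nb:length(xp)]
  as.numeric(stats::filter(ma, -a[-1L], method = "recursive",
                           init = rep(y0, length(a) - 1L)))
}

#' Emulate legacy activity counts from raw acceleration
#'
#' Converts a raw tri-axial recording into per-epoch, per-axis legacy
#' activity counts. Per axis, in order: linear-interpolation resample to
#' the intermediate rate, band-pass filter, decimate to the accumulation
#' rate, saturate, rectify, dead-band, quantize, and sum into epoch bins.
#' The epoch grid is anchored to whole minutes of the clock: output starts
#' at the first whole epoch boundary at or after the recording start, and a
#' partial trailing epoch is discarded.
#'
#' @param raw A [raw_triaxial()] recording with `rate >=` the intermediate
#'   rate.
#' @param params A [count_params()] object.
#' @return A `count_epochs` data frame: `epoch_start`, `counts_x`,
#'   `counts_y`, `counts_z`, `vm` (resultant vector magnitude), with the
#'   epoch length as attribute `epoch_length`.
#' @export
emulate_counts <- function(raw, params = count_params()) {
  stopifnot(inherits(raw, "raw_triaxial"))
  if (raw$rate < params$intermediate_rate) {
    stop("recording rate ", raw$rate, " Hz is below the intermediate rate ",
         params$intermediate_rate, " Hz", call. = FALSE)
  }
  n <- nrow(raw$samples)
  dur <- n / raw$rate
  t0 <- as.numeric(raw$start_time)
  e0 <- ceiling(t0 / params$epoch_length) * params$epoch_length
  if (t0 + dur < e0 + params$epoch_length) {
    stop("empty-series error: recording shorter than one whole epoch",
         call. = FALSE)
  }
  fr <- params$intermediate_rate
  dec <- as.integer(round(fr / params$accumulation_rate))
  n30 <- floor(dur * fr)
  rel_in <- (seq_len(n) - 1L) / raw$rate
  rel_out <- (seq_len(n30) - 1L) / fr
  per_axis <- function(x) {
    xr <- stats::approx(rel_in, x, xout = rel_out, rule = 2)$y
    yf <- bandpass_filter(xr, params$band_pass)
    yd <- yf[seq(1L, n30, by = dec)]
    yd[yd > params$saturation] <- params$saturation
    yd[yd < -params$saturation] <- -params$saturation
    yd <- abs(yd)
    yd[yd < params$dead_band] <- 0
    floor(yd / params$adc_resolution)
  }
  q <- vapply(1:3, function(j) per_axis(raw$samples[, j]),
              numeric(length(seq(1L, n30, by = dec))))
  # map accumulation-rate samples onto the minute-anchored epoch grid
  ar <- params$accumulation_rate
  tq <- t0 + (seq_len(nrow(q)) - 1L) / ar
  k0 <- which(tq >= e0 - 1e-9)[1L]
  per_epoch <- ar * params$epoch_length
  m <- (nrow(q) - k0 + 1L) %/% per_epoch
  if (is.na(k0) || m < 1L) {
    stop("empty-series error: recording shorter than one whole epoch",
         call. = FALSE)
  }
  idx <- k0:(k0 + m * per_epoch - 1L)
  grp <- rep(seq_len(m), each = per_epoch)
  counts <- vapply(1:3, function(j) {
    as.numeric(rowsum(q[idx, j], grp, reorder = FALSE))
  }, numeric(m))
  out <- data.frame(
    epoch_start = clock_time(e0 + (seq_len(m) - 1L) * params$epoch_length),
    counts_x = counts[, 1L], counts_y = counts[, 2L], counts_z = counts[, 3L])
  attr(out, "epoch_length") <- params$epoch_length
  class(out) <- c("count_epochs", "data.frame")
  vector_magnitude(out)
}

#' Resultant vector magnitude of per-axis counts
#'
#' Populates `vm` as the per-epoch Euclidean norm of the three axis counts.
#' Kept unrounded: downstream non-wear detection thresholds on `vm`.
#'
#' @param series A `count_epochs` data frame with `counts_x/y/z`.
#' @return The series with `vm` (re)computed.
#' @export
vector_magnitude <- function(series) {
  stopifnot(all(c("counts_x", "counts_y", "counts_z") %in% names(series)))
  series$vm <- sqrt(series$counts_x^2 + series$counts_y^2 + series$counts_z^2)
  series
}
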