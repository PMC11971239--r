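# Independent oracle implementations, deliberately naive: plain loops over
# the written definitions, sharing no code path with the package internals.

# Count emulation oracle: per-sample loop through resample -> band-pass
# (direct-form difference equation with steady-state initial conditions) ->
# decimate -> saturate -> rectify -> dead-band -> quantize -> epoch sum.
oracle_counts <- function(raw, params = count_params()) {
  bp <- params$band_pass
  b <- bp$b * bp$gain
  a <- bp$a
  nb <- length(b)
  fr <- params$intermediate_rate
  dec <- round(fr / params$accumulation_rate)
  n <- nrow(raw$samples)
  n30 <- floor(n / raw$rate * fr)
  t_in <- (seq_len(n) - 1) / raw$rate
  t0 <- as.numeric(raw$start_time)
  el <- params$epoch_length
  e0 <- ceiling(t0 / el) * el
  axis_counts <- function(x) {
    xr <- numeric(n30)
    for (k in seq_len(n30)) {
      t <- (k - 1) / fr
      i <- findInterval(t, t_in)
      if (i >= n) {
        xr[k] <- x[n]
      } else {
        x1 <- t_in[i]
        xr[k] <- x[i] + (x[i + 1] - x[i]) * ((t - x1) / (t_in[i + 1] - x1))
      }
    }
    x0 <- xr[1]
    y0 <- x0 * sum(b) / sum(a)
    y <- numeric(n30)
    for (nn in seq_len(n30)) {
      acc <- 0
      for (j in 0:(nb - 1)) {
        acc <- acc + b[j + 1] * (if (nn - j >= 1) xr[nn - j] else x0)
      }
      for (k in 1:(nb - 1)) {
        acc <- acc - a[k + 1] * (if (nn - k >= 1) y[nn - k] else y0)
      }
      y[nn] <- acc
    }
    yd <- y[seq(1, n30, by = dec)]
    q <- numeric(length(yd))
    for (k in seq_along(yd)) {
      v <- yd[k]
      if (v > params$saturation) v <- params$saturation
      if (v < -params$saturation) v <- -params$saturation
      v <- abs(v)
      if (v < params$dead_band) v <- 0
      q[k] <- floor(v / params$adc_resolution)
    }
    q
  }
  qs <- lapply(1:3, function(j) axis_counts(raw$samples[, j]))
  ar <- params$accumulation_rate
  nq <- length(qs[[1]])
  tq <- t0 + (seq_len(nq) - 1) / ar
  epoch_of <- floor(tq / el) * el
  keep <- epoch_of >= e0
  full <- el * ar
  counts <- lapply(qs, function(q) {
    sums <- tapply(q[keep], epoch_of[keep], sum)
    ns <- tapply(q[keep], epoch_of[keep], length)
    as.numeric(sums[ns == full])
  })
  starts <- as.numeric(names(table(epoch_of[keep])))
  ns <- as.numeric(table(epoch_of[keep]))
  data.frame(epoch_start = starts[ns == full],
             counts_x = counts[[1]], counts_y = counts[[2]],
             counts_z = counts[[3]])
}

# Brute-force non-wear oracle: tests every epoch interval against the
# written rule (still endpoints, only still or isolated spike epochs, at
# most K spikes, span >= the run threshold) and takes the union.
oracle_nonwear <- function(vm, params) {
  n <- length(vm)
  doffed <- logical(n)
  still <- vm <= params$zero_threshold
  spike <- !still & vm <= params$spike_max_vm
  other <- !still & !spike
  mr <- params$min_nonwear_run
  K <- params$spike_tolerance_epochs
  for (i in seq_len(n)) {
    if (!still[i]) next
    for (j in i:n) {
      if (other[j]) break
      if (j - i + 1 < mr) next
      if (!still[j]) next
      sp <- spike[i:j]
      if (sum(sp) > K) break
      if (any(sp[-1] & sp[-length(sp)])) break
      doffed[i:j] <- TRUE
    }
  }
  doffed
}
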