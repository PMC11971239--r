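# Programmatic fixtures shared across test files.

DAY0 <- "2024-03-04"

# A raw_triaxial built from per-axis functions of time (seconds), sampled
# at `rate` for `dur` seconds.
make_raw <- function(fx = function(t) 0 * t, fy = fx, fz = fx,
                     dur = 300, rate = 50, start = paste(DAY0, "08:00:00")) {
  t <- (seq_len(dur * rate) - 1) / rate
  raw_triaxial(start, rate, cbind(fx(t), fy(t), fz(t)))
}

# A count_epochs series from a bare vm vector (per-axis counts chosen so
# vm comes out as given), on a 60-s grid from `start`.
make_series <- function(vm, start = paste(DAY0, "00:00:00")) {
  t0 <- as.numeric(clock_time(start))
  df <- data.frame(
    epoch_start = clock_time(t0 + (seq_along(vm) - 1) * 60),
    counts_x = as.numeric(vm), counts_y = numeric(length(vm)),
    counts_z = numeric(length(vm)), vm = as.numeric(vm))
  class(df) <- c("count_epochs", "data.frame")
  attr(df, "epoch_length") <- 60
  df
}

# One full day (1440 epochs) of behaviour data, default all-sedentary.
# Interval arguments are 2-col matrices of decimal hours [from, to) whose
# whole epochs get 60 s of the class; steps at `cadence` per stepping min.
day_table <- function(date = DAY0, lying = NULL, stepping = NULL,
                      nonwear = NULL, upright = NULL, cadence = 100,
                      n_epochs = 1440) {
  t0 <- as.numeric(clock_time(date))
  cls <- behaviour_classes()
  m <- matrix(0, n_epochs, length(cls), dimnames = list(NULL, cls))
  m[, "sedentary"] <- 60
  hrs <- (seq_len(n_epochs) - 1) / 60
  set_cls <- function(iv, cl) {
    if (is.null(iv)) return()
    for (i in seq_len(nrow(iv))) {
      sel <- hrs >= iv[i, 1] & hrs < iv[i, 2]
      m[sel, ] <<- 0
      m[sel, cl] <<- 60
    }
  }
  set_cls(lying, "primary_lying")
  set_cls(upright, "upright")
  set_cls(nonwear, "non_wear")
  set_cls(stepping, "stepping")
  df <- data.frame(epoch_start = clock_time(t0 + (seq_len(n_epochs) - 1) * 60))
  df <- cbind(df, as.data.frame(m))
  df$steps <- ifelse(m[, "stepping"] > 0, cadence, 0)
  behaviour_epochs(df)
}

iv <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# small cohort config used by the cheaper end-to-end tests
small_config <- function(...) {
  cohort_config(n_participants = 2, n_days = 2, seed = 421, ...)
}
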