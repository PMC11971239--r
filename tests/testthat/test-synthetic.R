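test_that("schedules are reproducible from the seed", {
  a <- simulate_truth(small_config())
  b <- simulate_truth(small_config())
  for (id in names(a$schedules)) {
    expect_equal(a$schedules[[id]]$wear, b$schedules[[id]]$wear)
    expect_equal(a$schedules[[id]]$excursions, b$schedules[[id]]$excursions)
    expect_equal(a$schedules[[id]]$bouts, b$schedules[[id]]$bouts)
    expect_equal(a$schedules[[id]]$sleep, b$schedules[[id]]$sleep)
  }
  c <- simulate_truth(cohort_config(n_participants = 2, n_days = 2,
                                    seed = 422))
  expect_false(identical(a$schedules$P1$wear, c$schedules$P1$wear))
})

test_that("don-at-departure structure holds by construction", {
  truth <- simulate_truth(cohort_config(n_participants = 4, n_days = 3,
                                        seed = 5,
                                        don_at_departure_prob = 1))
  for (s in truth$schedules) {
    for (i in seq_len(nrow(s$excursions))) {
      dep <- s$excursions$depart[i]
      ret <- s$excursions$return[i]
      lead <- dep - s$wear$don
      expect_true(any(lead >= 0 & lead <= 600))
      lag <- s$wear$doff - ret
      expect_true(any(lag >= 0 & lag <= 1800))
    }
  }
})

test_that("simulated wear hours concentrate on the configured mean", {
  cfg <- cohort_config(
    n_participants = 20, n_days = 7, seed = 9,
    wear_hours_mean = list(previous_user = c(T0 = 10, T1 = 10, T2 = 10),
                           new_user = c(T0 = 10, T1 = 10, T2 = 10)))
  truth <- simulate_truth(cfg)
  daily <- unlist(lapply(truth$schedules, function(s) {
    vapply(seq_len(s$n_days), function(d) {
      d0 <- s$start + (d - 1) * 86400
      w <- s$wear[s$wear$don >= d0 & s$wear$don < d0 + 86400, ]
      sum(w$doff - w$don) / 3600
    }, numeric(1))
  }))
  expect_lt(abs(mean(daily) - 10), 1)
})

test_that("infeasible configurations are rejected as generation errors", {
  expect_error(cohort_config(excursion_duration_h = c(8, 14)), "generation")
  expect_error(cohort_config(don_at_departure_prob = 2), "generation")
  expect_error(cohort_config(transition_walk_s = c(100, 200)), "generation")
  expect_error(cohort_config(home_bout_s = c(20, 58)), "generation")
  expect_error(cohort_config(wear_hours_mean = list(
    previous_user = c(T0 = 20, T1 = 20, T2 = 20),
    new_user = c(T0 = 20, T1 = 20, T2 = 20))), "generation")
})

test_that("a fully doffed wrist renders to zero counts everywhere", {
  truth <- simulate_truth(small_config())
  s <- truth$schedules$P1
  s$wear <- s$wear[0, ]                 # strip all wear intervals
  raw <- render_wrist(s, truth$config, days = 1)
  counts <- emulate_counts(raw)
  expect_true(all(counts$vm == 0))
})

test_that("a known worn block is recovered to the quarter hour", {
  truth <- simulate_truth(small_config())
  s <- truth$schedules$P1
  d0 <- s$start
  s$wear <- data.frame(don = d0 + 8 * 3600, doff = d0 + 18 * 3600)
  raw <- render_wrist(s, truth$config, days = 1)
  mask <- detect_wear(emulate_counts(raw))
  daily <- daily_wear_summary(mask)
  expect_lt(abs(daily$wear_hours[1] - 10), 0.25)
  ev <- extract_events(mask)
  expect_equal(as.character(ev$kind), c("don", "doff"))
  expect_lte(abs(as.numeric(ev$time[1]) - (d0 + 8 * 3600)), 120)
  expect_lte(abs(as.numeric(ev$time[2]) - (d0 + 18 * 3600)), 120)
})

test_that("doubling the burst amplitude never decreases counts", {
  cfg1 <- small_config()
  cfg2 <- small_config(burst_amp_g = 1.0)
  t1 <- simulate_truth(cfg1)
  t2 <- simulate_truth(cfg2)
  c1 <- emulate_counts(render_wrist(t1$schedules$P1, cfg1, days = 1))
  c2 <- emulate_counts(render_wrist(t2$schedules$P1, cfg2, days = 1))
  expect_true(all(c2$counts_x - c1$counts_x >= 0))
  expect_true(all(c2$counts_y - c1$counts_y >= 0))
})

test_that("the thigh rendering reflects the schedule", {
  truth <- simulate_truth(small_config())
  s <- truth$schedules$P1
  tab <- render_thigh(s, truth$config)
  expect_s3_class(tab, "behaviour_epochs")     # row sums validated there
  # sleep epochs are pure primary lying
  mid_sleep <- floor((s$sleep$start[2] + 600) / 60) * 60
  expect_equal(tab$primary_lying[as.numeric(tab$epoch_start) == mid_sleep],
               60)
  # every departure walk yields exactly one transition at its start
  tr <- detect_transitions(extract_stepping_bouts(tab))
  for (dep in s$excursions$depart) {
    hits <- abs(as.numeric(tr$time) - dep) <= 60
    expect_equal(sum(hits), 1)
  }
  expect_equal(nrow(tr), 2 * nrow(s$excursions))
  # step totals are conserved up to per-epoch rounding
  expect_lt(abs(sum(tab$steps) -
                  sum(s$bouts$cadence * s$bouts$duration / 60)),
            nrow(s$bouts) * 2 + 2)
})

test_that("rendered outputs round-trip through the readers unchanged", {
  truth <- simulate_truth(small_config())
  s <- truth$schedules$P2
  tab <- render_thigh(s, truth$config, days = 1)
  tf <- tempfile(fileext = ".csv")
  write_behaviour_epochs(tab, tf)
  back <- read_behaviour_epochs(tf)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE)
  raw <- render_wrist(s, truth$config, days = 1)
  wf <- tempfile(fileext = ".wav")
  write_raw_wrist(raw, wf, dialect(format = "wav", wav_scale = 16))
  rec <- read_raw_wrist(wf, dialect(format = "wav", wav_scale = 16),
                        start_time = raw$start_time)
  expect_equal(rec$rate, raw$rate)
  expect_lt(max(abs(rec$samples - raw$samples)), 1e-5)
})
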