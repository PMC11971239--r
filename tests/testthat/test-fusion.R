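test_that("alignment shifts the thigh clock and finds the overlap", {
  vm <- rep(100, 1440)
  mask <- detect_wear(make_series(vm))
  tab <- day_table()
  al <- align_streams(mask, tab, offset = 0)
  expect_equal(as.numeric(al$overlap[2] - al$overlap[1], units = "hours"),
               24)
  expect_equal(as.numeric(al$behaviour$epoch_start),
               as.numeric(tab$epoch_start))
  # a +120 s thigh clock lead moves every epoch 120 s earlier
  al2 <- align_streams(mask, tab, offset = 120)
  expect_equal(as.numeric(al2$behaviour$epoch_start),
               as.numeric(tab$epoch_start) - 120)
  # disjoint recordings cannot be fused
  late <- day_table(date = "2024-04-01")
  expect_error(align_streams(mask, late), "alignment")
})

test_that("event windows count stepping epochs before and after", {
  mask <- detect_wear(make_series(rep(100, 1440)))
  # stepping only 08:00-08:30
  tab <- day_table(stepping = iv(8, 8.5), lying = iv(0, 6))
  al <- align_streams(mask, tab)
  don <- data.frame(time = clock_time(paste(DAY0, "08:00:00")),
                    kind = factor("don", c("don", "doff")))
  st <- stepping_around_events(al, don)
  expect_equal(st$pre_stepping_min, 0)
  expect_equal(st$post_stepping_min, 30)
  expect_true(st$complete)
  # an event 10 min after the table starts has a truncated pre window
  short <- tab[tab$epoch_start >= clock_time(paste(DAY0, "07:50:00")), ]
  al2 <- align_streams(mask, short)
  st2 <- stepping_around_events(al2, don)
  expect_false(st2$complete)
  expect_equal(st2$pre_stepping_min, 0)
  # window conservation: at most 60 epochs across both sides
  expect_true(all(st$pre_stepping_min + st$post_stepping_min <= 60))
})

test_that("alternating stepping gives symmetric windows", {
  mask <- detect_wear(make_series(rep(100, 1440)))
  tab <- day_table()
  odd <- seq(1, 1440, by = 2)
  tab$stepping[odd] <- 60
  tab$sedentary[odd] <- 0
  tab$steps[odd] <- 100
  tab <- behaviour_epochs(as.data.frame(tab))
  al <- align_streams(mask, tab)
  ev <- data.frame(time = clock_time(paste(DAY0, "12:00:00")),
                   kind = factor("don", c("don", "doff")))
  st <- stepping_around_events(al, ev)
  expect_equal(st$pre_stepping_min, 15)
  expect_equal(st$post_stepping_min, 15)
})

test_that("windows overlapping missing data, non-wear or a neighbouring event are incomplete", {
  mask <- detect_wear(make_series(rep(100, 1440)))
  tab <- day_table(nonwear = iv(10, 10.2))
  al <- align_streams(mask, tab)
  ev <- data.frame(
    time = clock_time(paste(DAY0, c("10:30:00", "15:00:00", "15:20:00"))),
    kind = factor(c("don", "don", "doff"), c("don", "doff")))
  st <- stepping_around_events(al, ev)
  expect_false(st$complete[1])    # non-wear epochs in the pre window
  expect_false(st$complete[2])    # doff 20 min later
  expect_false(st$complete[3])
})

test_that("group aggregation averages complete windows and keeps gaps", {
  mk <- function(times, kinds, pre, post, complete = TRUE) {
    data.frame(time = clock_time(times), kind = factor(kinds, c("don", "doff")),
               pre_stepping_min = pre, post_stepping_min = post,
               complete = complete)
  }
  stats <- list(
    P1 = mk(c(0, 7200), c("don", "don"), c(1, 3), c(20, 30)),
    P2 = mk(14400, "doff", 9, 2),
    P3 = mk(20000, "don", 5, 5, complete = FALSE))
  groups <- c(P1 = "previous_user", P2 = "previous_user", P3 = "new_user")
  agg <- aggregate_group(stats, groups, phases = "T1")
  s <- agg$summary
  prev_don <- s[s$group == "previous_user" & s$kind == "don", ]
  expect_equal(prev_don$mean_post_stepping_min, 25)
  expect_equal(prev_don$n_events, 2L)
  # the incomplete window contributes nothing: its cell stays missing
  new_don <- s[s$group == "new_user" & s$kind == "don", ]
  expect_true(is.na(new_don$mean_post_stepping_min))
  expect_equal(new_don$n_events, 0L)
  new_doff <- s[s$group == "new_user" & s$kind == "doff", ]
  expect_true(is.na(new_doff$mean_pre_stepping_min))
})

test_that("shuffled event times erase the pre/post asymmetry", {
  mask <- detect_wear(make_series(rep(100, 2880)))
  # stepping packed into the half hour after each of four don times
  dons <- clock_time(paste(rep(c(DAY0, "2024-03-05"), each = 2),
                           c("09:00:00", "15:00:00")))
  step_iv <- do.call(rbind, lapply(as.numeric(dons), function(t) {
    h <- (t - as.numeric(clock_time(DAY0))) / 3600
    iv(h, h + 0.5)
  }))
  tab <- day_table(stepping = step_iv, n_epochs = 2880)
  al <- align_streams(mask, tab)
  ev <- data.frame(time = dons, kind = factor(rep("don", 4), c("don", "doff")))
  obs <- stepping_around_events(al, ev)
  observed_gap <- mean(obs$post_stepping_min - obs$pre_stepping_min)
  expect_equal(observed_gap, 30)
  set.seed(11)
  gaps <- replicate(20, {
    sh <- ev
    sh$time <- clock_time(as.numeric(clock_time(DAY0)) +
                            round(runif(4, 8 * 60, 40 * 60)) * 60)
    s <- stepping_around_events(al, sh)
    mean(s$post_stepping_min - s$pre_stepping_min)
  })
  expect_lt(abs(mean(gaps)), observed_gap / 4)
})

test_that("clock-offset estimation recovers an induced lag", {
  set.seed(3)
  vm <- pmax(0, round(rnorm(720, 50, 60)))
  series <- make_series(vm)
  lag_min <- 3
  tab <- day_table(n_epochs = 720 + lag_min)
  steps <- c(rep(0, lag_min), round(vm / 2))
  tab$stepping <- ifelse(steps > 0, 60, 0)
  tab$sedentary <- 60 - tab$stepping
  tab$steps <- steps
  tab <- behaviour_epochs(as.data.frame(tab))
  est <- estimate_clock_offset(series, tab)
  expect_equal(est$offset_s, lag_min * 60)
})
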