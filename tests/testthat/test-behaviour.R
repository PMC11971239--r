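test_that("dominant labelling takes the largest class with fixed ties", {
  df <- day_table(n_epochs = 3)
  df[1, behaviour_classes()] <- c(20, 0, 40, 0, 0, 0, 0, 0)  # stepping 40
  df[2, behaviour_classes()] <- c(30, 30, 0, 0, 0, 0, 0, 0)  # tie
  df[3, behaviour_classes()] <- c(0, 0, 0, 0, 0, 0, 0, 60)   # non-wear
  df$steps <- c(60, 0, 0)
  lab <- label_dominant(behaviour_epochs(as.data.frame(df)))
  expect_equal(as.character(lab$label), c("stepping", "upright", "non_wear"))
})

test_that("stepping bouts are maximal runs of near-full stepping epochs", {
  mk <- function(stepping_s) {
    df <- day_table(n_epochs = length(stepping_s))
    df$stepping <- stepping_s
    df$sedentary <- 60 - stepping_s
    df$steps <- ifelse(stepping_s > 0, round(stepping_s * 1.7), 0)
    behaviour_epochs(as.data.frame(df))
  }
  b1 <- extract_stepping_bouts(mk(c(60, 60, 60)))
  expect_equal(b1$duration, 180)
  b2 <- extract_stepping_bouts(mk(c(60, 0, 60)))
  expect_equal(b2$duration, c(60, 60))
  b3 <- extract_stepping_bouts(mk(c(58, 57)))
  expect_equal(b3$duration, 115)
  expect_equal(as.numeric(b3$end - b3$start, units = "secs"), 115)
  # sub-threshold epochs never join a bout
  b4 <- extract_stepping_bouts(mk(c(54, 60, 54)))
  expect_equal(b4$duration, 60)
  # grid gaps break runs even when both sides qualify
  tab <- mk(c(60, 60, 60, 60))
  tab <- tab[-2, ]
  b5 <- extract_stepping_bouts(tab)
  expect_equal(b5$duration, c(60, 120))
  expect_error(extract_stepping_bouts(tab, mode = "no_such"), "config")
})

test_that("event-stream bouts pass through with ordering checks", {
  raw <- data.frame(start = clock_time(c(120, 0)), duration = c(70, 30))
  out <- extract_stepping_bouts(raw, mode = "event_stream")
  expect_equal(out$duration, c(30, 70))
  bad <- data.frame(start = clock_time(c(0, 20)), duration = c(30, 10))
  expect_error(extract_stepping_bouts(bad, mode = "event_stream"),
               "overlap")
})

test_that("transitions fire on long bouts or straight sub-segments", {
  bouts <- data.frame(start = clock_time(c(0, 1000, 2000)),
                      end = clock_time(c(70, 1040, 2020)),
                      duration = c(70, 40, 20), source = "event_stream")
  # winding heading everywhere except a 30-s straight stretch in bout 2
  ht <- seq(0, 2100, by = 1)
  hd <- cumsum(rep(c(-8, 9, 8, -9), length.out = length(ht)))
  straight <- ht >= 1005 & ht <= 1035
  hd[straight] <- hd[which(straight)[1]] + seq(0, 4, length.out = sum(straight))
  heading <- data.frame(time = clock_time(ht), heading_deg = hd)
  tr <- detect_transitions(bouts, heading = heading)
  expect_equal(as.character(tr$rule), c("long_bout", "straight_line"))
  expect_equal(as.numeric(tr$time), c(0, 1000))
  # without heading, only the long bout fires; a 60-s bout does not
  tr2 <- detect_transitions(bouts)
  expect_equal(nrow(tr2), 1)
  b60 <- data.frame(start = clock_time(0), end = clock_time(60),
                    duration = 60, source = "event_stream")
  expect_equal(nrow(detect_transitions(b60)), 0)
})

test_that("raising the long-bout threshold never adds transitions", {
  set.seed(7)
  durs <- sample(20:200, 40, replace = TRUE)
  starts <- cumsum(durs + 300)
  bouts <- data.frame(start = clock_time(starts),
                      end = clock_time(starts + durs), duration = durs,
                      source = "event_stream")
  prev <- Inf
  for (ls in c(30, 60, 90, 120)) {
    n <- nrow(detect_transitions(bouts, long_s = ls))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("sleep periods merge brief interruptions and need 3 h", {
  # 31 h of data: the night period crosses midnight intact
  tab <- day_table(lying = iv(0, 6.5, 22, 30.5), n_epochs = 1860)
  sl <- detect_sleep(label_dominant(tab))
  expect_equal(nrow(sl), 2)
  expect_equal(sl$duration_h, c(6.5, 8.5))
  # 10-min sedentary interruption inside the night is absorbed
  tab2 <- day_table(lying = iv(0, 3, 3 + 10 / 60, 6.5))
  sl2 <- detect_sleep(label_dominant(tab2))
  expect_equal(nrow(sl2), 1)
  expect_equal(sl2$duration_h, 6.5)
  # beyond the tolerance the runs stay separate and short ones drop out
  tab3 <- day_table(lying = iv(0, 2, 2.5, 6.5))
  sl3 <- detect_sleep(label_dominant(tab3))
  expect_equal(sl3$duration_h, 4)
  # no lying at all
  expect_equal(nrow(detect_sleep(label_dominant(day_table()))), 0)
})

test_that("home/away toggling between sleep anchors measures away hours", {
  # sleep to 06:30 and from 22:00; transition walks at 09:00 and 17:00
  tab <- day_table(lying = iv(0, 6.5, 22, 30.5), n_epochs = 1860,
                   stepping = iv(9, 9 + 5 / 60, 17, 17 + 5 / 60))
  bouts <- extract_stepping_bouts(tab)
  tr <- detect_transitions(bouts)
  expect_equal(nrow(tr), 2)
  sl <- detect_sleep(label_dominant(tab))
  part <- classify_home_away(tr, sl, tab)
  expect_equal(part$away_hours[1], 8)
  expect_true(part$valid[1])
  expect_true(part$anchored[1])
  # no transitions at all -> zero away time
  tab0 <- day_table(lying = iv(0, 6.5, 22, 30.5), n_epochs = 1860)
  p0 <- classify_home_away(detect_transitions(extract_stepping_bouts(tab0)),
                           detect_sleep(label_dominant(tab0)), tab0)
  expect_equal(p0$away_hours[1], 0)
})

test_that("multiple excursions sum and away time respects waking hours", {
  tab <- day_table(lying = iv(0, 6.5, 22, 30.5), n_epochs = 1860,
                   stepping = iv(8, 8.1, 10, 10.1, 13, 13.1, 19, 19.1))
  tr <- detect_transitions(extract_stepping_bouts(tab))
  sl <- detect_sleep(label_dominant(tab))
  part <- classify_home_away(tr, sl, tab)
  expect_equal(part$away_hours[1], (10 - 8) + (19 - 13))
  expect_lte(part$away_hours[1], 24 - 6.5 - 2)   # waking hours of day 1
  intervals <- part$away_intervals[[1]]
  expect_equal(nrow(intervals), 2)
})

test_that("days below the 20-h data threshold are flagged invalid", {
  tab <- day_table(lying = iv(0, 6.5, 22, 30.5), n_epochs = 1860,
                   stepping = iv(9, 9.1, 17, 17.1),
                   nonwear = iv(10, 14.5))          # 4.5 h monitor off
  tr <- detect_transitions(extract_stepping_bouts(tab))
  part <- classify_home_away(tr, detect_sleep(label_dominant(tab)), tab)
  expect_equal(part$observed_hours[1], 19.5)
  expect_false(part$valid[1])
  # exactly 20 h is still invalid: the rule is strictly more than 20
  tab2 <- day_table(lying = iv(0, 6.5, 22, 30.5), n_epochs = 1860,
                    nonwear = iv(10, 14))
  p2 <- classify_home_away(detect_transitions(extract_stepping_bouts(tab2)),
                           detect_sleep(label_dominant(tab2)), tab2)
  expect_equal(p2$observed_hours[1], 20)
  expect_false(p2$valid[1])
})

test_that("a day without a sleep anchor is excluded from classification", {
  tab <- day_table(stepping = iv(9, 9.1, 17, 17.1))  # no lying anywhere
  tr <- detect_transitions(extract_stepping_bouts(tab))
  part <- classify_home_away(tr, detect_sleep(label_dominant(tab)), tab)
  expect_false(part$anchored)
  expect_equal(part$away_hours, 0)
})

test_that("adding one qualifying bout adds at most one transition", {
  tab <- day_table(lying = iv(0, 6.5, 22, 24),
                   stepping = iv(9, 9.1, 17, 17.1))
  n0 <- nrow(detect_transitions(extract_stepping_bouts(tab)))
  tab2 <- day_table(lying = iv(0, 6.5, 22, 24),
                    stepping = iv(9, 9.1, 12, 12 + 61 / 3600, 17, 17.1))
  n1 <- nrow(detect_transitions(extract_stepping_bouts(tab2)))
  expect_lte(n1 - n0, 1)
})
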