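test_that("presses are attributed to the preceding occlusion onset", {
  sched <- occlusion_event_times(slow_small, 80)  # 24 events, 3.33 s apart
  # one CW press shortly after onset: a single stable percept
  ts <- events_to_trials(make_log(0.5, "CW"), sched)
  expect_length(ts$theta, 24)
  expect_equal(ts$theta, rep(1, 24))
  # a CCW press 0.4 s after occlusion 10 switches theta at that interval
  ev <- sched$event_times_s
  ts2 <- events_to_trials(make_log(c(0.5, ev[10] + 0.4), c("CW", "CCW")),
                          sched)
  expect_equal(ts2$theta, c(rep(1, 10), rep(0, 14)))
  # MIXED then CW within the same interval: last press wins
  ts3 <- events_to_trials(
    make_log(c(0.5, ev[5] + 0.3, ev[5] + 0.9), c("CCW", "MIXED", "CW")),
    sched)
  expect_equal(ts3$theta[6], 1)
  expect_equal(ts3$theta[5], 0)
  # MIXED not followed by a clear press leaves intervals missing
  ts4 <- events_to_trials(make_log(c(0.5, ev[5] + 0.3), c("CW", "MIXED")),
                          sched)
  expect_true(all(is.na(ts4$theta[6:24])))
  expect_equal(ts4$theta[1:5], rep(1, 5))
  # an empty log yields an all-missing series, not an error
  ts5 <- events_to_trials(make_log(numeric(0), character(0)), sched)
  expect_true(all(is.na(ts5$theta)))
})

test_that("clear fraction counts mixed presses in the denominator", {
  log <- make_log(seq_len(25), c(rep("CW", 24), "MIXED"))
  expect_equal(clear_fraction(log), 0.96)
  expect_equal(clear_fraction(make_log(1:3, rep("CCW", 3))), 1)
  expect_equal(clear_fraction(make_log(1:2, rep("MIXED", 2))), 0)
  expect_error(clear_fraction(make_log(numeric(0), character(0))),
               "undefined")
})

test_that("phase durations span consecutive percept changes", {
  sched <- occlusion_event_times(slow_small, 80)
  ev <- sched$event_times_s
  # stable percept: no completed phase
  ts <- events_to_trials(make_log(0.5, "CW"), sched)
  expect_length(phase_durations(ts), 0)
  # switches at intervals 5 and 10 (3.33-s spacing): one 16.67-s phase
  ts2 <- events_to_trials(
    make_log(c(0.5, ev[5] + 0.4, ev[10] + 0.4), c("CW", "CCW", "CW")),
    sched)
  expect_equal(phase_durations(ts2), 50 / 3, tolerance = 1e-6)
  # zero-latency observer: durations are multiples of the interval
  log <- simulate_markov(schedule_n(2000),
                         observer_config("markov", switch_prob = 0.3,
                                         rt_mean_s = 0, rt_sd_s = 0,
                                         mixed_rate = 0, seed = 3))
  dur <- phase_durations(events_to_trials(log, schedule_n(2000)))
  interval <- 1 / 0.6
  expect_true(all(abs(dur / interval - round(dur / interval)) < 1e-6))
})

test_that("preprocessing recovers the simulator's percept sequence", {
  sched <- schedule_n(5000)
  log <- simulate_markov(sched,
                         observer_config("markov", switch_prob = 0.25,
                                         rt_mean_s = 0, rt_sd_s = 0,
                                         mixed_rate = 0, seed = 17))
  ts <- events_to_trials(log, sched)
  expect_equal(ts$theta, as.numeric(attr(log, "percept")))
  expect_equal(sum(diff(ts$theta) != 0),
               sum(diff(attr(log, "percept")) != 0))
  # re-serialization of the inputs leaves the series unchanged
  log2 <- make_log(log$time_s, log$key)
  expect_equal(events_to_trials(log2, sched)$theta, ts$theta)
})

test_that("transition presses concentrate in a lag window after occlusions", {
  sched <- occlusion_event_times(slow_small, 80)
  # zero latency: all mass exactly at the occlusion phases
  log0 <- simulate_markov(schedule_n(4000, f = 0.15),
                          observer_config("markov", switch_prob = 0.5,
                                          rt_mean_s = 0, rt_sd_s = 0,
                                          mixed_rate = 0, seed = 5))
  h0 <- press_phase_histogram(log0, schedule_n(4000, f = 0.15), bin_deg = 10)
  hot <- h0$phase_deg[h0$count > 0]
  expect_true(all(hot %in% c(0, 180)))
  # 0.55 s latency at 0.15 rps shifts the cluster by about 30 degrees
  log1 <- simulate_markov(schedule_n(4000, f = 0.15),
                          observer_config("markov", switch_prob = 0.5,
                                          rt_mean_s = 0.55, rt_sd_s = 0.15,
                                          mixed_rate = 0, seed = 6))
  clear <- log1[log1$key %in% c("CW", "CCW"), ]
  trans <- clear[-1, ][diff(clear$key == "CW") != 0, ]
  ph <- (360 * 0.15 * trans$time_s) %% 360
  expect_lt(abs(mean(ph %% 180) - 0.55 * 54), 3)
  # the histogram total equals the number of transition presses
  h1 <- press_phase_histogram(log1, schedule_n(4000, f = 0.15), bin_deg = 10)
  expect_equal(sum(h1$count), nrow(trans))
})
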