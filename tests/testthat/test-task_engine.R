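test_that("spout travel time is distance over actuator speed", {
  expect_equal(spout_travel_time(spout_model("servo", 40)), 0.8)
  expect_equal(spout_travel_time(spout_model("linear", 25)), 1.0)
  expect_equal(spout_travel_time(spout_model("servo", 0)), 0)
  expect_error(spout_model("servo", 40, speed_mm_per_s = 0),
               "invalid-config")
})

test_that("response classification matches the sliding-window brute force", {
  # requirement 1: first lick wins
  licks <- data.frame(time = 0.3, spout = "left")
  expect_equal(evaluate_response(licks, c(0, 2), 1)$side, "left")
  # requirement 4: an early single right lick loses to a left burst
  licks <- data.frame(time = c(0.05, 0.1, 0.2, 0.3, 0.4),
                      spout = c("right", rep("left", 4)))
  expect_equal(evaluate_response(licks, c(0, 2), 4)$side, "left")
  expect_true(is.na(evaluate_response(
    data.frame(time = numeric(0), spout = character(0)), c(0, 2), 1)$side))
  # randomized cases against the exhaustive oracle
  set.seed(41)
  for (case in 1:40) {
    n <- sample(0:12, 1)
    licks <- data.frame(time = sort(runif(n, 0, 2.2)),
                        spout = sample(c("left", "right"), n,
                                       replace = TRUE))
    k <- sample(1:5, 1)
    got <- evaluate_response(licks, c(0, 2), k)
    want <- brute_evaluate(licks, c(0, 2), k)
    expect_identical(got$side, want$side)
    expect_equal(got$time, want$time)
  }
})

test_that("a perfectly lateralized subject is 100% correct over 100 trials", {
  cfg <- session_config("2afc", `Number of Trials` = 100L,
                        `Percentage of Center Rewards` = 0)
  res <- run_session(cfg, perfect_subject(), seed = 21)
  expect_equal(nrow(res$trials), 100L)
  expect_true(all(res$trials$outcome %in% c("correct_left",
                                            "correct_right")))
  expect_equal(summarize_session(res)$percent_correct, 100)
})

test_that("retrial mode repeats the same stimulus until resolved", {
  cfg <- session_config("2afc", `Number of Trials` = 10L,
                        `Retrial Mode` = TRUE, `Max Retrials` = 4L,
                        `Percentage of Right Trials` = 100,
                        `Override Consec Constraint` = TRUE,
                        `Percentage of Center Rewards` = 0)
  # subject always licks left: every right trial is wrong, retried up to
  # the cap, and no new side is scheduled meanwhile
  res <- run_session(cfg, one_sided_subject("left"), seed = 4)
  tr <- res$trials
  expect_true(all(tr$kind == "2afc-right"))
  expect_equal(sum(tr$outcome == "retrial"), 4L * 10L)
  expect_true(all(tr$outcome %in% c("retrial", "incorrect")))
  # within each retrial chain the stimulus never changes
  for (tag in unique(stats::na.omit(tr$retrial_of))) {
    chain <- tr[which(tr$retrial_of == tag), ]
    expect_equal(length(unique(chain$stimulus)), 1L)
  }
  # a subject variant that can lick right ends chains with a correct choice
  res2 <- run_session(cfg, subject_params(alpha = 4, beta = 2,
                                          guess = 0, lapse = 0), seed = 4)
  done <- res2$trials[res2$trials$outcome != "retrial", ]
  expect_true(all(done$outcome %in% c("correct_right", "incorrect",
                                      "no_response")))
})

test_that("event log is monotone, bounded per trial, and reward-conserving", {
  cfg <- session_config("2afc", `Number of Trials` = 60L,
                        `Percentage of Center Rewards` = 30,
                        `TCSA reward` = TRUE)
  res <- run_session(cfg, subject_params(alpha = 4, beta = 1.5), seed = 9)
  ev <- res$events
  expect_true(all(diff(ev$time) >= 0))
  # every trial's events fall between its start and the next trial's start
  starts <- ev$time[ev$channel == "state" &
                      startsWith(ev$payload, "trial_start")]
  for (tr in unique(ev$trial[!is.na(ev$trial)])) {
    tt <- ev$time[!is.na(ev$trial) & ev$trial == tr]
    expect_gte(min(tt), starts[tr])
    if (tr < length(starts)) expect_lte(max(tt), starts[tr + 1])
  }
  # reward conservation: reward events = rewarded outcomes + center rewards
  n_reward_events <- sum(ev$channel == "reward")
  n_center <- sum(ev$channel == "reward" & ev$payload == "center")
  expect_equal(n_reward_events,
               sum(res$trials$rewarded) + n_center)
  # response window never opens before side-spout arrival
  for (tr in unique(ev$trial[!is.na(ev$trial)])) {
    s <- ev[!is.na(ev$trial) & ev$trial == tr, ]
    open <- s$time[s$channel == "state" & s$payload == "window_open"]
    arrive <- s$time[s$channel == "side_spout" & s$payload == "extended"]
    if (length(open) && length(arrive)) expect_gte(open[1], arrive[1])
  }
})

test_that("no-response initiation timeout keeps the session going", {
  cfg <- session_config("2afc", `Number of Trials` = 5L)
  res <- run_session(cfg, subject_params(engagement = 0), seed = 2)
  expect_equal(nrow(res$trials), 5L)
  expect_true(all(res$trials$outcome == "no_response"))
  expect_true(any(res$events$payload == "initiation_timeout"))
})

test_that("GNG delay table yields the exact offset-to-window intervals", {
  cfg <- session_config("gng", `Delay Period (s) Min` = 1,
                        `Delay Period (s) Max` = 5,
                        `Delay Period (s) Steps` = 6L,
                        `Stimulus Duration (ms)` = 200,
                        `Number of Trials` = 24L)
  res <- run_session(cfg, subject_params(), seed = 31)
  ints <- measured_offset_to_window(res)
  expect_setequal(round(sort(unique(ints)), 10),
                  c(0.8, 1.6, 2.4, 3.2, 4.0, 4.8))
  # phase-duration fidelity: measured interval equals scheduled delay minus
  # the stimulus duration, exactly (virtual clock)
  expect_equal(ints, res$trials$post_stim_delay - 0.2)
  # offset reference switch
  cfg2 <- session_config("gng", `Delay Reference` = "offset",
                         `Delay Period (s) Min` = 1,
                         `Delay Period (s) Max` = 1,
                         `Delay Period (s) Steps` = 1L,
                         `Number of Trials` = 4L)
  res2 <- run_session(cfg2, subject_params(), seed = 31)
  expect_equal(unique(round(measured_offset_to_window(res2), 10)), 1)
})

test_that("GNG outcomes map onto the four cells with the right ITI rule", {
  # a never-licking subject: all misses and correct rejections
  cfg <- session_config("gng", `Number of Trials` = 40L,
                        `Short ITI Min (s)` = 0.5,
                        `Short ITI Max (s)` = 0.5,
                        `ITI Min (s)` = 5, `ITI Max (s)` = 5)
  res <- run_session(cfg, subject_params(engagement = 0), seed = 6)
  expect_true(all(res$trials$outcome %in% c("miss", "correct_rejection")))
  expect_true(all(res$trials$iti[res$trials$outcome ==
                                   "correct_rejection"] == 0.5))
  expect_true(all(res$trials$iti[res$trials$outcome == "miss"] == 5))
  # an always-licking subject: every go trial is a rewarded hit
  res2 <- run_session(cfg, subject_params(p_lick_go = 1, p_lick_nogo = 1,
                                          rt_meanlog = log(0.2)),
                      seed = 6)
  go <- res2$trials[res2$trials$kind == "go", ]
  expect_true(all(go$outcome == "hit"))
  expect_true(all(go$rewarded))
  expect_equal(sum(res2$events$channel == "reward"), nrow(go))
  # CR rule: trial after a correct rejection is a go trial
  cfg3 <- session_config("gng", `Number of Trials` = 60L,
                         `CR rule ON` = TRUE)
  res3 <- run_session(cfg3, subject_params(p_lick_go = 0.8,
                                           p_lick_nogo = 0.1), seed = 13)
  after_cr <- which(res3$trials$outcome == "correct_rejection") + 1L
  after_cr <- after_cr[after_cr <= nrow(res3$trials)]
  expect_true(all(res3$trials$kind[after_cr] == "go"))
})

test_that("passive blocks schedule combination and multisensory stimuli", {
  cfg <- session_config("passive", `Number of Presentations` = 8L,
                        `Combination` = TRUE)
  res <- run_session(cfg, seed = 3)
  on_ids <- sub("^on:", "",
                res$events$payload[startsWith(res$events$payload, "on:")])
  expect_equal(length(on_ids), 8L)
  expect_true(all(table(on_ids) == 2L))  # 4 orientations, each twice
  # multisensory: auditory onset = visual onset + delay
  cfg2 <- session_config("passive", `Number of Presentations` = 5L,
                         `Multisensory` = TRUE, `Visual first` = TRUE,
                         `delay between (ms)` = 100)
  res2 <- run_session(cfg2, seed = 3)
  ev <- res2$events
  v_on <- ev$time[startsWith(ev$payload, "on:visual_")]
  a_on <- ev$time[startsWith(ev$payload, "on:auditory_")]
  expect_equal(a_on - v_on, rep(0.1, 5))
  # ISI scan oracle: onsets spaced by at least isi + stimulus duration
  cfg3 <- session_config("passive", `Number of Presentations` = 5L,
                         `Interstimulus Interval (s)` = 2)
  res3 <- run_session(cfg3, seed = 3)
  onsets <- res3$events$time[startsWith(res3$events$payload, "on:")]
  expect_equal(length(onsets), 5L)
  expect_true(all(diff(sort(onsets)) >= 2 + 0.2 - 1e-12))
})

test_that("identical config and seed replay byte-identical sessions", {
  cfg <- session_config("gng", `Number of Trials` = 30L)
  r1 <- run_session(cfg, subject_params(), seed = 77)
  r2 <- run_session(cfg, subject_params(), seed = 77)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_session_log(r1, f1)
  write_session_log(r2, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
})
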