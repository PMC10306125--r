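test_that("percent right by column counts responded trials only", {
  trials <- data.frame(
    column = c(0, 0, 8, 8, 4, 4),
    side = c("right", "right", "right", "right", NA, "left"),
    outcome = c("incorrect", "incorrect", "correct_right", "correct_right",
                "no_response", "incorrect"))
  prc <- percent_right_by_column(trials)
  expect_equal(prc$p_right[prc$column == 0], 1)
  expect_equal(prc$p_right[prc$column == 8], 1)
  expect_equal(prc$p_right[prc$column == 4], 0)  # NA side excluded
  expect_equal(prc$n_total[prc$column == 4], 1L)
  expect_true(all(is.na(prc$p_right[prc$column %in% c(1:3, 5:7)])))
  # empty session -> all-absent vector
  empty <- percent_right_by_column(trials[0, ])
  expect_true(all(is.na(empty$p_right)))
  # retrial exclusion toggle
  trials$outcome[1] <- "retrial"
  expect_equal(percent_right_by_column(trials)$n_total[1], 1L)
  expect_equal(percent_right_by_column(
    trials, include_retrials = TRUE)$n_total[1], 2L)
})

test_that("column means fall within binomial CI of psi (simulated subject)", {
  s <- subject_params(alpha = 4, beta = 0.8, guess = 0.02, lapse = 0.03)
  rng <- rng_stream(23, "ci")
  n <- 200
  trials <- do.call(rbind, lapply(0:8, function(x) {
    sides <- vapply(seq_len(n), function(i) choose_side(x, s, rng),
                    character(1))
    data.frame(column = x, side = sides,
               outcome = ifelse(sides == "right", "correct_right",
                                "correct_left"))
  }))
  prc <- percent_right_by_column(trials)
  p_true <- psychometric(0:8, 4, 0.8, 0.02, 0.03)
  expect_true(all(abs(prc$p_right - p_true) <=
                    3.5 * sqrt(p_true * (1 - p_true) / n) + 1e-9))
})

test_that("psychometric fitting recovers exact generating data", {
  x <- 0:8
  n <- rep(100000L, 9)
  p <- psychometric(x, 4, 0.8, 0.02, 0.03)
  fit <- fit_psychometric(data.frame(column = x, n_right = round(n * p),
                                     n_total = n))
  expect_equal(fit$alpha, 4, tolerance = 0.02)
  expect_equal(fit$beta, 0.8, tolerance = 0.05)
  expect_equal(fit$guess, 0.02, tolerance = 0.01)
  expect_equal(fit$lapse, 0.03, tolerance = 0.01)
  expect_true(fit$converged)
  expect_false(fit$unidentifiable)
  # mirrored data: alpha -> 8 - alpha, beta unchanged
  fit_m <- fit_psychometric(data.frame(
    column = 8 - x, n_right = n - round(n * p), n_total = n))
  expect_equal(fit_m$alpha, 8 - fit$alpha, tolerance = 0.05)
  expect_equal(fit_m$beta, fit$beta, tolerance = 0.05)
  # flat 50% data: alpha unidentifiable flag
  flat <- fit_psychometric(data.frame(column = x, n_right = rep(50L, 9),
                                      n_total = rep(100L, 9)))
  expect_true(flat$unidentifiable)
  expect_error(fit_psychometric(data.frame(column = 0:2, n_right = 0:2,
                                           n_total = rep(5L, 3))),
               "at least 4")
})

test_that("fit likelihood beats every deterministic grid start", {
  set.seed(31)
  x <- 0:8
  n <- rep(150L, 9)
  k <- rbinom(9, n, psychometric(x, 3.2, 1.1, 0.08, 0.05))
  fit <- fit_psychometric(data.frame(column = x, n_right = k, n_total = n))
  nll <- function(par) {
    p <- pmin(pmax(psychometric(x, par[1], par[2], par[3], par[4]),
                   1e-9), 1 - 1e-9)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  starts <- expand.grid(alpha = quantile(x, c(0.25, 0.5, 0.75)),
                        beta = 8 * c(0.05, 0.15, 0.5),
                        guess = 0.02, lapse = 0.02)
  for (i in seq_len(nrow(starts))) {
    expect_lte(-fit$logLik, nll(as.numeric(starts[i, ])) + 1e-6)
  }
})

test_that("d-prime matches the normal-quantile oracle and its properties", {
  # frozen quantile-oracle values
  expect_equal(dprime(50, 50, 50, 50)$d_prime, 0)
  expect_equal(dprime(90, 10, 20, 80)$d_prime, 2.1231728,
               tolerance = 1e-6)
  expect_equal(dprime(99, 1, 1, 99)$d_prime, 4.6526957, tolerance = 1e-6)
  # empty class -> absent with reason
  r <- dprime(0, 0, 5, 5)
  expect_true(is.na(r$d_prime))
  expect_match(r$reason, "empty")
  # antisymmetry: swapping hit and false-alarm rates flips the sign
  set.seed(7)
  for (i in 1:25) {
    h <- sample(0:40, 1); m <- sample(0:40, 1)
    fa <- sample(0:40, 1); cr <- sample(0:40, 1)
    if (h + m == 0 || fa + cr == 0) next
    # fixed clip so the correction is symmetric under the class swap
    d1 <- dprime(h, m, fa, cr, clip = 0.01)$d_prime
    d2 <- dprime(fa, cr, h, m, clip = 0.01)$d_prime
    expect_equal(d1, -d2, tolerance = 1e-12)
  }
  # perfect rates stay finite through the 1/(2N) clip
  expect_lt(dprime(100, 0, 0, 100)$d_prime, Inf)
  expect_equal(dprime(100, 0, 0, 100)$d_prime,
               qnorm(1 - 1 / 200) - qnorm(1 / 200))
})

test_that("session summaries, learning curves and advancement criteria", {
  res <- run_session(session_config("2afc", `Number of Trials` = 80L),
                     subject_params(alpha = 4, beta = 0.5), seed = 15)
  summ <- summarize_session(res)
  # brute-force recount
  t <- res$trials[!res$trials$outcome %in% c("no_response", "retrial"), ]
  pc_brute <- 100 * mean(t$outcome %in% c("correct_left", "correct_right"))
  expect_equal(summ$percent_correct, pc_brute)
  # learning curve: single session
  expect_equal(learning_curve(list(summ))$percent_correct,
               summ$percent_correct)
  # scripted improvement schedule -> monotone mean curve
  mk <- function(idx, pc) {
    structure(list(session_index = idx, percent_correct = pc,
                   d_prime = NA_real_, n_trials = 100L),
              class = "session_summary")
  }
  subj1 <- lapply(1:5, function(i) mk(i, 50 + 8 * i))
  subj2 <- lapply(1:3, function(i) mk(i, 55 + 8 * i))
  lc <- learning_curve(list(subj1, subj2))
  gm <- unique(lc[, c("session", "group_mean")])
  expect_true(all(diff(gm$group_mean[order(gm$session)]) > 0))
  # mixed lengths: sessions 4-5 average over the one subject that has them
  expect_equal(gm$group_mean[gm$session == 5], 90)
  expect_equal(gm$group_mean[gm$session == 1], mean(c(58, 63)))
  # advancement criteria
  expect_true(advancement_criterion(c(80, 78, 76), "2afc"))
  expect_false(advancement_criterion(c(80, 70, 90), "2afc"))
  expect_true(advancement_criterion(c(1.6, 1.7, 1.8), "gng"))
  expect_false(advancement_criterion(c(1.6, 1.4, 1.8), "gng"))
  expect_error(advancement_criterion(c(80, 90), "2afc"), "not-evaluable")
})

test_that("lick rasters align, re-debounce cleanly, and estimate rate", {
  res <- run_session(session_config("2afc", `Number of Trials` = 25L),
                     subject_params(lick_rate_hz = 10), seed = 19)
  lr <- lick_raster(res, align_to = "on:")
  # manual single-trial check
  ev <- res$events
  tr1 <- ev[!is.na(ev$trial) & ev$trial == 1, ]
  stim_on <- tr1$time[tr1$channel == "stimulus" &
                        startsWith(tr1$payload, "on:")][1]
  licks1 <- debounce_licks(sort(tr1$time[tr1$channel %in%
    c("center_lick", "left_lick", "right_lick")]))
  expect_equal(lr$raster[["1"]], licks1 - stim_on)
  # simulated ~10 Hz licker: rate estimate near 10 Hz
  expect_gt(lr$rate_hz, 7)
  expect_lt(lr$rate_hz, 13)
  # debounced input re-debounced is unchanged inside each trial's raster
  for (r in lr$raster) expect_identical(debounce_licks(r), r)
})
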