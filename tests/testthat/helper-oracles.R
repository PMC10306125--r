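# Independent oracles used across the suite. These deliberately do not
# share code with the implementation paths they check.

# scan a side sequence for the two randomization constraints:
# longest identical-side run and longest streak of consecutive switches
scan_side_sequence <- function(sides) {
  r <- rle(sides)
  max_run <- max(r$lengths)
  switches <- sides[-1] != sides[-length(sides)]
  max_switch_streak <- if (!any(switches)) 0L else {
    s <- rle(switches)
    max(s$lengths[s$values])
  }
  list(max_run = max_run, max_switch_streak = max_switch_streak)
}

# brute-force legality of appending `side` to `history` under the rules
# (history itself assumed legal)
brute_side_legal <- function(history, side, max_run = 3, max_switches = 4) {
  st <- scan_side_sequence(c(history, side))
  st$max_run <= max_run && st$max_switch_streak <= max_switches
}

# sliding-window response rule by exhaustive search
brute_evaluate <- function(licks, window, k) {
  licks <- licks[licks$time >= window[1] & licks$time < window[2], ,
                 drop = FALSE]
  best <- list(side = NA_character_, time = Inf)
  for (i in seq_len(nrow(licks))) {
    t_i <- licks$time[i]
    sp <- licks$spout[i]
    cnt <- sum(licks$spout == sp & licks$time >= t_i - 1 &
                 licks$time <= t_i)
    if (cnt >= k && t_i < best$time) best <- list(side = sp, time = t_i)
  }
  if (is.infinite(best$time)) list(side = NA_character_, time = NA_real_)
  else best
}

# truncated-exponential CDF by numerical integration of the density
oracle_trunc_exp_cdf <- function(q, minimum, maximum, rate) {
  span <- maximum - minimum
  norm <- stats::integrate(function(x) rate * exp(-rate * x), 0,
                           span)$value
  vapply(q, function(qq) {
    x <- min(max(qq - minimum, 0), span)
    if (x == 0) return(0)
    stats::integrate(function(y) rate * exp(-rate * y), 0, x)$value / norm
  }, numeric(1))
}

# a virtual subject that always answers on one side
one_sided_subject <- function(side) {
  if (side == "right") {
    subject_params(alpha = -100, beta = 1e-6, guess = 0, lapse = 0)
  } else {
    subject_params(alpha = 100, beta = 1e-6, guess = 0, lapse = 0)
  }
}

# deterministic, perfectly lateralized subject (g = l = 0, beta -> 0+)
perfect_subject <- function() {
  subject_params(alpha = 4, beta = 1e-9, guess = 0, lapse = 0)
}

# offset-to-window-open intervals measured from a session's event log
measured_offset_to_window <- function(result) {
  ev <- result$events
  vapply(sort(unique(ev$trial[!is.na(ev$trial)])), function(tr) {
    s <- ev[!is.na(ev$trial) & ev$trial == tr, , drop = FALSE]
    off <- s$time[s$channel == "stimulus" & startsWith(s$payload, "off:")]
    open <- s$time[s$channel == "state" & s$payload == "window_open"]
    if (length(off) && length(open)) open[1] - off[1] else NA_real_
  }, numeric(1))
}
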