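#' Virtual session clock and event buffer
#'
#' The engine is a pure discrete-event simulation: no wall-clock sleeping,
#' a single monotone session clock, and an append-only event buffer with
#' amortized O(1) growth. Every state transition, spout movement, lick,
#' stimulus edge, reward and punishment is stamped as an event.
#'
#' @param t0 session start time in seconds.
#' @return Object of class `session_clock`.
#' @export
session_clock <- function(t0 = 0) {
  cl <- new.env(parent = emptyenv())
  cl$now <- t0
  cl$n <- 0L
  # chunked buffer: small active chunk (cheap subassignment) flushed into a
  # list, avoiding the quadratic copy of one ever-growing vector
  cl$chunk_size <- 128L
  cl$i <- 0L
  cl$ct <- numeric(128L)
  cl$cc <- character(128L)
  cl$cp <- character(128L)
  cl$ctr <- integer(128L)
  cl$chunks <- list()
  class(cl) <- "session_clock"
  cl
}

flush_chunk <- function(clock) {
  if (clock$i == 0L) return(invisible(NULL))
  idx <- seq_len(clock$i)
  clock$chunks[[length(clock$chunks) + 1L]] <-
    list(time = clock$ct[idx], channel = clock$cc[idx],
         payload = clock$cp[idx], trial = clock$ctr[idx])
  clock$i <- 0L
  invisible(NULL)
}

emit <- function(clock, time, channel, payload, trial = NA_integer_) {
  i <- clock$i + 1L
  if (i > clock$chunk_size) {
    flush_chunk(clock)
    i <- 1L
  }
  clock$ct[i] <- time
  clock$cc[i] <- channel
  clock$cp[i] <- payload
  clock$ctr[i] <- trial
  clock$i <- i
  clock$n <- clock$n + 1L
  invisible(NULL)
}

advance <- function(clock, dt) {
  stopifnot(dt >= 0)
  clock$now <- clock$now + dt
  invisible(clock$now)
}

# all emitted events, sorted stably by time (events are scheduled out of
# order within a trial, e.g. a spout move that starts before a delay
# elapses)
events_df <- function(clock) {
  flush_chunk(clock)
  pull <- function(f) unlist(lapply(clock$chunks, `[[`, f),
                             use.names = FALSE)
  df <- data.frame(time = pull("time"), channel = pull("channel"),
                   payload = pull("payload"), trial = pull("trial"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Spout actuator model
#'
#' Travel time of a lick spout between retracted and extended positions.
#' The linear ("rod") actuator moves at 25 mm/s; the servo-driven
#' linear-converter assembly at 50 mm/s. Travel distance is the
#' GUI-entered millimeter value.
#'
#' @param actuator `"linear"` or `"servo"`.
#' @param travel_mm travel distance, mm (>= 0).
#' @param speed_mm_per_s override of the actuator's speed.
#' @return Object of class `spout_model`.
#' @export
spout_model <- function(actuator = c("servo", "linear"), travel_mm = 40,
                        speed_mm_per_s = NULL) {
  actuator <- match.arg(actuator)
  if (is.null(speed_mm_per_s)) {
    speed_mm_per_s <- switch(actuator, linear = 25, servo = 50)
  }
  if (speed_mm_per_s <= 0) {
    stop("invalid-config: actuator speed must be positive", call. = FALSE)
  }
  stopifnot(travel_mm >= 0)
  structure(list(actuator = actuator, travel_mm = travel_mm,
                 speed_mm_per_s = speed_mm_per_s), class = "spout_model")
}

#' Spout travel time
#'
#' @param model a [spout_model()].
#' @return seconds between movement start and arrival.
#' @export
spout_travel_time <- function(model) {
  stopifnot(inherits(model, "spout_model"))
  model$travel_mm / model$speed_mm_per_s
}

#' Classify a response from lick trains
#'
#' The first spout to accumulate `required_licks_per_s` licks within any
#' 1 s sliding sub-window of the response window wins; a requirement of 1
#' reduces to first-lick-wins. Used to enforce deliberate choice by
#' requiring sustained licking (typically raised to four or five licks per
#' second late in training).
#'
#' @param licks data.frame with columns `time` (s) and `spout`, or a list
#'   of `lick_train` objects.
#' @param window numeric length-2 response window `[open, close)`.
#' @param required_licks_per_s integer >= 1.
#' @return list with `side` (spout name or `NA`) and `time` (decision
#'   time, `NA` if none).
#' @export
evaluate_response <- function(licks, window, required_licks_per_s = 1L) {
  stopifnot(required_licks_per_s >= 1)
  k <- as.integer(required_licks_per_s)
  if (inherits(licks, "lick_train")) licks <- list(licks)
  if (is.list(licks) && !is.data.frame(licks)) {
    licks <- do.call(rbind, lapply(licks, function(tr) {
      if (length(tr$times) == 0L) return(NULL)
      data.frame(time = tr$times, spout = tr$spout,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(licks) || nrow(licks) == 0L) {
    return(list(side = NA_character_, time = NA_real_))
  }
  licks <- licks[licks$time >= window[1] & licks$time < window[2], ,
                 drop = FALSE]
  if (nrow(licks) == 0L) return(list(side = NA_character_, time = NA_real_))
  best_side <- NA_character_
  best_time <- Inf
  for (sp in unique(licks$spout)) {
    tt <- sort(licks$time[licks$spout == sp])
    if (length(tt) < k) next
    if (k == 1L) {
      q <- tt[1L]
    } else {
      ok <- which(tt[k:length(tt)] - tt[seq_len(length(tt) - k + 1L)] <= 1)
      if (length(ok) == 0L) next
      q <- tt[ok[1L] + k - 1L]
    }
    if (q < best_time) {
      best_time <- q
      best_side <- sp
    }
  }
  if (is.na(best_side)) list(side = NA_character_, time = NA_real_)
  else list(side = best_side, time = best_time)
}

# emit a lick train on a spout channel, applying the sensor lockout
emit_licks <- function(clock, train_times, channel, lockout, trial) {
  kept <- debounce_licks(train_times, lockout)
  for (t in kept) emit(clock, t, channel, "lick", trial)
  kept
}

lick_channel <- function(side) {
  switch(side, left = "left_lick", right = "right_lick",
         center = "center_lick")
}

#' Run one 2AFC trial
#'
#' State machine: the center spout extends and the trial waits for a
#' self-initiation lick (rewarded with probability "Percentage of Center
#' Rewards"); a prestimulus delay follows, then the stimulus, then the
#' poststimulus delay with the side spouts still retracted (center licks
#' during this hold are logged, and rewarded once when "TCSA reward" is
#' enabled); the side spouts then extend — their movement is scheduled so
#' arrival coincides with the end of the delay — and the response window
#' opens; the response is classified under the lick-per-second
#' requirement, rewarded or punished, and the trial closes with its ITI.
#' A subject that never initiates within "Initiation Timeout (s)" yields
#' a `no_response` outcome and the session continues.
#'
#' @param spec one-row data.frame trial spec (see [schedule_trials()]).
#' @param subject a [subject_params()].
#' @param config a [session_config()] for the 2AFC task.
#' @param clock a [session_clock()].
#' @param rngs named list of [rng_stream()]s (`subject`, `rewards`).
#' @return Outcome list: `label`, `side`, `response_time`, `rewarded`.
#' @export
run_2afc_trial <- function(spec, subject, config, clock, rngs) {
  trial <- spec$index
  model <- spout_model(config[["Actuator"]], config[["Spout Travel (mm)"]])
  travel <- spout_travel_time(model)
  lockout <- config[["Lick Lockout (s)"]]
  emit(clock, clock$now, "state", sprintf("trial_start:%d", trial), trial)

  # center spout out; initiation
  emit(clock, clock$now, "center_spout", "move_out", trial)
  advance(clock, travel)
  emit(clock, clock$now, "center_spout", "extended", trial)
  engaged <- with_stream(rngs$subject, runif(1)) < subject$engagement
  init_lat <- if (engaged) {
    with_stream(rngs$subject,
                stats::rlnorm(1, subject$rt_meanlog, subject$rt_sdlog))
  } else Inf
  timeout <- config[["Initiation Timeout (s)"]]
  if (init_lat > timeout) {
    advance(clock, timeout)
    emit(clock, clock$now, "state", "initiation_timeout", trial)
    emit(clock, clock$now, "center_spout", "move_in", trial)
    advance(clock, travel)
    emit(clock, clock$now, "center_spout", "retracted", trial)
    emit(clock, clock$now, "state", "iti_start", trial)
    advance(clock, spec$iti)
    return(list(label = "no_response", side = NA_character_,
                response_time = NA_real_, rewarded = FALSE))
  }
  advance(clock, init_lat)
  emit(clock, clock$now, "center_lick", "lick", trial)
  emit(clock, clock$now, "state", "initiated", trial)
  if (with_stream(rngs$rewards, runif(1)) <
      config[["Percentage of Center Rewards"]] / 100) {
    emit(clock, clock$now, "reward", "center", trial)
  }

  # prestimulus delay, stimulus
  advance(clock, spec$stim_start_delay)
  stim_on <- clock$now
  emit(clock, stim_on, "stimulus", sprintf("on:%s", spec$stimulus), trial)
  stim_dur <- config[["Stimulus Duration (ms)"]] / 1000
  stim_off <- stim_on + stim_dur
  emit(clock, stim_off, "stimulus", sprintf("off:%s", spec$stimulus), trial)

  # poststimulus hold (Time Center Spout Available), side spouts retracted
  t_open <- stim_off + spec$post_stim_delay
  if (spec$post_stim_delay > 0) {
    hold <- generate_licks("center", spec$post_stim_delay, subject,
                           rng = rngs$subject)
    kept <- emit_licks(clock, stim_off + hold$times, "center_lick",
                       lockout, trial)
    if (isTRUE(config[["TCSA reward"]]) && length(kept)) {
      emit(clock, kept[1L], "reward", "center", trial)
    }
  }
  emit(clock, max(stim_off, t_open - travel), "side_spout", "move_out",
       trial)
  clock$now <- max(t_open, stim_off + travel)
  t_open <- clock$now
  emit(clock, t_open, "side_spout", "extended", trial)
  emit(clock, t_open, "state", "window_open", trial)

  # response
  win_len <- config[["Response Window (s)"]]
  responded <- with_stream(rngs$subject, runif(1)) < subject$engagement
  choice <- list(side = NA_character_, time = NA_real_)
  if (responded) {
    side <- choose_side(spec$column, subject, rng = rngs$subject)
    train <- generate_licks(side, win_len, subject, rng = rngs$subject)
    kept <- emit_licks(clock, t_open + train$times, lick_channel(side),
                       lockout, trial)
    choice <- evaluate_response(
      data.frame(time = kept, spout = side, stringsAsFactors = FALSE),
      c(t_open, t_open + win_len),
      config[["Required Licks Per Second"]])
  }
  advance(clock, win_len)
  emit(clock, clock$now, "side_spout", "move_in", trial)
  emit(clock, clock$now + travel, "side_spout", "retracted", trial)

  correct_side <- if (spec$kind == "2afc-right") "right" else "left"
  if (is.na(choice$side)) {
    label <- "no_response"
    rewarded <- FALSE
  } else if (choice$side == correct_side) {
    label <- if (correct_side == "right") "correct_right" else "correct_left"
    rewarded <- TRUE
    emit(clock, choice$time, "reward", choice$side, trial)
  } else {
    label <- "incorrect"
    rewarded <- FALSE
    emit(clock, choice$time, "punishment", "on:noise", trial)
    emit(clock, choice$time + config[["Punishment Duration (s)"]],
         "punishment", "off", trial)
  }
  emit(clock, clock$now, "state", sprintf("outcome:%s", label), trial)
  emit(clock, clock$now, "state", "iti_start", trial)
  advance(clock, spec$iti)
  rt <- if (is.na(choice$time)) NA_real_ else choice$time - t_open
  list(label = label, side = choice$side, response_time = rt,
       rewarded = rewarded)
}

#' Run one Go-NoGo trial
#'
#' Trials start automatically after the ITI, optionally signaled by a
#' visual or auditory cue ("Trial Start Signal"); a prestimulus delay
#' ("Stim Start Delay") precedes the stimulus, and a poststimulus "Delay
#' Period" separates it from the response window. The delay timer starts
#' at stimulus onset by default (`Delay Reference = "onset"`): the
#' configuration (min 1, max 5, 6 steps) with a 200 ms stimulus then
#' yields window openings 0.8-4.8 s after stimulus offset. The spout's
#' outward movement is scheduled so that it arrives exactly when the delay
#' elapses. A lick in the window is a hit (go, rewarded) or false alarm
#' (nogo, punished); withholding is a miss or correct rejection. A correct
#' rejection draws the next ITI from the "Short ITI" range, all other
#' outcomes from the long range.
#'
#' @inheritParams run_2afc_trial
#' @return Outcome list: `label`, `response_time`, `rewarded`,
#'   `short_iti` (logical).
#' @export
run_gng_trial <- function(spec, subject, config, clock, rngs) {
  trial <- spec$index
  model <- spout_model(config[["Actuator"]], config[["Spout Travel (mm)"]])
  travel <- spout_travel_time(model)
  lockout <- config[["Lick Lockout (s)"]]
  emit(clock, clock$now, "state", sprintf("trial_start:%d", trial), trial)

  cue <- config[["Trial Start Signal"]]
  if (!identical(cue, "none")) {
    dur <- config[["Trial Start Signal Duration (s)"]]
    emit(clock, clock$now, "stimulus", sprintf("cue_on:%s", cue), trial)
    advance(clock, dur)    # cue and stimulus never overlap
    emit(clock, clock$now, "stimulus", sprintf("cue_off:%s", cue), trial)
  }
  advance(clock, spec$stim_start_delay)
  stim_on <- clock$now
  stim_dur <- config[["Stimulus Duration (ms)"]] / 1000
  stim_off <- stim_on + stim_dur
  emit(clock, stim_on, "stimulus", sprintf("on:%s", spec$stimulus), trial)
  emit(clock, stim_off, "stimulus", sprintf("off:%s", spec$stimulus), trial)

  ref <- if (identical(config[["Delay Reference"]], "offset")) stim_off
         else stim_on
  t_open <- max(ref + spec$delay_period, stim_off)
  emit(clock, max(stim_off, t_open - travel), "center_spout", "move_out",
       trial)
  clock$now <- t_open
  emit(clock, t_open, "center_spout", "extended", trial)
  emit(clock, t_open, "state", "window_open", trial)

  win_len <- config[["Response Window (s)"]]
  resp <- respond_gng(spec$kind, t_open - stim_off, subject,
                      rng = rngs$subject)
  licked <- resp$lick && resp$latency < win_len
  if (licked) {
    train <- generate_licks("center", win_len, subject, rng = rngs$subject,
                            reaction_time = resp$latency)
    times <- unique(sort(c(resp$latency, train$times)))
    emit_licks(clock, t_open + times, "center_lick", lockout, trial)
  }
  advance(clock, win_len)
  emit(clock, clock$now, "center_spout", "move_in", trial)
  emit(clock, clock$now + travel, "center_spout", "retracted", trial)

  label <- if (spec$kind == "go") {
    if (licked) "hit" else "miss"
  } else {
    if (licked) "false_alarm" else "correct_rejection"
  }
  rewarded <- label == "hit"
  if (rewarded) emit(clock, t_open + resp$latency, "reward", "center", trial)
  if (label == "false_alarm") {
    emit(clock, t_open + resp$latency, "punishment", "on:noise", trial)
    emit(clock, t_open + resp$latency + config[["Punishment Duration (s)"]],
         "punishment", "off", trial)
  }
  emit(clock, clock$now, "state", sprintf("outcome:%s", label), trial)
  emit(clock, clock$now, "state", "iti_start", trial)
  short <- label == "correct_rejection"
  advance(clock, if (short) spec$iti_short else spec$iti_long)
  list(label = label, side = if (licked) "center" else NA_character_,
       response_time = if (licked) resp$latency else NA_real_,
       rewarded = rewarded, short_iti = short)
}

#' Run a passive-stimulation block
#'
#' Presents `Number of Presentations` stimuli separated by the configured
#' interstimulus interval. In "Combination" mode the four bar orientations
#' (0, 45 left, 45 right, 90 degrees) are presented randomly via a
#' sampling pool (equal sampling). In multisensory mode each presentation
#' pairs a visual and an auditory stimulus ordered by the "Visual first"
#' flag and separated by "delay between (ms)". On/off edges are emitted
#' as alignment pulses.
#'
#' @param config a [session_config()] for the passive task.
#' @param clock a [session_clock()].
#' @param rngs named list with stream `stimuli`.
#' @return invisible event count.
#' @export
run_passive_block <- function(config, clock, rngs) {
  n <- config[["Number of Presentations"]]
  isi <- config[["Interstimulus Interval (s)"]]
  stopifnot(n >= 1, isi >= 0)
  stim_dur <- config[["Stimulus Duration (ms)"]] / 1000
  pool <- if (isTRUE(config[["Combination"]])) {
    sampling_pool(c("0", "45left", "45right", "90"))
  }
  for (i in seq_len(n)) {
    id <- if (!is.null(pool)) {
      paste0("bars_", draw_from_pool(pool, rngs$stimuli))
    } else config[["Stimulus"]]
    if (isTRUE(config[["Multisensory"]])) {
      gap <- config[["delay between (ms)"]] / 1000
      first <- if (isTRUE(config[["Visual first"]])) "visual" else "auditory"
      second <- if (first == "visual") "auditory" else "visual"
      t1 <- clock$now
      t2 <- t1 + gap
      emit(clock, t1, "stimulus", sprintf("on:%s_%s", first, id), i)
      emit(clock, t1 + stim_dur, "stimulus",
           sprintf("off:%s_%s", first, id), i)
      emit(clock, t2, "stimulus", sprintf("on:%s_%s", second, id), i)
      emit(clock, t2 + stim_dur, "stimulus",
           sprintf("off:%s_%s", second, id), i)
      clock$now <- max(t1 + stim_dur, t2 + stim_dur)
    } else {
      emit(clock, clock$now, "stimulus", sprintf("on:%s", id), i)
      advance(clock, stim_dur)
      emit(clock, clock$now, "stimulus", sprintf("off:%s", id), i)
    }
    if (i < n) advance(clock, isi)
  }
  invisible(clock$n)
}
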