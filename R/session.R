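#' Run a complete simulated session
#'
#' Orchestrates scheduler, engine and virtual subject on the virtual
#' clock. Trial specs are generated lazily so that outcome-dependent rules
#' (the Go-NoGo CR rule, short vs long ITI, 2AFC retrial mode) see the
#' true previous outcome. All randomness flows from `seed` through named
#' sub-streams (`sides`, `delays`, `itis`, `mix`, `subject`, `rewards`,
#' `stimuli`), so identical config + seed replays a byte-identical
#' session.
#'
#' @param config a [session_config()].
#' @param subject a [subject_params()] (ignored for the passive task).
#' @param seed integer session seed.
#' @return Object of class `session_result`: list with `task`, `seed`,
#'   `config`, `trials` (one row per trial attempt) and `events`
#'   (timestamped log).
#' @export
run_session <- function(config, subject = subject_params(), seed = 1L) {
  stopifnot(inherits(config, "session_config"))
  task <- config[["Task"]]
  rngs <- lapply(
    stats::setNames(nm = c("sides", "delays", "itis", "mix", "subject",
                           "rewards", "stimuli")),
    function(nm) rng_stream(seed, nm))
  clock <- session_clock()
  trials <- switch(task,
    "2afc" = run_session_2afc(config, subject, clock, rngs),
    "gng" = run_session_gng(config, subject, clock, rngs),
    "passive" = {
      run_passive_block(config, clock, rngs)
      data.frame()
    })
  structure(list(task = task, seed = as.integer(seed), config = config,
                 trials = trials, events = events_df(clock)),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result: %s, %d trial rows, %d events, seed %d>\n",
              x$task, nrow(x$trials), nrow(x$events), x$seed))
  invisible(x)
}

# expand the GUI (min, max, steps) triple into a sampling pool, or NULL
# for a single fixed value
delay_pool <- function(config, prefix) {
  tbl <- build_delay_table(config[[paste0(prefix, " Min")]],
                           config[[paste0(prefix, " Max")]],
                           config[[paste0(prefix, " Steps")]])
  if (tbl$steps == 1L) tbl$values[1] else sampling_pool(tbl$values)
}

pool_or_fixed <- function(pool, rng) {
  if (inherits(pool, "sampling_pool")) draw_from_pool(pool, rng) else pool
}

# columnar trial-table accumulator: data.frame work only once per session
trial_acc <- function(n_guess) {
  a <- new.env(parent = emptyenv())
  a$n <- 0L
  a$cap <- n_guess
  a$index <- integer(n_guess); a$kind <- character(n_guess)
  a$stimulus <- character(n_guess); a$column <- numeric(n_guess)
  a$training <- logical(n_guess); a$retrial_of <- integer(n_guess)
  a$stim_start_delay <- numeric(n_guess)
  a$post_stim_delay <- numeric(n_guess); a$iti <- numeric(n_guess)
  a$outcome <- character(n_guess); a$side <- character(n_guess)
  a$response_time <- numeric(n_guess); a$rewarded <- logical(n_guess)
  a
}

acc_push <- function(a, index, kind, stimulus, column, training,
                     retrial_of, stim_start_delay, post_stim_delay, iti,
                     out) {
  i <- a$n + 1L
  if (i > a$cap) {
    a$cap <- a$cap * 2L
    for (f in c("index", "kind", "stimulus", "column", "training",
                "retrial_of", "stim_start_delay", "post_stim_delay",
                "iti", "outcome", "side", "response_time", "rewarded")) {
      length(a[[f]]) <- a$cap
    }
  }
  a$index[i] <- index; a$kind[i] <- kind
  a$stimulus[i] <- as.character(stimulus); a$column[i] <- column
  a$training[i] <- training; a$retrial_of[i] <- retrial_of
  a$stim_start_delay[i] <- stim_start_delay
  a$post_stim_delay[i] <- post_stim_delay; a$iti[i] <- iti
  a$outcome[i] <- out$label
  a$side[i] <- if (is.null(out$side)) NA_character_ else out$side
  a$response_time[i] <- out$response_time; a$rewarded[i] <- out$rewarded
  a$n <- i
}

acc_df <- function(a) {
  i <- seq_len(a$n)
  data.frame(index = a$index[i], kind = a$kind[i], stimulus = a$stimulus[i],
             column = a$column[i], training = a$training[i],
             retrial_of = a$retrial_of[i],
             stim_start_delay = a$stim_start_delay[i],
             post_stim_delay = a$post_stim_delay[i], iti = a$iti[i],
             outcome = a$outcome[i], side = a$side[i],
             response_time = a$response_time[i], rewarded = a$rewarded[i],
             stringsAsFactors = FALSE)
}

run_session_2afc <- function(config, subject, clock, rngs) {
  n <- config[["Number of Trials"]]
  mix <- mix_trials(config[["Fraction Training"]],
                    parse_id_list(config[["Training Stimuli"]]),
                    parse_id_list(config[["Novel Stimuli"]]),
                    n, rng = rngs$mix, exact = config[["Exact Mix"]])
  train_ids <- parse_id_list(config[["Training Stimuli"]])
  ssd_pool <- delay_pool(config, "Stim Start Delay (s)")
  tcsa_pool <- delay_pool(config, "Time Center Spout Available (s)")
  constraints_on <- !isTRUE(config[["Override Consec Constraint"]])
  p_right <- config[["Percentage of Right Trials"]] / 100
  history <- character(n)
  n_hist <- 0L
  acc <- trial_acc(n + 16L)
  attempt <- 0L
  for (i in seq_len(n)) {
    training <- mix$training[i]
    if (training) {
      side <- next_trial_side(history[seq_len(n_hist)], p_right,
                              constraints_on, rng = rngs$sides)
      stimulus <- if (side == "right") max(train_ids) else min(train_ids)
    } else {
      stimulus <- mix$stimulus[i]
      col <- suppressWarnings(as.numeric(stimulus))
      side <- if (is.na(col) || col == 4) {
        with_stream(rngs$sides, if (runif(1) < 0.5) "right" else "left")
      } else if (col > 4) "right" else "left"
    }
    n_hist <- n_hist + 1L
    history[n_hist] <- side
    kind <- paste0("2afc-", side)
    column <- suppressWarnings(as.numeric(stimulus))
    ssd <- pool_or_fixed(ssd_pool, rngs$delays)
    psd <- pool_or_fixed(tcsa_pool, rngs$delays)
    retrial_of <- NA_integer_
    n_retrials <- 0L
    repeat {
      attempt <- attempt + 1L
      spec <- list(index = attempt, kind = kind, stimulus = stimulus,
                   column = column, stim_start_delay = ssd,
                   post_stim_delay = psd,
                   iti = sample_iti(config[["ITI Min (s)"]],
                                    config[["ITI Max (s)"]],
                                    rng = rngs$itis))
      out <- run_2afc_trial(spec, subject, config, clock, rngs)
      retry <- isTRUE(config[["Retrial Mode"]]) &&
        mix$retrial_eligible[i] && identical(out$label, "incorrect") &&
        n_retrials < config[["Max Retrials"]]
      if (retry) {
        out$label <- "retrial"
        if (is.na(retrial_of)) retrial_of <- attempt
        n_retrials <- n_retrials + 1L
      }
      acc_push(acc, attempt, kind, stimulus, column, training, retrial_of,
               ssd, psd, spec$iti, out)
      if (!retry) break
    }
  }
  acc_df(acc)
}

run_session_gng <- function(config, subject, clock, rngs) {
  n <- config[["Number of Trials"]]
  ssd_pool <- delay_pool(config, "Stim Start Delay (s)")
  go_pool <- delay_pool(config, "Delay Period (s)")
  nogo_pool <- delay_pool(config, "Delay Period (s)")  # separate draws
  p_go <- config[["Percentage of Go Trials"]] / 100
  prev <- NA_character_
  acc <- trial_acc(n)
  for (i in seq_len(n)) {
    kind <- next_trial_gng(p_go, config[["CR rule ON"]], prev,
                           rng = rngs$sides)
    spec <- list(
      index = i, kind = kind,
      stimulus = if (kind == "go") config[["Go Stimulus"]]
                 else config[["NoGo Stimulus"]],
      stim_start_delay = pool_or_fixed(ssd_pool, rngs$delays),
      delay_period = pool_or_fixed(
        if (kind == "go") go_pool else nogo_pool, rngs$delays),
      iti_short = sample_iti(config[["Short ITI Min (s)"]],
                             config[["Short ITI Max (s)"]],
                             rng = rngs$itis),
      iti_long = sample_iti(config[["ITI Min (s)"]],
                            config[["ITI Max (s)"]], rng = rngs$itis))
    out <- run_gng_trial(spec, subject, config, clock, rngs)
    prev <- out$label
    acc_push(acc, i, kind, spec$stimulus, NA_real_, TRUE, NA_integer_,
             spec$stim_start_delay, spec$delay_period,
             if (out$short_iti) spec$iti_short else spec$iti_long, out)
  }
  acc_df(acc)
}
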