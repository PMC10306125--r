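#' Build a delay table
#'
#' The GUI's three-box idiom (minimum, maximum, number of steps) expands to
#' an evenly spaced inclusive grid of delays in seconds. `steps = 1` defines
#' a single delay equal to `minimum` regardless of `maximum`, matching the
#' single-delay idiom (min = max = steps = 1).
#'
#' @param minimum,maximum delay range in seconds, `maximum >= minimum`.
#' @param steps positive integer number of grid points.
#' @return Object of class `delay_table` with fields `minimum`, `maximum`,
#'   `steps`, `values`.
#' @examples
#' build_delay_table(1, 6, 6)$values  # 1 2 3 4 5 6
#' @export
build_delay_table <- function(minimum, maximum, steps) {
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 ||
      steps != as.integer(steps)) {
    stop("invalid-config: steps must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(minimum) || !is.numeric(maximum) || maximum < minimum) {
    stop("invalid-config: maximum must be >= minimum", call. = FALSE)
  }
  steps <- as.integer(steps)
  values <- if (steps == 1L) minimum else seq(minimum, maximum, length.out = steps)
  structure(list(minimum = minimum, maximum = maximum, steps = steps,
                 values = values),
            class = "delay_table")
}

#' @export
print.delay_table <- function(x, ...) {
  cat(sprintf("<delay_table %g..%g s, %d steps: %s>\n", x$minimum, x$maximum,
              x$steps, paste(signif(x$values, 4), collapse = ", ")))
  invisible(x)
}

#' Sampling pool: random draws without replacement, reshuffled on depletion
#'
#' Items are drawn randomly without replacement until the pool is depleted,
#' then the pool is refilled and reshuffled, guaranteeing equal sampling:
#' after k * length(items) draws every item has appeared exactly k times.
#'
#' @param items non-empty vector or list of values.
#' @return Object of class `sampling_pool` (mutable environment).
#' @export
sampling_pool <- function(items) {
  if (length(items) == 0L) {
    stop("invalid-config: sampling pool requires a non-empty item list",
         call. = FALSE)
  }
  p <- new.env(parent = emptyenv())
  p$items <- items
  p$remaining <- integer(0)  # indices into items not yet drawn this cycle
  class(p) <- "sampling_pool"
  p
}

#' Draw one item from a sampling pool
#'
#' @param pool a [sampling_pool()].
#' @param rng optional [rng_stream()].
#' @return One element of `pool$items`.
#' @export
draw_from_pool <- function(pool, rng = NULL) {
  stopifnot(inherits(pool, "sampling_pool"))
  if (length(pool$remaining) == 0L) {
    pool$remaining <- with_stream(rng, sample.int(length(pool$items)))
  }
  i <- pool$remaining[1L]
  pool$remaining <- pool$remaining[-1L]
  pool$items[[i]]
}

# Trailing run length of identical sides and trailing count of consecutive
# side switches; sides is a character vector of "left"/"right".
.side_tail_stats <- function(sides) {
  n <- length(sides)
  run <- 0L
  if (n > 0L) {
    run <- 1L
    while (run < n && sides[n - run] == sides[n]) run <- run + 1L
  }
  switches <- 0L
  i <- n
  while (i > 1L && sides[i] != sides[i - 1L]) {
    switches <- switches + 1L
    i <- i - 1L
  }
  list(run = run, switches = switches)
}

#' Draw the next 2AFC trial side under the consecutive-trial constraints
#'
#' A Bernoulli(`p_right`) draw proposes a side; if appending it would create
#' a run of more than three identical sides, or a streak of more than four
#' consecutive left/right switches, the side is forced to the unique
#' rule-obeying alternative (the two rules can never forbid both sides at
#' once: a long identical run implies a broken switch streak and vice
#' versa). With `constraints_on = FALSE` ("Override Consec Constraint") the
#' raw draw is returned, needed when more than ~66% of trials should go to
#' one side.
#'
#' @param history character vector of previous sides (`"left"`/`"right"`).
#' @param p_right probability of proposing a right trial.
#' @param constraints_on logical; apply the two rules.
#' @param rng optional [rng_stream()].
#' @return `"left"` or `"right"`.
#' @export
next_trial_side <- function(history = character(0), p_right = 0.5,
                            constraints_on = TRUE, rng = NULL) {
  stopifnot(p_right >= 0, p_right <= 1)
  side <- with_stream(rng, if (runif(1) < p_right) "right" else "left")
  if (!constraints_on) return(side)
  if (side_violates(history, side)) side <- other_side(side)
  side
}

other_side <- function(side) if (side == "left") "right" else "left"

# TRUE if appending `side` to `history` breaks either constraint:
# identical-side run > 3, or consecutive switch streak > 4.
side_violates <- function(history, side,
                          max_run = 3L, max_switches = 4L) {
  st <- .side_tail_stats(c(history, side))
  st$run > max_run || st$switches > max_switches
}

#' Draw the next Go-NoGo trial kind
#'
#' With the "CR rule ON" box checked, a correct rejection is followed by a
#' Go trial; otherwise the kind is Bernoulli over Go/NoGo with the
#' configured "Percentage of Go Trials".
#'
#' @param p_go probability of a Go trial.
#' @param cr_rule_on logical.
#' @param previous_outcome outcome label of the previous trial (or `NA`).
#' @param rng optional [rng_stream()].
#' @return `"go"` or `"nogo"`.
#' @export
next_trial_gng <- function(p_go = 0.5, cr_rule_on = FALSE,
                           previous_outcome = NA_character_, rng = NULL) {
  stopifnot(p_go >= 0, p_go <= 1)
  if (isTRUE(cr_rule_on) && identical(previous_outcome, "correct_rejection")) {
    return("go")
  }
  with_stream(rng, if (runif(1) < p_go) "go" else "nogo")
}

#' Sample an intertrial interval
#'
#' ITIs are exponential within a user-defined (minimum, maximum) window:
#' `minimum + E` with E a truncated exponential on `[0, maximum - minimum]`,
#' sampled by inverse CDF. The rate defaults to `3 / (maximum - minimum)`
#' so the untruncated mean is a third of the window (~95% of the mass
#' inside it); the source system does not pin the rate, so it is exposed.
#'
#' @param minimum,maximum window in seconds, `maximum >= minimum >= 0`.
#' @param rng optional [rng_stream()].
#' @param rate exponential rate in 1/s; default `3 / (maximum - minimum)`.
#' @return A single ITI in seconds, always within `[minimum, maximum]`.
#' @export
sample_iti <- function(minimum, maximum, rng = NULL, rate = NULL) {
  if (!is.numeric(minimum) || !is.numeric(maximum) ||
      minimum < 0 || maximum < minimum) {
    stop("invalid-config: need maximum >= minimum >= 0", call. = FALSE)
  }
  span <- maximum - minimum
  if (span == 0) return(minimum)
  if (is.null(rate)) rate <- 3 / span
  stopifnot(rate > 0)
  u <- with_stream(rng, runif(1))
  # inverse CDF of exponential truncated to [0, span]
  minimum + (-log(1 - u * (1 - exp(-rate * span))) / rate)
}

#' Truncated-exponential ITI distribution function
#'
#' CDF of the ITI produced by [sample_iti()]; exposed for goodness-of-fit
#' testing against empirical samples.
#'
#' @param q quantiles in seconds.
#' @inheritParams sample_iti
#' @export
piti <- function(q, minimum, maximum, rate = NULL) {
  span <- maximum - minimum
  if (span == 0) return(as.numeric(q >= minimum))
  if (is.null(rate)) rate <- 3 / span
  x <- pmin(pmax(q - minimum, 0), span)
  (1 - exp(-rate * x)) / (1 - exp(-rate * span))
}

#' Mix training and novel (test) stimuli into a trial sequence
#'
#' Each trial is a training trial with probability `fraction_training`
#' (per-trial Bernoulli; `exact = TRUE` instead fixes the count to
#' `round(fraction_training * n)` and shuffles). Training stimulus identity
#' is drawn from `training_stimuli`, novel identity from a
#' [sampling_pool()] over `novel_stimuli` so that every novel stimulus is
#' sampled near-equally. Retrial/punishment eligibility is granted only to
#' training trials, so novel stimuli never trigger corrective feedback.
#'
#' @param fraction_training proportion of training trials in `[0, 1]`;
#'   the psychometric-testing phase uses 0.7.
#' @param training_stimuli,novel_stimuli non-empty vectors of stimulus ids
#'   (a set may be empty only if its fraction is 0).
#' @param n number of trials.
#' @param rng optional [rng_stream()].
#' @param exact logical; enforce the mix exactly per session.
#' @return data.frame with columns `stimulus`, `training` (logical),
#'   `retrial_eligible` (logical).
#' @export
mix_trials <- function(fraction_training, training_stimuli, novel_stimuli,
                       n, rng = NULL, exact = FALSE) {
  stopifnot(n >= 1, fraction_training >= 0, fraction_training <= 1)
  if (fraction_training > 0 && length(training_stimuli) == 0L) {
    stop("invalid-config: training stimulus set is empty", call. = FALSE)
  }
  if (fraction_training < 1 && length(novel_stimuli) == 0L) {
    stop("invalid-config: novel stimulus set is empty", call. = FALSE)
  }
  training <- if (exact) {
    k <- round(fraction_training * n)
    with_stream(rng, sample(c(rep(TRUE, k), rep(FALSE, n - k))))
  } else {
    with_stream(rng, runif(n) < fraction_training)
  }
  train_pool <- if (length(training_stimuli)) sampling_pool(training_stimuli)
  novel_pool <- if (length(novel_stimuli)) sampling_pool(novel_stimuli)
  stimulus <- vector(mode = "list", n)
  for (i in seq_len(n)) {
    stimulus[[i]] <- if (training[i]) {
      draw_from_pool(train_pool, rng)
    } else {
      draw_from_pool(novel_pool, rng)
    }
  }
  data.frame(stimulus = unlist(stimulus), training = training,
             retrial_eligible = training, stringsAsFactors = FALSE)
}
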