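#' Virtual subject parameters
#'
#' A stochastic agent that converts trial stimuli into lick trains. Its
#' 2AFC choices follow the four-parameter psychometric function
#' \deqn{\psi(x) = g + (1 - g - l) / (1 + \exp(-(x - \alpha)/\beta))}
#' where \eqn{\alpha} locates the curve on the stimulus axis (column
#' units), \eqn{\beta} is the discrimination sensitivity (slope), and
#' \eqn{g}, \eqn{l} are the guess and lapse rates. Licking is a
#' reaction-time-shifted burst at `lick_rate_hz` (typical licking is about
#' 10 Hz). Reaction times are log-normal with median
#' `exp(rt_meanlog)` seconds. No published generative model of the animal
#' exists: this subject is a test harness, not a behavioral claim.
#'
#' @param alpha psychometric location, stimulus-column units.
#' @param beta discrimination sensitivity (> 0).
#' @param guess,lapse guess and lapse rates, each in `[0, 0.5]`,
#'   `guess + lapse < 1`.
#' @param lick_rate_hz licking frequency of a lick burst, Hz.
#' @param rt_meanlog,rt_sdlog log-normal reaction-time parameters
#'   (defaults give median 0.3 s).
#' @param engagement probability of initiating/responding on a trial.
#' @param p_lick_go,p_lick_nogo Go-NoGo response rates to the go and nogo
#'   stimulus; their separation sets the generated d'.
#' @param delay_decay_tau optional time constant (s) for exponential decay
#'   of the go/nogo rate separation with the response delay; `Inf`
#'   disables decay (memory effects are optional and phenomenological).
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(alpha = 4, beta = 1, guess = 0.05, lapse = 0.05,
                           lick_rate_hz = 10, rt_meanlog = log(0.3),
                           rt_sdlog = 0.35, engagement = 1,
                           p_lick_go = 0.9, p_lick_nogo = 0.2,
                           delay_decay_tau = Inf) {
  stopifnot(beta >= 0, guess >= 0, guess <= 0.5, lapse >= 0, lapse <= 0.5,
            guess + lapse < 1, lick_rate_hz > 0,
            engagement >= 0, engagement <= 1,
            p_lick_go >= 0, p_lick_go <= 1, p_lick_nogo >= 0,
            p_lick_nogo <= 1, delay_decay_tau > 0)
  structure(list(alpha = alpha, beta = beta, guess = guess, lapse = lapse,
                 lick_rate_hz = lick_rate_hz, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, engagement = engagement,
                 p_lick_go = p_lick_go, p_lick_nogo = p_lick_nogo,
                 delay_decay_tau = delay_decay_tau),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    "<subject alpha=%g beta=%g g=%g l=%g lick=%g Hz engage=%g>\n",
    x$alpha, x$beta, x$guess, x$lapse, x$lick_rate_hz, x$engagement))
  invisible(x)
}

#' Four-parameter psychometric function
#'
#' Probability of a rightward choice at stimulus value `x`. `beta = 0` is
#' taken as the step-function limit.
#'
#' @param x stimulus-axis value(s).
#' @param alpha,beta,guess,lapse curve parameters (see [subject_params()]).
#' @return Probabilities in `[guess, 1 - lapse]`.
#' @export
psychometric <- function(x, alpha, beta, guess = 0, lapse = 0) {
  core <- if (beta == 0) as.numeric(x > alpha) + 0.5 * (x == alpha)
          else stats::plogis((x - alpha) / beta)
  guess + (1 - guess - lapse) * core
}

#' Choose a 2AFC side for a stimulus
#'
#' @param stimulus_x stimulus-axis value (LED column, 0-8).
#' @param params a [subject_params()].
#' @param rng optional [rng_stream()].
#' @return `"left"` or `"right"`.
#' @export
choose_side <- function(stimulus_x, params, rng = NULL) {
  p <- psychometric(stimulus_x, params$alpha, params$beta,
                    params$guess, params$lapse)
  with_stream(rng, if (runif(1) < p) "right" else "left")
}

#' Go-NoGo response of the virtual subject
#'
#' The subject licks with a stimulus-dependent rate (`p_lick_go` /
#' `p_lick_nogo`). With a finite `delay_decay_tau` the separation between
#' the two rates decays exponentially over the response delay toward their
#' common mean, emulating performance decay over enforced delays.
#' Disengaged trials (probability `1 - engagement`) never lick.
#'
#' @param trial_kind `"go"` or `"nogo"`.
#' @param delay seconds between stimulus and response window.
#' @param params a [subject_params()].
#' @param rng optional [rng_stream()].
#' @return list with `lick` (logical) and `latency` (s from window open;
#'   `NA` when withholding).
#' @export
respond_gng <- function(trial_kind = c("go", "nogo"), delay = 0, params,
                        rng = NULL) {
  trial_kind <- match.arg(trial_kind)
  stopifnot(delay >= 0)
  mid <- (params$p_lick_go + params$p_lick_nogo) / 2
  shrink <- exp(-delay / params$delay_decay_tau)
  p <- if (trial_kind == "go") {
    mid + (params$p_lick_go - mid) * shrink
  } else {
    mid + (params$p_lick_nogo - mid) * shrink
  }
  p <- p * params$engagement
  with_stream(rng, {
    if (runif(1) < p) {
      list(lick = TRUE,
           latency = stats::rlnorm(1, params$rt_meanlog, params$rt_sdlog))
    } else {
      list(lick = FALSE, latency = NA_real_)
    }
  })
}

#' Generate a lick train on one spout
#'
#' A reaction-time-shifted homogeneous Poisson burst at `lick_rate_hz`,
#' clipped to the window. Emitted times are relative to the window start;
#' pass them through [debounce_licks()] to model the sensor.
#'
#' @param side `"left"`, `"center"` or `"right"`.
#' @param window_length seconds of spout availability (> 0).
#' @param params a [subject_params()].
#' @param rng optional [rng_stream()].
#' @param reaction_time optional fixed reaction time (s); drawn from the
#'   log-normal law when `NULL`.
#' @return Object of class `lick_train`: list with `spout` and sorted
#'   `times`.
#' @export
generate_licks <- function(side, window_length, params, rng = NULL,
                           reaction_time = NULL) {
  stopifnot(window_length > 0)
  with_stream(rng, {
    rt <- if (is.null(reaction_time)) {
      stats::rlnorm(1, params$rt_meanlog, params$rt_sdlog)
    } else reaction_time
    occupied <- window_length - rt
    times <- if (occupied <= 0) numeric(0) else {
      n <- stats::rpois(1, params$lick_rate_hz * occupied)
      sort(stats::runif(n, rt, window_length))
    }
    structure(list(spout = side, times = times), class = "lick_train")
  })
}
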