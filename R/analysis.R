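#' Percentage of right-side licks per stimulus column
#'
#' The 2AFC psychometric raw material: for each LED column (0-8, left to
#' right), the fraction of responded trials on which the subject licked
#' right. Retrial attempts and no-response trials are excluded by default.
#'
#' @param trials trial table of a `session_result` (or the result itself).
#' @param columns column grid to report (default 0:8).
#' @param include_retrials logical; count retrial attempts.
#' @return data.frame with `column`, `n_right`, `n_total`, `p_right`
#'   (`NA` where a column was never sampled).
#' @export
percent_right_by_column <- function(trials, columns = 0:8,
                                    include_retrials = FALSE) {
  if (inherits(trials, "session_result")) trials <- trials$trials
  keep <- !is.na(trials$column) & !is.na(trials$side) &
    trials$side %in% c("left", "right")
  if (!include_retrials) keep <- keep & trials$outcome != "retrial"
  t <- trials[keep, , drop = FALSE]
  n_total <- vapply(columns, function(cc) sum(t$column == cc), integer(1))
  n_right <- vapply(columns, function(cc) {
    sum(t$column == cc & t$side == "right")
  }, integer(1))
  data.frame(column = columns, n_right = n_right, n_total = n_total,
             p_right = ifelse(n_total > 0, n_right / n_total, NA_real_))
}

# negative binomial log-likelihood of the 4-parameter logistic
.psy_nll <- function(par, x, k, n) {
  p <- psychometric(x, par[1], par[2], par[3], par[4])
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit the four-parameter psychometric function
#'
#' Maximum-likelihood fit of
#' \eqn{\psi(x) = g + (1-g-l)/(1+\exp(-(x-\alpha)/\beta))} under binomial
#' observation, with bounded parameters (\eqn{g, l \in [0, 0.5]},
#' \eqn{\beta > 0}) and a deterministic multistart grid (alpha over the
#' data range crossed with three slope scales), so the fit is reproducible
#' without randomness. Degenerate data raise diagnostic flags rather than
#' errors: all-identical proportions set `unidentifiable` (alpha is
#' meaningless on flat data) and estimates on the box edge set
#' `boundary_fit`.
#'
#' @param column_data data.frame with columns `column` (or `x`), `n_right`
#'   (or `k`), `n_total` (or `n`), e.g. from [percent_right_by_column()];
#'   unsampled columns are dropped. At least 4 sampled columns required.
#' @return Object of class `psychometric_fit`: list with `alpha`, `beta`,
#'   `guess`, `lapse`, `logLik`, `converged`, `boundary_fit`,
#'   `unidentifiable`, and the `data` used.
#' @export
fit_psychometric <- function(column_data) {
  x <- column_data[["column"]] %||% column_data[["x"]]
  k <- column_data[["n_right"]] %||% column_data[["k"]]
  n <- column_data[["n_total"]] %||% column_data[["n"]]
  keep <- !is.na(x) & !is.na(k) & n > 0
  x <- x[keep]; k <- k[keep]; n <- n[keep]
  if (length(x) < 4L) {
    stop("fit_psychometric needs at least 4 sampled columns", call. = FALSE)
  }
  span <- max(diff(range(x)), 1)
  lower <- c(min(x) - span, 1e-3, 0, 0)
  upper <- c(max(x) + span, 10 * span, 0.5, 0.5)
  starts <- expand.grid(
    alpha = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    beta = span * c(0.05, 0.15, 0.5),
    guess = 0.02, lapse = 0.02)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), .psy_nll, x = x, k = k, n = n,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric fit failed from every start")
  p_obs <- k / n
  flat <- diff(range(p_obs)) < 0.05
  at_bound <- any(abs(best$par - lower) < 1e-6 |
                  abs(best$par - upper) < 1e-6)
  structure(list(alpha = best$par[1], beta = best$par[2],
                 guess = best$par[3], lapse = best$par[4],
                 logLik = -best$value, converged = best$convergence == 0,
                 boundary_fit = at_bound, unidentifiable = flat,
                 data = data.frame(x = x, k = k, n = n)),
            class = "psychometric_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit alpha=%.3f beta=%.3f g=%.3f l=%.3f logLik=%.2f%s%s>\n",
    x$alpha, x$beta, x$guess, x$lapse, x$logLik,
    if (x$boundary_fit) " [boundary]" else "",
    if (x$unidentifiable) " [unidentifiable]" else ""))
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  psychometric(x, object$alpha, object$beta, object$guess, object$lapse)
}

#' Signal-detection sensitivity d'
#'
#' \eqn{d' = \Phi^{-1}(H) - \Phi^{-1}(FA)} with hit rate H and
#' false-alarm rate FA, positive when H > FA. Extreme rates are clipped to
#' `[1/(2N), 1 - 1/(2N)]` per class (log-linear correction) before
#' z-scoring, since a perfect rate has an infinite quantile; the clip is
#' configurable via `clip`.
#'
#' @param hits,misses,false_alarms,correct_rejections outcome counts; or
#'   pass a trial table via [gng_rate_stats()].
#' @param clip `NULL` for the default 1/(2N) rule, a number for a fixed
#'   clip, or `FALSE` to disable (infinite d' possible).
#' @return list with `d_prime` (NA with a `reason` when a class has no
#'   trials), `H`, `FA`.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   clip = NULL) {
  n_go <- hits + misses
  n_nogo <- false_alarms + correct_rejections
  if (n_go == 0L || n_nogo == 0L) {
    return(list(d_prime = NA_real_, H = NA_real_, FA = NA_real_,
                reason = "a trial class is empty"))
  }
  H <- hits / n_go
  FA <- false_alarms / n_nogo
  clipper <- function(r, n) {
    if (isFALSE(clip)) return(r)
    eps <- if (is.numeric(clip)) clip else 1 / (2 * n)
    min(max(r, eps), 1 - eps)
  }
  list(d_prime = stats::qnorm(clipper(H, n_go)) -
         stats::qnorm(clipper(FA, n_nogo)),
       H = H, FA = FA)
}

#' Go-NoGo outcome counts from a trial table
#'
#' @param trials trial table of a Go-NoGo `session_result`.
#' @return list of counts consumable by [dprime()] plus rates `H`, `FA`.
#' @export
gng_rate_stats <- function(trials) {
  if (inherits(trials, "session_result")) trials <- trials$trials
  cnt <- function(lbl) sum(trials$outcome == lbl)
  hits <- cnt("hit"); misses <- cnt("miss")
  fas <- cnt("false_alarm"); crs <- cnt("correct_rejection")
  list(hits = hits, misses = misses, false_alarms = fas,
       correct_rejections = crs,
       H = if (hits + misses > 0) hits / (hits + misses) else NA_real_,
       FA = if (fas + crs > 0) fas / (fas + crs) else NA_real_)
}

#' Per-session performance summary
#'
#' Percent correct over responded trials (retrials and no-response trials
#' excluded by default), d' for Go-NoGo sessions, and the per-column
#' right-lick percentages for 2AFC sessions.
#'
#' @param result a `session_result` or its trial table plus `task`.
#' @param session_index ordinal session number.
#' @param include_retrials logical.
#' @return Object of class `session_summary`.
#' @export
summarize_session <- function(result, session_index = 1L,
                              include_retrials = FALSE) {
  trials <- if (inherits(result, "session_result")) result$trials else result
  task <- if (inherits(result, "session_result")) result$task else "2afc"
  keep <- !trials$outcome %in% c("no_response")
  if (!include_retrials) keep <- keep & trials$outcome != "retrial"
  t <- trials[keep, , drop = FALSE]
  correct_labels <- c("correct_left", "correct_right", "hit",
                      "correct_rejection")
  pc <- if (nrow(t)) 100 * sum(t$outcome %in% correct_labels) / nrow(t)
        else NA_real_
  dp <- if (task == "gng") {
    s <- gng_rate_stats(t)
    dprime(s$hits, s$misses, s$false_alarms, s$correct_rejections)$d_prime
  } else NA_real_
  pr <- if (task == "2afc") {
    percent_right_by_column(trials, include_retrials = include_retrials)
  }
  structure(list(session_index = session_index, percent_correct = pc,
                 d_prime = dp, percent_right = pr, n_trials = nrow(t)),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session %d: %.1f%% correct%s, %d trials>\n",
              x$session_index, x$percent_correct,
              if (!is.na(x$d_prime)) sprintf(", d'=%.2f", x$d_prime) else "",
              x$n_trials))
  invisible(x)
}

#' Learning curve across sessions
#'
#' Percent correct against session number; with multiple subjects, the
#' group mean at each session index over the subjects that reached it.
#'
#' @param summaries list of [summarize_session()] objects, or a list of
#'   such lists (one per subject).
#' @return data.frame with `session`, `percent_correct` (per subject rows
#'   when multiple subjects) and, for groups, a `mean` attribute column
#'   `group_mean` merged by session.
#' @export
learning_curve <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  one <- function(ss, subject_id) {
    data.frame(subject = subject_id,
               session = vapply(ss, `[[`, numeric(1), "session_index"),
               percent_correct = vapply(ss, `[[`, numeric(1),
                                        "percent_correct"))
  }
  multi <- !inherits(summaries[[1]], "session_summary")
  df <- if (multi) {
    do.call(rbind, Map(one, summaries, seq_along(summaries)))
  } else one(summaries, 1L)
  df <- df[order(df$subject, df$session), , drop = FALSE]
  means <- stats::aggregate(percent_correct ~ session, df, mean)
  names(means)[2] <- "group_mean"
  merge(df, means, by = "session", sort = TRUE)
}

#' Stage-advancement criterion
#'
#' Stable performance over the last three consecutive sessions: at least
#' 75% correct on every one (2AFC), or d' above 1.5 on every one
#' (Go-NoGo).
#'
#' @param summaries exactly 3 consecutive [summarize_session()] objects
#'   (or a numeric vector of 3 percent-correct / d' values).
#' @param task `"2afc"` or `"gng"`.
#' @return `TRUE`/`FALSE`; fewer than 3 sessions is an error
#'   ("not-evaluable").
#' @export
advancement_criterion <- function(summaries, task = c("2afc", "gng")) {
  task <- match.arg(task)
  vals <- if (is.numeric(summaries)) summaries else {
    field <- if (task == "2afc") "percent_correct" else "d_prime"
    vapply(summaries, `[[`, numeric(1), field)
  }
  if (length(vals) != 3L) {
    stop("not-evaluable: advancement needs exactly 3 consecutive sessions",
         call. = FALSE)
  }
  if (task == "2afc") all(vals >= 75) else all(vals > 1.5)
}

#' Per-trial lick raster
#'
#' Lick times relative to an alignment event in each trial, after
#' debouncing, plus a session-wide inter-lick-rate histogram.
#'
#' @param result a `session_result`.
#' @param align_to payload prefix of the alignment event (default
#'   `"on:"` on the stimulus channel, i.e. stimulus onset).
#' @param align_channel channel of the alignment event.
#' @param lockout debounce lockout (s).
#' @return list with `raster` (list of per-trial relative lick times;
#'   trials lacking the alignment event are skipped with a warning) and
#'   `rate_hz` (median inverse inter-lick interval, `NA` if < 2 licks).
#' @export
lick_raster <- function(result, align_to = "on:",
                        align_channel = "stimulus", lockout = 0.010) {
  ev <- result$events
  lick_ch <- c("center_lick", "left_lick", "right_lick")
  trials <- sort(unique(ev$trial[!is.na(ev$trial)]))
  raster <- list()
  skipped <- 0L
  ilis <- numeric(0)
  for (tr in trials) {
    sub <- ev[!is.na(ev$trial) & ev$trial == tr, , drop = FALSE]
    a <- sub$time[sub$channel == align_channel &
                    startsWith(sub$payload, align_to)]
    if (length(a) == 0L) {
      skipped <- skipped + 1L
      next
    }
    licks <- debounce_licks(sort(sub$time[sub$channel %in% lick_ch]),
                            lockout)
    raster[[as.character(tr)]] <- licks - a[1L]
    if (length(licks) > 1L) ilis <- c(ilis, diff(licks))
  }
  if (skipped > 0L) {
    warning(sprintf("%d trial(s) lacked the alignment event; skipped",
                    skipped))
  }
  list(raster = raster,
       rate_hz = if (length(ilis)) 1 / stats::median(ilis) else NA_real_)
}
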