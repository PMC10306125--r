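#' Visual stimulus descriptor
#'
#' Stimuli shown on the 9x16 LED crescent: the full panel, multiple
#' stationary bars at one of four angles (0 degrees, 45 left, 45 right,
#' 90), or a single moving bar of 1, 2 or 3 pixel width. The stimulus is
#' anchored to one of the nine crescent columns (0-8, left to right) used
#' by the 2AFC/psychometric axis.
#'
#' @param style `"full_panel"`, `"stationary_bars"` or `"moving_bar"`.
#' @param column_position crescent column 0-8.
#' @param duration seconds.
#' @param angle bar angle for `stationary_bars`: one of `"0"`, `"45left"`,
#'   `"45right"`, `"90"`.
#' @param bar_width moving-bar width in pixels, 1-3.
#' @param flash_frequency Hz square-wave gating of the pattern, or `NULL`
#'   for steady display.
#' @param frame_period_s moving-bar frame period; the advance rate is one
#'   pixel column per frame. Not printed anywhere authoritative; default
#'   0.03 s.
#' @return Object of class `visual_stimulus`.
#' @export
visual_stimulus <- function(style = c("full_panel", "stationary_bars",
                                      "moving_bar"),
                            column_position = 4, duration = 0.2,
                            angle = c("0", "45left", "45right", "90"),
                            bar_width = 1, flash_frequency = NULL,
                            frame_period_s = 0.03) {
  style <- match.arg(style)
  angle <- match.arg(angle)
  if (!column_position %in% 0:8) {
    stop("invalid-config: column_position must be in 0..8", call. = FALSE)
  }
  if (style == "moving_bar" && !bar_width %in% 1:3) {
    stop("invalid-config: moving-bar width must be 1, 2 or 3 pixels",
         call. = FALSE)
  }
  stopifnot(duration > 0, frame_period_s > 0)
  structure(list(style = style, column_position = column_position,
                 duration = duration, angle = angle, bar_width = bar_width,
                 flash_frequency = flash_frequency,
                 frame_period_s = frame_period_s),
            class = "visual_stimulus")
}

#' Auditory stimulus descriptor
#'
#' Tones from the 2-32 kHz library or white noise, optionally pulsed at a
#' presentation rate, on the left, right or both speakers.
#'
#' @param pitch_hz tone frequency in `[2000, 32000]`, or `NA` for white
#'   noise.
#' @param side `"left"`, `"right"` or `"both"`.
#' @param duration seconds.
#' @param presentation_rate_hz pulse rate or `NULL` for continuous.
#' @return Object of class `auditory_stimulus`.
#' @export
auditory_stimulus <- function(pitch_hz = 8000,
                              side = c("both", "left", "right"),
                              duration = 0.2, presentation_rate_hz = NULL) {
  side <- match.arg(side)
  if (!is.na(pitch_hz) && (pitch_hz < 2000 || pitch_hz > 32000)) {
    stop("invalid-config: tonal pitch must lie in [2000, 32000] Hz",
         call. = FALSE)
  }
  stopifnot(duration > 0)
  structure(list(pitch_hz = pitch_hz, side = side, duration = duration,
                 presentation_rate_hz = presentation_rate_hz),
            class = "auditory_stimulus")
}

# pattern-table cache (read once per session from inst/extdata)
.pattern_env <- new.env(parent = emptyenv())

load_bar_patterns <- function() {
  if (!is.null(.pattern_env$patterns)) return(.pattern_env$patterns)
  path <- system.file("extdata", "bar_patterns.txt", package = "lickbench")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  pats <- list()
  cur <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(cur)) {
      m <- do.call(rbind, lapply(rows, function(s) {
        as.integer(strsplit(s, "")[[1]])
      }))
      stopifnot(nrow(m) == 9L, ncol(m) == 16L)
      pats[[cur]] <<- m
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "pattern: ")) {
      flush()
      cur <- sub("^pattern: ", "", ln)
      rows <- list()
    } else if (nzchar(trimws(ln))) {
      rows[[length(rows) + 1L]] <- trimws(ln)
    }
  }
  flush()
  .pattern_env$patterns <- pats
  pats
}

#' Render one LED frame
#'
#' Pure function of the stimulus and time: returns the 9x16 binary pixel
#' matrix shown at time `t` after stimulus onset. The moving bar advances
#' one pixel column per frame period, wrapping at the panel edge;
#' stationary patterns are time-invariant unless gated by
#' `flash_frequency` (on during the first half of each flash cycle).
#'
#' @param stimulus a [visual_stimulus()].
#' @param t seconds since stimulus onset, `0 <= t < duration`.
#' @return 9x16 integer matrix of 0/1.
#' @export
render_frame <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "visual_stimulus"))
  if (t < 0 || t >= stimulus$duration) {
    stop("out-of-range: t must satisfy 0 <= t < duration", call. = FALSE)
  }
  gate <- TRUE
  if (!is.null(stimulus$flash_frequency)) {
    phase <- (t * stimulus$flash_frequency) %% 1
    gate <- phase < 0.5
  }
  frame <- switch(stimulus$style,
    full_panel = matrix(1L, 9, 16),
    stationary_bars = load_bar_patterns()[[stimulus$angle]],
    moving_bar = {
      k <- floor(t / stimulus$frame_period_s)
      start <- (stimulus$column_position * 2 + k) %% 16
      cols <- (start + seq_len(stimulus$bar_width) - 1L) %% 16 + 1L
      m <- matrix(0L, 9, 16)
      m[, cols] <- 1L
      m
    })
  if (!gate) frame <- matrix(0L, 9, 16)
  frame
}

#' Synthesize tone samples through a 32-point lookup table
#'
#' Sine waves are generated the way the firmware does: a 32-point sine
#' lookup table read by a phase accumulator, with linear interpolation
#' between adjacent table entries, which yields near-pure tones. The
#' white-noise style returns uniform noise in `[-1, 1]`.
#'
#' @param stimulus an [auditory_stimulus()].
#' @param sample_rate Hz; must exceed twice the pitch for tonal stimuli.
#' @param rng optional [rng_stream()] (white noise only).
#' @return numeric waveform in `[-1, 1]`, length
#'   `round(duration * sample_rate)`.
#' @export
tone_samples <- function(stimulus, sample_rate, rng = NULL) {
  stopifnot(inherits(stimulus, "auditory_stimulus"), sample_rate > 0)
  n <- round(stimulus$duration * sample_rate)
  if (is.na(stimulus$pitch_hz)) {
    return(with_stream(rng, stats::runif(n, -1, 1)))
  }
  if (sample_rate <= 2 * stimulus$pitch_hz) {
    stop("invalid-config: sample_rate must exceed twice the pitch (Nyquist)",
         call. = FALSE)
  }
  lut <- sin(2 * pi * (0:31) / 32)
  # phase accumulator in table units (32 units = one cycle)
  phase <- (seq_len(n) - 1) * 32 * stimulus$pitch_hz / sample_rate
  idx <- floor(phase) %% 32
  frac <- phase - floor(phase)
  lo <- lut[idx + 1]
  hi <- lut[(idx + 1) %% 32 + 1]
  wave <- lo + frac * (hi - lo)
  if (!is.null(stimulus$presentation_rate_hz)) {
    tt <- (seq_len(n) - 1) / sample_rate
    wave <- wave * as.numeric((tt * stimulus$presentation_rate_hz) %% 1 < 0.5)
  }
  wave
}

#' Encode an LED crescent column as a DAQ signal level
#'
#' The LED-panel DAQ channel encodes the stimulus location along the
#' crescent as a voltage. The package convention is nine equally spaced
#' normalized levels: column c maps to `(c + 1) / 10`, i.e. 0.1 for column
#' 0 (minimum) to 0.9 for column 8 (maximum), with 0 meaning panel off.
#' The encoding is bit-exact and invertible via
#' [signal_level_to_column()].
#'
#' @param column_position integer column 0-8.
#' @return normalized level in `(0, 1)`.
#' @export
column_to_signal_level <- function(column_position) {
  if (any(!column_position %in% 0:8)) {
    stop("out-of-range: column must be in 0..8", call. = FALSE)
  }
  (column_position + 1) / 10
}

#' @rdname column_to_signal_level
#' @param level normalized level as produced by [column_to_signal_level()].
#' @export
signal_level_to_column <- function(level) {
  col <- round(level * 10) - 1
  if (any(col < 0 | col > 8)) {
    stop("out-of-range: level does not decode to a column in 0..8",
         call. = FALSE)
  }
  as.integer(col)
}
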