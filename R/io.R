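#' Debounce a lick train through the sensor lockout
#'
#' The capacitive lick detector is disabled for 10 ms after a registered
#' lick, capping the detectable rate at 100 Hz. Implemented as the greedy
#' left-to-right pass: keep a lick only if it falls at least `lockout`
#' after the last kept lick. Idempotent.
#'
#' @param raw_times sorted lick times, seconds.
#' @param lockout refractory period, seconds (default 0.010).
#' @return kept lick times; inter-lick intervals all >= `lockout`.
#' @export
debounce_licks <- function(raw_times, lockout = 0.010) {
  if (length(raw_times) == 0L) return(numeric(0))
  if (is.unsorted(raw_times)) {
    stop("debounce_licks requires sorted input times", call. = FALSE)
  }
  stopifnot(lockout >= 0)
  kept <- numeric(length(raw_times))
  kept[1L] <- raw_times[1L]
  m <- 1L
  eps <- 1e-9  # absorb fp error in regular lick grids (e.g. 5 ms steps)
  for (t in raw_times[-1L]) {
    if (t - kept[m] >= lockout - eps) {
      m <- m + 1L
      kept[m] <- t
    }
  }
  kept[seq_len(m)]
}

# ---- 3-byte device command codec -------------------------------------------

#' Device command table
#'
#' The controller is driven by 3-byte serial instructions:
#' `[device, assignment, action]`. The single documented instruction is the
#' valve command `['k' 1 1]` (device 'k' = valves, assignment 1 = Center,
#' action 1 = open); the rest of the table is package-defined plumbing,
#' published here as the protocol reference.
#'
#' @format data.frame with columns `device` (single character), `device_name`,
#'   `assignment` (byte), `assignment_name`, `action` (byte), `action_name`.
#' @export
device_command_table <- function() {
  rbind(
    expand.grid(device = "k", device_name = "valve",
                assignment = 1:3, action = 0:1, stringsAsFactors = FALSE),
    expand.grid(device = "s", device_name = "spout",
                assignment = 1:2, action = 0:1, stringsAsFactors = FALSE),
    expand.grid(device = "d", device_name = "led_panel",
                assignment = 0:8, action = 0:1, stringsAsFactors = FALSE),
    expand.grid(device = "a", device_name = "audio",
                assignment = 1:2, action = 0:1, stringsAsFactors = FALSE),
    expand.grid(device = "p", device_name = "punishment",
                assignment = 1:2, action = 0:1, stringsAsFactors = FALSE)
  ) -> tbl
  assign_names <- function(dev, a) switch(dev,
    k = c("center", "left", "right")[a],
    s = c("center", "side")[a],
    d = paste0("column", a),
    a = c("left", "right")[a],
    p = c("noise", "airpuff")[a])
  action_names <- function(dev, act) switch(dev,
    k = c("close", "open")[act + 1L],
    s = c("retract", "extend")[act + 1L],
    d = c("off", "on")[act + 1L],
    a = c("off", "on")[act + 1L],
    p = c("off", "on")[act + 1L])
  tbl$assignment_name <- mapply(assign_names, tbl$device, tbl$assignment)
  tbl$action_name <- mapply(action_names, tbl$device, tbl$action)
  tbl[order(tbl$device, tbl$assignment, tbl$action),
      c("device", "device_name", "assignment", "assignment_name",
        "action", "action_name")]
}

#' Construct a device command
#'
#' @param device one-character device code (e.g. `"k"` for the valves).
#' @param assignment device index byte (e.g. 1 = Center valve).
#' @param action action byte (e.g. 1 = open).
#' @return Object of class `device_command`.
#' @export
device_command <- function(device, assignment, action) {
  dev <- if (is.character(device)) utf8ToInt(device) else as.integer(device)
  if (length(dev) != 1L || dev < 0 || dev > 255 ||
      assignment < 0 || assignment > 255 || action < 0 || action > 255) {
    stop("protocol error: each command field must fit in one byte",
         call. = FALSE)
  }
  structure(list(device = dev, assignment = as.integer(assignment),
                 action = as.integer(action)), class = "device_command")
}

#' Encode / decode the 3-byte command wire format
#'
#' @param cmd a [device_command()].
#' @return `encode_command()`: a raw vector of exactly 3 bytes
#'   `[device, assignment, action]`; `decode_command()` inverts it.
#' @export
encode_command <- function(cmd) {
  stopifnot(inherits(cmd, "device_command"))
  as.raw(c(cmd$device, cmd$assignment, cmd$action))
}

#' @rdname encode_command
#' @param bytes raw vector of length 3.
#' @export
decode_command <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) != 3L) {
    stop("protocol error: a device command is exactly 3 bytes",
         call. = FALSE)
  }
  v <- as.integer(bytes)
  device_command(v[1L], v[2L], v[3L])
}

#' @export
print.device_command <- function(x, ...) {
  cat(sprintf("<device_command '%s' %d %d>\n", intToUtf8(x$device),
              x$assignment, x$action))
  invisible(x)
}

# ---- session log ------------------------------------------------------------

# Line grammar, version 1:
#   # lickbench session log v1
#   # setting: <key> = <value>          (one per config key)
#   # seed: <int>
#   # records
#   <time ms, %.3f s>\t<channel>\t<payload>\t<trial or NA>
#   # trials
#   <tab-separated trial table, header + rows>
#   # end: complete

#' Write a session log
#'
#' Plain-text event log: a settings header (the full configuration
#' snapshot), millisecond-precision timestamped records, the trial/outcome
#' table, and a closure footer. The companion settings export
#' ([write_settings_xls()]) is written alongside when `xls = TRUE`.
#' Round-trips losslessly: `parse_session_log(write_session_log(x))`
#' reproduces every analysis-relevant field and re-writing gives
#' byte-identical text.
#'
#' @param result a [run_session()] result.
#' @param path output file path (`.txt`).
#' @param xls also write `<path>.xls` settings export.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(result, path, xls = FALSE) {
  stopifnot(inherits(result, "session_result"))
  con <- file(path, open = "wb")  # binary: fixed \n endings for byte-identity
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")
  w("# lickbench session log v1")
  for (k in names(result$config)) {
    w("# setting: %s = %s", k, format_setting(result$config[[k]]))
  }
  w("# seed: %d", result$seed)
  w("# records")
  ev <- result$events
  if (nrow(ev)) {
    w("%s", paste(sprintf("%.3f", ev$time), ev$channel, ev$payload,
                  ifelse(is.na(ev$trial), "NA", ev$trial), sep = "\t"))
  }
  w("# trials")
  tr <- result$trials
  if (nrow(tr)) {
    w("%s", paste(names(tr), collapse = "\t"))
    cells <- vapply(seq_len(nrow(tr)), function(i) {
      paste(vapply(tr[i, ], format_log_cell, character(1)), collapse = "\t")
    }, character(1))
    w("%s", cells)
  }
  w("# end: complete")
  if (xls) write_settings_xls(result$config, paste0(path, ".xls"))
  invisible(path)
}

format_log_cell <- function(v) {
  if (is.na(v)) return("NA")
  if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
  if (is.numeric(v)) return(format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE))
  as.character(v)
}

#' Parse a session log
#'
#' @param path a log written by [write_session_log()].
#' @return a `session_result`; a log missing the closure footer is flagged
#'   with attribute `unclosed = TRUE`.
#' @export
parse_session_log <- function(path) {
  if (!file.exists(path)) {
    stop("parse error: no such log file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != "# lickbench session log v1") {
    stop("parse error at line 1: not a lickbench session log", call. = FALSE)
  }
  settings <- list()
  seed <- NA_integer_
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "# setting: ")) {
    m <- regexec("^# setting: (.*?) = (.*)$", lines[i])[[1]]
    if (m[1] == -1) stop(sprintf("parse error at line %d", i), call. = FALSE)
    parts <- regmatches(lines[i], regexec("^# setting: (.*?) = (.*)$",
                                          lines[i]))[[1]]
    settings[[parts[2]]] <- parse_setting(parts[3])
    i <- i + 1L
  }
  if (i <= length(lines) && startsWith(lines[i], "# seed: ")) {
    seed <- as.integer(sub("^# seed: ", "", lines[i]))
    i <- i + 1L
  }
  if (i > length(lines) || lines[i] != "# records") {
    stop(sprintf("parse error at line %d: expected '# records'", i),
         call. = FALSE)
  }
  i <- i + 1L
  rec_lines <- character(0)
  while (i <= length(lines) && !startsWith(lines[i], "# ")) {
    rec_lines <- c(rec_lines, lines[i])
    i <- i + 1L
  }
  events <- if (length(rec_lines)) {
    parts <- strsplit(rec_lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) {
      stop(sprintf("parse error at line %d: malformed record",
                   i - length(rec_lines) + bad[1L] - 1L), call. = FALSE)
    }
    data.frame(
      time = as.numeric(vapply(parts, `[`, character(1), 1L)),
      channel = vapply(parts, `[`, character(1), 2L),
      payload = vapply(parts, `[`, character(1), 3L),
      trial = suppressWarnings(
        as.integer(vapply(parts, `[`, character(1), 4L))),
      stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), channel = character(0),
               payload = character(0), trial = integer(0))
  }
  trials <- data.frame()
  if (i <= length(lines) && lines[i] == "# trials") {
    i <- i + 1L
    tr_lines <- character(0)
    while (i <= length(lines) && !startsWith(lines[i], "# ")) {
      tr_lines <- c(tr_lines, lines[i])
      i <- i + 1L
    }
    if (length(tr_lines) >= 2L) {
      trials <- utils::read.table(
        text = paste(tr_lines, collapse = "\n"), header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, na.strings = "NA")
      trials$stimulus <- as.character(trials$stimulus)
    }
  }
  closed <- i <= length(lines) && lines[i] == "# end: complete"
  cfg <- tryCatch(settings_from_pairs(names(settings), settings),
                  error = function(e) settings)
  res <- structure(list(task = settings[["Task"]], seed = seed,
                        config = cfg, trials = trials, events = events),
                   class = "session_result")
  if (!closed) attr(res, "unclosed") <- TRUE
  res
}

#' Export settings as a single-sheet spreadsheet file
#'
#' Key/value layout, one setting per row, written as tab-separated text
#' with an `.xls` extension (spreadsheet programs open tab-delimited
#' text transparently; no binary workbook writer is required).
#'
#' @param config a [session_config()].
#' @param path output path (conventionally `.xls`).
#' @return `path`, invisibly.
#' @export
write_settings_xls <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  lines <- c("Setting\tValue",
             vapply(names(config), function(k) {
               sprintf("%s\t%s", k, format_setting(config[[k]]))
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# ---- DAQ trace --------------------------------------------------------------

#' Render the multichannel DAQ-style trace of a session
#'
#' Reconstructs what a data-acquisition board wired to the rig would
#' record: step-function channels sampled on a uniform grid. Spout
#' channels are high while the spout is extended; lick channels are short
#' pulses (2 ms by default); the LED channel carries the column-encoding
#' level of [column_to_signal_level()] while a visual stimulus is on (1.0
#' for non-column stimuli); the reward channel uses the three-level spout
#' encoding low/medium/high for left/center/right; the punishment channel
#' gates between its on and offset.
#'
#' @param events event data.frame from a `session_result`.
#' @param sample_rate Hz (default 5000).
#' @param pulse_width_s lick/reward pulse width (default 0.002).
#' @param duration_s optional trace length; defaults to last event + 10 ms.
#' @return Object of class `daq_trace`: data.frame with `time` plus the
#'   channels `center_spout`, `side_spout`, `led_panel`, `center_licks`,
#'   `left_licks`, `right_licks`, `rewards`, `punishment`.
#' @export
render_daq_trace <- function(events, sample_rate = 5000,
                             pulse_width_s = 0.002, duration_s = NULL) {
  stopifnot(sample_rate > 0)
  if (inherits(events, "session_result")) events <- events$events
  t_end <- if (!is.null(duration_s)) duration_s else {
    if (nrow(events)) max(events$time) + 0.01 else 0.01
  }
  grid <- seq(0, t_end, by = 1 / sample_rate)
  n <- length(grid)
  chan <- function() numeric(n)
  tr <- data.frame(time = grid, center_spout = chan(), side_spout = chan(),
                   led_panel = chan(), center_licks = chan(),
                   left_licks = chan(), right_licks = chan(),
                   rewards = chan(), punishment = chan())
  gate <- function(col, t_on, t_off, level = 1) {
    i <- grid >= t_on & grid < t_off
    tr[[col]][i] <<- level
  }
  pulse <- function(col, t, level = 1) gate(col, t, t + pulse_width_s, level)
  # spout availability: high between extended and move_in
  for (ch in c("center_spout", "side_spout")) {
    sub <- events[events$channel == ch, , drop = FALSE]
    t_on <- NA_real_
    for (j in seq_len(nrow(sub))) {
      if (sub$payload[j] == "extended") t_on <- sub$time[j]
      if (sub$payload[j] == "move_in" && !is.na(t_on)) {
        gate(ch, t_on, sub$time[j])
        t_on <- NA_real_
      }
    }
    if (!is.na(t_on)) gate(ch, t_on, t_end)
  }
  # LED / stimulus channel
  stim <- events[events$channel == "stimulus", , drop = FALSE]
  on_time <- NA_real_
  on_level <- 1
  for (j in seq_len(nrow(stim))) {
    p <- stim$payload[j]
    if (startsWith(p, "on:") || startsWith(p, "cue_on:")) {
      on_time <- stim$time[j]
      id <- sub("^(cue_)?on:", "", p)
      col <- suppressWarnings(as.numeric(id))
      on_level <- if (!is.na(col) && col %in% 0:8) {
        column_to_signal_level(col)
      } else 1
    } else if (!is.na(on_time)) {
      gate("led_panel", on_time, stim$time[j], on_level)
      on_time <- NA_real_
    }
  }
  # licks
  for (ch in c("center_lick", "left_lick", "right_lick")) {
    col <- sub("lick$", "licks", ch)
    for (t in events$time[events$channel == ch]) pulse(col, t)
  }
  # rewards: low/medium/high for left/center/right during the dispense window
  rew <- events[events$channel == "reward", , drop = FALSE]
  for (j in seq_len(nrow(rew))) {
    level <- switch(rew$payload[j], left = 1 / 3, center = 2 / 3, right = 1)
    gate("rewards", rew$time[j], rew$time[j] + pulse_width_s * 10, level)
  }
  # punishment gate
  pun <- events[events$channel == "punishment", , drop = FALSE]
  t_on <- NA_real_
  for (j in seq_len(nrow(pun))) {
    if (startsWith(pun$payload[j], "on")) t_on <- pun$time[j]
    else if (!is.na(t_on)) {
      gate("punishment", t_on, pun$time[j])
      t_on <- NA_real_
    }
  }
  structure(tr, class = c("daq_trace", "data.frame"),
            sample_rate = sample_rate, pulse_width_s = pulse_width_s)
}

#' Export a DAQ trace as CSV
#'
#' @param trace a [render_daq_trace()] result.
#' @param path output CSV path.
#' @export
write_daq_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
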