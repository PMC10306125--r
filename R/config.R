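#' Session configuration
#'
#' Every GUI-settable parameter needed to run a session deterministically
#' given a seed. Keys mirror the GUI labels verbatim where such labels
#' exist ("Percentage of Go Trials", "Delay Period (s)", "Override Consec
#' Constraint", "CR rule ON", "Short ITI", ...). Ranged delay boxes are the
#' GUI's three-box (minimum, maximum, steps) triple.
#'
#' @param task one of `"2afc"`, `"gng"`, `"passive"`.
#' @param ... overrides of default keys, e.g.
#'   `session_config("gng", \`Percentage of Go Trials\` = 70)`.
#' @return Object of class `session_config` (a named list).
#' @export
session_config <- function(task = c("2afc", "gng", "passive"), ...) {
  task <- match.arg(task)
  cfg <- default_settings(task)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("invalid-config: unknown key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

#' Shipped default settings
#'
#' @param task task name.
#' @return named list of defaults (unclassed).
#' @export
default_settings <- function(task = c("2afc", "gng", "passive")) {
  task <- match.arg(task)
  common <- list(
    "Task" = task,
    "Number of Trials" = 100L,
    "Stimulus Duration (ms)" = 200,
    "Stim Start Delay (s) Min" = 0.5,
    "Stim Start Delay (s) Max" = 0.5,
    "Stim Start Delay (s) Steps" = 1L,
    "ITI Min (s)" = 2,
    "ITI Max (s)" = 6,
    "Actuator" = "servo",          # servo 50 mm/s, linear 25 mm/s
    "Spout Travel (mm)" = 40,
    "Valve Open Time (ms)" = 30,
    "Punishment Duration (s)" = 1,
    "Lick Lockout (s)" = 0.010,
    "Required Licks Per Second" = 1L,
    "Response Window (s)" = 2
  )
  extra <- switch(task,
    "2afc" = list(
      "Percentage of Center Rewards" = 10,
      "Percentage of Right Trials" = 50,
      "Override Consec Constraint" = FALSE,
      "Retrial Mode" = FALSE,
      "Max Retrials" = 10L,
      "Initiation Timeout (s)" = 30,
      "Time Center Spout Available (s) Min" = 0.5,
      "Time Center Spout Available (s) Max" = 0.5,
      "Time Center Spout Available (s) Steps" = 1L,
      "TCSA reward" = FALSE,
      "Fraction Training" = 1,
      "Exact Mix" = FALSE,
      "Training Stimuli" = "0,8",
      "Novel Stimuli" = "1,2,3,4,5,6,7"
    ),
    "gng" = list(
      "Percentage of Go Trials" = 50,
      "CR rule ON" = FALSE,
      "Trial Start Signal" = "none",   # none | visual | auditory
      "Trial Start Signal Duration (s)" = 0.1,
      "Delay Period (s) Min" = 1,
      "Delay Period (s) Max" = 1,
      "Delay Period (s) Steps" = 1L,
      "Delay Reference" = "onset",     # onset | offset of the stimulus
      "Short ITI Min (s)" = 1,
      "Short ITI Max (s)" = 3,
      "Go Stimulus" = "go_tone",
      "NoGo Stimulus" = "nogo_tone"
    ),
    "passive" = list(
      "Number of Presentations" = 10L,
      "Interstimulus Interval (s)" = 2,
      "Combination" = FALSE,
      "Multisensory" = FALSE,
      "Visual first" = TRUE,
      "delay between (ms)" = 100,
      "Stimulus" = "full_panel"
    ))
  c(common, extra)
}

validate_config <- function(cfg) {
  stopifnot(cfg[["Task"]] %in% c("2afc", "gng", "passive"))
  num_pos <- c("Stimulus Duration (ms)", "Spout Travel (mm)",
               "Valve Open Time (ms)", "Response Window (s)")
  for (k in intersect(num_pos, names(cfg))) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      stop("invalid-config: ", k, " must be a non-negative number",
           call. = FALSE)
    }
  }
  if (cfg[["ITI Max (s)"]] < cfg[["ITI Min (s)"]]) {
    stop("invalid-config: ITI Max (s) < ITI Min (s)", call. = FALSE)
  }
  if (!is.null(cfg[["Percentage of Go Trials"]])) {
    p <- cfg[["Percentage of Go Trials"]]
    if (p < 0 || p > 100) stop("invalid-config: Percentage of Go Trials",
                               call. = FALSE)
  }
  structure(cfg, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config: %s task, %d keys>\n", x[["Task"]],
              length(x)))
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format_setting(x[[k]])))
  invisible(x)
}

# parse a comma-separated stimulus id list ("0,8" -> c(0, 8))
parse_id_list <- function(s) {
  if (is.numeric(s)) return(s)
  out <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
  if (anyNA(out)) trimws(strsplit(s, ",")[[1]]) else out
}

format_setting <- function(v) {
  if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
  if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
  as.character(v)
}

parse_setting <- function(s) {
  if (s %in% c("TRUE", "FALSE")) return(s == "TRUE")
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) {
    if (n == round(n) && !grepl("[.eE]", s)) return(as.integer(n))
    return(n)
  }
  s
}

# merge parsed key/value pairs into the shipped defaults, coercing each
# value to the storage type of its default so that save -> load round-trips
# preserve types exactly
settings_from_pairs <- function(keys, vals) {
  if (is.null(vals[["Task"]]) ||
      !vals[["Task"]] %in% c("2afc", "gng", "passive")) {
    stop("settings lack a valid Task", call. = FALSE)
  }
  defaults <- default_settings(vals[["Task"]])
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop("unknown settings key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in keys) {
    v <- vals[[k]]
    d <- defaults[[k]]
    defaults[[k]] <- if (is.integer(d) && is.numeric(v)) as.integer(v)
      else if (is.double(d) && is.numeric(v)) as.double(v)
      else v
  }
  validate_config(defaults)
}

#' Settings store: save, load, and roll back session settings
#'
#' A settings store is a directory holding `latest_settings.txt` (flat
#' `key = value` lines, rewritten whenever a configuration is saved, so the
#' latest settings persist across restarts). Loading falls back to the
#' shipped defaults when no settings file is present or when the file is
#' corrupt (with a warning); [reset_to_defaults()] restores the shipped
#' defaults explicitly.
#'
#' @param store directory path of the settings store.
#' @param config a [session_config()].
#' @param task task whose defaults to fall back to.
#' @return `load_settings()` and `reset_to_defaults()` return a
#'   [session_config()]; `save_settings()` returns the file path invisibly.
#' @name settings_store
NULL

#' @rdname settings_store
#' @export
save_settings <- function(config, store) {
  stopifnot(inherits(config, "session_config"))
  if (!dir.exists(store)) dir.create(store, recursive = TRUE)
  path <- file.path(store, "latest_settings.txt")
  writeLines(settings_lines(config), path)
  invisible(path)
}

settings_lines <- function(config) {
  vapply(names(config),
         function(k) sprintf("%s = %s", k, format_setting(config[[k]])),
         character(1))
}

#' @rdname settings_store
#' @export
load_settings <- function(store, task = "2afc") {
  path <- file.path(store, "latest_settings.txt")
  if (!file.exists(path)) return(session_config(task))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^(.*?) = (.*)$", lines))
  if (any(lengths(m) != 3L)) {
    warning("corrupt settings file; falling back to defaults")
    return(session_config(task))
  }
  keys <- vapply(m, `[`, character(1), 2L)
  vals <- lapply(m, function(x) parse_setting(x[3L]))
  names(vals) <- keys
  tryCatch(settings_from_pairs(keys, vals), error = function(e) {
    warning("corrupt settings file; falling back to defaults")
    session_config(task)
  })
}

#' @rdname settings_store
#' @export
reset_to_defaults <- function(store, task = "2afc") {
  cfg <- session_config(task)
  save_settings(cfg, store)
  cfg
}
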