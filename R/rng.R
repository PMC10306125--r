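#' Named, seedable random sub-streams
#'
#' All randomness in a session flows from one session-level seed through
#' named sub-streams (sides, delays, ITIs, subject, ...) so that each
#' component is independently reproducible: changing how many draws one
#' component makes never perturbs another component's sequence.
#'
#' A stream is an environment holding its own saved `.Random.seed`; drawing
#' through [with_stream()] swaps the stream state in, evaluates, and swaps
#' the previous global state back.
#'
#' @param seed integer session seed.
#' @param name character stream name; distinct names give independent
#'   streams deterministically derived from `seed`.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed, name = "default") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  e <- new.env(parent = emptyenv())
  e$seed <- substream_seed(seed, name)
  e$name <- name
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

# Deterministic 31-bit hash of (seed, name). Kept simple and stable: the
# exact mixing does not matter, only that distinct names decorrelate.
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- as.double(as.integer(seed) %% m)
  for (cp in utf8ToInt(name)) h <- (h * 69069 + cp * 2654435761) %% m
  as.integer(h)
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param stream an [rng_stream()], or `NULL` to use the current global RNG.
#' @param expr expression making R random draws.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  if (is.null(stream)) return(expr)
  stopifnot(inherits(stream, "rng_stream"))
  genv <- globalenv()
  had_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = genv)
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (had_old) {
      assign(".Random.seed", old, envir = genv)
    } else {
      rm(".Random.seed", envir = genv)
    }
  })
  expr
}

#' @export
print.rng_stream <- function(x, ...) {
  cat(sprintf("<rng_stream '%s' seed=%d %s>\n", x$name, x$seed,
              if (is.null(x$state)) "fresh" else "advanced"))
  invisible(x)
}
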