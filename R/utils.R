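# internal helpers: argument checking and seed management

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_proportion <- function(x, field, allow_vec = FALSE) {
  if (!allow_vec && length(x) != 1L) stop_bad(field, "must be a single value")
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_bad(field, "must be a proportion in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_bad(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

#' Derive independent sub-stream seeds from one master seed
#'
#' A single global seed drives every stochastic component through a
#' deterministic sequence of per-component seeds, so sub-streams are
#' independent of each other and of the order in which components run.
#'
#' @param seed Master integer seed.
#' @param names Character vector naming the sub-streams.
#' @return Named integer vector of seeds, one per requested name.
#' @export
seed_streams <- function(seed, names) {
  check_count(seed, "seed")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  stats::setNames(s, names)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# evaluate expr under a local seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
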