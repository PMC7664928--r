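# Internal helpers shared across modules.

# Deterministic child seeds from a root seed, without clobbering the
# caller's RNG state. Used to pair resampling repeats across model
# candidates and base-temperature grid points.
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a local RNG seeded with `seed`; caller's RNG untouched.
with_local_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)

thermophen_stop <- function(fmt, ..., class = "thermophen_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

year_of <- function(date) as.integer(format(date, "%Y"))
doy_of <- function(date) as.integer(format(date, "%j"))
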