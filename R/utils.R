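# Seed plumbing: every stochastic entry point takes an integer seed, draws one
# if absent, and records it, so whole reports regenerate bit-identically.

materialize_seed <- function(seed) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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

# One master seed deterministically yields independent per-batch seeds, so the
# two Theorem-2 batches are independent yet jointly reproducible.
derive_seeds <- function(master, n_streams) {
  master <- materialize_seed(master)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n_streams)
}

# Moment-based sample skewness; used as a heavy-tail caution for BF samples.
sample_skewness <- function(x) {
  if (length(x) < 2L) {
    return(0)
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    return(0)
  }
  mean((x - m)^3) / s^3
}
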