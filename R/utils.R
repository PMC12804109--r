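# Internal helpers shared across modules.

# Evaluate `code` with the global RNG seeded at `seed`, restoring any
# pre-existing RNG state afterwards so package functions never leak
# global side effects.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small offset from a string label, used to decorrelate
# sub-streams (e.g. the two genotypes) drawn from one design seed.
seed_offset <- function(label) {
  if (is.null(label) || !nzchar(label)) return(0L)
  as.integer(sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L)
}

geomean <- function(x) exp(mean(log(x)))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}
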