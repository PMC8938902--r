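## Seed plumbing: every stochastic operation takes an explicit integer seed,
## evaluates under it, and restores the caller's RNG state afterwards, so the
## package never perturbs the user's random stream.

withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive n child seeds from a master seed (documented scheme: one
## sample.int() draw under the master seed). Keeps all seeds < 2^31.
deriveSeeds <- function(master, n) {
  withSeed(master, sample.int(.Machine$integer.max - 1L, n))
}

## Minimal self-contained linear-congruential stream for discrete tie-breaks
## (sequence search); independent of R's RNG so greedy restarts are cheap and
## deterministic.
localRNG <- function(seed) {
  state <- (as.double(seed) %% 2147483647) + 1
  list(int = function(n) {
    state <<- (state * 48271) %% 2147483647
    as.integer(state %% n) + 1L
  })
}
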