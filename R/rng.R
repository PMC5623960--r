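# Seeded randomness plumbing.
#
# Every stochastic operation takes an explicit integer seed; sub-streams are
# derived from (seed, label) so that stages draw independent, reproducible
# streams and never touch the caller's global RNG state.

.hash_label <- function(label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  h
}

.sub_seed <- function(seed, label) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + .hash_label(label)) %% 2147483647)
}

# Evaluate expr under set.seed(seed) without disturbing global RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# A resumable uniform stream: each call rng(n) returns n runif draws,
# carrying its own RNG state across calls.
.rng_stream <- function(seed, label) {
  state <- NULL
  function(n = 1L) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    if (is.null(state)) set.seed(.sub_seed(seed, label))
    else assign(".Random.seed", state, envir = globalenv())
    x <- runif(n)
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    x
  }
}

# Lognormal multiplicative noise with unit mean and coefficient of
# variation cv (vectorized over cv; cv = 0 gives exactly 1).
.lnoise <- function(n, cv) {
  cv <- rep(cv, length.out = n)
  sdl <- sqrt(log(1 + pmax(cv, 0)^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}
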