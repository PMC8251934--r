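# Counter-based per-person random streams.
#
# Each simulated person owns independent uniform streams (one for natural
# history, one for screening), derived deterministically from (seed, person,
# stream). The generator is a Wichmann-Hill combination whose state update and
# seeding use only exact double-precision integer arithmetic (< 2^53), so the
# compiled engine and the interpreted reference engine reproduce the same
# uniforms bit-for-bit. Stream identity across arms is what makes the paired
# no-screening/screening comparison a common-random-number design: the policy
# can never perturb a person's disease draws.

.PS_M <- 2147483647
.PS_A <- 16807

.ps_mix <- function(x) (.PS_A * x) %% .PS_M

#' Create a per-person uniform random stream
#'
#' Returns the three-component Wichmann-Hill state for the stream identified by
#' `(seed, person, stream)`. States are derived through a multiplicative
#' scrambler so that nearby persons get well-separated states. Stream 1 is used
#' for natural-history draws, stream 2 for screening draws.
#'
#' @param seed integer scenario seed (any value below 2^31).
#' @param person 1-based person index.
#' @param stream stream identifier (1 = natural history, 2 = screening).
#' @return numeric vector of length 3: the generator state.
#' @keywords internal
ps_stream <- function(seed, person, stream) {
  s <- (abs(seed) %% .PS_M) + 1
  s <- .ps_mix(s)
  s <- (s + person) %% .PS_M
  if (s == 0) s <- 1
  s <- .ps_mix(s)
  s <- (s + 97 * stream + 1) %% .PS_M
  if (s == 0) s <- 1
  s <- .ps_mix(s)
  s <- .ps_mix(s)
  s1 <- s %% 30268 + 1
  s <- .ps_mix(s)
  s2 <- s %% 30306 + 1
  s <- .ps_mix(s)
  s3 <- s %% 30322 + 1
  c(s1, s2, s3)
}

#' Advance a stream and draw one uniform
#'
#' Draws a single uniform on `[0, 1)` and returns the advanced state. The state
#' is carried in an environment by the reference engine to avoid copy churn.
#'
#' @param state numeric length-3 generator state.
#' @return list with elements `u` (the uniform) and `state`.
#' @keywords internal
ps_next <- function(state) {
  s1 <- (171 * state[1]) %% 30269
  s2 <- (172 * state[2]) %% 30307
  s3 <- (170 * state[3]) %% 30323
  u <- (s1 / 30269 + s2 / 30307 + s3 / 30323) %% 1
  list(u = u, state = c(s1, s2, s3))
}

# Mutable stream wrapper used by the interpreted reference engine.
ps_stream_env <- function(seed, person, stream) {
  e <- new.env(parent = emptyenv())
  e$state <- ps_stream(seed, person, stream)
  e
}

ps_draw <- function(env) {
  nx <- ps_next(env$state)
  env$state <- nx$state
  nx$u
}

#' Draw uniforms from a person stream (R implementation)
#'
#' Mainly a testing surface: returns the first `n` uniforms of a stream, for
#' comparison against the compiled engine's identical generator.
#'
#' @inheritParams ps_stream
#' @param n number of uniforms.
#' @return numeric vector of `n` uniforms in `[0, 1)`.
#' @export
ps_uniforms <- function(seed, person, stream, n) {
  st <- ps_stream(seed, person, stream)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nx <- ps_next(st)
    out[i] <- nx$u
    st <- nx$state
  }
  out
}
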