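#' Derive a reproducible child seed from a shared seed
#'
#' All stochastic components of the package draw their randomness from a
#' single session seed. Independent components (schedule, observer licks,
#' each simulated fiber, each model trial block) receive child seeds derived
#' deterministically from the shared seed and a component key, so that
#' changing one component's draws never perturbs another's.
#'
#' The splitting rule is: interpret the key as its UTF-8 byte values
#' \code{b_i} and return \code{(seed * 69069 + sum(b_i * i)) mod (2^31 - 1)},
#' i.e. a multiplicative congruential step keyed by a positional byte sum.
#' The result is always a valid 32-bit R integer seed.
#'
#' @param seed Integer scalar, the shared parent seed.
#' @param key Character scalar naming the component (e.g. "schedule",
#'   "fiber-17").
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
#' @examples
#' child_seed(1, "schedule")
#' child_seed(1, "fiber-1") != child_seed(1, "fiber-2")
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2^31 - 1
  b <- as.numeric(utf8ToInt(key))
  mix <- sum(b * seq_along(b)) %% m
  as.integer((seed %% m * 69069 + mix) %% m)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# state. NULL seed means "use the current stream" (non-reproducible).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
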