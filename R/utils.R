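# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded draws inside
#' package functions never perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stable 31-bit string hash (polynomial rolling hash)
#'
#' Used to derive per-subject RNG substreams from one global seed.  The hash
#' is a pure function of the string bytes, so identical configs give
#' identical cohorts across platforms and sessions.
#' @noRd
stable_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Derive a child seed below 2^31 from a parent seed and a label
#' @noRd
child_seed <- function(seed, label) {
  as.integer((as.double(seed) * 48271 + stable_hash(label)) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

#' Sample standard deviation that returns 0 (not NA) for length-1 input
#' @noRd
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
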