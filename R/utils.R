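#' Derive a reproducible integer seed from a base seed and string labels
#'
#' Stable 31-multiplier string hash modulo 2^31 - 1, so per-subject random
#' streams do not depend on generation order and are identical across
#' platforms.
#'
#' @param seed base integer seed
#' @param ... labels (coerced to character) identifying the stream
#' @return an integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  s <- paste(as.integer(seed), paste(vapply(list(...), as.character, ""),
                                     collapse = "\r"), sep = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so library functions that consume
#' randomness do not perturb the caller's stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of \code{code}
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
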