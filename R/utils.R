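# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' All user-facing stochastic functions take an explicit `seed` and run their
#' draws inside this wrapper, so the global RNG state of the session is left
#' untouched and results are reproducible per call.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a root seed and string labels
#'
#' Stable across platforms and R sessions: a polynomial rolling hash of the
#' UTF-8 bytes of the labels, folded with the root seed modulo 2^31 - 1, so the
#' result is always a valid positive 32-bit integer seed. Used by the pipeline
#' to give every (stage, pair) its own reproducible stream.
#'
#' @param root_seed integer root seed.
#' @param ... character labels identifying the consumer (stage, pair name, ...).
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(root_seed, ...) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, !is.na(root_seed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(root_seed) %% m
  for (lab in as.character(unlist(list(...)))) {
    for (b in utf8ToInt(lab)) {
      h <- (h * 131 + b) %% m
    }
    h <- (h * 131 + 7) %% m  # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h %% (m - 2) + 1)
}

# Stop with a formatted message (sprintf-style), without the call.
halt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Single-string assertion helper.
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
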