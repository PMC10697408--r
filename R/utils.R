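# Internal helpers shared across modules.

fmt_stop <- function(...) stop(sprintf(...), call. = FALSE)

fmt_warn <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb surrounding randomness. A `NULL` seed evaluates the expression
#' under the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic seed substream derivation: folds integer keys into a master
# seed with a multiplicative congruential mix. Keeps everything < 2^31 so the
# result is a valid R integer seed; collisions across distinct key tuples are
# astronomically unlikely at the stream counts used here.
derive_seed <- function(master, ...) {
  keys <- c(...)
  h <- as.double(master) %% 2147483629
  for (k in keys) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483629
  }
  as.integer(h)
}

# One draw from a Dirichlet distribution with parameter vector `alpha`.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) {
    # numerically degenerate draw (all shapes tiny); fall back to the mode
    x[which.max(alpha)] <- 1
  }
  x / sum(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
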