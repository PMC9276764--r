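# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards. `seed = NULL` leaves the
#' current stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Lehmer-style mixing keeps derived seeds inside the 32-bit integer range
#' so downstream `set.seed()` calls are portable.
#' @param seed master seed (integer)
#' @param k stage index (integer >= 0)
#' @return integer in \[1, 2^31 - 2\]
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(max(1L, as.integer(k) + 1L))) {
    x <- (x * 48271 + 11) %% m
  }
  as.integer(max(1, x))
}

# clamp frequencies away from {0,1} before logit; eps per observation
squeeze_freq <- function(p, n_eff) {
  eps <- 1 / (2 * n_eff + 2)
  pmin(pmax(p, eps), 1 - eps)
}

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("erparallel_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_config(sprintf("'%s' must be a single number in [%s, %s]",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}
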