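# Internal helpers: seeded evaluation without touching global RNG state,
# and per-stage seed derivation so pipeline stages can be rerun independently.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed`, so callers never perturb (or depend on)
#' global RNG state.  Every stochastic operation in the package routes its
#' randomness through this helper.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-seed for a named stage; stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 100003L
  as.integer((abs(as.numeric(seed)) + 97 * h) %% 2147483629)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_binary_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

# Competition (min) ranking on descending value; NA values get NA rank.
competition_rank <- function(x) {
  r <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  r[ok] <- rank(-x[ok], ties.method = "min")
  r
}
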