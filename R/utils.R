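# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed without
#' clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, what, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("%s must be a single finite number", what)
  }
  x <- as.numeric(x)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("%s must lie in %s%g, %g%s (got %g)", what,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]", x)
  }
  x
}

check_probability <- function(x, what) check_number(x, what, 0, 1)

# Field accessor for parsed config lists: a missing field is a validation
# error naming the field, not a silent NULL.
need_field <- function(lst, field, where) {
  if (is.null(lst[[field]])) {
    stopf("missing field '%s' in %s", field, where)
  }
  lst[[field]]
}
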