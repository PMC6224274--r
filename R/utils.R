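# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local random seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so package functions never leak random state. A `NULL`
#' seed evaluates `code` with the current RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a seed to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_field(field, sprintf(
      "must be in %s%s, %s%s (got %g)",
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x))
  }
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < lower) {
    stop_field(field, sprintf("must be an integer >= %d", lower))
  }
  invisible(as.integer(x))
}
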