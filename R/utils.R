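#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE,
                         open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (integer && x != round(x)) stopf("'%s' must be an integer", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("'%s' = %g is outside its allowed range %s%g, %g%s", name, x,
          if (open_lower) "(" else "[", lower, upper,
          if (open_upper) ")" else "]")
  }
  invisible(x)
}

## Canonical patient order used everywhere downstream of alignment.
canonical_order <- function(ids) sort(ids, method = "radix")
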