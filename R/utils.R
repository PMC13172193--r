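# Internal validation and RNG helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("'%s' must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stop_invalid("'%s' must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stop_invalid("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_invalid("'%s' must be a single integer", name)
  if (x < lower)
    stop_invalid("'%s' must be >= %d (got %d)", name, lower, as.integer(x))
  invisible(as.integer(x))
}

#' Derive a per-unit child seed from a base seed
#'
#' Generators draw each cell/particle/replicate from its own derived stream
#' so that enlarging `n` never alters the data of earlier units.
#'
#' @param seed base integer seed.
#' @param index 1-based unit index (may be a vector).
#' @return integer seed(s) in [0, 2^31 - 1).
#' @keywords internal
derive_seed <- function(seed, index) {
  # splitmix-style integer mix kept inside 31 bits for R's RNG seeding
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269 + 11) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
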