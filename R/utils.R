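# Internal helpers: seed discipline and input checking.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so that package functions taking a `seed` argument never
#' disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed for a named pipeline stage; keeps results < 2^31
# so they remain valid R integer seeds.
derive_seed <- function(seed, tag, index = 0L) {
  h <- sum(utf8ToInt(as.character(tag)) *
             (seq_along(utf8ToInt(as.character(tag))) + 13))
  as.integer((abs(seed) * 1009 + h * 31 + index * 7919) %% 2147483629)
}

stop_config <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config(sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
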