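# Internal helpers shared across modules.

#' @keywords internal
mp_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "marmopull_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(...) mp_stop(paste0(...), "mp_validation_error")
format_error     <- function(...) mp_stop(paste0(...), "mp_format_error")

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package route randomness through this
#' helper so that identical seeds give identical outputs and callers' RNG
#' streams are never disturbed.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    validation_error("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical number formatting for on-disk CSVs: full double precision,
# never scientific notation, locale-independent.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15)
      sprintf("%.0f", v)
    else
      sprintf("%.15g", v)
  }, character(1))
  out
}

fmt_int <- function(x) ifelse(is.na(x), "", sprintf("%d", as.integer(x)))

chr_or_empty <- function(x) ifelse(is.na(x), "", as.character(x))

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(name, " must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    validation_error(name, " = ", x, " outside the allowed range")
  invisible(x)
}

# unit-normalize a 3-vector; returns NULL when degenerate
unitize <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < tol) return(NULL)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
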