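#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-hot numeric vector of length n with a single 1 at i
one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

# cumulative trapezoidal integral of y over t; returns vector same length as t,
# starting at 0
cum_trapz <- function(t, y) {
  n <- length(t)
  if (n == 1L) return(0)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

# evaluate an expression with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# z-score a numeric vector; constant vectors are returned centred (all zero)
z_score <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

stop2 <- function(...) stop(..., call. = FALSE)
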