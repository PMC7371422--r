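invlogit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is_scalar_number(x))
    stop_config(sprintf("'%s' must be a single finite number", name))
  bad <- if (strict_lower) x <= lower else x < lower
  if (bad || x > upper)
    stop_config(sprintf("'%s' must be in %s%g, %g]", name,
                        if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

# Dirichlet sampler used by the exceedance-probability estimate.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
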