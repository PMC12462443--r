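# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Run expr with a fixed RNG seed without disturbing the caller's RNG state.
## seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Gaussian smoothing of a vector with nearest-edge padding.
## sigma in samples; sigma <= 0 returns x unchanged.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], r), x, rep(x[n], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
}

## Linear interpolation of the crossing time between samples i and i+1
## where y crosses `level` (y[i] and y[i+1] bracket it). Returns fractional
## index (1-based).
cross_index <- function(y1, y2, i, level) {
  if (y2 == y1) return(i)
  i + (level - y1) / (y2 - y1)
}
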