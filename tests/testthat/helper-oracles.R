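# independent oracles and small fixtures used across the suite

## short paradigm keeping simulations light: few cycles, shortened baseline
## (the 90 s cycle period is kept so the default 78 s epoch window fits)
short_paradigm <- function(n_cycles = 2)
  make_paradigm(onset_duration = 8, cycle_period = 90, n_cycles = n_cycles,
                baseline_lead = 12)

## brute-force double-sum discrete convolution, truncated to length(x)
conv_bruteforce <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(min(i, length(k)))
    out[i] <- sum(k[j] * x[i - j + 1])
  }
  out
}

## closed-form per-voxel OLS (solve the normal equations one voxel at a time)
ols_bruteforce <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dof
  list(beta = drop(beta), sigma2 = sigma2, dof = dof,
       tstat = function(cvec)
         drop(t(cvec) %*% beta) / sqrt(sigma2 * drop(t(cvec) %*%
                                                       solve(XtX) %*% cvec)))
}

## Mann-Whitney U for x vs y (number of (x_i, y_j) pairs with x_i > y_j,
## halves for ties)
u_stat <- function(x, y)
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

## exact two-tailed Mann-Whitney p by complete enumeration of labelings,
## mirroring the doubled one-tail convention
mw_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  u <- u_stat(x, y)
  p <- if (u > n1 * length(y) / 2) 2 * mean(us >= u) else 2 * mean(us <= u)
  min(1, p)
}
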