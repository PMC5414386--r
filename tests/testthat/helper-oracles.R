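# Independent oracles: brute-force counterparts of the package's
# computations, built on base/stats primitives only.

# all n! permutations of 1..n as rows (n <= 7 in tests)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[as.vector(t(sub))], nrow = nrow(sub), byrow = TRUE),
          deparse.level = 0)
  }))
}

# OLS slope via covariance identity (independent of the package's normal
# equations)
oracle_slope <- function(y, x = seq_along(y)) {
  if (length(y) < 2L) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

oracle_statistic <- function(y, k, segment_rule = "include") {
  n <- length(y)
  seg <- if (segment_rule == "include") {
    list(b = seq_len(k), a = k:n)
  } else {
    list(b = seq_len(k - 1L), a = if (k < n) (k + 1L):n else integer(0))
  }
  abs(oracle_slope(y[seg$a], seg$a) - oracle_slope(y[seg$b], seg$b))
}

# exact permutation p-value by full enumeration
oracle_exact_pvalue <- function(y, k, segment_rule = "include") {
  obs <- oracle_statistic(y, k, segment_rule)
  P <- all_permutations(length(y))
  stats <- apply(P, 1, function(idx) oracle_statistic(y[idx], k, segment_rule))
  mean(stats >= obs - 1e-9)
}

# brute-force control band and flag set via stats::lm
oracle_flags <- function(y, multiplier = 1.65) {
  x <- seq_along(y)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  sigma <- sqrt(mean(res^2))
  f <- stats::fitted(fit)
  list(
    fitted = unname(f), sigma = sigma,
    ucl = unname(f) + multiplier * sigma, lcl = unname(f) - multiplier * sigma,
    high = which(y > f + multiplier * sigma),
    low = which(y < f - multiplier * sigma)
  )
}
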