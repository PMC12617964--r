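# Independent oracles used across the suite. Each reimplements the target
# quantity from first principles, never through the package's own code path.

# Least squares by explicit normal equations on a given design matrix.
oracle_ols <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# Tie-corrected Kruskal-Wallis H from the rank formula.
oracle_kw_h <- function(values, groups) {
  g <- as.factor(groups)
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  tie_sizes <- table(values)
  correction <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  h / correction
}

# Exhaustive permutation p-value for H (all N! relabelings; N must be small).
oracle_kw_perm_p <- function(values, groups) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  h_obs <- oracle_kw_h(values, groups)
  h_all <- vapply(perms(values), oracle_kw_h, numeric(1), groups = groups)
  mean(h_all >= h_obs - 1e-12)
}

# Spearman rho as Pearson correlation of average (mid) ranks.
oracle_spearman_rho <- function(x, y) {
  cor(rank(x), rank(y))
}

# DTW distance by explicit enumeration of every admissible warping path.
oracle_dtw <- function(x, y, squared = FALSE) {
  d <- abs(outer(x, y, "-"))
  if (squared) d <- d^2
  n <- length(x)
  m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + d[i, j]
    if (acc >= best) return(invisible())  # prune: costs are nonnegative
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# A linear-trend monthly series with Gaussian noise and known slope/month.
linear_series <- function(n = 68, start = "2018-12", intercept = 40,
                          slope_per_month = 0.5, noise_sd = 0) {
  dates <- month_grid(start, n)
  value <- intercept + slope_per_month * (seq_len(n) - 1)
  if (noise_sd > 0) value <- value + rnorm(n, 0, noise_sd)
  tibble::tibble(date = dates, value = value)
}
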