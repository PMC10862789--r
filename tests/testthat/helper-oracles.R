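# Independent textbook-formula oracles. These are deliberately written from
# the published formulas, not from the package's code paths, so agreement is
# a genuine cross-check.

# Welch two-sample t-test with Welch-Satterthwaite df
oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Welch (1951) k-group heteroscedastic ANOVA
oracle_welch_anova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  s <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * s
  F <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * s)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Brown-Forsythe: one-way ANOVA F on absolute deviations from group medians
oracle_brown_forsythe <- function(groups) {
  d <- lapply(groups, function(g) abs(g - median(g)))
  k <- length(d)
  n <- lengths(d)
  N <- sum(n)
  dbar_i <- vapply(d, mean, numeric(1))
  dbar <- mean(unlist(d))
  ms_between <- sum(n * (dbar_i - dbar)^2) / (k - 1)
  ms_within <- sum(vapply(d, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  F <- ms_between / ms_within
  list(F = F, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Closed-form simple OLS via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- cor(x, y)^2
  list(slope = slope, intercept = intercept, r2 = r2)
}
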