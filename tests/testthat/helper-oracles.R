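# Independent oracles, coded on a different route than the implementation.

# OLS via the normal equations in matrix form (implementation uses centred
# scalar sums).
oracle_ols <- function(x, y, alpha = 0.05) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  covb <- s2 * solve(crossprod(X))
  list(intercept = beta[1], slope = beta[2],
       se_intercept = sqrt(covb[1, 1]), se_slope = sqrt(covb[2, 2]),
       resid_sd = sqrt(s2), t_crit = qt(1 - alpha / 2, n - 2))
}

# Mean-response / new-observation interval half-widths via lm + predict.
oracle_bands <- function(x, y, x0, interval) {
  f <- lm(y ~ x)
  p <- predict(f, newdata = data.frame(x = x0), interval = interval,
               level = 0.95)
  (p[, "upr"] - p[, "lwr"]) / 2
}

# Skewness / excess kurtosis via central moments (implementation
# standardizes first).
oracle_moments <- function(v) {
  m <- mean(v)
  m2 <- mean((v - m)^2)
  list(skewness = mean((v - m)^3) / m2^1.5,
       excess_kurtosis = mean((v - m)^4) / m2^2 - 3)
}

# Exact Bigelow table: D generated from log10 D = log10(d_tref) + (t_ref-T)/z
exact_bigelow_table <- function(z = 30, d_tref = 50, t_ref = 120,
                                temps = seq(80, 130, by = 10), ci = 0) {
  dt_table(temps, 10^(log10(d_tref) + (t_ref - temps) / z), ci)
}
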