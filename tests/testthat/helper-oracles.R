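# Independent oracles, deliberately naive and separate from the package's
# computation paths.

# Per-subject loop version of the normalized dot product.
oracle_edp <- function(z, effects) {
  shared <- intersect(effects$phenotype, setdiff(names(z), "subject_id"))
  vapply(seq_len(nrow(z)), function(s) {
    acc <- 0; n <- 0L
    for (ph in shared) {
      p <- z[[ph]][s]
      if (!is.na(p)) {
        acc <- acc + p * effects$effect[effects$phenotype == ph]
        n <- n + 1L
      }
    }
    if (n == 0L) NA_real_ else acc / n
  }, numeric(1))
}

oracle_check_loss <- function(u, tau) sum(u * (tau - as.numeric(u < 0)))

# Exhaustive vertex enumeration for simple quantile regression: the optimal
# line interpolates two data points; try every pair, keep the minimal check
# loss (ties: lexicographically smallest (intercept, slope)).
oracle_rq_vertex <- function(y, x, tau) {
  n <- length(y)
  best <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      loss <- oracle_check_loss(y - a - b * x, tau)
      cand <- c(intercept = a, slope = b, loss = loss)
      if (is.null(best) || loss < best["loss"] - 1e-12 ||
          (abs(loss - best["loss"]) <= 1e-12 &&
           (a < best["intercept"] - 1e-12 ||
            (abs(a - best["intercept"]) <= 1e-12 && b < best["slope"])))) {
        best <- cand
      }
    }
  }
  best
}

# Direct sum-based Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Normal-equations least squares slope t-statistic for y ~ x.
oracle_slope_t <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  drop(beta[2] / se)
}

# Mean of a clamped normal N(mu, sd^2) restricted to [a, b] by clamping
# (closed form used as the generative-mean oracle).
oracle_clamped_normal_mean <- function(mu, sd, a = 0, b = 4) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  a * pnorm(al) + b * (1 - pnorm(be)) +
    mu * (pnorm(be) - pnorm(al)) - sd * (dnorm(be) - dnorm(al))
}

# Small quick-running cohort configuration for unit tests.
tiny_config <- function(...) {
  cohort_config(n_per_group = 60, seed = 424242, ...)
}
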