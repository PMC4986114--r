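# Independent reference implementations used as oracles. Deliberately
# written as plain loops / alternative identities, sharing no code with the
# package internals.

# streaming per-column mean and sample sd, ignoring NA
oracle_mean_sd <- function(m) {
  k <- ncol(m)
  out <- data.frame(n = integer(k), mean = numeric(k), sd = numeric(k))
  for (j in seq_len(k)) {
    n <- 0L; s <- 0; s2 <- 0
    for (i in seq_len(nrow(m))) {
      v <- m[i, j]
      if (!is.na(v)) { n <- n + 1L; s <- s + v; s2 <- s2 + v * v }
    }
    out$n[j] <- n
    out$mean[j] <- if (n >= 1L) s / n else NA_real_
    out$sd[j] <- if (n >= 2L) sqrt((s2 - s^2 / n) / (n - 1)) else NA_real_
  }
  out
}

# Cronbach's alpha via the covariance-matrix identity:
# alpha = k/(k-1) * (1 - tr(C)/sum(C)), C the item covariance matrix
oracle_alpha <- function(x) {
  C <- stats::cov(x)
  k <- ncol(x)
  (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
}

# straight-line TOPSIS with explicit loops and selection-based ranking
oracle_topsis <- function(x, w, dirs) {
  n <- nrow(x); m <- ncol(x)
  r <- matrix(0, n, m)
  for (j in seq_len(m)) {
    nrm <- 0
    for (i in seq_len(n)) nrm <- nrm + x[i, j]^2
    nrm <- sqrt(nrm)
    for (i in seq_len(n)) r[i, j] <- x[i, j] / nrm
  }
  v <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) v[i, j] <- w[j] * r[i, j]
  ideal <- numeric(m); anti <- numeric(m)
  for (j in seq_len(m)) {
    if (dirs[j] == "benefit") {
      ideal[j] <- max(v[, j]); anti[j] <- min(v[, j])
    } else {
      ideal[j] <- min(v[, j]); anti[j] <- max(v[, j])
    }
  }
  dp <- numeric(n); dm <- numeric(n)
  for (i in seq_len(n)) {
    sp <- 0; sm <- 0
    for (j in seq_len(m)) {
      sp <- sp + (v[i, j] - ideal[j])^2
      sm <- sm + (v[i, j] - anti[j])^2
    }
    dp[i] <- sqrt(sp); dm[i] <- sqrt(sm)
  }
  cl <- numeric(n)
  for (i in seq_len(n))
    cl[i] <- if (dp[i] + dm[i] == 0) 0.5 else dm[i] / (dp[i] + dm[i])
  # ranking by repeated selection: highest closeness, ties -> lowest index
  # (row order == ascending id suffix in all oracle uses)
  ranks <- integer(n)
  remaining <- seq_len(n)
  for (pos in seq_len(n)) {
    best <- remaining[1L]
    for (i in remaining) if (cl[i] > cl[best]) best <- i
    ranks[best] <- pos
    remaining <- setdiff(remaining, best)
  }
  list(r = r, v = v, ideal = ideal, anti_ideal = anti,
       d_plus = dp, d_minus = dm, closeness = cl, ranks = ranks)
}

# mean of Normal(mu, sigma) truncated to [lo, hi], by quadrature
oracle_truncnorm_mean <- function(mu, sigma, lo, hi) {
  z <- stats::integrate(function(t) stats::dnorm(t, mu, sigma), lo, hi)$value
  stats::integrate(function(t) t * stats::dnorm(t, mu, sigma),
                   lo, hi)$value / z
}

# random importance panel used across tests
random_importance_panel <- function(n, k, missing_rate = 0) {
  m <- matrix(sample(1:100, n * k, replace = TRUE), n, k)
  if (missing_rate > 0)
    m[matrix(stats::runif(n * k) < missing_rate, n, k)] <- NA_real_
  importance_panel(m)
}
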