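# Independent brute-force oracles, deliberately written as direct loops over
# the definitions, separate from the package implementations they check.

# 6mDM8h by exhaustive enumeration: every 8-hour window of every day, daily
# maxima, then every 6-consecutive-month mean over a 365-day no-leap year.
oracle_6mdm8h <- function(series) {
  n <- length(series)
  n_days <- n / 24
  dm8h <- numeric(n_days)
  for (d in seq_len(n_days)) {
    best <- -Inf
    for (h in 1:24) {
      s <- (d - 1) * 24 + h
      e <- min(s + 7, n)
      if (e - s + 1 >= 6) best <- max(best, mean(series[s:e]))
    }
    dm8h[d] <- best
  }
  ml <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month_of_day <- rep(1:12, times = ml)
  best_season <- -Inf
  for (m0 in 1:12) {
    months <- ((m0 - 1) + 0:5) %% 12 + 1
    idx <- which(month_of_day %in% months)
    best_season <- max(best_season, mean(dm8h[idx]))
  }
  best_season
}

# closed-form GP posterior mean: hand-built Matern 5/2 kernel matrix and
# solve(), no Cholesky reuse, mirroring the textbook formula
oracle_gp_posterior_mean <- function(X, y, Xnew, ell, nugget, bounds) {
  norm <- function(M) sweep(sweep(M, 2, bounds[1], `-`), 2, bounds[2] - bounds[1], `/`)
  U <- norm(X); Un <- norm(Xnew)
  m52 <- function(a, b) {
    r <- sqrt(sum(((a - b) / ell)^2))
    (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  n <- nrow(U)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- m52(U[i, ], U[j, ])
  K <- K + diag(nugget, n)
  mu <- mean(y); sdv <- sd(y)
  z <- (y - mu) / sdv
  a <- solve(K, z)
  out <- numeric(nrow(Un))
  for (i in seq_len(nrow(Un))) {
    ks <- vapply(1:n, function(j) m52(Un[i, ], U[j, ]), numeric(1))
    out[i] <- mu + sdv * sum(ks * a)
  }
  out
}

# NMBF/NMAEF evaluated directly from the factor-metric definitions
oracle_nmbf <- function(model, obs) {
  if (mean(model) >= mean(obs)) mean(model) / mean(obs) - 1
  else 1 - mean(obs) / mean(model)
}
oracle_nmaef <- function(model, obs) {
  if (mean(model) >= mean(obs)) sum(abs(model - obs)) / sum(obs)
  else sum(abs(model - obs)) / sum(model)
}
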