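#' Fit a Gaussian-process emulator
#'
#' Fits a zero-mean Gaussian process with a Matern 5/2 kernel and
#' per-dimension length-scales (automatic relevance determination) to a
#' small designed set of simulator runs. Inputs are rescaled to the unit
#' cube using `bounds`; the output is centred and scaled to unit
#' variance. The process variance is concentrated out of the marginal
#' likelihood analytically, and the length-scales are optimized by
#' L-BFGS-B on the concentrated negative log marginal likelihood from
#' `restarts + 1` seeded starting points (one central, the rest random);
#' ties break toward the higher likelihood, then lexicographically
#' smaller log length-scales.
#'
#' @param X Numeric design matrix (n_runs x n_dims).
#' @param y Numeric response vector (length n_runs).
#' @param bounds 2 x n_dims matrix (or length-2 vector recycled) of input
#'   bounds used for normalization.
#' @param nugget Jitter added to the correlation diagonal on the
#'   standardized scale (> 0); absorbs simulator round-off and keeps the
#'   Cholesky factor well conditioned.
#' @param restarts Number of random restarts for hyperparameter
#'   optimization (>= 0).
#' @param seed Integer seed controlling the restart draws.
#' @return An object of class `gp_emulator`.
#' @seealso [predict.gp_emulator()]
#' @export
gp_fit <- function(X, y, bounds = c(0, 1.5), nugget = 1e-6,
                   restarts = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite training values")
  if (nugget <= 0) stop("nugget must be > 0")
  if (!is.matrix(bounds)) bounds <- matrix(rep(bounds, d), nrow = 2L)

  span <- bounds[2, ] - bounds[1, ]
  U <- sweep(sweep(X, 2, bounds[1, ], `-`), 2, span, `/`)

  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) {
    # degenerate constant response: predictions are that constant
    return(structure(list(constant = y_mean, bounds = bounds, X = X, y = y,
                          nugget = nugget),
                     class = "gp_emulator"))
  }
  z <- (y - y_mean) / y_sd

  neg_cll <- function(log_ell) {
    R <- matern52_cor(U, U, exp(log_ell))
    diag(R) <- diag(R) + nugget
    L <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), z))
    s2 <- sum(z * a) / n
    if (s2 <= 0) return(1e10)
    as.numeric(n / 2 * log(s2) + sum(log(diag(L))))
  }

  lower <- rep(log(0.05), d); upper <- rep(log(20), d)
  rng <- local_seed(seed)
  starts <- rbind(rep(log(1), d))
  if (restarts > 0)
    starts <- rbind(starts,
                    matrix(stats::runif(restarts * d, log(0.2), log(5)),
                           ncol = d))
  restore_seed(rng)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], neg_cll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         lex_less(fit$par, best$par))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("hyperparameter optimization failed for all starts")

  ell <- exp(best$par)
  R <- matern52_cor(U, U, ell)
  diag(R) <- diag(R) + nugget
  L <- tryCatch(chol(R), error = function(e)
    stop("singular kernel matrix at the optimized hyperparameters"))
  alpha <- backsolve(L, forwardsolve(t(L), z))
  s2 <- sum(z * alpha) / n

  structure(list(
    U = U, z = z, alpha = alpha, L = L,
    ell = ell, s2 = s2, nugget = nugget,
    y_mean = y_mean, y_sd = y_sd,
    bounds = bounds, X = X, y = y,
    log_marginal = -best$value - n / 2 * (log(2 * pi) + 1)
  ), class = "gp_emulator")
}

# Matern 5/2 correlation between row sets A (n x d) and B (m x d),
# per-dimension length-scales ell
matern52_cor <- function(A, B, ell) {
  As <- sweep(A, 2, ell, `/`)
  Bs <- sweep(B, 2, ell, `/`)
  d2 <- outer(rowSums(As^2), rep(1, nrow(Bs))) +
    outer(rep(1, nrow(As)), rowSums(Bs^2)) - 2 * As %*% t(Bs)
  r <- sqrt(pmax(d2, 0))
  sr <- sqrt(5) * r
  (1 + sr + sr^2 / 3) * exp(-sr)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Predict from a Gaussian-process emulator
#'
#' Posterior mean (and optionally posterior SD) at new input points.
#'
#' @param object A `gp_emulator`.
#' @param newdata Matrix (or vector for a single point) of inputs.
#' @param se Return the posterior predictive SD as well?
#' @param ... Unused.
#' @return Numeric vector of posterior means, or a list `mean`, `sd` when
#'   `se = TRUE`.
#' @export
predict.gp_emulator <- function(object, newdata, se = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) {
    mu <- rep(object$constant, nrow(newdata))
    if (se) return(list(mean = mu, sd = rep(0, nrow(newdata))))
    return(mu)
  }
  span <- object$bounds[2, ] - object$bounds[1, ]
  Un <- sweep(sweep(newdata, 2, object$bounds[1, ], `-`), 2, span, `/`)
  K <- matern52_cor(Un, object$U, object$ell)
  mu <- object$y_mean + object$y_sd * as.vector(K %*% object$alpha)
  if (!se) return(mu)
  V <- forwardsolve(t(object$L), t(K))
  # posterior variance on the standardized scale: s2 * (1 + nugget - k*' R^-1 k*)
  var_z <- pmax(object$s2 * (1 + object$nugget - colSums(V^2)), 0)
  list(mean = mu, sd = object$y_sd * sqrt(var_z))
}

#' @export
print.gp_emulator <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<gp_emulator> degenerate constant response (%.4g)\n", x$constant))
  } else {
    cat(sprintf("<gp_emulator> n = %d, Matern 5/2 ARD; length-scales: %s\n",
                nrow(x$U), paste(signif(x$ell, 3), collapse = ", ")))
  }
  invisible(x)
}

#' @export
residuals.gp_emulator <- function(object, ...) {
  object$y - predict(object, object$X)
}
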