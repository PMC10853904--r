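# Gaussian-process surrogate for the Bayesian-optimization planner.
# Matern-5/2 kernel with automatic-relevance-determination length scales and an
# observation-noise term; inputs live on the unit square (normalized over the
# design bounds), objective values are standardized before fitting, and
# hyperparameters are set by maximum marginal likelihood with a small
# multistart.

matern52 <- function(X1, X2, signal_var, lengthscales) {
  d1 <- outer(X1[, 1] / lengthscales[1], X2[, 1] / lengthscales[1], "-")
  d2 <- outer(X1[, 2] / lengthscales[2], X2[, 2] / lengthscales[2], "-")
  r <- sqrt(d1^2 + d2^2)
  s5r <- sqrt(5) * r
  signal_var * (1 + s5r + (5 / 3) * r^2) * exp(-s5r)
}

gp_nll <- function(theta, X, y) {
  sf2 <- exp(theta[1]); ls <- exp(theta[2:3]); sn2 <- exp(theta[4])
  n <- length(y)
  K <- matern52(X, X, sf2, ls) + diag(sn2 + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

#' Fit the Gaussian-process surrogate to campaign observations
#'
#' Conditions are normalized to the unit square over the bounds and objective
#' values standardized to zero mean / unit variance; a Matern-5/2 kernel with
#' per-dimension length scales plus an observation-noise term (replicated
#' center points make noise-free interpolation inappropriate) is fitted by
#' maximizing the marginal likelihood from three fixed starting points. If the
#' observations are degenerate (a single point, or identical objective
#' values), fixed moderate hyperparameters are used instead and flagged.
#'
#' @param ss,temp_C,y training conditions and objective values.
#' @param b a [bounds()] defining the normalization.
#' @return An object of class `gp_surrogate`.
#' @export
fit_surrogate <- function(ss, temp_C, y, b) {
  stopifnot(length(ss) == length(y), length(temp_C) == length(y),
            length(y) >= 1, inherits(b, "bounds"))
  U <- cbind((ss - b$ss_min) / (b$ss_max - b$ss_min),
             (temp_C - b$t_min) / (b$t_max - b$t_min))
  ymu <- mean(y)
  ysd <- stats::sd(y)
  degenerate <- length(y) < 2 || !is.finite(ysd) || ysd < 1e-12
  if (degenerate) ysd <- 1
  z <- (y - ymu) / ysd

  if (degenerate || length(unique(paste(ss, temp_C))) < 2) {
    theta <- log(c(1, 0.5, 0.5, 1e-4))
  } else {
    starts <- list(log(c(1, 0.3, 0.3, 1e-2)),
                   log(c(1, 1.0, 1.0, 1e-2)),
                   log(c(2, 0.15, 0.15, 1e-4)))
    fits <- lapply(starts, function(s)
      tryCatch(stats::optim(s, gp_nll, X = U, y = z, method = "L-BFGS-B",
                            lower = log(c(1e-3, 0.03, 0.03, 1e-6)),
                            upper = log(c(1e3, 10, 10, 10))),
               error = function(e) list(par = s, value = gp_nll(s, U, z))))
    theta <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]$par
  }
  sf2 <- exp(theta[1]); ls <- exp(theta[2:3]); sn2 <- exp(theta[4])
  K <- matern52(U, U, sf2, ls) + diag(sn2 + 1e-10, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), z))
  structure(list(U = U, z = z, y_mean = ymu, y_sd = ysd, bounds = b,
                 signal_var = sf2, lengthscales = ls, noise_var = sn2,
                 L = L, alpha = alpha, degenerate = degenerate),
            class = "gp_surrogate")
}

#' Posterior mean and standard deviation of the surrogate
#'
#' @param state a `gp_surrogate` from [fit_surrogate()].
#' @param ss,temp_C query conditions (vectors).
#' @param standardized return the posterior on the standardized-objective
#'   scale (the scale the acquisition works on) instead of the original scale.
#' @return List with numeric vectors `mean` and `sd`.
#' @export
gp_posterior <- function(state, ss, temp_C, standardized = FALSE) {
  b <- state$bounds
  Us <- cbind((ss - b$ss_min) / (b$ss_max - b$ss_min),
              (temp_C - b$t_min) / (b$t_max - b$t_min))
  Ks <- matern52(state$U, Us, state$signal_var, state$lengthscales)
  mu <- drop(crossprod(Ks, state$alpha))
  v <- forwardsolve(t(state$L), Ks)
  var <- pmax(state$signal_var - colSums(v^2), 0)
  sd <- sqrt(var)
  if (!standardized) {
    mu <- mu * state$y_sd + state$y_mean
    sd <- sd * state$y_sd
  }
  list(mean = mu, sd = sd)
}

#' Expected improvement with an exploration jitter
#'
#' Expected improvement for minimization with the improvement margin shifted
#' by the acquisition jitter xi: `EI = (best - mu - xi) Phi(z) + sigma phi(z)`
#' with `z = (best - mu - xi)/sigma`; at `sigma = 0` it degenerates to
#' `max(best - mu - xi, 0)`. Larger jitter discounts exploitation of the
#' posterior mean and pushes recommendations toward uncertain regions.
#'
#' @param mu,sd posterior mean and standard deviation (vectors).
#' @param best best (lowest) objective value observed so far.
#' @param jitter acquisition jitter xi, >= 0.
#' @return Nonnegative numeric vector.
#' @export
expected_improvement <- function(mu, sd, best, jitter = 0) {
  stopifnot(all(sd >= 0), jitter >= 0)
  imp <- best - mu - jitter
  ei <- pmax(imp, 0)
  pos <- sd > 0
  z <- imp[pos] / sd[pos]
  ei[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  pmax(ei, 0)
}

#' Recommend the next experiment by maximizing expected improvement
#'
#' Scans a dense grid over the bounds (lexicographic in supersaturation then
#' temperature, so flat-acquisition ties break deterministically toward the
#' lowest supersaturation, then the lowest temperature), then polishes the
#' best cell with a local simplex search. The returned condition lies strictly
#' inside the bounds. The acquisition works on the objective's own scale, so
#' the jitter ladder (0.001-10) spans roughly the objective's dynamic range:
#' 10 buys almost pure exploration, 0.001 almost pure exploitation.
#'
#' @param state a `gp_surrogate`.
#' @param jitter acquisition jitter (objective units).
#' @param grid_n grid resolution per axis.
#' @return A [condition()] with attribute `ei` (the acquisition value there).
#' @export
recommend_next <- function(state, jitter, grid_n = 101) {
  b <- state$bounds
  best <- min(state$z * state$y_sd + state$y_mean)
  u1 <- seq(0, 1, length.out = grid_n)
  # expand.grid varies its first factor fastest, so (u2, u1) orders rows
  # lexicographically by (SS, T); which.max then ties-breaks to lowest SS/T.
  grid <- expand.grid(u2 = u1, u1 = u1)[, c("u1", "u2")]
  ss <- b$ss_min + grid$u1 * (b$ss_max - b$ss_min)
  tt <- b$t_min + grid$u2 * (b$t_max - b$t_min)
  post <- gp_posterior(state, ss, tt)
  ei <- expected_improvement(post$mean, post$sd, best, jitter)
  i <- which.max(ei)
  u_best <- c(grid$u1[i], grid$u2[i])
  ei_best <- ei[i]

  neg_ei <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    p <- gp_posterior(state, b$ss_min + u[1] * (b$ss_max - b$ss_min),
                      b$t_min + u[2] * (b$t_max - b$t_min))
    -expected_improvement(p$mean, p$sd, best, jitter)
  }
  pol <- tryCatch(stats::optim(u_best, neg_ei, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && -pol$value > ei_best) {
    u_best <- pmin(pmax(pol$par, 0), 1)
    ei_best <- -pol$value
  }
  eps <- 1e-6
  u_best <- pmin(pmax(u_best, eps), 1 - eps)
  out <- condition(b$ss_min + u_best[1] * (b$ss_max - b$ss_min),
                   b$t_min + u_best[2] * (b$t_max - b$t_min))
  attr(out, "ei") <- ei_best
  out
}
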