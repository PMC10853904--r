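# Ensemble minimization of the response-surface objective. Four independent
# derivative-free minimizers (real-coded genetic algorithm, differential
# evolution, CMA-ES, Hooke-Jeeves pattern search, plus optional Nelder-Mead)
# run on the unit square; solutions stuck on a bound or failed are discarded
# and the survivors aggregated by coordinate-wise median, which is robust to
# the single-algorithm outliers that a mean would drag.

unit_clip <- function(u) pmin(pmax(u, 0), 1)

# Real-coded genetic algorithm: tournament selection, blend crossover,
# Gaussian mutation.
.opt_ga <- function(fn, pop_size = 40, generations = 60) {
  pop <- matrix(stats::runif(pop_size * 2), ncol = 2)
  fit <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    parents <- t(vapply(seq_len(pop_size), function(i) {
      cand <- sample.int(pop_size, 3)
      pop[cand[which.min(fit[cand])], ]
    }, numeric(2)))
    mates <- parents[sample.int(pop_size), , drop = FALSE]
    alpha <- matrix(stats::runif(pop_size * 2, -0.25, 1.25), ncol = 2)
    child <- unit_clip(parents + alpha * (mates - parents))
    mut <- matrix(stats::runif(pop_size * 2) < 0.15, ncol = 2)
    child[mut] <- unit_clip(child[mut] + stats::rnorm(sum(mut), sd = 0.08))
    cfit <- apply(child, 1, fn)
    # elitist replacement
    keep <- cfit < fit
    pop[keep, ] <- child[keep, , drop = FALSE]
    fit[keep] <- cfit[keep]
  }
  i <- which.min(fit)
  list(par = pop[i, ], value = fit[i], converged = TRUE)
}

# Differential evolution, rand/1/bin.
.opt_de <- function(fn, pop_size = 30, generations = 80, F = 0.7, CR = 0.9) {
  pop <- matrix(stats::runif(pop_size * 2), ncol = 2)
  fit <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      idx <- sample(setdiff(seq_len(pop_size), i), 3)
      v <- unit_clip(pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ]))
      cross <- stats::runif(2) < CR
      cross[sample(2, 1)] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      tf <- fn(trial)
      if (tf <= fit[i]) { pop[i, ] <- trial; fit[i] <- tf }
    }
  }
  i <- which.min(fit)
  list(par = pop[i, ], value = fit[i], converged = TRUE)
}

# Covariance matrix adaptation evolution strategy (mu/mu_w, lambda), standard
# rank-based weights; box handled by clipping candidates.
.opt_cmaes <- function(fn, sigma = 0.3, lambda = 12, iterations = 80) {
  n <- 2
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- stats::runif(n)
  pc <- ps <- numeric(n)
  C <- diag(n)
  best <- list(par = xmean, value = fn(xmean))
  for (it in seq_len(iterations)) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    Z <- matrix(stats::rnorm(lambda * n), nrow = n)
    Y <- B %*% (D * Z)
    X <- unit_clip(xmean + sigma * t(Y))
    f <- apply(X, 1, fn)
    ord <- order(f)
    if (f[ord[1]] < best$value) best <- list(par = X[ord[1], ], value = f[ord[1]])
    xold <- xmean
    xmean <- drop(w %*% X[ord[seq_len(mu)], , drop = FALSE])
    yw <- (xmean - xold) / sigma
    Cinvsqrt <- B %*% diag(1 / D, n) %*% t(B)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) * drop(Cinvsqrt %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * it)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * yw
    artmp <- t((X[ord[seq_len(mu)], , drop = FALSE] - matrix(xold, mu, n, byrow = TRUE)) / sigma)
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% diag(w, mu) %*% t(artmp)
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1) sigma <- 1
    if (sigma < 1e-12) break
  }
  list(par = unit_clip(best$par), value = best$value, converged = TRUE)
}

# Hooke-Jeeves pattern search with step halving.
.opt_pattern <- function(fn, start = c(0.5, 0.5), step = 0.25, tol = 1e-6) {
  x <- start
  fx <- fn(x)
  while (step > tol) {
    improved <- FALSE
    for (d in 1:2) for (s in c(step, -step)) {
      cand <- x
      cand[d] <- min(max(cand[d] + s, 0), 1)
      fc <- fn(cand)
      if (fc < fx) { x <- cand; fx <- fc; improved <- TRUE }
    }
    if (!improved) step <- step / 2
  }
  list(par = x, value = fx, converged = TRUE)
}

.opt_nelder_mead <- function(fn) {
  pen <- function(u) {
    if (any(u < 0) || any(u > 1)) return(fn(unit_clip(u)) + 10 * sum(pmax(0, -u) + pmax(0, u - 1)))
    fn(u)
  }
  res <- tryCatch(stats::optim(c(0.5, 0.5), pen, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(res)) return(list(par = c(NA, NA), value = Inf, converged = FALSE))
  list(par = unit_clip(res$par), value = fn(unit_clip(res$par)),
       converged = res$convergence == 0)
}

#' Locate the minimum of an objective surface with an algorithm ensemble
#'
#' Minimizes `f(ss, temp_C)` over the design space with four independent
#' derivative-free algorithms (genetic algorithm, differential evolution,
#' CMA-ES, Hooke-Jeeves pattern search; optionally Nelder-Mead as a fifth).
#' Each runs on the unit square under a fixed per-algorithm seed. Solutions
#' that failed to converge or sit on a bound — symptomatic of an algorithm
#' sliding along the box rather than finding an interior optimum — are
#' discarded, and the survivors are aggregated by coordinate-wise median.
#'
#' @param f objective function of `(ss, temp_C)` returning a scalar.
#' @param b a [bounds()].
#' @param seed integer seed; each algorithm derives its own sub-seed.
#' @param include_nelder_mead also run Nelder-Mead (often boundary-stuck on
#'   these surfaces, hence excluded from the default ensemble and discarded
#'   when it is).
#' @param boundary_tol fraction of each span within which a solution counts as
#'   on-boundary.
#' @return A `minimizer_report`: data frame `per_algorithm` (algorithm, ss,
#'   temp_C, value, converged, at_boundary, used) and the aggregated
#'   [condition()] under `$minimum`.
#' @export
minimize_surface <- function(f, b, seed = 1L, include_nelder_mead = FALSE,
                             boundary_tol = 1e-3) {
  stopifnot(inherits(b, "bounds"), is.function(f))
  span_ss <- b$ss_max - b$ss_min
  span_t <- b$t_max - b$t_min
  fn <- function(u) f(b$ss_min + u[1] * span_ss, b$t_min + u[2] * span_t)

  algos <- list(ga = .opt_ga, de = .opt_de, cmaes = .opt_cmaes,
                pattern_search = .opt_pattern)
  if (include_nelder_mead) algos$nelder_mead <- .opt_nelder_mead

  rows <- lapply(seq_along(algos), function(i) {
    res <- with_seed(seed + i * 1000L, algos[[i]](fn))
    u <- res$par
    at_bound <- any(u <= boundary_tol) || any(u >= 1 - boundary_tol)
    data.frame(algorithm = names(algos)[i],
               ss = b$ss_min + u[1] * span_ss,
               temp_C = b$t_min + u[2] * span_t,
               value = res$value, converged = res$converged,
               at_boundary = at_bound,
               used = res$converged && !at_bound,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (!any(per$used))
    stop("all minimizers converged onto the design-space boundary or failed; ",
         "the optimum likely lies outside the bounds - consider widening them")
  keep <- per[per$used, , drop = FALSE]
  structure(list(per_algorithm = per,
                 minimum = condition(stats::median(keep$ss),
                                     stats::median(keep$temp_C))),
            class = "minimizer_report")
}

#' @export
print.minimizer_report <- function(x, ...) {
  cat("Surface-minimizer ensemble report\n")
  print(x$per_algorithm, row.names = FALSE)
  cat(sprintf("aggregated minimum (median of %d used): SS %.4f, %.3f degC\n",
              sum(x$per_algorithm$used), x$minimum$ss, x$minimum$temp_C))
  invisible(x)
}
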