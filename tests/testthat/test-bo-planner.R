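test_that("GP posterior interpolates data and reverts to the prior far away", {
  b <- lamivudine_bounds()
  st <- fit_surrogate(2.1, 8, 1.7, b)
  at <- gp_posterior(st, 2.1, 8)
  expect_equal(at$mean, 1.7, tolerance = 1e-4)
  expect_lt(at$sd, 0.05)  # only the small noise nugget remains at the datum
  far <- gp_posterior(st, 3, 50, standardized = TRUE)
  expect_gt(far$sd, 0.99 * sqrt(st$signal_var))
})

test_that("GP posterior matches the closed-form two-point conditional", {
  b <- lamivudine_bounds()
  st <- fit_surrogate(c(2.2, 2.8), c(15, 40), c(1.0, 3.0), b)
  # independent oracle: direct conditional-Gaussian formulas via solve()
  mat52 <- function(u, v) {
    r <- sqrt(sum(((u - v) / st$lengthscales)^2))
    st$signal_var * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  U <- st$U
  K <- outer(1:2, 1:2, Vectorize(function(i, j) mat52(U[i, ], U[j, ]))) +
    diag(st$noise_var + 1e-10, 2)
  q <- c(0.35, 0.6) # normalized query
  ks <- c(mat52(U[1, ], q), mat52(U[2, ], q))
  mu_oracle <- sum(ks * solve(K, st$z))
  sd_oracle <- sqrt(mat52(q, q) - drop(t(ks) %*% solve(K, ks)))
  got <- gp_posterior(st,
                      b$ss_min + q[1] * (b$ss_max - b$ss_min),
                      b$t_min + q[2] * (b$t_max - b$t_min), standardized = TRUE)
  expect_lt(abs(got$mean - mu_oracle), 1e-8)
  expect_lt(abs(got$sd - sd_oracle), 1e-8)
})

test_that("expected improvement handles the degenerate zero-variance limit", {
  expect_equal(expected_improvement(0.2, 0, best = 1, jitter = 0.5), 0.3)
  expect_equal(expected_improvement(0.6, 0, best = 1, jitter = 0.5), 0)
  expect_equal(expected_improvement(2, 0, best = 1, jitter = 0), 0)
})

test_that("expected improvement matches a Monte-Carlo oracle", {
  set.seed(301)
  zdraw <- stats::rnorm(1e5)
  zdraw <- c(zdraw, -zdraw) # antithetic
  cases <- expand.grid(mu = c(-1, 0, 0.8), sd = c(0.1, 1), best = c(0, 1),
                       jitter = c(0, 0.5, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    mc <- mean(pmax(cs$best - cs$jitter - (cs$mu + cs$sd * zdraw), 0))
    expect_lt(abs(expected_improvement(cs$mu, cs$sd, cs$best, cs$jitter) - mc),
              2e-3)
  }
})

test_that("jitter ladder steps at the 10% and 5% fractions and never rises", {
  s <- jitter_schedule("adaptive")
  expect_equal(s$jitter, 10)
  s <- update_jitter(s, latest = 0.8, maximum = 10)  # fraction 0.08
  expect_equal(s$jitter, 1)
  s <- update_jitter(s, latest = 5, maximum = 10)    # fraction 0.5: no rise
  expect_equal(s$jitter, 1)
  s <- update_jitter(s, latest = 0.3, maximum = 10)  # fraction 0.03
  expect_equal(s$jitter, 0.1)
  s <- update_jitter(s, latest = 0.01, maximum = 10)
  expect_equal(s$jitter, 0.1)

  f <- jitter_schedule(1)
  expect_equal(update_jitter(f, 0.01, 10)$jitter, 1) # fixed mode never moves
  expect_error(jitter_schedule(3), "fixed jitter")
})

test_that("recommendations are deterministic, in-bounds, and explorative under
           a large jitter", {
  b <- lamivudine_bounds()
  st <- fit_surrogate(2.5, 27.5, 1.7, b)
  r1 <- recommend_next(st, jitter = 10)
  r2 <- recommend_next(st, jitter = 10)
  expect_identical(r1, r2)
  # far from the single center observation, in normalized units
  d <- sqrt(((r1$ss - 2.5) / 1)^2 + ((r1$temp_C - 27.5) / 45)^2)
  expect_gt(d, 0.25)

  set.seed(88)
  for (i in 1:20) {
    st2 <- fit_surrogate(stats::runif(4, 2, 3), stats::runif(4, 5, 50),
                         stats::runif(4, 0.2, 5), b)
    r <- recommend_next(st2, jitter = sample(c(0.001, 0.1, 1, 10), 1))
    expect_true(r$ss >= b$ss_min && r$ss <= b$ss_max)
    expect_true(r$temp_C >= b$t_min && r$temp_C <= b$t_max)
  }
})

test_that("campaigns initialize with exactly three center replicates", {
  tg <- lamivudine_targets()
  b <- lamivudine_bounds()
  lab <- virtual_lab(noisy_truth())
  camp <- run_bo_campaign(lab, tg, b, mode = 1, max_experiments = 3, seed = 5)
  expect_equal(nrow(camp$log), 3)
  expect_true(all(camp$log$iteration == 0))
  expect_true(all(camp$log$ss == 2.5 & camp$log$temp_C == 27.5))
  # replicates differ under noise (distinct derived seeds)
  expect_gt(stats::sd(camp$log$nuc_rate_per_s), 0)
})

test_that("campaign jitter sequence is non-increasing, drawn from the ladder,
           and the running best objective never rises", {
  tg <- lamivudine_targets()
  b <- lamivudine_bounds()
  lab <- virtual_lab(noisy_truth())
  camp <- run_bo_campaign(lab, tg, b, mode = "adaptive", max_experiments = 20,
                          seed = 42)
  expect_true(all(diff(camp$log$jitter) <= 0))
  expect_true(all(camp$log$jitter %in% c(10, 1, 0.1, 0.001)))
  tr <- convergence_trace(camp)
  expect_true(all(diff(tr$best_objective) <= 0))
  expect_true(all(camp$log$ss >= b$ss_min & camp$log$ss <= b$ss_max))
  expect_true(all(camp$log$temp_C >= b$t_min & camp$log$temp_C <= b$t_max))

  camp2 <- run_bo_campaign(lab, tg, b, mode = "adaptive", max_experiments = 20,
                           seed = 42)
  expect_identical(camp$log, camp2$log)
})

test_that("a DoE warm start seeds the surrogate with the screen data", {
  tg <- lamivudine_targets()
  b <- lamivudine_bounds()
  lab <- virtual_lab(exact_truth())
  doe <- run_doe_campaign(lab, tg, b, center = condition(2.4, 20),
                          max_iterations = 1, seed = 3)
  camp <- run_bo_campaign(lab, tg, b, mode = 1, max_experiments = 33, seed = 5,
                          warm_start = doe$log)
  expect_equal(sum(camp$log$iteration == 0), 28 + 3)
})
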