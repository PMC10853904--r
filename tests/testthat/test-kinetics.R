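test_that("eval_relation evaluates linear and exponential forms", {
  lin <- kinetic_relation("growth_rate", "supersaturation", coeff_a = 1,
                          coeff_b = 0)
  expect_equal(eval_relation(lin, 2), 2)
  exp0 <- kinetic_relation("nucleation_rate", "temperature", coeff_A = 1,
                           coeff_a = 0, coeff_b = 0)
  expect_equal(eval_relation(exp0, c(-5, 0, 42)), rep(1, 3))
  exp1 <- kinetic_relation("induction_time", "supersaturation", coeff_A = 2,
                           coeff_a = 1, coeff_b = 0)
  expect_equal(eval_relation(exp1, log(3)), 6)
})

test_that("eval_relation floors predicted values at a small positive epsilon", {
  lin <- kinetic_relation("growth_rate", "temperature", coeff_a = -1,
                          coeff_b = 0)
  expect_equal(eval_relation(lin, 10), 1e-12)
  expect_gt(eval_relation(lin, 10), 0)
})

test_that("fit_relation reproduces a line through two points and rejects one", {
  rel <- fit_relation(c(0, 1), c(1, 3), "growth_rate", "supersaturation")
  expect_equal(rel$coeff_a, 2)
  expect_equal(rel$coeff_b, 1)
  expect_error(fit_relation(1, 2, "growth_rate", "supersaturation"),
               "distinct")
  expect_error(fit_relation(c(2, 2, 2), c(1, 2, 3), "growth_rate",
                            "supersaturation"), "distinct")
})

test_that("fit_relation inverts eval_relation on noise-free data", {
  gen <- kinetic_relation("induction_time", "supersaturation", coeff_A = 100,
                          coeff_a = -1.5, coeff_b = 0)
  x <- seq(1, 3, length.out = 7)
  rel <- fit_relation(x, eval_relation(gen, x), "induction_time",
                      "supersaturation")
  expect_lt(abs(rel$coeff_A - 100) / 100, 1e-6)
  expect_lt(abs(rel$coeff_a - (-1.5)) / 1.5, 1e-6)
  # and for every registry relation
  for (gen in recovery_relations()) {
    x <- seq(min(recovery_x(gen, 2)), max(recovery_x(gen, 2)), length.out = 9)
    rel <- fit_relation(x, eval_relation(gen, x), gen$parameter, gen$variable)
    expect_lt(abs(rel$coeff_a - gen$coeff_a) / abs(gen$coeff_a), 1e-6)
    if (rel$form == "exponential")
      expect_lt(abs(rel$coeff_A - gen$coeff_A) / gen$coeff_A, 1e-6)
    else
      expect_lt(abs(rel$coeff_b - gen$coeff_b) / abs(gen$coeff_b), 1e-6)
  }
})

test_that("distance transforms vanish at the target and grow with deviation", {
  expect_equal(distance_exponential(3600, 3600), 0)
  expect_equal(distance_exponential(1, exp(1)), 1)
  for (k in c(1.5, 3, 10))
    expect_equal(distance_exponential(2, 2 * k), distance_exponential(2, 2 / k))
  expect_error(distance_exponential(1, -1), "positive")

  expect_equal(distance_linear(0.1, 0.1), 0)
  expect_equal(distance_linear(0.1, 0.3), 0.2)
  expect_equal(distance_linear(0.1, 0.1 + 0.07), distance_linear(0.1, 0.1 - 0.07))
})

test_that("response-surface objective is zero at the crossing point,
           nonnegative, and weights growth terms", {
  tg <- kinetic_targets()
  model <- target_crossing_model(2.4, 25, tg)
  expect_equal(doe_objective(model, tg, 2.4, 25), 0)

  # grid sweep: nonnegative and continuous (no jumps) over the bounds
  b <- lamivudine_bounds()
  ss <- seq(b$ss_min, b$ss_max, length.out = 50)
  tt <- seq(b$t_min, b$t_max, length.out = 50)
  g <- expand.grid(ss = ss, temp_C = tt)
  f <- doe_objective(model, tg, g$ss, g$temp_C)
  expect_true(all(f >= 0))
  fm <- matrix(f, 50, 50)
  expect_lt(max(abs(diff(fm))), 0.5)        # along SS
  expect_lt(max(abs(diff(t(fm)))), 0.5)     # along T

  # perturbing only the growth-SS relation adds growth_weight * d
  pert <- model
  d <- 0.004
  pert[["growth_rate~supersaturation"]]$coeff_b <-
    pert[["growth_rate~supersaturation"]]$coeff_b + d
  expect_equal(doe_objective(pert, tg, 2.4, 25) - doe_objective(model, tg, 2.4, 25),
               tg$growth_weight * d)
})

test_that("measured-kinetics objective is a sum of absolute log ratios", {
  tg <- kinetic_targets()
  on_target <- structure(list(t_ind_s = tg$t_ind_s, censored_all = FALSE,
                              nuc_rate_per_s = tg$r_nuc_per_s,
                              growth_um_s = tg$r_growth_um_s),
                         class = "measured_kinetics")
  expect_equal(bo_objective(on_target, tg), 0)

  one_off <- on_target
  one_off$nuc_rate_per_s <- exp(1) * tg$r_nuc_per_s
  expect_equal(bo_objective(one_off, tg), 1)

  # scale invariance: rescaling a parameter and its target leaves it unchanged
  tg2 <- kinetic_targets(tg$t_ind_s * 7, tg$r_nuc_per_s, tg$r_growth_um_s)
  scaled <- one_off
  scaled$t_ind_s <- scaled$t_ind_s * 7
  expect_equal(bo_objective(scaled, tg2), bo_objective(one_off, tg))
})

test_that("fully censored experiments get a finite penalty objective", {
  tg <- kinetic_targets()
  cens <- structure(list(censored_all = TRUE), class = "measured_kinetics")
  p0 <- bo_objective(cens, tg, hold_s = 10800, max_term_so_far = 0)
  expect_equal(p0, abs(log(10800 / 3600)))
  p1 <- bo_objective(cens, tg, hold_s = 10800, max_term_so_far = 2.5)
  expect_equal(p1, abs(log(3)) + 5)
  expect_true(is.finite(p1))
})

test_that("fit_kinetics fits all five relations from an experiment table", {
  tr <- exact_truth()
  lab <- virtual_lab(tr)
  des <- make_initial_design(condition(2.4, 20), lamivudine_bounds())
  rows <- lapply(seq_len(nrow(des)), function(i) {
    m <- lab(condition(des$ss[i], des$temp_C[i]), i)
    data.frame(ss = m$ss, temp_C = m$temp_C, t_ind_s = m$t_ind_s,
               censored = as.integer(m$censored_all),
               nuc_rate_per_s = m$nuc_rate_per_s, growth_um_s = m$growth_um_s)
  })
  model <- fit_kinetics(do.call(rbind, rows))
  expect_s3_class(model, "kinetic_model")
  expect_length(model, 5)
  # the induction-time relation is exact: it depends on supersaturation only
  rel <- model[["induction_time~supersaturation"]]
  tru <- tr$model[["induction_time~supersaturation"]]
  expect_equal(eval_relation(rel, 2.4), eval_relation(tru, 2.4),
               tolerance = 0.01)
  expect_error(fit_kinetics(data.frame(ss = 1)), "lacks columns")
})

test_that("kinetic_model construction demands exactly the registry relations", {
  expect_error(kinetic_model(recovery_relations()[1:4]), "missing")
  m <- kinetic_model(recovery_relations())
  expect_s3_class(m, "kinetic_model")
  expect_error(kinetic_relation("induction_time", "temperature", coeff_a = 1),
               "no modelled relation")
})
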