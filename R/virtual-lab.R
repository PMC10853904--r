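# Stochastic virtual laboratory: simulates one parallel-reactor crystallization
# experiment (repeated heat/dissolve/cool/hold cycles with imaging) from a
# ground-truth kinetic model, so planners can be exercised without hardware.

#' Ground truth for the virtual laboratory
#'
#' Defines the generating kinetics and the experimental protocol emulated by
#' [run_experiment()]: five heat-dissolve-cool-hold cycles per vial, a 3 h
#' isothermal hold, and images every 5 s (so detected induction times are
#' quantized to the imaging grid and right-censored at the hold).
#'
#' @param model a `kinetic_model` used as generating truth.
#' @param rate_noise_cv coefficient of variation of the multiplicative
#'   lognormal noise on nucleation and growth rates (0.2 emulates the
#'   measurement scatter of image-analysis rate estimates; 0 disables noise).
#' @param n_cycles nucleation cycles per vial.
#' @param hold_s isothermal hold, seconds.
#' @param obs_dt_s imaging interval, seconds.
#' @param solubility_g_mL reference solubility, g/mL, at `solubility_T_ref_C`.
#' @param solubility_T_ref_C reference temperature for the solubility, deg C.
#' @param solubility_k exponential temperature coefficient of solubility,
#'   per deg C (van 't Hoff-style).
#' @param vial_volume_mL working volume per experiment.
#' @param deterministic if `TRUE`, induction times equal their distribution
#'   mean instead of being drawn; with `rate_noise_cv = 0` the whole simulator
#'   — and any planner loop driven by it — becomes deterministic.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(model, rate_noise_cv = 0.2, n_cycles = 5,
                         hold_s = 10800, obs_dt_s = 5,
                         solubility_g_mL = 0.1, solubility_T_ref_C = 25,
                         solubility_k = 0.02, vial_volume_mL = 5,
                         deterministic = FALSE) {
  stopifnot(inherits(model, "kinetic_model"), rate_noise_cv >= 0,
            n_cycles >= 1, hold_s > 0, obs_dt_s > 0, vial_volume_mL > 0,
            solubility_g_mL > 0)
  structure(list(model = model, rate_noise_cv = rate_noise_cv,
                 n_cycles = as.integer(n_cycles), hold_s = hold_s,
                 obs_dt_s = obs_dt_s, solubility_g_mL = solubility_g_mL,
                 solubility_T_ref_C = solubility_T_ref_C,
                 solubility_k = solubility_k, vial_volume_mL = vial_volume_mL,
                 deterministic = deterministic),
            class = "ground_truth")
}

#' Example ground truth with an interior optimum
#'
#' A generating kinetic model whose five relations all pass through the default
#' lamivudine-style targets (3600 s, 0.1 /s, 0.01 um/s) at supersaturation 2.4
#' and 25 deg C, inside the 2-3 / 5-50 deg C design space: induction time
#' falls steeply (exponentially) with supersaturation, nucleation rate rises
#' with both supersaturation and temperature, growth rate rises gently with
#' both. Useful as a default truth for simulated campaigns and as a case where
#' the response-surface objective has a known interior zero.
#'
#' @param ss_star,temp_star condition at which every relation crosses its
#'   target.
#' @param targets a [kinetic_targets()] the relations should cross.
#' @param ... passed to [ground_truth()] (noise level, protocol settings).
#' @return An object of class `ground_truth`.
#' @export
default_ground_truth <- function(ss_star = 2.4, temp_star = 25,
                                 targets = kinetic_targets(), ...) {
  model <- kinetic_model(
    # t_ind drops about 20x per unit supersaturation
    kinetic_relation("induction_time", "supersaturation", coeff_A = 1,
                     coeff_a = -3, coeff_b = log(targets$t_ind_s) + 3 * ss_star),
    kinetic_relation("nucleation_rate", "supersaturation",
                     coeff_a = 0.15, coeff_b = targets$r_nuc_per_s - 0.15 * ss_star),
    kinetic_relation("growth_rate", "supersaturation",
                     coeff_a = 0.008, coeff_b = targets$r_growth_um_s - 0.008 * ss_star),
    # strongly thermally activated nucleation (~90x over the 45 degC span, as
    # classical nucleation kinetics suggest), growth ~5x over the span
    kinetic_relation("nucleation_rate", "temperature", coeff_A = 1,
                     coeff_a = 0.1, coeff_b = log(targets$r_nuc_per_s) - 0.1 * temp_star),
    kinetic_relation("growth_rate", "temperature",
                     coeff_a = 4e-4, coeff_b = targets$r_growth_um_s - 4e-4 * temp_star))
  ground_truth(model, ...)
}

# Evaluate the generating value of a rate at a 2-D condition: the geometric
# mean of the two marginal predictions, which is symmetric, positive, and
# reduces to either marginal when the other relation is flat at the same level.
truth_rate <- function(truth, parameter, ss, temp_C) {
  sqrt(eval_relation(model_relation(truth$model, parameter, "supersaturation"), ss) *
       eval_relation(model_relation(truth$model, parameter, "temperature"), temp_C))
}

truth_induction_mean <- function(truth, ss) {
  eval_relation(model_relation(truth$model, "induction_time", "supersaturation"), ss)
}

# Run a block of code with the RNG seeded locally, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate one crystallization experiment
#'
#' Runs the virtual protocol at a condition: each cycle draws an induction
#' time from an exponential distribution (memoryless primary nucleation) whose
#' mean is the ground-truth induction relation at the condition's
#' supersaturation, rounds it up to the next imaging frame (detection cannot
#' precede an image), and censors it at the isothermal hold. Nucleation and
#' growth rates combine the two marginal ground-truth relations by geometric
#' mean and are perturbed by mean-1 multiplicative lognormal noise with the
#' configured coefficient of variation. Output is bit-identical for identical
#' `(cond, truth, seed)`.
#'
#' @param cond a [condition()].
#' @param truth a [ground_truth()].
#' @param seed integer seed fixing all randomness of this experiment.
#' @return An object of class `measured_kinetics` with fields
#'   `induction_times_s` (NA where a cycle saw no nucleation before the hold
#'   ended), `censored` (per-cycle flags), `t_ind_s` (mean of uncensored
#'   cycles; NA if all censored), `censored_all`, `nuc_rate_per_s`,
#'   `growth_um_s`.
#' @export
run_experiment <- function(cond, truth, seed) {
  stopifnot(inherits(cond, "condition"), inherits(truth, "ground_truth"))
  with_seed(seed, {
    mu <- truth_induction_mean(truth, cond$ss)
    raw <- if (truth$deterministic) rep(mu, truth$n_cycles)
           else stats::rexp(truth$n_cycles, rate = 1 / mu)
    t_obs <- ceiling(raw / truth$obs_dt_s) * truth$obs_dt_s
    cens <- t_obs > truth$hold_s
    t_obs[cens] <- NA_real_

    rn <- truth_rate(truth, "nucleation_rate", cond$ss, cond$temp_C)
    rg <- truth_rate(truth, "growth_rate", cond$ss, cond$temp_C)
    if (truth$rate_noise_cv > 0) {
      sdlog <- sqrt(log(1 + truth$rate_noise_cv^2))
      noise <- stats::rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rn <- rn * noise[1]
      rg <- rg * noise[2]
    }
    structure(list(
      induction_times_s = t_obs,
      censored = cens,
      t_ind_s = if (all(cens)) NA_real_ else mean(t_obs[!cens]),
      censored_all = all(cens),
      nuc_rate_per_s = rn,
      growth_um_s = rg,
      ss = cond$ss, temp_C = cond$temp_C), class = "measured_kinetics")
  })
}

#' Coerce an experiment-table row to measured kinetics
#'
#' @param row one-row data frame in the experiment-table dialect.
#' @return A `measured_kinetics` object (cycle-level detail absent).
#' @export
as_measured_kinetics <- function(row) {
  structure(list(induction_times_s = row$t_ind_s, censored = row$censored == 1,
                 t_ind_s = row$t_ind_s, censored_all = row$censored == 1,
                 nuc_rate_per_s = row$nuc_rate_per_s,
                 growth_um_s = row$growth_um_s,
                 ss = row$ss, temp_C = row$temp_C),
            class = "measured_kinetics")
}

#' Solute mass required for one experiment
#'
#' Grams of active ingredient needed to prepare one vial at a condition:
#' supersaturation times the solubility at the condition temperature (used as
#' the saturation-temperature proxy) times the working volume. Supports
#' material-usage accounting across campaigns.
#'
#' @param cond a [condition()].
#' @param truth a [ground_truth()] carrying the solubility parameters.
#' @return Mass in grams.
#' @export
material_for_run <- function(cond, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  sol <- truth$solubility_g_mL *
    exp(truth$solubility_k * (cond$temp_C - truth$solubility_T_ref_C))
  cond$ss * sol * truth$vial_volume_mL
}

#' Package a ground truth as a laboratory function
#'
#' Wraps a [ground_truth()] into the `lab` interface the planners consume: a
#' function `(cond, seed) -> measured_kinetics`, carrying the truth's hold
#' time and material model as attributes so campaigns can apply the censoring
#' penalty and account for solute usage.
#'
#' @param truth a [ground_truth()].
#' @return A function of class `virtual_lab`.
#' @export
virtual_lab <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  f <- function(cond, seed) run_experiment(cond, truth, seed)
  attr(f, "truth") <- truth
  class(f) <- c("virtual_lab", "function")
  f
}

lab_hold_s <- function(lab) {
  tr <- attr(lab, "truth")
  if (is.null(tr)) 10800 else tr$hold_s
}

lab_material <- function(lab, cond) {
  tr <- attr(lab, "truth")
  if (is.null(tr)) NA_real_ else material_for_run(cond, tr)
}

#' @export
print.measured_kinetics <- function(x, ...) {
  cat(sprintf("Measured kinetics at SS %.3f, %.2f degC\n", x$ss, x$temp_C))
  if (x$censored_all) {
    cat("  no nucleation detected in any cycle (fully censored)\n")
  } else {
    cat(sprintf("  induction time : %.1f s (%d/%d cycles uncensored)\n",
                x$t_ind_s, sum(!x$censored), length(x$censored)))
  }
  cat(sprintf("  nucleation rate: %.4g /s\n  growth rate    : %.4g um/s\n",
              x$nuc_rate_per_s, x$growth_um_s))
  invisible(x)
}
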