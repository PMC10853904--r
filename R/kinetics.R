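# Kinetic relations between process inputs (supersaturation, temperature) and
# measured crystallization kinetics, plus the target-distance transforms that
# turn them into optimization objectives.

#' Kinetic target objectives
#'
#' Bundle of the three kinetic target values a campaign steers toward, plus the
#' weight applied to the growth-rate terms of the response-surface objective.
#' Growth rates are one to two orders of magnitude smaller than the other
#' objectives, so weighting them by 10 puts all terms on a comparable scale.
#'
#' @param t_ind_s target induction time, seconds.
#' @param r_nuc_per_s target nucleation rate, counts per second.
#' @param r_growth_um_s target growth rate, micrometers per second.
#' @param growth_weight dimensionless multiplier applied to both growth-rate
#'   terms of the design-of-experiments objective.
#' @return An object of class `kinetic_targets`.
#' @examples
#' kinetic_targets(3600, 0.1, 0.01)
#' @export
kinetic_targets <- function(t_ind_s = 3600, r_nuc_per_s = 0.1,
                            r_growth_um_s = 0.01, growth_weight = 10) {
  stopifnot(t_ind_s > 0, r_nuc_per_s > 0, r_growth_um_s > 0, growth_weight > 0)
  structure(list(t_ind_s = t_ind_s, r_nuc_per_s = r_nuc_per_s,
                 r_growth_um_s = r_growth_um_s, growth_weight = growth_weight),
            class = "kinetic_targets")
}

#' Input-parameter bounds
#'
#' Rectangular design space over supersaturation ratio and isothermal
#' temperature. Supersaturation is dimensionless (1 at equilibrium solubility);
#' temperature is in degrees Celsius.
#'
#' @param ss_min,ss_max supersaturation bounds, `ss_min < ss_max`, both >= 1.
#' @param t_min,t_max temperature bounds in deg C, `t_min < t_max`.
#' @return An object of class `bounds`.
#' @examples
#' bounds(2, 3, 5, 50)    # broad metastable zone, e.g. lamivudine/ethanol
#' bounds(1.05, 2, 5, 50) # narrow metastable zone, e.g. aspirin/ethyl acetate
#' @export
bounds <- function(ss_min, ss_max, t_min, t_max) {
  stopifnot(is.finite(ss_min), is.finite(ss_max), is.finite(t_min),
            is.finite(t_max), ss_min < ss_max, t_min < t_max, ss_min >= 1)
  structure(list(ss_min = ss_min, ss_max = ss_max, t_min = t_min,
                 t_max = t_max), class = "bounds")
}

#' Experiment condition
#'
#' A single (supersaturation, temperature) setting.
#'
#' @param ss supersaturation ratio.
#' @param temp_C isothermal temperature, deg C.
#' @return An object of class `condition`.
#' @export
condition <- function(ss, temp_C) {
  stopifnot(is.finite(ss), is.finite(temp_C))
  structure(list(ss = ss, temp_C = temp_C), class = "condition")
}

clip_to_bounds <- function(ss, temp_C, b) {
  list(ss = pmin(pmax(ss, b$ss_min), b$ss_max),
       temp_C = pmin(pmax(temp_C, b$t_min), b$t_max))
}

in_bounds <- function(ss, temp_C, b, tol = 0) {
  ss >= b$ss_min - tol & ss <= b$ss_max + tol &
    temp_C >= b$t_min - tol & temp_C <= b$t_max + tol
}

# Registry of the five modelled relations. Induction time has no temperature
# relation: there is no direct domain relationship between the two, so that
# pair is never instantiated. Exponential forms capture the steep
# supersaturation dependence of induction time and the thermally activated
# nucleation rate; the remaining rate relations are treated as locally linear.
.relation_registry <- data.frame(
  parameter = c("induction_time", "nucleation_rate", "growth_rate",
                "nucleation_rate", "growth_rate"),
  variable  = c("supersaturation", "supersaturation", "supersaturation",
                "temperature", "temperature"),
  form      = c("exponential", "linear", "linear", "exponential", "linear"),
  stringsAsFactors = FALSE
)

#' Registry of modelled kinetic relations
#'
#' Which functional form links each kinetic parameter to each input variable:
#' induction time vs supersaturation and nucleation rate vs temperature are
#' exponential; the other three instantiated relations are linear. The
#' induction time / temperature pair is deliberately absent.
#'
#' @return A data frame with columns `parameter`, `variable`, `form`.
#' @export
relation_registry <- function() .relation_registry

registry_form <- function(parameter, variable) {
  i <- which(.relation_registry$parameter == parameter &
             .relation_registry$variable == variable)
  if (length(i) != 1L)
    stop("no modelled relation between '", parameter, "' and '", variable, "'")
  .relation_registry$form[i]
}

#' Construct a kinetic relation
#'
#' One fitted (or user-supplied) relation between a kinetic parameter and one
#' input variable. Linear relations evaluate as `a*x + b`; exponential
#' relations as `A*exp(a*x + b)`.
#'
#' @param parameter one of `"induction_time"`, `"nucleation_rate"`,
#'   `"growth_rate"`.
#' @param variable one of `"supersaturation"`, `"temperature"`.
#' @param coeff_A amplitude of the exponential form (ignored by linear forms).
#' @param coeff_a slope coefficient.
#' @param coeff_b intercept/offset coefficient.
#' @return An object of class `kinetic_relation`.
#' @export
kinetic_relation <- function(parameter, variable, coeff_A = 1, coeff_a,
                             coeff_b = 0) {
  form <- registry_form(parameter, variable)
  stopifnot(is.finite(coeff_A), is.finite(coeff_a), is.finite(coeff_b))
  if (form == "exponential" && coeff_A <= 0)
    stop("exponential relations require a positive amplitude")
  structure(list(parameter = parameter, variable = variable, form = form,
                 coeff_A = coeff_A, coeff_a = coeff_a, coeff_b = coeff_b),
            class = "kinetic_relation")
}

#' Evaluate a kinetic relation
#'
#' Evaluates the relation at input value(s) `x`. Predicted rates and times are
#' floored at `1e-12` so that downstream logarithms stay defined; linear fits
#' extrapolated outside the screened region can otherwise go nonpositive.
#'
#' @param rel a [kinetic_relation()].
#' @param x numeric vector of input values (supersaturation or deg C).
#' @return Numeric vector of predicted kinetic parameter values.
#' @export
eval_relation <- function(rel, x) {
  stopifnot(inherits(rel, "kinetic_relation"), all(is.finite(x)))
  if (is.null(rel$coeff_a) || !is.finite(rel$coeff_a))
    stop("relation coefficients are not set")
  y <- if (rel$form == "linear") rel$coeff_a * x + rel$coeff_b
       else rel$coeff_A * exp(rel$coeff_a * x + rel$coeff_b)
  pmax(y, 1e-12)
}

#' Fit one kinetic relation by least squares
#'
#' Fits the registry form for `(parameter, variable)` to observed pairs.
#' Linear forms are fitted by ordinary least squares. Exponential forms are
#' fitted by least squares on the log scale (`log y ~ x`), which is the
#' maximum-likelihood fit under the multiplicative lognormal measurement noise
#' these kinetics carry; the amplitude `A` is estimated with the offset `b`
#' fixed at zero, since `A` and `exp(b)` are not separately identifiable.
#' Censored observations must be excluded by the caller.
#'
#' @param x numeric input values (all finite; for exponential fits `y > 0`).
#' @param y observed kinetic parameter values.
#' @param parameter,variable registry keys selecting the form.
#' @return A [kinetic_relation()] with attributes `residual_norm` (residual
#'   sum-of-squares square root, on the fitting scale) and `n_points`.
#' @export
fit_relation <- function(x, y, parameter, variable) {
  form <- registry_form(parameter, variable)
  ok <- is.finite(x) & is.finite(y)
  if (form == "exponential") ok <- ok & y > 0
  x <- x[ok]; y <- y[ok]
  ndistinct <- length(unique(x))
  need <- if (form == "exponential") 2L else 2L
  if (length(x) < need || ndistinct < 2L)
    stop("cannot fit ", form, " relation for ", parameter, " vs ", variable,
         ": need >= ", need, " points with at least 2 distinct x values, got ",
         length(x), " (", ndistinct, " distinct)")
  if (form == "linear") {
    fit <- stats::lm.fit(cbind(x = x, intercept = 1), y)
    rel <- kinetic_relation(parameter, variable, coeff_a = fit$coefficients[["x"]],
                            coeff_b = fit$coefficients[["intercept"]])
  } else {
    fit <- stats::lm.fit(cbind(x = x, intercept = 1), log(y))
    rel <- kinetic_relation(parameter, variable,
                            coeff_A = exp(fit$coefficients[["intercept"]]),
                            coeff_a = fit$coefficients[["x"]], coeff_b = 0)
  }
  attr(rel, "residual_norm") <- sqrt(sum(fit$residuals^2))
  attr(rel, "n_points") <- length(x)
  rel
}

#' Log-ratio distance for exponential relations
#'
#' Distance transform applied to kinetic parameters whose input relation is
#' exponential: `|ln(fitted) - ln(target)|`. Zero exactly at the target and
#' symmetric under multiplicative deviation, so overshooting the target by a
#' factor k costs the same as undershooting by 1/k.
#'
#' @param target,fitted strictly positive values (vectors recycle).
#' @return Nonnegative numeric vector.
#' @export
distance_exponential <- function(target, fitted) {
  if (any(!is.finite(target) | target <= 0) || any(!is.finite(fitted) | fitted <= 0))
    stop("distance_exponential requires strictly positive arguments")
  abs(log(fitted) - log(target))
}

#' Absolute-difference distance for linear relations
#'
#' Distance transform applied to kinetic parameters whose input relation is
#' linear: `|fitted - target|`.
#'
#' @param target,fitted finite values (vectors recycle).
#' @return Nonnegative numeric vector.
#' @export
distance_linear <- function(target, fitted) {
  stopifnot(all(is.finite(target)), all(is.finite(fitted)))
  abs(fitted - target)
}

#' Fit the full kinetic model to an experiment table
#'
#' Fits all five registry relations to accumulated experiment results. Rows
#' with a censored induction time contribute their rate measurements but are
#' excluded from the induction-time fit; rows with nonpositive rates are
#' excluded from the corresponding exponential fits.
#'
#' @param data a data frame in the experiment-table dialect: columns `ss`,
#'   `temp_C`, `t_ind_s`, `censored` (0/1), `nuc_rate_per_s`, `growth_um_s`.
#' @return An object of class `kinetic_model`: a named list of five
#'   [kinetic_relation()] objects keyed `"<parameter>~<variable>"`.
#' @seealso [predict.kinetic_model()], [doe_objective()]
#' @export
fit_kinetics <- function(data) {
  need <- c("ss", "temp_C", "t_ind_s", "censored", "nuc_rate_per_s",
            "growth_um_s")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("experiment table lacks columns: ", paste(missing_cols, collapse = ", "))
  unc <- data$censored == 0 & is.finite(data$t_ind_s)
  rels <- list(
    "induction_time~supersaturation" =
      fit_relation(data$ss[unc], data$t_ind_s[unc],
                   "induction_time", "supersaturation"),
    "nucleation_rate~supersaturation" =
      fit_relation(data$ss, data$nuc_rate_per_s,
                   "nucleation_rate", "supersaturation"),
    "growth_rate~supersaturation" =
      fit_relation(data$ss, data$growth_um_s,
                   "growth_rate", "supersaturation"),
    "nucleation_rate~temperature" =
      fit_relation(data$temp_C, data$nuc_rate_per_s,
                   "nucleation_rate", "temperature"),
    "growth_rate~temperature" =
      fit_relation(data$temp_C, data$growth_um_s,
                   "growth_rate", "temperature"))
  structure(rels, class = "kinetic_model", n_obs = nrow(data))
}

#' Construct a kinetic model from known relations
#'
#' Assembles a `kinetic_model` directly from five relations, e.g. to define a
#' virtual-lab ground truth. All five registry relations must be present.
#'
#' @param ... five [kinetic_relation()] objects (order free).
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(...) {
  rels <- list(...)
  if (length(rels) == 1L && is.list(rels[[1]]) &&
      !inherits(rels[[1]], "kinetic_relation")) rels <- rels[[1]]
  keys <- vapply(rels, function(r) paste0(r$parameter, "~",
                 c(supersaturation = "supersaturation",
                   temperature = "temperature")[[r$variable]]), "")
  names(rels) <- keys
  expected <- paste0(.relation_registry$parameter, "~", .relation_registry$variable)
  if (!setequal(keys, expected))
    stop("kinetic_model needs exactly the five registry relations; missing: ",
         paste(setdiff(expected, keys), collapse = ", "))
  structure(rels[expected], class = "kinetic_model")
}

model_relation <- function(model, parameter, variable) {
  key <- paste0(parameter, "~", variable)
  rel <- model[[key]]
  if (is.null(rel)) stop("kinetic model is missing relation ", key)
  rel
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Fitted crystallization kinetic model (5 relations)\n")
  for (rel in x) {
    eq <- if (rel$form == "linear")
      sprintf("%.6g * x + %.6g", rel$coeff_a, rel$coeff_b)
    else
      sprintf("%.6g * exp(%.6g * x + %.6g)", rel$coeff_A, rel$coeff_a, rel$coeff_b)
    cat(sprintf("  %-15s ~ %-16s [%-11s]  y = %s\n",
                rel$parameter, rel$variable, rel$form, eq))
  }
  invisible(x)
}

#' @export
coef.kinetic_model <- function(object, ...) {
  do.call(rbind, lapply(object, function(r)
    data.frame(parameter = r$parameter, variable = r$variable, form = r$form,
               A = r$coeff_A, a = r$coeff_a, b = r$coeff_b,
               row.names = NULL)))
}

#' Predict kinetic parameters from a fitted model
#'
#' @param object a `kinetic_model`.
#' @param parameter which kinetic parameter to predict.
#' @param variable which marginal relation to use.
#' @param x input values (supersaturation ratio or deg C).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.kinetic_model <- function(object, parameter, variable, x, ...) {
  eval_relation(model_relation(object, parameter, variable), x)
}

#' Response-surface objective for the DoE planner
#'
#' Evaluates the smoothed objective surface at condition(s): the sum over the
#' five fitted relations of the matching distance transform between target and
#' fitted value (log-ratio distance for the exponential relations, absolute
#' difference for the linear ones), with both growth-rate terms multiplied by
#' `targets$growth_weight`. Zero exactly where every fitted relation passes
#' through its target.
#'
#' @param model a fitted `kinetic_model`.
#' @param targets a [kinetic_targets()].
#' @param ss,temp_C condition coordinates (equal-length vectors recycle).
#' @return Nonnegative numeric vector of objective values.
#' @export
doe_objective <- function(model, targets, ss, temp_C) {
  stopifnot(inherits(model, "kinetic_model"), inherits(targets, "kinetic_targets"))
  w <- targets$growth_weight
  distance_exponential(targets$t_ind_s,
      eval_relation(model_relation(model, "induction_time", "supersaturation"), ss)) +
  distance_linear(targets$r_nuc_per_s,
      eval_relation(model_relation(model, "nucleation_rate", "supersaturation"), ss)) +
  w * distance_linear(targets$r_growth_um_s,
      eval_relation(model_relation(model, "growth_rate", "supersaturation"), ss)) +
  distance_exponential(targets$r_nuc_per_s,
      eval_relation(model_relation(model, "nucleation_rate", "temperature"), temp_C)) +
  w * distance_linear(targets$r_growth_um_s,
      eval_relation(model_relation(model, "growth_rate", "temperature"), temp_C))
}

#' Measured-kinetics objective for the Bayesian-optimization planner
#'
#' Sum over the three kinetic parameters of the absolute log-ratio between the
#' measured value and its target, `|ln(P_target) - ln(P_exp)|`. The log form
#' already places induction time, nucleation rate and growth rate on the same
#' scale, so no extra weighting is applied by default (set
#' `weight_growth = TRUE` to multiply the growth term by
#' `targets$growth_weight`). A fully censored experiment (no nucleation in any
#' cycle) returns a finite penalty instead of raising: the log-ratio between
#' the hold time and the induction-time target plus twice the largest
#' single-term contribution observed so far in the campaign, keeping the
#' surrogate model well behaved while marking the region as poor.
#'
#' @param measured a `measured_kinetics` result from [run_experiment()] or a
#'   row of an experiment table coerced via [as_measured_kinetics()].
#' @param targets a [kinetic_targets()].
#' @param weight_growth apply the growth weight to the growth term?
#' @param hold_s isothermal hold used for the censoring penalty, seconds.
#' @param max_term_so_far largest per-term contribution observed so far in the
#'   campaign (0 before any uncensored result).
#' @return Nonnegative scalar objective value.
#' @export
bo_objective <- function(measured, targets, weight_growth = FALSE,
                         hold_s = 10800, max_term_so_far = 0) {
  stopifnot(inherits(targets, "kinetic_targets"))
  if (isTRUE(measured$censored_all))
    return(abs(log(hold_s / targets$t_ind_s)) + 2 * max_term_so_far)
  gw <- if (weight_growth) targets$growth_weight else 1
  abs(log(targets$t_ind_s) - log(max(measured$t_ind_s, 1e-12))) +
    abs(log(targets$r_nuc_per_s) - log(max(measured$nuc_rate_per_s, 1e-12))) +
    gw * abs(log(targets$r_growth_um_s) - log(max(measured$growth_um_s, 1e-12)))
}
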