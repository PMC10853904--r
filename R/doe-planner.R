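# Adaptive design-of-experiments planner: an initial 5x5 full-factorial screen
# with center replicates, then successive shrinking two-level factorials
# centered at the ensemble-predicted minimum of the physics-smoothed objective
# surface, until successive recommendations stop moving.

#' Shrinking design schedule for the adaptive DoE
#'
#' Half-widths of the factorial designs per iteration: the initial screen
#' spans supersaturation +/-0.4 and temperature +/-10 degC; follow-up
#' iterations shrink to +/-0.2/10, +/-0.1/5, +/-0.05/2, and iterations past
#' the third reuse the final exploitative plan.
#'
#' @param ss_deltas supersaturation half-widths: initial, then iterations 1-3.
#' @param temp_deltas temperature half-widths (deg C), same layout.
#' @return An object of class `doe_schedule`.
#' @export
doe_schedule <- function(ss_deltas = c(0.4, 0.2, 0.1, 0.05),
                         temp_deltas = c(10, 10, 5, 2)) {
  stopifnot(length(ss_deltas) == length(temp_deltas),
            all(diff(ss_deltas) <= 0), all(diff(temp_deltas) <= 0),
            all(ss_deltas > 0), all(temp_deltas > 0))
  structure(list(ss_deltas = ss_deltas, temp_deltas = temp_deltas),
            class = "doe_schedule")
}

schedule_deltas <- function(schedule, iteration) {
  # iteration 0 = initial screen; >= length reuses the last (exploitative) row
  i <- min(iteration, length(schedule$ss_deltas) - 1L) + 1L
  c(ss = schedule$ss_deltas[i], temp = schedule$temp_deltas[i])
}

#' Initial full-factorial screen
#'
#' Five equally spaced levels per factor spanning the center +/- delta, fully
#' crossed (25 runs), plus three center-point replicates: 28 conditions.
#' Conditions falling outside the bounds are clipped onto them, keeping the
#' run count fixed.
#'
#' @param center a [condition()]; must lie within `b`.
#' @param b a [bounds()].
#' @param ss_delta,temp_delta design half-widths (defaults: the initial-screen
#'   row of [doe_schedule()]).
#' @return Data frame of 28 rows with columns `ss`, `temp_C`.
#' @export
make_initial_design <- function(center, b, ss_delta = 0.4, temp_delta = 10) {
  stopifnot(inherits(center, "condition"), inherits(b, "bounds"))
  if (!in_bounds(center$ss, center$temp_C, b))
    stop("design center lies outside the input-parameter bounds")
  ss_levels <- seq(center$ss - ss_delta, center$ss + ss_delta, length.out = 5)
  t_levels <- seq(center$temp_C - temp_delta, center$temp_C + temp_delta,
                  length.out = 5)
  grid <- expand.grid(temp_C = t_levels, ss = ss_levels)[, c("ss", "temp_C")]
  des <- rbind(grid, data.frame(ss = rep(center$ss, 3),
                                temp_C = rep(center$temp_C, 3)))
  cl <- clip_to_bounds(des$ss, des$temp_C, b)
  data.frame(ss = cl$ss, temp_C = cl$temp_C)
}

#' Follow-up two-level factorial
#'
#' The exploitation screen run at each adaptive iteration: the four corners of
#' center +/- the iteration's half-widths plus three center replicates — 7
#' conditions, clipped into the bounds.
#'
#' @param center a [condition()].
#' @param iteration follow-up iteration index (1-based).
#' @param schedule a [doe_schedule()].
#' @param b a [bounds()].
#' @return Data frame of 7 rows with columns `ss`, `temp_C`.
#' @export
make_followup_design <- function(center, iteration, schedule = doe_schedule(),
                                 b) {
  stopifnot(inherits(center, "condition"), inherits(schedule, "doe_schedule"),
            inherits(b, "bounds"), iteration >= 1)
  d <- schedule_deltas(schedule, iteration)
  corners <- expand.grid(temp_C = center$temp_C + c(-1, 1) * d[["temp"]],
                         ss = center$ss + c(-1, 1) * d[["ss"]])[, c("ss", "temp_C")]
  des <- rbind(corners, data.frame(ss = rep(center$ss, 3),
                                   temp_C = rep(center$temp_C, 3)))
  cl <- clip_to_bounds(des$ss, des$temp_C, b)
  data.frame(ss = cl$ss, temp_C = cl$temp_C)
}

#' Campaign termination check
#'
#' TRUE when successive recommended conditions differ by strictly less than
#' 2 deg C in temperature and strictly less than 0.02 in supersaturation.
#'
#' @param previous,current successive recommended [condition()]s.
#' @param ss_tol,temp_tol strict thresholds.
#' @return Logical scalar.
#' @export
check_termination <- function(previous, current, ss_tol = 0.02, temp_tol = 2) {
  stopifnot(inherits(previous, "condition"), inherits(current, "condition"))
  abs(current$temp_C - previous$temp_C) < temp_tol &&
    abs(current$ss - previous$ss) < ss_tol
}

# Run a design through the lab, returning experiment-table rows.
run_design <- function(design, lab, targets, seed_base, iteration,
                       max_term_env) {
  hold <- lab_hold_s(lab)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    cond <- condition(design$ss[i], design$temp_C[i])
    m <- lab(cond, seed_base + i)
    obj <- bo_objective(m, targets, hold_s = hold,
                        max_term_so_far = max_term_env$max_term)
    if (!m$censored_all) {
      terms <- c(abs(log(targets$t_ind_s) - log(max(m$t_ind_s, 1e-12))),
                 abs(log(targets$r_nuc_per_s) - log(max(m$nuc_rate_per_s, 1e-12))),
                 abs(log(targets$r_growth_um_s) - log(max(m$growth_um_s, 1e-12))))
      max_term_env$max_term <- max(max_term_env$max_term, terms)
    }
    data.frame(iteration = iteration, ss = cond$ss, temp_C = cond$temp_C,
               t_ind_s = m$t_ind_s, censored = as.integer(m$censored_all),
               nuc_rate_per_s = m$nuc_rate_per_s, growth_um_s = m$growth_um_s,
               objective = obj, material_g = lab_material(lab, cond))
  })
  do.call(rbind, rows)
}

#' Run an adaptive DoE optimization campaign
#'
#' The closed loop: run the initial 28-experiment screen, fit the five kinetic
#' relations to all accumulated uncensored data, minimize the smoothed
#' objective surface with the algorithm ensemble, center a 7-experiment
#' follow-up screen at the aggregated minimum, refit, and repeat until two
#' successive recommended centers differ by less than 0.02 in supersaturation
#' and 2 degC in temperature (or the iteration budget runs out). After k
#' iterations the log holds exactly 28 + 7(k-1) experiments.
#'
#' @param lab a [virtual_lab()] or any function `(condition, seed) ->
#'   measured_kinetics`.
#' @param targets a [kinetic_targets()].
#' @param b a [bounds()].
#' @param center starting [condition()] for the initial screen (default: the
#'   bounds midpoint).
#' @param schedule a [doe_schedule()].
#' @param max_iterations iteration budget (initial screen counts as 1).
#' @param seed campaign seed; per-experiment and per-minimizer seeds derive
#'   from it.
#' @param ss_tol,temp_tol termination thresholds on the movement of successive
#'   recommendations (strict; set to 0 to disable termination and run the full
#'   iteration budget).
#' @return A `campaign` object (see [print.campaign()]): experiment `log`,
#'   per-iteration `iterations` table, and a `summary` list.
#' @export
run_doe_campaign <- function(lab, targets, b, center = NULL,
                             schedule = doe_schedule(), max_iterations = 15,
                             seed = 1L, ss_tol = 0.02, temp_tol = 2) {
  stopifnot(is.function(lab), inherits(targets, "kinetic_targets"),
            inherits(b, "bounds"))
  if (is.null(center))
    center <- condition((b$ss_min + b$ss_max) / 2, (b$t_min + b$t_max) / 2)
  max_term_env <- new.env()
  max_term_env$max_term <- 0
  log_df <- NULL
  iters <- NULL
  prev_rec <- NULL
  terminated <- FALSE
  current_center <- center

  for (k in seq_len(max_iterations)) {
    d0 <- schedule_deltas(schedule, k - 1L)
    design <- if (k == 1L)
      make_initial_design(current_center, b, d0[["ss"]], d0[["temp"]])
    else
      make_followup_design(current_center, k - 1L, schedule, b)
    new_rows <- run_design(design, lab, targets, seed_base = seed + k * 10000L,
                           iteration = k, max_term_env = max_term_env)
    log_df <- rbind(log_df, new_rows)

    model <- tryCatch(fit_kinetics(log_df), error = function(e) e)
    rep <- if (inherits(model, "error")) model else
      tryCatch(minimize_surface(function(ss, t) doe_objective(model, targets, ss, t),
                                b, seed = seed + k),
               error = function(e) e)
    if (inherits(rep, "error")) {
      # Not enough uncensored data to fit all relations, or every minimizer
      # ended on the design-space boundary: fall back to the best measured
      # condition so far as the next center and try again.
      warning("iteration ", k, ": ", conditionMessage(rep),
              "; re-centering on best observed condition", call. = FALSE)
      best <- log_df[which.min(log_df$objective), ]
      rec <- condition(best$ss, best$temp_C)
      obj_at_rec <- if (inherits(model, "error")) NA_real_ else
        doe_objective(model, targets, rec$ss, rec$temp_C)
    } else {
      rec <- rep$minimum
      obj_at_rec <- doe_objective(model, targets, rec$ss, rec$temp_C)
    }
    iters <- rbind(iters, data.frame(iteration = k, center_ss = current_center$ss,
                                     center_T = current_center$temp_C,
                                     rec_ss = rec$ss, rec_T = rec$temp_C,
                                     objective = obj_at_rec))
    if (!is.null(prev_rec) && check_termination(prev_rec, rec, ss_tol, temp_tol)) {
      terminated <- TRUE
      current_center <- rec
      break
    }
    prev_rec <- rec
    current_center <- rec
  }
  log_df$experiment <- seq_len(nrow(log_df))
  log_df$planner <- "doe"
  new_campaign(log_df, iterations = iters, planner = "doe", targets = targets,
               bounds = b, terminated = terminated,
               final_condition = current_center,
               final_objective = iters$objective[nrow(iters)])
}
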