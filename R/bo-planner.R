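# Bayesian-optimization planner: GP surrogate over the measured-kinetics
# objective, expected-improvement acquisition, and a discrete adaptive jitter
# ladder that starts exploration-focused and steps down to exploitation as the
# objective falls relative to the worst value seen.

#' Acquisition-jitter schedule
#'
#' Fixed mode pins the jitter at one ladder value for the whole campaign.
#' Adaptive mode starts at 10 (exploration-focused) and steps down the ladder
#' when the latest objective falls below 10% (to jitter 1) and then 5% (to
#' jitter 0.1) of the maximum objective observed so far in the campaign; the
#' jitter never increases.
#'
#' @param mode `"adaptive"` or a fixed jitter value from the ladder
#'   `c(10, 1, 0.1, 0.001)`.
#' @return An object of class `jitter_schedule` with fields `mode`, `jitter`,
#'   `ladder`.
#' @export
jitter_schedule <- function(mode = "adaptive") {
  ladder <- c(10, 1, 0.1, 0.001)
  if (identical(mode, "adaptive")) {
    jit <- 10
  } else {
    mode <- as.numeric(mode)
    if (!isTRUE(mode %in% ladder))
      stop("fixed jitter must be one of ", paste(ladder, collapse = ", "))
    jit <- mode
  }
  structure(list(mode = mode, jitter = jit, ladder = ladder),
            class = "jitter_schedule")
}

#' Step the adaptive jitter ladder
#'
#' Computes `fraction = latest / maximum`; a fraction strictly below 0.10
#' drops the jitter to 1 (if above), and strictly below 0.05 drops it to 0.1
#' (if above). Fixed-mode schedules pass through unchanged; the jitter is
#' non-increasing over any campaign.
#'
#' @param schedule a [jitter_schedule()].
#' @param latest latest measured objective value.
#' @param maximum maximum objective observed so far (> 0).
#' @return The updated schedule.
#' @export
update_jitter <- function(schedule, latest, maximum) {
  stopifnot(inherits(schedule, "jitter_schedule"), maximum > 0)
  if (!identical(schedule$mode, "adaptive")) return(schedule)
  fraction <- latest / maximum
  if (fraction < 0.10 && schedule$jitter > 1) schedule$jitter <- 1
  if (fraction < 0.05 && schedule$jitter > 0.1) schedule$jitter <- 0.1
  schedule
}

#' Run a Bayesian-optimization campaign
#'
#' Measures three replicate experiments at the starting condition, then loops:
#' fit the GP surrogate to all (condition, objective) pairs, recommend the
#' expected-improvement maximizer under the current jitter, run it, score it
#' with the measured-kinetics objective, step the adaptive jitter ladder, and
#' stop once two successive recommendations differ by less than 0.02 in
#' supersaturation and 2 degC in temperature (or the experiment budget is
#' spent, in which case the log is returned with `terminated = FALSE`).
#'
#' @param lab a [virtual_lab()] or any function `(condition, seed) ->
#'   measured_kinetics`.
#' @param targets a [kinetic_targets()].
#' @param b a [bounds()].
#' @param mode `"adaptive"` or a fixed jitter in `c(0.001, 0.1, 1, 10)`.
#' @param max_experiments total experiment budget including the three
#'   initialization runs.
#' @param seed campaign seed (initial replicates use three distinct derived
#'   seeds so they differ under noise).
#' @param init_center starting [condition()] (default: the bounds midpoint).
#' @param warm_start optional experiment table (e.g. an initial DoE screen) to
#'   seed the surrogate with, in addition to the three center points.
#' @param weight_growth apply the growth weight inside the objective (off by
#'   default: the log form already balances the terms).
#' @param ss_tol,temp_tol termination thresholds on the movement of successive
#'   recommendations (strict; set to 0 to disable termination).
#' @return A `campaign` object.
#' @export
run_bo_campaign <- function(lab, targets, b, mode = "adaptive",
                            max_experiments = 50, seed = 1L,
                            init_center = NULL, warm_start = NULL,
                            weight_growth = FALSE, ss_tol = 0.02,
                            temp_tol = 2) {
  stopifnot(is.function(lab), inherits(targets, "kinetic_targets"),
            inherits(b, "bounds"))
  if (is.null(init_center))
    init_center <- condition((b$ss_min + b$ss_max) / 2, (b$t_min + b$t_max) / 2)
  hold <- lab_hold_s(lab)
  max_term <- 0
  obj_of <- function(m) {
    obj <- bo_objective(m, targets, weight_growth = weight_growth,
                        hold_s = hold, max_term_so_far = max_term)
    if (!m$censored_all) {
      terms <- c(abs(log(targets$t_ind_s) - log(max(m$t_ind_s, 1e-12))),
                 abs(log(targets$r_nuc_per_s) - log(max(m$nuc_rate_per_s, 1e-12))),
                 abs(log(targets$r_growth_um_s) - log(max(m$growth_um_s, 1e-12))))
      max_term <<- max(max_term, terms)
    }
    obj
  }
  row_of <- function(m, cond, iteration, jitter) {
    data.frame(iteration = iteration, ss = cond$ss, temp_C = cond$temp_C,
               t_ind_s = m$t_ind_s, censored = as.integer(m$censored_all),
               nuc_rate_per_s = m$nuc_rate_per_s, growth_um_s = m$growth_um_s,
               objective = obj_of(m), jitter = jitter,
               material_g = lab_material(lab, cond))
  }

  sched <- jitter_schedule(mode)
  log_df <- NULL
  if (!is.null(warm_start)) {
    ws <- warm_start
    ws$iteration <- 0L
    ws$jitter <- sched$jitter
    if (is.null(ws$material_g)) ws$material_g <- NA_real_
    keep <- c("iteration", "ss", "temp_C", "t_ind_s", "censored",
              "nuc_rate_per_s", "growth_um_s", "objective", "jitter",
              "material_g")
    if (is.null(ws$objective))
      ws$objective <- vapply(seq_len(nrow(ws)), function(i)
        obj_of(as_measured_kinetics(ws[i, ])), 0)
    log_df <- ws[, keep]
  }
  for (i in 1:3) {
    m <- lab(init_center, seed + i)
    log_df <- rbind(log_df, row_of(m, init_center, 0L, sched$jitter))
  }

  prev_rec <- NULL
  terminated <- FALSE
  last_rec <- init_center
  t <- 0L
  while (nrow(log_df) < max_experiments) {
    t <- t + 1L
    state <- fit_surrogate(log_df$ss, log_df$temp_C, log_df$objective, b)
    rec <- recommend_next(state, sched$jitter)
    m <- lab(rec, seed + 1000L + t)
    log_df <- rbind(log_df, row_of(m, rec, t, sched$jitter))
    latest <- log_df$objective[nrow(log_df)]
    sched <- update_jitter(sched, latest, max(log_df$objective))
    last_rec <- rec
    if (!is.null(prev_rec) && check_termination(prev_rec, rec, ss_tol, temp_tol)) {
      terminated <- TRUE
      break
    }
    prev_rec <- rec
  }
  log_df$experiment <- seq_len(nrow(log_df))
  log_df$planner <- if (identical(sched$mode, "adaptive")) "bo_adaptive"
                    else paste0("bo_", sched$mode)
  new_campaign(log_df, iterations = NULL, planner = log_df$planner[1],
               targets = targets, bounds = b, terminated = terminated,
               final_condition = last_rec,
               final_objective = min(log_df$objective))
}

#' Export surrogate heat-map panels
#'
#' Writes the posterior mean, posterior standard deviation and acquisition
#' surfaces of a fitted surrogate over the bounds grid, as a three-panel PNG
#' and a long-format CSV — the standard diagnostic view of where the model
#' believes the optimum is and where it is still uncertain.
#'
#' @param state a `gp_surrogate`.
#' @param jitter acquisition jitter used for the acquisition panel.
#' @param file_png,file_csv output paths (`NULL` skips that format).
#' @param grid_n grid resolution per axis.
#' @return Invisibly, the long-format data frame.
#' @export
export_surrogate_maps <- function(state, jitter = 0.1, file_png = NULL,
                                  file_csv = NULL, grid_n = 101) {
  b <- state$bounds
  ss <- seq(b$ss_min, b$ss_max, length.out = grid_n)
  tt <- seq(b$t_min, b$t_max, length.out = grid_n)
  g <- expand.grid(ss = ss, temp_C = tt)
  post <- gp_posterior(state, g$ss, g$temp_C)
  postz <- gp_posterior(state, g$ss, g$temp_C, standardized = TRUE)
  acq <- expected_improvement(postz$mean, postz$sd, min(state$z), jitter)
  df <- data.frame(g, posterior_mean = post$mean, posterior_sd = post$sd,
                   acquisition = acq)
  if (!is.null(file_csv)) utils::write.csv(df, file_csv, row.names = FALSE)
  if (!is.null(file_png)) {
    grDevices::png(file_png, width = 1500, height = 500, res = 110)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    for (panel in c("posterior_mean", "posterior_sd", "acquisition")) {
      graphics::image(ss, tt, matrix(df[[panel]], grid_n, grid_n),
                      col = grDevices::hcl.colors(64, "viridis"),
                      xlab = "supersaturation", ylab = "temperature (degC)",
                      main = gsub("_", " ", panel))
    }
  }
  invisible(df)
}
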