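# Campaign logs, comparison arithmetic between planners, and table/config I/O.

round_half_up <- function(x) floor(x + 0.5)

new_campaign <- function(log, iterations, planner, targets, bounds, terminated,
                         final_condition, final_objective) {
  first <- c("experiment", "planner", "iteration", "ss", "temp_C")
  log <- log[, c(first, setdiff(names(log), first))]
  structure(list(
    log = log,
    iterations = iterations,
    planner = planner,
    targets = targets,
    bounds = bounds,
    summary = list(
      n_experiments = nrow(log),
      total_material_g = sum(log$material_g),
      terminated = terminated,
      final_condition = final_condition,
      final_objective = final_objective,
      best_objective = min(log$objective, na.rm = TRUE))),
    class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<%s campaign> %d experiments%s\n", x$planner, s$n_experiments,
              if (s$terminated) ", terminated" else ", budget exhausted"))
  cat(sprintf("  final recommendation: SS %.3f, %.2f degC\n",
              s$final_condition$ss, s$final_condition$temp_C))
  cat(sprintf("  best measured objective: %.4f", s$best_objective))
  if (!is.na(s$total_material_g))
    cat(sprintf(" | material used: %.2f g", s$total_material_g))
  cat("\n")
  invisible(x)
}

#' @export
summary.campaign <- function(object, ...) {
  s <- object$summary
  out <- data.frame(planner = object$planner,
                    n_experiments = s$n_experiments,
                    terminated = s$terminated,
                    final_ss = s$final_condition$ss,
                    final_temp_C = s$final_condition$temp_C,
                    final_objective = s$final_objective,
                    best_objective = s$best_objective,
                    total_material_g = s$total_material_g)
  class(out) <- c("summary.campaign", "data.frame")
  out
}

#' @export
print.summary.campaign <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Convergence trace of a campaign
#'
#' Best (lowest) measured objective as a function of experiment index — the
#' standard view for comparing how fast planners drive the objective down.
#'
#' @param campaign a `campaign`.
#' @return Data frame with columns `experiment`, `objective`,
#'   `best_objective`, `planner`.
#' @export
convergence_trace <- function(campaign) {
  stopifnot(inherits(campaign, "campaign"))
  data.frame(experiment = campaign$log$experiment,
             objective = campaign$log$objective,
             best_objective = cummin(campaign$log$objective),
             planner = campaign$planner)
}

#' @export
plot.campaign <- function(x, ..., log_y = TRUE) {
  tr <- convergence_trace(x)
  graphics::plot(tr$experiment, tr$best_objective, type = "s",
                 log = if (log_y) "y" else "",
                 xlab = "experiment", ylab = "best objective so far",
                 main = paste(x$planner, "campaign convergence"), ...)
  graphics::points(tr$experiment, tr$objective, pch = 16, cex = 0.5,
                   col = "grey50")
  invisible(x)
}

#' Experiment count of an exhaustive grid search
#'
#' How many experiments a grid search over the design space would take at the
#' resolution of the termination criteria: the product of the two span/step
#' ratios, rounded half-up. No +1 per axis is added — the count is the number
#' of resolvable cells, which is the convention that reproduces 1125 for the
#' 2-3 / 5-50 degC space and 1069 for 1.05-2 / 5-50 degC.
#'
#' @param b a [bounds()].
#' @param ss_step,t_step grid resolution (defaults: the termination
#'   increments, 0.02 supersaturation and 2 degC).
#' @return Integer experiment count.
#' @export
grid_search_count <- function(b, ss_step = 0.02, t_step = 2) {
  stopifnot(inherits(b, "bounds"), ss_step > 0, t_step > 0)
  as.integer(round_half_up(((b$ss_max - b$ss_min) / ss_step) *
                           ((b$t_max - b$t_min) / t_step)))
}

#' Percentage reduction in experiment count
#'
#' @param reference experiment count of the baseline method (> 0).
#' @param method experiment count of the method being credited.
#' @return Integer percent, rounded half-up.
#' @export
percent_reduction <- function(reference, method) {
  if (!is.finite(reference) || reference <= 0)
    stop("reference count must be positive")
  as.integer(round_half_up(100 * (reference - method) / reference))
}

#' Compare campaigns run against the same targets
#'
#' Tabulates, per campaign, the experiment count, termination status, best and
#' final objectives, material usage, percentage reduction in experiments
#' relative to the first (reference) campaign, and the grid-search-equivalent
#' count for the shared bounds. Also bundles the convergence traces; for DoE
#' campaigns the initial screen appears as a flat segment back-extrapolated to
#' experiment 1.
#'
#' @param ... two or more `campaign` objects (or one list of them).
#' @return An object of class `campaign_comparison` with elements `table`,
#'   `traces`, `grid_search_count`.
#' @export
compare_campaigns <- function(...) {
  logs <- list(...)
  if (length(logs) == 1L && is.list(logs[[1]]) && !inherits(logs[[1]], "campaign"))
    logs <- logs[[1]]
  stopifnot(length(logs) >= 2, all(vapply(logs, inherits, TRUE, "campaign")))
  ref_t <- logs[[1]]$targets
  same <- vapply(logs, function(l) isTRUE(all.equal(l$targets, ref_t)), TRUE)
  if (!all(same))
    stop("campaigns were run against different targets and cannot be compared")
  ref_n <- logs[[1]]$summary$n_experiments
  tab <- do.call(rbind, lapply(logs, function(l) {
    s <- summary(l)
    s$pct_fewer_experiments_vs_reference <-
      percent_reduction(ref_n, s$n_experiments)
    s
  }))
  structure(list(table = as.data.frame(tab),
                 traces = do.call(rbind, lapply(logs, convergence_trace)),
                 grid_search_count = grid_search_count(logs[[1]]$bounds)),
            class = "campaign_comparison")
}

#' @export
print.campaign_comparison <- function(x, ...) {
  cat("Campaign comparison (reference = first row)\n")
  print.data.frame(x$table, row.names = FALSE)
  cat(sprintf("equivalent grid search over these bounds: %d experiments\n",
              x$grid_search_count))
  invisible(x)
}

#' Write / read a campaign log as CSV
#'
#' The on-disk experiment-table dialect: one row per experiment with columns
#' `experiment, planner, iteration, ss, temp_C, t_ind_s, censored,
#' nuc_rate_per_s, growth_um_s, objective, material_g` plus `jitter` (BO) or
#' nothing extra (DoE); DoE per-iteration centers go to a side table
#' `<path>_iterations.csv` when present.
#'
#' @param campaign a `campaign`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_campaign <- function(campaign, path) {
  stopifnot(inherits(campaign, "campaign"))
  utils::write.csv(campaign$log, path, row.names = FALSE)
  if (!is.null(campaign$iterations))
    utils::write.csv(campaign$iterations,
                     sub("\\.csv$", "_iterations.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read an experiment table
#'
#' @param path CSV path in the experiment-table dialect (at minimum `ss,
#'   temp_C, t_ind_s, censored, nuc_rate_per_s, growth_um_s`).
#' @return A data frame.
#' @export
read_experiment_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ss", "temp_C", "t_ind_s", "censored", "nuc_rate_per_s",
            "growth_um_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("experiment table ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read a campaign configuration
#'
#' YAML or JSON with blocks `targets` (t_ind_s, r_nuc_per_s, r_growth_um_s,
#' optional growth_weight), `bounds` (ss_min, ss_max, t_min, t_max), optional
#' `center` (ss, temp_C) and optional `truth` (relation coefficients for the
#' virtual lab: a list of entries with parameter, variable, A, a, b, plus
#' simulator settings).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `targets`, `bounds`, and optionally `center`,
#'   `truth`.
#' @export
read_campaign_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$targets) || is.null(cfg$bounds))
    stop("campaign config needs 'targets' and 'bounds' blocks")
  out <- list(
    targets = kinetic_targets(
      t_ind_s = cfg$targets$t_ind_s,
      r_nuc_per_s = cfg$targets$r_nuc_per_s,
      r_growth_um_s = cfg$targets$r_growth_um_s,
      growth_weight = if (is.null(cfg$targets$growth_weight)) 10
                      else cfg$targets$growth_weight),
    bounds = bounds(cfg$bounds$ss_min, cfg$bounds$ss_max,
                    cfg$bounds$t_min, cfg$bounds$t_max))
  if (!is.null(cfg$center))
    out$center <- condition(cfg$center$ss, cfg$center$temp_C)
  if (!is.null(cfg$truth)) {
    rels <- lapply(cfg$truth$relations, function(r)
      kinetic_relation(r$parameter, r$variable,
                       coeff_A = if (is.null(r$A)) 1 else r$A,
                       coeff_a = r$a,
                       coeff_b = if (is.null(r$b)) 0 else r$b))
    sim <- cfg$truth
    sim$relations <- NULL
    out$truth <- do.call(ground_truth, c(list(model = kinetic_model(rels)), sim))
  }
  out
}
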