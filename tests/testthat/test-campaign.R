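test_that("grid-search counts reproduce the termination-resolution arithmetic", {
  expect_equal(grid_search_count(bounds(2, 3, 5, 50)), 1125L)
  expect_equal(grid_search_count(bounds(1.05, 2, 5, 50)), 1069L)
  expect_equal(grid_search_count(bounds(1.98, 2, 5, 7)), 1L)
  # monotone non-decreasing in each span
  expect_gte(grid_search_count(bounds(2, 3.1, 5, 50)),
             grid_search_count(bounds(2, 3, 5, 50)))
  expect_gte(grid_search_count(bounds(2, 3, 5, 60)),
             grid_search_count(bounds(2, 3, 5, 50)))
})

test_that("percentage reductions round half-up", {
  expect_equal(percent_reduction(70, 32), 54L)
  expect_equal(percent_reduction(70, 15), 79L)
  expect_equal(percent_reduction(70, 70), 0L)
  expect_equal(percent_reduction(200, 199), 1L) # 0.5 rounds up
  expect_error(percent_reduction(0, 5), "positive")
})

test_that("campaign comparison tabulates counts, reductions and totals", {
  tg <- lamivudine_targets()
  b <- lamivudine_bounds()
  lab <- virtual_lab(noisy_truth())
  doe <- run_doe_campaign(lab, tg, b, center = condition(2.4, 20),
                          max_iterations = 2, seed = 21, ss_tol = 0)
  bo <- run_bo_campaign(lab, tg, b, mode = "adaptive", max_experiments = 16,
                        seed = 21)
  cmp <- compare_campaigns(doe, bo)
  expect_equal(cmp$table$n_experiments, c(35L, 16L))
  expect_equal(cmp$table$pct_fewer_experiments_vs_reference,
               c(0L, percent_reduction(35, 16)))
  expect_equal(cmp$grid_search_count, 1125L)
  # totals equal column aggregates
  expect_equal(cmp$table$total_material_g[1], sum(doe$log$material_g))
  expect_equal(cmp$table$best_objective[2], min(bo$log$objective))
  # identical logs give zero reduction
  cmp2 <- compare_campaigns(doe, doe)
  expect_equal(cmp2$table$pct_fewer_experiments_vs_reference, c(0L, 0L))
  # mismatched targets refuse to compare
  bo2 <- bo
  bo2$targets <- aspirin_targets()
  expect_error(compare_campaigns(doe, bo2), "different targets")
})

test_that("campaign logs round-trip through CSV", {
  tg <- lamivudine_targets()
  b <- lamivudine_bounds()
  lab <- virtual_lab(noisy_truth())
  camp <- run_bo_campaign(lab, tg, b, mode = 0.1, max_experiments = 8, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_campaign(camp, path)
  back <- read_experiment_table(path)
  expect_equal(nrow(back), nrow(camp$log))
  expect_equal(back$ss, camp$log$ss)
  expect_equal(back$objective, camp$log$objective)
  expect_error(read_experiment_table({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(ss = 1), p, row.names = FALSE)
    p
  }), "lacks columns")
})

test_that("experiment indices are contiguous and summaries match the log", {
  tg <- lamivudine_targets()
  b <- lamivudine_bounds()
  lab <- virtual_lab(noisy_truth())
  camp <- run_doe_campaign(lab, tg, b, center = condition(2.4, 20),
                           max_iterations = 2, seed = 8, ss_tol = 0)
  expect_equal(camp$log$experiment, seq_len(nrow(camp$log)))
  expect_equal(camp$summary$n_experiments, nrow(camp$log))
  expect_equal(camp$summary$total_material_g, sum(camp$log$material_g))
  expect_equal(camp$summary$best_objective, min(camp$log$objective))
})

test_that("campaign configs parse from YAML and JSON", {
  cfg <- list(targets = list(t_ind_s = 3600, r_nuc_per_s = 0.1,
                             r_growth_um_s = 0.01),
              bounds = list(ss_min = 2, ss_max = 3, t_min = 5, t_max = 50),
              center = list(ss = 2.4, temp_C = 20))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  got <- read_campaign_config(yml)
  expect_equal(got$targets$t_ind_s, 3600)
  expect_equal(got$targets$growth_weight, 10)
  expect_equal(got$bounds$ss_max, 3)
  expect_equal(got$center$ss, 2.4)

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  got2 <- read_campaign_config(jsn)
  expect_equal(got2$bounds$t_max, 50)
  expect_error(read_campaign_config({
    p <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(bounds = cfg$bounds), p)
    p
  }), "targets")
})

test_that("surrogate heat-map export writes the three panels", {
  b <- lamivudine_bounds()
  st <- fit_surrogate(c(2.2, 2.5, 2.8), c(15, 30, 45), c(2, 0.5, 1.5), b)
  csv <- tempfile(fileext = ".csv")
  png <- tempfile(fileext = ".png")
  df <- export_surrogate_maps(st, jitter = 0.1, file_png = png, file_csv = csv,
                              grid_n = 21)
  expect_true(file.exists(csv))
  expect_true(file.exists(png))
  expect_equal(nrow(df), 21 * 21)
  expect_true(all(c("posterior_mean", "posterior_sd", "acquisition") %in%
                  names(df)))
  expect_true(all(df$acquisition >= 0))
})
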