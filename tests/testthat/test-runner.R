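small_cfg <- function(...) {
  run_config(n_agents = 40, equilibration_steps = 5, forcing_steps = 10,
             ensemble_size = 2, base_seed = 1, ...)
}

test_that("a trajectory spans equilibration plus forcing steps", {
  tr <- run_simulation(small_cfg(), seed = 3)
  expect_s3_class(tr, "coevo_trajectory")
  expect_equal(nrow(tr$metrics), 15)
  expect_equal(tr$baseline_step, 5)
  expect_true(all(tr$metrics$prevalence >= 0 & tr$metrics$prevalence <= 1))
})

test_that("identical config and seed reproduce bit-identical metrics", {
  t1 <- run_simulation(small_cfg(), seed = 11)
  t2 <- run_simulation(small_cfg(), seed = 11)
  expect_identical(t1$metrics, t2$metrics)
})

test_that("without forcing and without switching noise the prevalence is frozen", {
  cfg <- run_config(n_agents = 40, equilibration_steps = 12,
                    forcing_steps = 0, C = 1e-12, ensemble_size = 1)
  for (v in c("network", "coupled")) {
    cfg$variant <- v
    tr <- run_simulation(cfg, seed = 5)
    expect_equal(length(unique(tr$metrics$prevalence)), 1)
  }
})

test_that("variants sharing a seed consume identical structure and forcing paths", {
  cfgs <- lapply(c("coupled", "network", "interaction", "mean_field"),
                 function(v) small_cfg(variant = v))
  trs <- lapply(cfgs, run_simulation, seed = 9, keep_state = TRUE)
  ref <- trs[[1]]
  for (tr in trs[-1]) {
    expect_identical(tr$state$background, ref$state$background)
    expect_identical(tr$state$disposition_path, ref$state$disposition_path)
    expect_identical(tr$state$degree_preference, ref$state$degree_preference)
  }
})

test_that("contact degrees respect the degree preference at the end of a run", {
  tr <- run_simulation(small_cfg(), seed = 21, keep_state = TRUE)
  expect_true(all(rowSums(tr$state$contact) <= tr$state$degree_preference))
  # interaction variant never rewires: final contact equals the initial one
  tri <- run_simulation(small_cfg(variant = "interaction"), seed = 21,
                        keep_state = TRUE)
  cfg0 <- small_cfg()
  b <- tri$state$background
  p0 <- proximity_matrix(b, integer(40), cfg0$alpha)
  q <- tri$state$degree_preference
  expect_identical(tri$state$contact, initial_contact_network(p0, q))
})

test_that("ensemble means average the member trajectories and bands are nested", {
  cfg <- small_cfg()
  ens <- run_ensemble(cfg, n_runs = 3, base_seed = 31, ci = TRUE,
                      ci_reps = 200)
  t1 <- run_simulation(cfg, seed = 31)
  t2 <- run_simulation(cfg, seed = 32)
  t3 <- run_simulation(cfg, seed = 33)
  manual <- (t1$metrics$prevalence + t2$metrics$prevalence +
             t3$metrics$prevalence) / 3
  s <- ens$summary[ens$summary$metric == "prevalence", ]
  expect_equal(s$mean, manual)
  expect_true(all(s$lower_99 <= s$lower_95 + 1e-12))
  expect_true(all(s$upper_99 >= s$upper_95 - 1e-12))
  expect_true(all(s$lower_95 <= s$mean + 1e-12 & s$mean <= s$upper_95 + 1e-12))
})

test_that("variant comparison aligns series across variants and is idempotent", {
  cfg <- small_cfg()
  cmp <- compare_variants(cfg, c("coupled", "network"), n_runs = 2,
                          base_seed = 41)
  expect_equal(nrow(cmp$report), 2)
  expect_named(cmp$ensembles, c("coupled", "network"))
  expect_equal(dim(cmp$cp_change), c(2L, 5L))
  same <- compare_variants(cfg, c("coupled", "coupled"), n_runs = 2,
                           base_seed = 41)
  expect_equal(same$report$final_prevalence[1],
               same$report$final_prevalence[2])
  expect_equal(same$cp_change[1, ], same$cp_change[2, ])
})

test_that("metric series round-trip through the tidy CSV writer", {
  ens <- run_ensemble(small_cfg(), n_runs = 2, base_seed = 51, ci = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(ens, path)
  back <- read.csv(path)
  expect_named(back, c("run", "step", "metric", "value"))
  got <- back$value[back$metric == "prevalence" & back$run == 1]
  expect_equal(got, unname(ens$metrics[1, , "prevalence"]))
})
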