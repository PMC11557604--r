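test_that("configuration validation catches bad settings", {
  expect_error(experiment_config(cf_threshold = 101), "cf_threshold")
  expect_error(experiment_config(n_per_sample = 10, prevalence_A = 15),
               "whole")
  expect_error(experiment_config(estimators = "bayes"), "estimators")
  expect_error(experiment_config(predict_range = c(80, 70)), "predict_range")
  expect_s3_class(experiment_config(), "experiment_config")
})

test_that("zero missingness yields the benchmarks exactly", {
  cfg <- experiment_config(n_per_sample = 100, scenarios = 0, missing_sd = 0,
                           iterations = 1, seed = 3, glm_draws = 500)
  row <- run_iteration(cfg, 0, seed = 99)
  expect_identical(row$cf_A, 10)
  expect_identical(row$cf_B, 30)
  expect_equal(row$raw_A, 10)
  expect_equal(row$raw_B, 30)
  # constant completeness is aliased out of the GLM, not fatal
  expect_false(row$glm_failed)
  expect_equal(row$glm_A, 10, tolerance = 1)
  expect_equal(row$glm_B, 30, tolerance = 2)
})

test_that("iterations replay bit-for-bit from their child seed", {
  cfg <- tiny_config()
  inputs <- traumasim:::load_inputs(cfg)
  r1 <- run_iteration(cfg, 40, seed = 123, inputs)
  r2 <- run_iteration(cfg, 40, seed = 123, inputs)
  expect_identical(r1, r2)
  r3 <- run_iteration(cfg, 40, seed = 124, inputs)
  expect_false(identical(r1$cf_A, r3$cf_A) && identical(r1$glm_A, r3$glm_A))
})

test_that("full experiments are reproducible from the master seed", {
  cfg <- tiny_config()
  e1 <- run_experiment(cfg)
  e2 <- run_experiment(cfg)
  expect_identical(e1$results, e2$results)
  expect_identical(e1$summary, e2$summary)
})

test_that("pattern correctness requires defined estimates and strict order", {
  expect_true(correct_pattern(9.7, 29.1))
  expect_false(correct_pattern(0, 0))          # tie
  expect_false(correct_pattern(NA, 12))        # undefined
  expect_false(correct_pattern(30, 10))        # reversed
  expect_equal(correct_pattern(c(1, NA, 5), c(2, 3, 5)),
               c(TRUE, FALSE, FALSE))
})

fake_results <- function(cf_A, cf_B, scenario = 80) {
  data.frame(scenario = scenario, iteration = seq_along(cf_A),
             cf_A = cf_A, cf_B = cf_B,
             glm_A = NA_real_, glm_B = NA_real_,
             glm_fallback = NA_integer_, glm_failed = FALSE,
             raw_A = 5, raw_B = 15)
}

test_that("summaries use the documented denominators", {
  cfg <- experiment_config(estimators = "cf")
  res <- fake_results(cf_A = c(0, 0, 100, NA), cf_B = c(10, 0, 50, 20))
  s <- summarize_experiment(res, cfg)
  a <- s$estimates[s$estimates$sample == "A", ]
  expect_equal(a$median, 0)                    # median of {0, 0, 100}
  expect_equal(a$pct_produced, 75)
  expect_equal(a$pct_zero, 100 * 2 / 3)        # zeros among defined estimates
  expect_equal(a$pct_zero_all, 50)             # zeros over all iterations
  # pattern: iteration 1 correct, 2 tie, 3 reversed, 4 undefined
  expect_equal(s$pattern$pct_correct, 25)

  ident <- summarize_experiment(fake_results(rep(7, 4), rep(21, 4)), cfg)
  ai <- ident$estimates[ident$estimates$sample == "A", ]
  expect_equal(ai$lo, ai$hi)                   # degenerate spread collapses
  expect_equal(ai$median, 7)
})

test_that("raw-data checks flag zeros, reversals and tied benchmarks", {
  cfg <- experiment_config(estimators = "cf")
  good <- verify_raw_pattern(fake_results(c(1, 2), c(3, 4)), cfg)
  expect_true(good$ok)
  bad <- fake_results(c(1, 2), c(3, 4))
  bad$raw_A[1] <- 0
  bad$raw_B[2] <- 4; bad$raw_A[2] <- 4
  chk <- verify_raw_pattern(bad, cfg)
  expect_false(chk$ok)
  expect_equal(chk$n_zero, 1)
  expect_equal(chk$n_order_violations, 1)

  cfg_tie <- experiment_config(prevalence_A = 10, prevalence_B = 10,
                               estimators = "cf")
  tie <- verify_raw_pattern(fake_results(c(1, 2), c(3, 4)), cfg_tie)
  expect_false(tie$ordering_checked)
})

test_that("exports mirror the summary layout and conserve rows", {
  cfg <- tiny_config()
  ex <- run_experiment(cfg)
  dir <- tempfile()
  paths <- export_tables(ex, dir)
  expect_true(all(file.exists(paths)))
  a <- read.csv(paths[1])
  expect_setequal(names(a), c("scenario", "estimator", "sample", "median",
                              "lo", "hi"))
  expect_equal(nrow(a), 1 * 2 * 2)             # scenario x estimator x sample

  long <- export_plot_data(ex)
  n_def <- sum(!is.na(ex$results$cf_A)) + sum(!is.na(ex$results$cf_B)) +
    sum(!is.na(ex$results$glm_A)) + sum(!is.na(ex$results$glm_B))
  expect_equal(nrow(long), n_def)
  expect_setequal(unique(long$estimator), c("cf", "glm"))
})
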