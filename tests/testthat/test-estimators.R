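test_that("crude frequency applies the completeness threshold", {
  d <- data.frame(completeness = rep(100, 10), trauma = c(rep(1, 3), rep(0, 7)))
  expect_equal(cf_estimate(d)$point, 30)

  low <- data.frame(completeness = rep(50, 8), trauma = rep(1, 8))
  est <- cf_estimate(low)
  expect_false(est$defined)
  expect_true(is.na(est$point))
  expect_equal(est$n_used, 0)

  mix <- data.frame(completeness = c(rep(80, 6), rep(60, 4)),
                    trauma = c(1, 0, 0, 0, 0, 0, 1, 1, 0, 0))
  expect_equal(cf_estimate(mix)$point, 100 / 6, tolerance = 1e-12)
  expect_equal(cf_estimate(mix)$n_used, 6)

  # invariant to record order
  perm <- mix[sample(nrow(mix)), ]
  expect_equal(cf_estimate(perm)$point, cf_estimate(mix)$point)
  expect_error(cf_estimate(mix, threshold = 101), "threshold")
})

test_that("log-link GLM recovers prevalences on complete data", {
  d <- data.frame(
    sample = rep(c("A", "B"), each = 100),
    completeness = 100,
    trauma = c(rep(1, 10), rep(0, 90), rep(1, 30), rep(0, 70)))
  fit <- glm_fit(d)
  expect_s3_class(fit, "trauma_glm")
  expect_equal(unname(exp(fit$coef[1] + fit$coef[3] * 100)), 0.10,
               tolerance = 0.01)
  expect_equal(unname(exp(sum(fit$coef * c(1, 1, 100)))), 0.30,
               tolerance = 0.01)
  set.seed(1)
  pr <- glm_predict(fit, n_draws = 4000)
  expect_lt(pr$A$point, pr$B$point)
  expect_true(pr$A$interval[1] <= pr$A$point && pr$A$point <= pr$A$interval[2])
})

test_that("GLM fit recovers known coefficients from model-simulated data", {
  beta <- c(log(0.05), log(3), 0.005)
  set.seed(2024)
  d <- simulate_from_glm(beta, 500)
  fit <- glm_fit(d)
  expect_equal(fit$link, "log")
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coef - beta) < 2 * se))
})

test_that("GLM fit matches an independent glmmTMB fit", {
  skip_if_not_installed("glmmTMB")
  set.seed(33)
  d <- simulate_from_glm(c(log(0.08), log(2.5), 0.004), 400)
  fit <- glm_fit(d)
  tmb <- glmmTMB::glmmTMB(trauma ~ sample + completeness, data = d,
                          family = stats::binomial(link = "log"),
                          start = list(beta = c(log(mean(d$trauma)), 0, 0)))
  expect_equal(unname(fit$coef), unname(glmmTMB::fixef(tmb)$cond),
               tolerance = 1e-3)
})

test_that("degenerate responses are rejected as model failures", {
  d <- data.frame(sample = rep(c("A", "B"), each = 5), completeness = 50,
                  trauma = 0)
  expect_error(glm_fit(d), "degenerate")
  expect_error(glm_fit(data.frame(sample = "A", completeness = 50, trauma = 1)),
               "two sample")
})

fake_fit <- function(coef, vcov = diag(c(1e-4, 1e-4, 1e-8)), link = "log") {
  structure(list(coef = coef, vcov = vcov, link = link, fallback = 0L,
                 converged = TRUE, levels = c("A", "B")),
            class = "trauma_glm")
}

test_that("prediction averages draws over the completeness grid", {
  # no sample effect: estimates agree up to Monte-Carlo error of the draws
  f0 <- fake_fit(c(log(0.2), 0, 0))
  set.seed(9)
  pr <- glm_predict(f0, n_draws = 8000)
  expect_equal(pr$A$point, pr$B$point, tolerance = 0.15)
  expect_equal(pr$A$point, 20, tolerance = 0.5)

  # flat completeness effect (slope pinned at 0): prediction range irrelevant
  f_flat <- fake_fit(c(log(0.2), 0, 0), vcov = diag(c(1e-4, 1e-4, 0)))
  set.seed(10)
  lo <- glm_predict(f_flat, n_draws = 4000, predict_range = c(50, 75))
  set.seed(10)
  hi <- glm_predict(f_flat, n_draws = 4000, predict_range = c(75, 100))
  expect_equal(lo$A$point, hi$A$point, tolerance = 1e-9)

  # rising completeness effect: lower range predicts lower prevalence
  f2 <- fake_fit(c(log(0.02), log(3), 0.02))
  set.seed(11)
  lo2 <- glm_predict(f2, n_draws = 4000, predict_range = c(50, 75))
  set.seed(11)
  hi2 <- glm_predict(f2, n_draws = 4000, predict_range = c(75, 100))
  expect_lt(lo2$A$point, hi2$A$point)
  expect_lt(lo2$B$point, hi2$B$point)

  # reproducible under a fixed seed
  set.seed(12); a <- glm_predict(f2, n_draws = 2000)
  set.seed(12); b <- glm_predict(f2, n_draws = 2000)
  expect_identical(a, b)
})

test_that("clipping bounds log-link predictions at 100%", {
  f_hot <- fake_fit(c(log(0.9), log(2), 0.01))
  set.seed(13)
  pr <- glm_predict(f_hot, n_draws = 2000, clip = TRUE)
  expect_lte(pr$B$point, 100)
  set.seed(13)
  un <- glm_predict(f_hot, n_draws = 2000, clip = FALSE)
  expect_gt(un$B$point, 100)
})

test_that("estimate_prevalence combines both approaches on a specimen table", {
  set.seed(14)
  d <- simulate_from_glm(c(log(0.08), log(3), 0.004), 300)
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  out <- estimate_prevalence(f, n_draws = 2000)
  expect_named(out, c("cf", "glm", "fit"))
  expect_named(out$cf, c("A", "B"))
  expect_lt(out$glm$A$point, out$glm$B$point)
  expect_length(out$glm$A$interval, 2)
})
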