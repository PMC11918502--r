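test_that("class mean curves are cumulative sums of the change means", {
  cfg <- generator_config()
  # Mild Deterioration: endpoint = initial level + summed changes
  md <- class_mean_curve(3, cfg)
  expect_equal(md[1], 5.99, ignore_attr = TRUE)
  expect_equal(sum(cfg$trajectory$deltas[3, ]), 2.77)
  expect_equal(md[9], 5.99 + 2.77, ignore_attr = TRUE)
  # Shock-to-Resilience second wave
  expect_equal(class_mean_curve(4, cfg)[2], 17.33 - 13.50,
               ignore_attr = TRUE)
  # all-zero deltas give a flat curve
  flat <- generator_config(
    n = 10, class_proportions = c(1),
    trajectory = list(eta1 = c(7), deltas = matrix(0, 1, 8)),
    covariate_model = list(x = list(type = "bernoulli", p = 0.5)),
    membership_coefs = matrix(0, 1, 0, dimnames = list("x", NULL)),
    membership_intercepts = numeric(0),
    distal_probs = rbind(treatment_seeking = 0.1, diagnosis_T9 = 0.1))
  expect_equal(class_mean_curve(1, flat), rep(7, 9), ignore_attr = TRUE)
  expect_error(class_mean_curve(6, cfg), "1..5")
})

test_that("intercept calibration matches target marginals", {
  # symmetric case: zero effects, uniform target -> zero intercepts
  cm <- list(x = list(type = "bernoulli", p = 0.5))
  coefs <- matrix(0, 1, 2, dimnames = list("x", NULL))
  expect_equal(calibrate_intercepts(coefs, cm, rep(1 / 3, 3)),
               c(0, 0), ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(calibrate_intercepts(coefs, cm, c(0.5, 0.5, 0)),
               "positive")
  # default effects and target: marginals verified on an independent draw
  cfg <- generator_config()
  a <- calibrate_intercepts(cfg$membership_coefs, cfg$covariate_model,
                            cfg$class_proportions)
  Z <- lcsmm:::with_seed(202, lcsmm:::draw_covariates(2e5, cfg$covariate_model))
  Z <- Z[, rownames(cfg$membership_coefs)]
  eta <- cbind(sweep(Z %*% cfg$membership_coefs, 2, a, `+`), 0)
  achieved <- colMeans(lcsmm:::softmax_rows(eta))
  expect_lt(max(abs(achieved - cfg$class_proportions)), 0.005)
})

test_that("generated cohorts are deterministic given a seed", {
  a <- generate_cohort(generator_config(n = 200, seed = 31))
  b <- generate_cohort(generator_config(n = 200, seed = 31))
  expect_identical(a$data$y, b$data$y)
  expect_identical(a$truth, b$truth)
  expect_identical(a$data$outcomes, b$data$outcomes)
  c <- generate_cohort(generator_config(n = 200, seed = 32))
  expect_false(identical(a$data$y, c$data$y))
})

test_that("noise-free generation reproduces the class mean curves", {
  cfg <- generator_config(n = 2000, seed = 8, residual_sd = 1e-9,
                          retention_schedule = rep(1, 9))
  sim <- generate_cohort(cfg)
  # every Mild Deterioration subject hits round(8.76) = 9 at the last wave
  md_rows <- sim$truth$true_class == 3
  expect_true(any(md_rows))
  expect_true(all(sim$data$y[md_rows, 9] == 9))
  # continuous scale: per-class wave means equal the curves exactly
  cfg2 <- generator_config(n = 500, seed = 8, residual_sd = 1e-12,
                           retention_schedule = rep(1, 9),
                           integer_scores = FALSE)
  sim2 <- generate_cohort(cfg2)
  for (k in c(1, 3, 5)) {
    rows <- sim2$truth$true_class == k
    expect_equal(colMeans(sim2$data$y[rows, , drop = FALSE]),
                 class_mean_curve(k, cfg2), ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("retention schedule produces the expected wave coverage", {
  sim <- generate_cohort(generator_config(seed = 13))
  wr <- wave_retention(sim$data)
  expect_equal(wr$n_observed[1], 4361L)
  # binomial(4361, 2158/4361): allow 4 standard deviations
  sd2 <- sqrt(4361 * (2158 / 4361) * (1 - 2158 / 4361))
  expect_lt(abs(wr$n_observed[2] - 2158), 4 * sd2)
  expect_lt(abs(wr$n_observed[9] - 1269),
            4 * sqrt(4361 * (1269 / 4361) * (1 - 1269 / 4361)))
  # the default schedule is intermittent: T9 exceeds T8 in expectation
  cfg <- generator_config()
  expect_gt(cfg$retention_schedule[9], cfg$retention_schedule[8])
})

test_that("apply_missingness respects the schedule and the intake wave", {
  y <- matrix(1, 500, 3)
  mask <- matrix(TRUE, 500, 3)
  expect_identical(apply_missingness(y, mask, c(1, 1, 1), seed = 2), mask)
  m2 <- apply_missingness(y, mask, c(1, 0.5, 0.2), seed = 2)
  expect_true(all(m2[, 1]))
  expect_lt(abs(mean(m2[, 2]) - 0.5), 0.1)
  expect_error(apply_missingness(y, mask, c(0.9, 1, 1)), "must be 1")
  # MAR hook shifts observation probability with the score
  y2 <- matrix(rnorm(1500), 500, 3)
  m3 <- apply_missingness(y2, mask, c(1, 0.5, 0.5), seed = 3, mar_slope = 2)
  hi <- y2[, 2] > stats::median(y2[, 2])
  expect_gt(mean(m3[hi, 2]), mean(m3[!hi, 2]))
})

test_that("class frequencies and covariate effects match the generating model", {
  n <- 2e5
  sim <- generate_cohort(generator_config(n = n, seed = 77))
  freq <- tabulate(sim$truth$true_class, 5) / n
  expect_lt(max(abs(freq - generator_config()$class_proportions)), 0.01)
  # living-alone odds ratio, Strong Deterioration vs Consistent Resilience:
  # contingency-table estimate against the configured coefficient
  la <- sim$data$covariates$living_alone
  cls <- sim$truth$true_class
  tab <- table(la[cls %in% c(1, 5)], factor(cls[cls %in% c(1, 5)]))
  or_emp <- (tab["1", "1"] / tab["1", "5"]) / (tab["0", "1"] / tab["0", "5"])
  expect_equal(log(or_emp), log(2.98), tolerance = 0.08)
})

test_that("distal outcomes follow class-specific probabilities and T9 observation", {
  sim <- generate_cohort(generator_config(n = 3e4, seed = 21,
                                          outcomes_at_t9_only = FALSE))
  ts <- sim$data$outcomes$treatment_seeking
  means <- tapply(ts, sim$truth$true_class, mean)
  expect_lt(max(abs(unname(means) - c(0.45, 0.22, 0.30, 0.08, 0.06))),
            0.02)
  # ordering SD > MD > CH > SR, CR
  expect_true(means[1] > means[3] && means[3] > means[2] &&
                means[2] > max(means[4], means[5]))
  sim2 <- generate_cohort(generator_config(n = 500, seed = 21))
  expect_equal(is.na(sim2$data$outcomes$diagnosis_T9),
               !sim2$data$observed[, 9], ignore_attr = TRUE)
})
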