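test_that("mixture log-likelihood matches hand computation and reductions", {
  # two subjects, two classes, hand-set parameters, one missing cell
  y <- rbind(c(1, 2), c(3, NA))
  d <- panel_dataset(y)
  p <- mixture_params(pi = c(0.3, 0.7), eta1 = c(1, 4),
                      deltas = rbind(1, -1), theta = c(1, 4))
  by_hand <- function() {
    f <- function(x, m, v) stats::dnorm(x, m, sqrt(v))
    l1 <- 0.3 * f(1, 1, 1) * f(2, 2, 1) + 0.7 * f(1, 4, 4) * f(2, 3, 4)
    l2 <- 0.3 * f(3, 1, 1) + 0.7 * f(3, 4, 4)
    log(l1) + log(l2)
  }
  expect_equal(mixture_loglik(p, d), by_hand(), tolerance = 1e-12)

  # K = 1 equals the sum of independent normal log-densities and the
  # diagonal-covariance FIML likelihood
  d2 <- tiny_panel()
  p1 <- mixture_params(1, eta1 = 5, deltas = matrix(c(1, 2), 1),
                       theta = c(2, 3, 4))
  direct <- sum(stats::dnorm(d2$y,
                             matrix(p1$mu, 4, 3, byrow = TRUE),
                             matrix(sqrt(c(2, 3, 4)), 4, 3, byrow = TRUE),
                             log = TRUE))
  expect_equal(mixture_loglik(p1, d2), direct, tolerance = 1e-12)
  expect_equal(mixture_loglik(p1, d2),
               fiml_loglik(as.vector(p1$mu), diag(c(2, 3, 4)), d2),
               tolerance = 1e-10)
})

test_that("likelihood, ICs and entropy are invariant to class relabeling", {
  sim <- small_cohort(n = 150)
  p <- mixture_params(pi = c(0.2, 0.3, 0.5),
                      eta1 = c(4, 10, 16),
                      deltas = rbind(c(1, rep(0, 7)), c(-1, rep(0, 7)),
                                     c(0.5, rep(0, 7))),
                      theta = c(4, 9, 16))
  perm <- c(3, 1, 2)
  pp <- permute_classes(p, perm)
  expect_equal(mixture_loglik(p, sim$data), mixture_loglik(pp, sim$data),
               tolerance = 1e-10)
  post <- posterior_probs(p, sim$data)
  expect_equal(relative_entropy(post),
               relative_entropy(posterior_probs(pp, sim$data)),
               tolerance = 1e-10)
  ll <- mixture_loglik(p, sim$data)
  expect_identical(information_criteria(ll, 10, 150),
                   information_criteria(ll, 10, 150))
})

test_that("posterior probabilities follow Bayes rule and normalize", {
  # single subject, hand-applied Bayes rule
  d <- panel_dataset(matrix(c(2, 3), 1))
  p <- mixture_params(pi = c(0.4, 0.6), eta1 = c(2, 5),
                      deltas = rbind(0, 0), theta = c(1, 1))
  f <- function(m) prod(stats::dnorm(c(2, 3), m, 1))
  w <- c(0.4 * f(2), 0.6 * f(5))
  expect_equal(as.vector(posterior_probs(p, d)), w / sum(w),
               tolerance = 1e-12)
  # identical classes -> uniform rows; rows always sum to 1
  pid <- mixture_params(pi = c(0.5, 0.5), eta1 = c(3, 3),
                        deltas = rbind(0, 0), theta = c(2, 2))
  expect_equal(as.vector(posterior_probs(pid, d)), c(0.5, 0.5))
  sim <- small_cohort(n = 120)
  post <- posterior_probs(mixture_params(
    pi = c(0.3, 0.7), eta1 = c(4, 12),
    deltas = rbind(rep(0.1, 8), rep(-0.1, 8)),
    theta = c(9, 9)), sim$data)
  expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
})

test_that("relative entropy is 1 at one-hot and 0 at uniform posteriors", {
  onehot <- diag(4)[c(1, 2, 3, 4, 1), ]
  expect_equal(relative_entropy(onehot), 1)
  expect_equal(relative_entropy(matrix(0.25, 6, 4)), 0)
  expect_error(relative_entropy(matrix(1, 5, 1)), "K >= 2")
})

test_that("information criteria use the standard penalties", {
  ic <- information_criteria(-100, 10, 100)
  expect_equal(ic$aic, 220)
  expect_equal(ic$bic, 200 + 10 * log(100))
  expect_equal(ic$abic, 200 + 10 * log(102 / 24))
})

test_that("K = 1 EM equals the closed-form MLE", {
  sim <- small_cohort(n = 300)
  fit <- em_fit(sim$data, 1)
  Y <- sim$data$y
  mu <- colMeans(Y, na.rm = TRUE)
  v <- mean((sweep(Y, 2, mu)^2)[sim$data$observed])
  expect_equal(as.vector(fit$params$mu), unname(mu), tolerance = 1e-8)
  expect_equal(fit$params$theta[1, 1], v, tolerance = 1e-8)
  expect_equal(fit$params$pi, 1)
  # loglik consistent with its own parameters
  expect_equal(fit$loglik, mixture_loglik(fit$params, sim$data),
               tolerance = 1e-10)
})

test_that("EM increases the log-likelihood monotonically and recovers a
           well-separated two-class structure", {
  cfg <- two_class_config()
  sim <- generate_cohort(cfg)
  # debug = TRUE asserts monotone LL at every iteration of every start
  fit <- em_fit(sim$data, 2, em_control(n_starts = 8, refine_top = 3,
                                        seed = 3, debug = TRUE))
  expect_true(fit$converged)
  perm <- align_labels(fit$params, config_curves(cfg))
  fit <- permute_classes(fit, perm)
  expect_equal(fit$params$pi, c(0.4, 0.6), tolerance = 0.06,
               ignore_attr = TRUE)
  expect_lt(max(abs(fit$params$mu - config_curves(cfg))), 0.5)
  expect_equal(fit$loglik, mixture_loglik(fit$params, sim$data),
               tolerance = 1e-10)
  # classification is near-perfect here, entropy close to 1
  expect_gt(fit$entropy, 0.95)
})

test_that("label alignment recovers identity, swaps, and noisy matches", {
  cfg <- two_class_config()
  curves <- config_curves(cfg)
  p <- mixture_params(pi = c(0.4, 0.6), eta1 = curves[, 1],
                      deltas = t(apply(curves, 1, diff)),
                      theta = c(2, 2))
  expect_equal(align_labels(p, curves), c(1, 2))
  expect_equal(align_labels(p, curves[c(2, 1), ]), c(2, 1))
  # noisy five-class curves: generating assignment recovered every time
  cfg5 <- generator_config()
  curves5 <- config_curves(cfg5)
  set.seed(19)
  for (i in 1:25) {
    noisy <- curves5 + matrix(rnorm(45, sd = 0.4), 5, 9)
    shuffle <- sample(5)
    est <- mixture_params(pi = rep(0.2, 5), eta1 = noisy[shuffle, 1],
                          deltas = t(apply(noisy[shuffle, ], 1, diff)),
                          theta = rep(4, 5))
    perm <- align_labels(est, curves5)
    expect_equal(noisy[shuffle, ][perm, ], noisy, ignore_attr = TRUE)
  }
  expect_error(align_labels(matrix(0, 2, 3), matrix(0, 3, 3)), "mismatch")
})

test_that("observed-information standard errors shrink with n and cover truth", {
  cfg <- two_class_config(n = 900, seed = 23)
  sim <- generate_cohort(cfg)
  fit <- em_fit(sim$data, 2, em_control(n_starts = 5, refine_top = 2,
                                        seed = 2))
  fit <- permute_classes(fit, align_labels(fit$params, config_curves(cfg)))
  se <- mixture_se(fit, sim$data)
  # rough scale: SE of a mean from ~360 obs with sd 1.5 is ~0.08
  expect_true(all(se$se_eta1 > 0.02 & se$se_eta1 < 0.3))
  expect_true(all(abs(fit$params$eta1 - c(4, 18)) < 3 * se$se_eta1 + 0.05))
  expect_true(all(se$se_pi > 0 & se$se_pi < 0.1))
})
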