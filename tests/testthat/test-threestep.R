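test_that("modal assignment takes row maxima with low-index tie breaking", {
  onehot <- diag(3)[c(2, 3, 1), ]
  expect_equal(modal_assignment(onehot)$assignments, c(2, 3, 1))
  tie <- modal_assignment(rbind(c(0.5, 0.5), c(0.2, 0.8)))
  expect_equal(tie$assignments, c(1, 2))
  expect_equal(tie$n_ties, 1)
  set.seed(8)
  post <- matrix(runif(300), 100, 3)
  post <- post / rowSums(post)
  expect_equal(modal_assignment(post)$assignments,
               apply(post, 1, which.max))
})

test_that("classification-error matrix matches its definition", {
  # one-hot posterior -> identity
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  ct <- classification_errors(onehot, modal_assignment(onehot)$assignments)
  expect_equal(unname(ct$Q), diag(3))
  # four-subject toy with uniform rows: hand computation
  post <- matrix(0.5, 4, 2)
  a <- c(1, 1, 2, 2)
  ct2 <- classification_errors(post, a)
  expect_equal(unname(ct2$Q), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  # rows of Q sum to 1 on any input
  set.seed(4)
  post3 <- matrix(runif(500), 100, 5)
  post3 <- post3 / rowSums(post3)
  ct3 <- classification_errors(post3, modal_assignment(post3)$assignments)
  expect_lt(max(abs(rowSums(ct3$Q) - 1)), 1e-12)
})

test_that("step-3 multinomial with identity Q equals a standard multinomial fit", {
  skip_if_not_installed("nnet")
  set.seed(9)
  n <- 700
  z <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  eta <- cbind(0.6 * z$x1 + 0.9 * z$x2 + 0.2, -0.4 * z$x1 - 0.3)
  P <- exp(cbind(eta, 0)); P <- P / rowSums(P)
  cum <- P %*% upper.tri(diag(3), diag = TRUE)
  a <- max.col(runif(n) <= cum, ties.method = "first")
  fit <- step3_multinomial(a, diag(3), z, reference = 3)
  m0 <- nnet::multinom(factor(a, levels = c(3, 1, 2)) ~ x1 + x2, data = z,
                       trace = FALSE, reltol = 1e-14)
  expect_lt(max(abs(as.vector(fit$coefficients) -
                      as.vector(t(stats::coef(m0))))), 1e-4)
  # ORs exponentiate the coefficients with ordered Wald bounds
  expect_equal(fit$table$or, exp(fit$table$coef))
  expect_true(all(fit$table$ci_lower < fit$table$ci_upper))
})

test_that("step-3 multinomial corrects classification-error attenuation", {
  # true class generated from one binary covariate; posterior then blurred
  # with known error rates: the naive fit is attenuated, the corrected fit
  # recovers the generating coefficient
  set.seed(15)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  beta <- 1.2
  p1 <- stats::plogis(-0.4 + beta * x)
  cls <- 1L + rbinom(n, 1, 1 - p1)          # class 1 w.p. p1, else 2
  eps <- 0.18                               # symmetric assignment error
  flip <- runif(n) < eps
  a <- ifelse(flip, 3L - cls, cls)
  Q <- rbind(c(1 - eps, eps), c(eps, 1 - eps))
  naive <- step3_multinomial(a, diag(2), data.frame(x = x), reference = 2)
  corrected <- step3_multinomial(a, Q, data.frame(x = x), reference = 2)
  b_naive <- naive$coefficients["x", 1]
  b_corr <- corrected$coefficients["x", 1]
  expect_lt(b_naive, beta - 0.2)            # visibly attenuated
  expect_equal(b_corr, beta, tolerance = 0.2)
})

test_that("a null covariate effect is covered by the 95% interval", {
  cover <- 0
  for (rep in 1:20) {
    set.seed(100 + rep)
    n <- 800
    z <- data.frame(x = rnorm(n), null_cov = rnorm(n))
    eta <- cbind(0.8 * z$x, 0)               # null_cov has zero effect
    P <- exp(eta - apply(eta, 1, max)); P <- P / rowSums(P)
    a <- 1L + rbinom(n, 1, P[, 2])
    fit <- step3_multinomial(a, diag(2), z, reference = 2)
    row <- fit$table[fit$table$predictor == "null_cov", ]
    cover <- cover + (row$ci_lower <= 1 && 1 <= row$ci_upper)
  }
  expect_gte(cover, 17)                      # ~95% nominal coverage
})

test_that("step-3 distal model reduces, bounds, and corrects", {
  set.seed(12)
  n <- 900
  a <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  y <- rbinom(n, 1, c(0.7, 0.3, 0.1)[a])
  # identity Q: class-specific outcome means
  r <- step3_distal(a, diag(3), y)
  expect_equal(r$rho, as.vector(tapply(y, a, mean)), tolerance = 1e-6)
  expect_equal(r$pi, as.vector(table(a) / n), tolerance = 1e-6)
  # constant outcome: all probabilities collapse to the constant
  r0 <- step3_distal(a, diag(3), rep(0, n))
  expect_equal(r0$rho, rep(0, 3), tolerance = 1e-6)
  expect_true(r0$degenerate)
  # missing outcomes are excluded with a count
  y2 <- y; y2[1:50] <- NA
  r2 <- step3_distal(a, diag(3), y2)
  expect_equal(r2$n_dropped, 50)
  expect_equal(r2$n_used, n - 50)
  # known blur: corrected estimates de-attenuate toward the truth
  eps <- 0.2
  flip <- runif(n) < eps
  cls2 <- sample(1:2, n, replace = TRUE)
  y3 <- rbinom(n, 1, c(0.8, 0.1)[cls2])
  a3 <- ifelse(flip, 3L - cls2, cls2)
  Q <- rbind(c(1 - eps, eps), c(eps, 1 - eps))
  naive <- step3_distal(a3, diag(2), y3)
  corr <- step3_distal(a3, Q, y3)
  expect_gt(corr$rho[1] - corr$rho[2], naive$rho[1] - naive$rho[2])
  expect_equal(corr$rho, c(0.8, 0.1), tolerance = 0.08)
})

test_that("step-3 results are invariant to subject ordering", {
  set.seed(33)
  n <- 400
  z <- data.frame(x = rnorm(n))
  a <- sample(1:2, n, replace = TRUE)
  y <- rbinom(n, 1, c(0.6, 0.2)[a])
  Q <- rbind(c(0.9, 0.1), c(0.15, 0.85))
  ord <- sample(n)
  f1 <- step3_multinomial(a, Q, z, reference = 2)
  f2 <- step3_multinomial(a[ord], Q, z[ord, , drop = FALSE], reference = 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  d1 <- step3_distal(a, Q, y)
  d2 <- step3_distal(a[ord], Q, y[ord])
  expect_equal(d1$rho, d2$rho, tolerance = 1e-8)
})

test_that("univariable mode stacks one model per predictor", {
  set.seed(2)
  n <- 300
  z <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  a <- sample(1:2, n, replace = TRUE)
  fit <- step3_multinomial(a, diag(2), z, reference = 2,
                           mode = "univariable")
  # intercept rows appear once per predictor model
  expect_equal(sum(fit$table$predictor == "(intercept)"), 2)
  expect_true(all(c("x1", "x2") %in% fit$table$predictor))
})
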