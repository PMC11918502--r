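# Bias-adjusted 3-step analyses relating latent classes to external
# variables. Step 1 fits the unconditional mixture; step 2 assigns classes
# and quantifies the assignment's error rates; step 3 regresses class
# membership on covariates (Vermunt's ML variant) or models class-specific
# distal-outcome probabilities (Bolck-Croon-Hagenaars as extended by
# Vermunt), in both cases weighting by the classification-error matrix so
# that the external model is not biased by imperfect class separation and
# the classes themselves are never redefined by the external variables.

#' Modal class assignment
#'
#' Assigns each subject to the class with the highest posterior
#' probability. Ties are broken toward the lower class index; tie events
#' are counted and returned.
#'
#' @param posterior n x K posterior probability matrix.
#' @return List with `assignments` (integer vector) and `n_ties`.
#' @export
modal_assignment <- function(posterior) {
  posterior <- as.matrix(posterior)
  a <- max.col(posterior, ties.method = "first")
  rowmax <- posterior[cbind(seq_len(nrow(posterior)), a)]
  n_ties <- sum(rowSums(abs(posterior - rowmax) < 1e-12) > 1L)
  list(assignments = a, n_ties = n_ties)
}

#' Proportional (pseudo-draw) class assignment
#'
#' Assigns each subject to a class drawn from their posterior distribution.
#' Alternative to [modal_assignment()] for the 3-step procedures.
#'
#' @param posterior n x K posterior probability matrix.
#' @param seed integer seed.
#' @return List with `assignments`.
#' @export
proportional_assignment <- function(posterior, seed = NULL) {
  posterior <- as.matrix(posterior)
  with_seed(seed, {
    u <- stats::runif(nrow(posterior))
    cum <- posterior %*% upper.tri(diag(ncol(posterior)), diag = TRUE)
    list(assignments = max.col(u <= cum, ties.method = "first"))
  })
}

#' Classification-error matrix
#'
#' Quantifies how well the assignment recovers the latent classes:
#' `Q[k, s] = P(assigned = s | true = k)` estimated as
#' `sum_i p_ik 1[assign_i = s] / sum_i p_ik`, where `p_ik` are the step-1
#' posterior probabilities. Rows sum to 1; `Q` is the identity when the
#' posterior is one-hot (perfect separation).
#'
#' @param posterior n x K posterior probability matrix from step 1.
#' @param assignments integer class assignments derived from that posterior.
#' @return Object of class `classification_table`: `assignments`, `Q`,
#'   `counts` (assigned-class sizes), `n`.
#' @export
classification_errors <- function(posterior, assignments) {
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  n <- nrow(posterior)
  if (length(assignments) != n) stopf("assignments length != posterior rows")
  mass <- colSums(posterior)
  if (any(mass <= 0)) stopf("a class has zero total posterior mass")
  A <- matrix(0, n, K)
  A[cbind(seq_len(n), assignments)] <- 1
  Q <- crossprod(posterior, A) / mass
  dimnames(Q) <- list(true = seq_len(K), assigned = seq_len(K))
  structure(list(assignments = assignments, Q = Q,
                 counts = as.integer(tabulate(assignments, K)), n = n),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("classification_table: %d subjects, %d classes\n",
              x$n, ncol(x$Q)))
  cat("  assigned-class counts:", paste(x$counts, collapse = ", "), "\n")
  cat("  Q (rows: true class; cols: assigned class):\n")
  print(round(x$Q, 4))
  invisible(x)
}

#' Step-3 multinomial regression of class membership on covariates
#'
#' Vermunt's ML 3-step estimator: with `a_i` the step-2 assignment and `Q`
#' the classification-error matrix, maximizes
#' `sum_i log sum_k P(X = k | z_i; gamma) Q[k, a_i]`
#' over multinomial-logit coefficients `gamma` (reference class fixed at
#' zero). When `Q` is the identity this reduces to ordinary multinomial
#' logistic regression on the assigned classes. Standard errors come from
#' the numerically evaluated observed information; odds ratios are
#' `exp(gamma)` with 95\% Wald intervals. Step-1 sampling uncertainty is not
#' propagated (the usual limitation of the approach).
#'
#' @param assignments integer step-2 assignments (1..K).
#' @param Q K x K classification-error matrix (rows: true class).
#' @param covariates data.frame or matrix of predictors (complete cases
#'   only; rows with missing values are dropped with a count).
#' @param reference reference class index (no coefficients).
#' @param mode `"joint"` (all predictors in one model, default) or
#'   `"univariable"` (one model per predictor; rows are stacked).
#' @return Object of class `three_step_result` with a `table` data.frame
#'   (`predictor`, `class`, `coef`, `se`, `or`, `ci_lower`, `ci_upper`,
#'   `p_value`), the coefficient matrix, and diagnostics (`n_used`,
#'   `n_dropped`, `separation` flag).
#' @export
step3_multinomial <- function(assignments, Q, covariates, reference = NULL,
                              mode = c("joint", "univariable")) {
  mode <- match.arg(mode)
  Z <- as.matrix(as.data.frame(covariates))
  K <- ncol(Q)
  if (is.null(reference)) reference <- K
  keep <- stats::complete.cases(Z)
  n_dropped <- sum(!keep)
  Z <- Z[keep, , drop = FALSE]
  a <- assignments[keep]
  if (mode == "univariable") {
    tabs <- lapply(colnames(Z), function(nm)
      step3_multinomial(a, Q, Z[, nm, drop = FALSE], reference,
                        mode = "joint")$table)
    res <- step3_multinomial(a, Q, Z, reference, mode = "joint")
    res$table <- do.call(rbind, tabs)
    res$mode <- "univariable"
    return(res)
  }
  n <- nrow(Z); p <- ncol(Z)
  X <- cbind(`(intercept)` = 1, Z)
  nonref <- setdiff(seq_len(K), reference)
  # gamma: (p+1) x (K-1) with columns ordered as nonref
  Qa <- t(Q)[a, , drop = FALSE]            # n x K: Qa[i, k] = Q[k, a_i]
  negll_grad <- function(gvec) {
    G <- matrix(gvec, p + 1L, K - 1L)
    eta <- matrix(0, n, K)
    eta[, nonref] <- X %*% G
    P <- softmax_rows(eta)
    Li <- rowSums(P * Qa)
    W <- (P * Qa) / Li
    grad <- -crossprod(X, (W - P)[, nonref, drop = FALSE])
    list(value = -sum(log(Li)), grad = as.vector(grad))
  }
  fn <- function(g) negll_grad(g)$value
  gr <- function(g) negll_grad(g)$grad
  g0 <- rep(0, (p + 1L) * (K - 1L))
  opt <- stats::optim(g0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  # Hessian by central differences of the analytic gradient, then Newton
  # polish to drive the score to numerical zero (BFGS alone stalls around
  # 1e-5); the final Hessian doubles as the observed information
  hess_of <- function(g) {
    q <- length(g)
    H <- matrix(0, q, q)
    h <- pmax(abs(g), 1) * 1e-6
    for (j in seq_len(q)) {
      gp <- g; gp[j] <- gp[j] + h[j]
      gm <- g; gm[j] <- gm[j] - h[j]
      H[, j] <- (gr(gp) - gr(gm)) / (2 * h[j])
    }
    (H + t(H)) / 2
  }
  par <- opt$par
  H <- hess_of(par)
  for (it in 1:20) {
    g <- gr(par)
    if (max(abs(g)) < 1e-9) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    if (fn(cand) > fn(par) + 1e-12) break    # safeguard: keep BFGS point
    par <- cand
    H <- hess_of(par)
  }
  G <- matrix(par, p + 1L, K - 1L,
              dimnames = list(colnames(X), nonref))
  separation <- any(abs(G) > 15)
  V <- tryCatch(solve(H), error = function(e) {
    warning("singular observed information in step-3 multinomial model",
            call. = FALSE)
    matrix(NA_real_, length(par), length(par))
  })
  se <- matrix(sqrt(pmax(diag(V), 0)), p + 1L, K - 1L,
               dimnames = dimnames(G))
  rows <- expand.grid(predictor = colnames(X), class = nonref,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  coef <- mapply(function(pr, cl) G[pr, as.character(cl)],
                 rows$predictor, as.integer(rows$class))
  sev <- mapply(function(pr, cl) se[pr, as.character(cl)],
                rows$predictor, as.integer(rows$class))
  tab <- data.frame(rows, coef = coef, se = sev,
                    or = exp(coef),
                    ci_lower = exp(coef - 1.96 * sev),
                    ci_upper = exp(coef + 1.96 * sev),
                    p_value = 2 * stats::pnorm(-abs(coef / sev)),
                    row.names = NULL)
  structure(list(table = tab, coefficients = G, se = se,
                 reference = reference, loglik = -fn(par),
                 n_used = n, n_dropped = n_dropped,
                 separation = separation, mode = mode,
                 converged = opt$convergence == 0),
            class = "three_step_result")
}

#' Step-3 distal-outcome model
#'
#' BCH/Vermunt bias-adjusted estimation of class-specific probabilities of
#' a binary distal outcome: maximizes
#' `sum_i log sum_k pi_k Bernoulli(y_i; rho_k) Q[k, a_i]`
#' over class proportions `pi` and outcome probabilities `rho` by EM.
#' When `Q` is the identity, `rho_k` reduces to the outcome mean among
#' subjects assigned to class k. Wald CIs on the logit scale from the
#' numerically evaluated observed information.
#'
#' @param assignments integer step-2 assignments (1..K).
#' @param Q K x K classification-error matrix.
#' @param outcome binary 0/1 vector; missing values are excluded with a
#'   reported count.
#' @return Object of class `three_step_result` with a `table` data.frame
#'   (`class`, `prob`, `ci_lower`, `ci_upper`), `pi`, `rho`, `n_used`,
#'   `n_dropped`, and a `degenerate` flag when the outcome is constant.
#' @export
step3_distal <- function(assignments, Q, outcome) {
  K <- ncol(Q)
  keep <- !is.na(outcome)
  y <- outcome[keep]
  a <- assignments[keep]
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  n <- length(y)
  if (n == 0L) stopf("no observed outcomes")
  Qa <- t(Q)[a, , drop = FALSE]
  degenerate <- length(unique(y)) == 1L
  pi <- rep(1 / K, K)
  rho <- rep(mean(y), K) + (seq_len(K) - (K + 1) / 2) * 0.01
  rho <- pmin(pmax(rho, 1e-6), 1 - 1e-6)
  ll_old <- -Inf
  for (it in seq_len(2000L)) {
    like <- matrix(rho, n, K, byrow = TRUE)^y *
      matrix(1 - rho, n, K, byrow = TRUE)^(1 - y)
    num <- sweep(like * Qa, 2L, pi, `*`)
    Li <- rowSums(num)
    ll <- sum(log(Li))
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-12 * abs(ll_old)) break
    ll_old <- ll
    U <- num / Li
    mass <- colSums(U)
    pi <- mass / n
    rho <- pmin(pmax(colSums(U * y) / pmax(mass, 1e-12), 1e-8), 1 - 1e-8)
  }
  # observed-information CIs on (logit rho, logit pi vs class K)
  pack <- function(rho, pi) c(stats::qlogis(rho), log(pi[-K] / pi[K]))
  nll <- function(v) {
    r <- stats::plogis(v[seq_len(K)])
    al <- c(v[K + seq_len(K - 1L)], 0)
    pp <- exp(al) / sum(exp(al))
    like <- matrix(r, n, K, byrow = TRUE)^y *
      matrix(1 - r, n, K, byrow = TRUE)^(1 - y)
    -sum(log(rowSums(sweep(like * Qa, 2L, pp, `*`))))
  }
  ci <- matrix(NA_real_, K, 2L)
  if (!degenerate) {
    H <- num_hessian(nll, pack(rho, pi))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      se_logit <- sqrt(pmax(diag(V)[seq_len(K)], 0))
      lg <- stats::qlogis(rho)
      ci <- cbind(stats::plogis(lg - 1.96 * se_logit),
                  stats::plogis(lg + 1.96 * se_logit))
    }
  }
  tab <- data.frame(class = seq_len(K), prob = rho,
                    ci_lower = ci[, 1L], ci_upper = ci[, 2L])
  structure(list(table = tab, pi = pi, rho = rho, loglik = ll,
                 n_used = n, n_dropped = sum(!keep),
                 degenerate = degenerate),
            class = "three_step_result")
}

#' @export
print.three_step_result <- function(x, ...) {
  if (!is.null(x$rho)) {
    cat(sprintf("three_step_result (distal outcome): %d subjects used, %d dropped\n",
                x$n_used, x$n_dropped))
    tab <- x$table
    tab[c("prob", "ci_lower", "ci_upper")] <-
      lapply(tab[c("prob", "ci_lower", "ci_upper")], round, 4)
    print(tab, row.names = FALSE)
    if (isTRUE(x$degenerate))
      cat("  note: outcome constant; estimates degenerate\n")
  } else {
    cat(sprintf("three_step_result (class membership, %s): reference class %d, %d subjects used, %d dropped\n",
                x$mode, x$reference, x$n_used, x$n_dropped))
    tab <- x$table
    tab[c("coef", "se", "or", "ci_lower", "ci_upper")] <-
      round(tab[c("coef", "se", "or", "ci_lower", "ci_upper")], 3)
    tab$p_value <- signif(tab$p_value, 3)
    print(tab, row.names = FALSE)
    if (isTRUE(x$separation))
      cat("  warning: possible separation (very large coefficients)\n")
  }
  invisible(x)
}
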