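# Latent change score mixture model (LCSMM): finite mixture over
# class-specific trajectory means with within-class latent variance fixed
# at zero, so that all systematic between-person variability in level and
# change is carried by the discrete classes. Estimation is multi-start EM
# under the full-information missing-data likelihood: each subject
# contributes the Gaussian density of exactly their observed waves.

#' Mixture parameters
#'
#' Parameters of a K-class trajectory mixture: mixing proportions, per-class
#' initial-level means (`eta1`), per-class latent change-score means
#' (`deltas`, K x (T-1)), and residual variances `theta` (K x T, possibly
#' tied across classes and/or waves according to `theta_structure`).
#' The implied class mean curve is `mu[c, t] = eta1[c] + sum(deltas[c, 1:(t-1)])`.
#'
#' @param pi length-K simplex of mixing proportions.
#' @param eta1 length-K initial-level means.
#' @param deltas K x (T-1) matrix of change-score means.
#' @param theta residual variances: scalar, length-K vector, or K x T matrix.
#' @param theta_structure one of `"class"` (class-specific, time-constant;
#'   the default), `"class_wave"`, `"global"`.
#' @return An object of class `mixture_params` with an extra element `mu`
#'   (K x T implied mean curves).
#' @export
mixture_params <- function(pi, eta1, deltas, theta,
                           theta_structure = c("class", "class_wave", "global")) {
  theta_structure <- match.arg(theta_structure)
  K <- length(pi)
  deltas <- matrix(deltas, nrow = K)
  tt <- ncol(deltas) + 1L
  if (abs(sum(pi) - 1) > 1e-10) stopf("pi must sum to 1 (tolerance 1e-10)")
  if (any(pi < 0)) stopf("pi entries must be non-negative")
  if (length(eta1) != K) stopf("eta1 length != K")
  th <- if (is.matrix(theta)) theta else
    matrix(theta, nrow = K, ncol = tt,
           byrow = length(theta) == tt && length(theta) != K)
  if (length(theta) == 1L) th <- matrix(theta, K, tt)
  if (!all(dim(th) == c(K, tt))) stopf("theta must conform to K x T")
  if (any(th <= 0)) stopf("residual variances must be positive")
  cums <- deltas %*% upper.tri(diag(tt - 1L), diag = TRUE)  # row cumsums
  mu <- matrix(eta1, K, tt) + cbind(0, cums)
  structure(list(K = K, n_waves = tt, pi = pi, eta1 = eta1, deltas = deltas,
                 theta = th, theta_structure = theta_structure, mu = mu),
            class = "mixture_params")
}

# Number of free parameters implied by a parameter structure.
#' @noRd
mixture_n_params <- function(K, tt, theta_structure) {
  n_theta <- switch(theta_structure, class = K, class_wave = K * tt, global = 1L)
  (K - 1L) + K * tt + n_theta
}

# n x K matrix of class-conditional log-likelihoods over observed cells.
#' @noRd
class_loglik_matrix <- function(params, data) {
  Y <- data$y
  n <- nrow(Y); K <- params$K
  out <- matrix(0, n, K)
  for (c in seq_len(K)) {
    ld <- stats::dnorm(Y, mean = matrix(params$mu[c, ], n, data$n_waves,
                                        byrow = TRUE),
                       sd = matrix(sqrt(params$theta[c, ]), n, data$n_waves,
                                   byrow = TRUE), log = TRUE)
    out[, c] <- rowSums(ld, na.rm = TRUE)
  }
  out
}

#' Mixture log-likelihood
#'
#' Full-information observed-data log-likelihood of a trajectory mixture:
#' `sum_i log sum_c pi_c prod_{t observed} N(y_it; mu_ct, theta_ct)`,
#' computed with log-sum-exp stabilization. Subjects contribute only their
#' observed waves, so records with partially missing data are retained.
#'
#' @param params a [mixture_params].
#' @param data a [panel_dataset].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(params, data) {
  stopifnot(inherits(params, "mixture_params"), inherits(data, "panel_dataset"))
  if (params$n_waves != data$n_waves) stopf("wave count mismatch")
  lp <- sweep(class_loglik_matrix(params, data), 2L, log(params$pi), `+`)
  sum(row_logsumexp(lp))
}

#' Posterior class-membership probabilities
#'
#' Bayes rule per subject over that subject's observed waves:
#' `p_ic = pi_c f_c(y_i) / sum_k pi_k f_k(y_i)`.
#'
#' @inheritParams mixture_loglik
#' @return n x K matrix; rows sum to 1.
#' @export
posterior_probs <- function(params, data) {
  lp <- sweep(class_loglik_matrix(params, data), 2L, log(params$pi), `+`)
  p <- exp(lp - row_logsumexp(lp))
  p / rowSums(p)
}

#' Relative entropy of a classification
#'
#' `E = 1 - [-sum_i sum_c p_ic log p_ic] / (n log K)`, with `0 log 0 = 0`.
#' Equals 1 for perfectly separated (one-hot) posteriors and 0 for
#' completely uninformative (uniform) posteriors.
#'
#' @param posterior n x K posterior probability matrix.
#' @return Scalar in `[0, 1]`.
#' @export
relative_entropy <- function(posterior) {
  K <- ncol(posterior)
  if (is.null(K) || K < 2L) stopf("relative entropy requires K >= 2 classes")
  plogp <- posterior * log(posterior)
  plogp[posterior == 0] <- 0
  1 - (-sum(plogp)) / (nrow(posterior) * log(K))
}

#' Information criteria
#'
#' AIC, BIC, and the sample-size-adjusted BIC (aBIC), whose per-parameter
#' penalty is `log((n + 2) / 24)`.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size.
#' @return Named list `aic`, `bic`, `abic`.
#' @export
information_criteria <- function(loglik, n_params, n) {
  if (n_params < 1L || n < 2L) stopf("need n_params >= 1 and n >= 2")
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(n),
       abic = -2 * loglik + n_params * log((n + 2) / 24))
}

#' EM control settings
#'
#' @param n_starts number of random initializations.
#' @param refine_top number of best short-run starts refined to full
#'   convergence.
#' @param short_iter EM iterations per exploratory short run.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter iteration cap for refined runs.
#' @param theta_structure residual-variance tying; see [mixture_params()].
#' @param theta_floor lower bound on residual variances, preventing
#'   degenerate likelihood spikes.
#' @param seed master seed for start generation.
#' @param empty_restarts times an initialization with a collapsing class is
#'   re-drawn before the start is flagged as failed.
#' @param debug if `TRUE`, assert the EM monotonicity of the log-likelihood
#'   at every iteration.
#' @return List of class `em_control`.
#' @export
em_control <- function(n_starts = 50L, refine_top = 10L, short_iter = 40L,
                       tol = 1e-8, max_iter = 1000L,
                       theta_structure = "class", theta_floor = 1e-3,
                       seed = 1L, empty_restarts = 3L, debug = FALSE) {
  structure(list(n_starts = n_starts, refine_top = refine_top,
                 short_iter = short_iter, tol = tol, max_iter = max_iter,
                 theta_structure = theta_structure, theta_floor = theta_floor,
                 seed = as.integer(seed), empty_restarts = empty_restarts,
                 debug = debug), class = "em_control")
}

# One EM run from given params; returns params, loglik, iterations, and
# whether a class emptied out.
#' @noRd
em_run <- function(data, params, control, max_iter) {
  Y <- data$y; obs <- data$observed
  n <- nrow(Y); K <- params$K; tt <- ncol(Y)
  Y0 <- Y; Y0[!obs] <- 0
  ll_old <- -Inf
  converged <- FALSE; empty <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    lp <- sweep(class_loglik_matrix(params, data), 2L, log(params$pi), `+`)
    lse <- row_logsumexp(lp)
    ll <- sum(lse)
    if (control$debug && ll < ll_old - abs(ll_old) * 1e-10)
      stopf("EM log-likelihood decreased at iteration %d", iter)
    if (is.finite(ll_old) && abs(ll - ll_old) < control$tol * abs(ll_old)) {
      ll_old <- ll; converged <- TRUE; break
    }
    ll_old <- ll
    r <- exp(lp - lse)                       # n x K responsibilities
    mass <- colSums(r)
    if (any(mass < 1)) { empty <- TRUE; break }
    pi_new <- mass / n
    mu <- params$mu
    sq_tot <- numeric(K); w_tot <- numeric(K)
    sq_wave <- matrix(0, K, tt); w_wave <- matrix(0, K, tt)
    for (c in seq_len(K)) {
      w <- r[, c] * obs                      # n x T weights on observed cells
      wsum <- colSums(w)
      m <- colSums(r[, c] * Y0) / pmax(wsum, 1e-12)
      m[wsum < 1e-8] <- mu[c, wsum < 1e-8]   # keep old mean for empty cells
      mu[c, ] <- m
      res2 <- (Y - matrix(m, n, tt, byrow = TRUE))^2
      res2[!obs] <- 0
      sq <- colSums(r[, c] * res2)
      sq_wave[c, ] <- sq; w_wave[c, ] <- wsum
      sq_tot[c] <- sum(sq); w_tot[c] <- sum(wsum)
    }
    theta <- switch(control$theta_structure,
      class = matrix(sq_tot / pmax(w_tot, 1e-12), K, tt),
      class_wave = sq_wave / pmax(w_wave, 1e-12),
      global = matrix(sum(sq_tot) / sum(w_tot), K, tt))
    theta <- pmax(theta, control$theta_floor)
    params <- mixture_params(pi_new, mu[, 1L], row_diff(mu),
                             theta, control$theta_structure)
  }
  # on iteration-cap exit the last M-step changed params after ll was
  # computed; re-evaluate so loglik always matches params
  if (!converged && !empty) ll_old <- mixture_loglik(params, data)
  list(params = params, loglik = ll_old, iterations = iter,
       converged = converged, empty = empty)
}

# k-means++-style initialization: class mean curves seeded from observed
# subject trajectories (wave-mean imputed), spread out in trajectory space.
#' @noRd
em_init <- function(data, K, control) {
  Y <- data$y
  wave_means <- colMeans(Y, na.rm = TRUE)
  Yimp <- Y
  for (t in seq_len(ncol(Y))) Yimp[is.na(Y[, t]), t] <- wave_means[t]
  n <- nrow(Y)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  if (K > 1L) for (c in 2:K) {
    d2 <- rowSums((Yimp - Yimp[rep(centers[1L], n), , drop = FALSE])^2)
    for (j in seq_len(c - 1L))
      d2 <- pmin(d2, rowSums(sweep(Yimp, 2L, Yimp[centers[j], ])^2))
    d2[centers[seq_len(c - 1L)]] <- 0
    centers[c] <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else
      sample.int(n, 1L)
  }
  mu <- Yimp[centers, , drop = FALSE]
  v <- max(stats::var(as.vector(Y), na.rm = TRUE), control$theta_floor * 10)
  mixture_params(rep(1 / K, K), mu[, 1L],
                 row_diff(mu),
                 matrix(v, K, ncol(Y)), control$theta_structure)
}

#' Fit a trajectory mixture by multi-start EM
#'
#' Estimates the K-class LCSMM by maximum likelihood under the
#' full-information missing-data likelihood. The E-step computes posterior
#' responsibilities; the M-step has closed forms (responsibility-weighted
#' means of observed wave scores per class, differenced to recover the
#' initial level and change scores; responsibility-weighted residual mean
#' squares under the configured variance tying). Many short exploratory runs
#' are launched from trajectory-seeded random starts; the best few are
#' refined to full convergence, and replication of the best log-likelihood
#' across starts is reported, as unstable solutions should not be
#' interpreted.
#'
#' @param data a [panel_dataset].
#' @param K number of classes (`K >= 1`).
#' @param control an [em_control].
#' @return Object of class `fitted_mixture`: `params`, `posterior`,
#'   `loglik`, `n_params`, `ic` (AIC/BIC/aBIC), `entropy` (K >= 2),
#'   `converged`, `ll_replicated`, `start_logliks`, `n`, `K`.
#' @export
em_fit <- function(data, K, control = em_control()) {
  stopifnot(inherits(data, "panel_dataset"))
  n <- data$n_subjects
  if (K < 1L) stopf("K must be >= 1")
  if (n < K) stopf("need at least K subjects")
  if (K == 1L) return(fit_one_class(data, control))
  with_seed(control$seed, {
    runs <- vector("list", control$n_starts)
    for (s in seq_len(control$n_starts)) {
      run <- NULL
      for (attempt in seq_len(control$empty_restarts + 1L)) {
        init <- em_init(data, K, control)
        run <- em_run(data, init, control, control$short_iter)
        if (!run$empty) break
      }
      runs[[s]] <- run
    }
    short_ll <- vapply(runs, function(r) r$loglik, numeric(1))
    ok <- !vapply(runs, function(r) r$empty, logical(1))
    if (!any(ok)) stopf("all EM starts collapsed to an empty class")
    top <- order(ifelse(ok, short_ll, -Inf), decreasing = TRUE)
    top <- top[seq_len(min(control$refine_top, sum(ok)))]
    refined <- lapply(runs[top], function(r)
      em_run(data, r$params, control, control$max_iter))
    ref_ll <- vapply(refined, function(r) r$loglik, numeric(1))
    best <- refined[[which.max(ref_ll)]]
    replicated <- sum(ref_ll > max(ref_ll) - 1e-3) >= 2L
    if (!replicated)
      warning("best log-likelihood not replicated across starts; solution may be unstable",
              call. = FALSE)
    post <- posterior_probs(best$params, data)
    p <- mixture_n_params(K, data$n_waves, control$theta_structure)
    structure(list(params = best$params, posterior = post,
                   loglik = best$loglik, n_params = p,
                   ic = information_criteria(best$loglik, p, n),
                   entropy = relative_entropy(post),
                   converged = best$converged, ll_replicated = replicated,
                   start_logliks = short_ll, refined_logliks = ref_ll,
                   n = n, K = K, control = control),
              class = "fitted_mixture")
  })
}

# K = 1: the MLE is available in closed form (observed-cell wave means and
# residual variance under the tying structure); EM is not needed.
#' @noRd
fit_one_class <- function(data, control) {
  Y <- data$y; obs <- data$observed
  mu <- colMeans(Y, na.rm = TRUE)
  res2 <- sweep(Y, 2L, mu)^2
  theta <- switch(control$theta_structure,
    class = , global = max(mean(res2[obs]), control$theta_floor),
    class_wave = pmax(colMeans(res2, na.rm = TRUE), control$theta_floor))
  params <- mixture_params(1, mu[1L], matrix(diff(mu), 1L),
                           matrix(theta, 1L, ncol(Y), byrow = TRUE),
                           control$theta_structure)
  ll <- mixture_loglik(params, data)
  p <- mixture_n_params(1L, data$n_waves, control$theta_structure)
  structure(list(params = params,
                 posterior = matrix(1, data$n_subjects, 1L),
                 loglik = ll, n_params = p,
                 ic = information_criteria(ll, p, data$n_subjects),
                 entropy = NA_real_, converged = TRUE, ll_replicated = TRUE,
                 start_logliks = ll, refined_logliks = ll,
                 n = data$n_subjects, K = 1L, control = control),
            class = "fitted_mixture")
}

#' @export
print.fitted_mixture <- function(x, ...) {
  cat(sprintf("fitted_mixture: K = %d, n = %d, logLik = %.2f (%d parameters)\n",
              x$K, x$n, x$loglik, x$n_params))
  cat(sprintf("  AIC %.1f | BIC %.1f | aBIC %.1f",
              x$ic$aic, x$ic$bic, x$ic$abic))
  if (x$K >= 2L) cat(sprintf(" | entropy %.3f", x$entropy))
  cat("\n")
  cat(sprintf("  converged: %s | best LL replicated: %s\n",
              x$converged, x$ll_replicated))
  cat("  class proportions:", paste(sprintf("%.4f", x$params$pi),
                                    collapse = ", "), "\n")
  invisible(x)
}

# Simple recursive permutation enumeration (K <= 8 in practice).
#' @noRd
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_perms(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Align estimated classes to a reference by trajectory similarity
#'
#' The mixture likelihood is invariant to permuting class labels. This
#' resolves label switching by choosing the permutation of estimated
#' classes minimizing the total squared distance between estimated and
#' reference class mean curves (exact optimal assignment by enumeration).
#'
#' @param estimated a [mixture_params] or K x T matrix of mean curves.
#' @param reference a [mixture_params] or K x T matrix of mean curves.
#' @return Integer vector `perm` such that estimated class `perm[j]`
#'   corresponds to reference class `j`.
#' @seealso [permute_classes()]
#' @export
align_labels <- function(estimated, reference) {
  mu_e <- if (inherits(estimated, "mixture_params")) estimated$mu else
    as.matrix(estimated)
  mu_r <- if (inherits(reference, "mixture_params")) reference$mu else
    as.matrix(reference)
  if (!all(dim(mu_e) == dim(mu_r))) stopf("class/wave dimension mismatch")
  K <- nrow(mu_e)
  cost <- matrix(0, K, K)   # cost[j, k] = ||ref_j - est_k||^2
  for (j in seq_len(K)) for (k in seq_len(K))
    cost[j, k] <- sum((mu_r[j, ] - mu_e[k, ])^2)
  if (K > 8L) stopf("label alignment supports up to 8 classes")
  perms <- all_perms(K)
  tot <- vapply(perms, function(p) sum(cost[cbind(seq_len(K), p)]), numeric(1))
  unlist(perms[[which.min(tot)]])
}

#' Apply a class permutation to a fitted mixture or parameter set
#'
#' @param x a `fitted_mixture` or [mixture_params].
#' @param perm permutation as returned by [align_labels()]: element `j`
#'   names the current class that becomes class `j`.
#' @return Object of the same class with classes reordered.
#' @export
permute_classes <- function(x, perm) {
  if (inherits(x, "mixture_params")) {
    return(mixture_params(x$pi[perm], x$eta1[perm],
                          x$deltas[perm, , drop = FALSE],
                          x$theta[perm, , drop = FALSE], x$theta_structure))
  }
  stopifnot(inherits(x, "fitted_mixture"))
  x$params <- permute_classes(x$params, perm)
  x$posterior <- x$posterior[, perm, drop = FALSE]
  x
}

#' Standard errors for mixture parameters
#'
#' Observed-information standard errors at the ML solution: the Hessian of
#' the negative log-likelihood is computed by central finite differences on
#' the working scale (means untransformed, residual variances on the log
#' scale, mixing proportions as multinomial logits) and inverted; SEs for
#' proportions and variances are mapped back by the delta method. Intended
#' for final fitted models; cost grows quadratically in the parameter count.
#'
#' @param fit a `fitted_mixture`.
#' @param data the [panel_dataset] the model was fitted to.
#' @return List with `se_eta1`, `se_deltas`, `se_pi`, `se_theta`.
#' @export
mixture_se <- function(fit, data) {
  stopifnot(inherits(fit, "fitted_mixture"))
  par0 <- fit$params
  K <- par0$K; tt <- par0$n_waves
  struct <- par0$theta_structure
  theta_vec <- switch(struct, class = par0$theta[, 1L],
                      class_wave = as.vector(par0$theta),
                      global = par0$theta[1L, 1L])
  pack <- function(p) {
    c(as.vector(p$mu), log(theta_vec_of(p)),
      if (K > 1L) log(p$pi[-K] / p$pi[K]))
  }
  theta_vec_of <- function(p) switch(struct, class = p$theta[, 1L],
                                     class_wave = as.vector(p$theta),
                                     global = p$theta[1L, 1L])
  unpack <- function(v) {
    mu <- matrix(v[seq_len(K * tt)], K, tt)
    nth <- length(theta_vec)
    th <- exp(v[K * tt + seq_len(nth)])
    theta <- switch(struct, class = matrix(th, K, tt),
                    class_wave = matrix(th, K, tt), global = matrix(th, K, tt))
    pi <- if (K > 1L) {
      a <- c(v[K * tt + nth + seq_len(K - 1L)], 0)
      exp(a) / sum(exp(a))
    } else 1
    mixture_params(pi, mu[, 1L],
                   row_diff(mu), theta, struct)
  }
  nll <- function(v) -mixture_loglik(unpack(v), data)
  v0 <- pack(par0)
  H <- num_hessian(nll, v0)
  V <- tryCatch(solve(H), error = function(e)
    stopf("observed information is singular; SEs unavailable"))
  se <- sqrt(pmax(diag(V), 0))
  se_mu <- matrix(se[seq_len(K * tt)], K, tt)
  nth <- length(theta_vec)
  se_logth <- se[K * tt + seq_len(nth)]
  se_theta <- theta_vec * se_logth          # delta method on log scale
  se_pi <- if (K > 1L) {
    ia <- K * tt + nth + seq_len(K - 1L)
    Va <- V[ia, ia, drop = FALSE]
    a <- v0[ia]
    p <- exp(c(a, 0)) / sum(exp(c(a, 0)))
    J <- matrix(0, K, K - 1L)               # d pi / d alpha
    for (c in seq_len(K)) for (j in seq_len(K - 1L))
      J[c, j] <- p[c] * ((c == j) - p[j])
    sqrt(pmax(diag(J %*% Va %*% t(J)), 0))
  } else 0
  # SEs of eta1 and deltas from the mu covariance via differencing
  se_eta1 <- se_mu[, 1L]
  se_deltas <- matrix(NA_real_, K, tt - 1L)
  for (c in seq_len(K)) {
    idx <- (seq_len(tt) - 1L) * K + c       # positions of mu[c, ] in v
    Vc <- V[idx, idx, drop = FALSE]
    D <- diff(diag(tt))                     # (T-1) x T differencing matrix
    se_deltas[c, ] <- sqrt(pmax(diag(D %*% Vc %*% t(D)), 0))
  }
  list(se_eta1 = se_eta1, se_deltas = se_deltas, se_pi = se_pi,
       se_theta = se_theta)
}
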