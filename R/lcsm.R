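# Single-class latent change score model (LCSM).
#
# Each wave's true score equals the previous true score plus a latent
# change score; the observed score adds measurement error. In matrix form
# the implied moments are mu_t = mean_eta1 + sum_{s<=t} mean_delta_s and
# Sigma = L Psi L' + Theta, with L the lower-triangular cumulative-sum
# loading matrix over the latents (eta_1, delta_2, ..., delta_T), Psi their
# covariance block, and Theta the diagonal residual covariance. Estimation
# is full-information ML: subjects with partially missing waves contribute
# the density of their observed sub-vector.

#' LCSM specification
#'
#' Declares which parameters of the latent change score model are free,
#' fixed, or zero. The default mirrors a parsimonious growth specification:
#' free latent means, free initial-level variance, free change-score
#' variances, no latent covariances, constant residual variance.
#'
#' @param n_waves number of waves T.
#' @param free_mean_eta1,free_mean_deltas estimate the latent means?
#' @param var_eta1 `"free"` or a fixed non-negative value.
#' @param var_deltas `"free"`, `"zero"`, or a fixed non-negative value
#'   (applied to every change score).
#' @param cov_eta1_deltas `"free"` or `"zero"`: covariances between the
#'   initial level and each change score.
#' @param cov_deltas `"free"` or `"zero"`: covariances among change scores.
#' @param residual `"constant"`, `"per_wave"`, or a fixed positive value
#'   (applied to every wave).
#' @return Object of class `lcsm_spec`.
#' @export
lcsm_spec <- function(n_waves = 9L, free_mean_eta1 = TRUE,
                      free_mean_deltas = TRUE, var_eta1 = "free",
                      var_deltas = "free", cov_eta1_deltas = "zero",
                      cov_deltas = "zero", residual = "constant") {
  chk_opt <- function(x, allowed, nm) {
    if (is.character(x)) {
      if (!x %in% allowed) stopf("%s must be one of %s or a numeric value",
                                 nm, paste(allowed, collapse = "/"))
    } else if (!is.numeric(x) || x < 0) stopf("fixed %s must be >= 0", nm)
  }
  chk_opt(var_eta1, "free", "var_eta1")
  chk_opt(var_deltas, c("free", "zero"), "var_deltas")
  if (!cov_eta1_deltas %in% c("free", "zero")) stopf("bad cov_eta1_deltas")
  if (!cov_deltas %in% c("free", "zero")) stopf("bad cov_deltas")
  chk_opt(residual, c("constant", "per_wave"), "residual")
  if (is.numeric(residual) && residual <= 0) stopf("fixed residual must be > 0")
  spec <- structure(list(n_waves = as.integer(n_waves),
                         free_mean_eta1 = free_mean_eta1,
                         free_mean_deltas = free_mean_deltas,
                         var_eta1 = var_eta1, var_deltas = var_deltas,
                         cov_eta1_deltas = cov_eta1_deltas,
                         cov_deltas = cov_deltas, residual = residual),
                    class = "lcsm_spec")
  if (lcsm_n_params(spec) < 1L) stopf("specification has no free parameters")
  spec
}

#' @noRd
lcsm_n_params <- function(spec) {
  tt <- spec$n_waves
  p <- 0L
  if (spec$free_mean_eta1) p <- p + 1L
  if (spec$free_mean_deltas) p <- p + (tt - 1L)
  if (identical(spec$var_eta1, "free")) p <- p + 1L
  if (identical(spec$var_deltas, "free")) p <- p + (tt - 1L)
  if (spec$cov_eta1_deltas == "free") p <- p + (tt - 1L)
  if (spec$cov_deltas == "free") p <- p + (tt - 1L) * (tt - 2L) / 2L
  if (identical(spec$residual, "constant")) p <- p + 1L
  if (identical(spec$residual, "per_wave")) p <- p + tt
  as.integer(p)
}

#' Model-implied mean vector and covariance matrix
#'
#' @param spec an [lcsm_spec] (used for dimension checking).
#' @param params list with `mean_eta1` (scalar), `mean_deltas` (length T-1),
#'   `psi` ((T x T) latent covariance over eta_1 and the change scores),
#'   and `theta` (length-T residual variances).
#' @return List with `mean` (length T) and `cov` (T x T).
#' @export
implied_moments <- function(spec, params) {
  tt <- spec$n_waves
  if (length(params$mean_deltas) != tt - 1L) stopf("mean_deltas length != T-1")
  if (!all(dim(params$psi) == tt)) stopf("psi must be T x T")
  ev <- eigen(params$psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stopf("latent covariance psi is not positive semidefinite")
  L <- matrix(0, tt, tt)
  L[, 1L] <- 1
  for (j in 2:tt) L[j:tt, j] <- 1
  mean <- as.vector(L %*% c(params$mean_eta1, params$mean_deltas))
  cov <- L %*% params$psi %*% t(L) + diag(params$theta, tt)
  list(mean = mean, cov = cov)
}

#' Full-information Gaussian log-likelihood
#'
#' Sums, over subjects, the multivariate-normal log-density restricted to
#' each subject's observed waves. Subjects sharing a missingness pattern
#' are grouped so each pattern's sub-covariance is factorized once.
#'
#' @param mean length-T mean vector.
#' @param cov T x T covariance matrix (must be positive definite on every
#'   observed sub-pattern).
#' @param data a [panel_dataset].
#' @return Scalar log-likelihood.
#' @export
fiml_loglik <- function(mean, cov, data) {
  stopifnot(inherits(data, "panel_dataset"))
  Y <- data$y; obs <- data$observed
  pat <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  total <- 0
  for (p in unique(pat)) {
    rows <- which(pat == p)
    idx <- which(obs[rows[1L], ])
    S <- cov[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e)
      stopf("covariance singular on observed pattern %s", p))
    logdet <- 2 * sum(log(diag(ch)))
    Yc <- sweep(Y[rows, idx, drop = FALSE], 2L, mean[idx])
    # quadratic forms via backsolve against the Cholesky factor
    Q <- backsolve(ch, t(Yc), transpose = TRUE)
    quad <- colSums(Q^2)
    k <- length(idx)
    total <- total + sum(-0.5 * (k * log(2 * pi) + logdet + quad))
  }
  total
}

# Build params from a free-parameter vector under the spec (variances on
# the log scale), and starting values from the data.
#' @noRd
lcsm_unpack <- function(v, spec, floor = 1e-4) {
  tt <- spec$n_waves
  i <- 0L
  take <- function(k) { out <- v[i + seq_len(k)]; i <<- i + k; out }
  mean_eta1 <- if (spec$free_mean_eta1) take(1L) else 0
  mean_deltas <- if (spec$free_mean_deltas) take(tt - 1L) else rep(0, tt - 1L)
  var_eta1 <- if (identical(spec$var_eta1, "free")) exp(take(1L)) else
    spec$var_eta1
  var_deltas <- if (identical(spec$var_deltas, "free")) exp(take(tt - 1L))
    else if (identical(spec$var_deltas, "zero")) rep(0, tt - 1L)
    else rep(spec$var_deltas, tt - 1L)
  psi <- diag(c(var_eta1, var_deltas), tt)
  if (spec$cov_eta1_deltas == "free") {
    cv <- take(tt - 1L)
    psi[1L, 2:tt] <- psi[2:tt, 1L] <- cv
  }
  if (spec$cov_deltas == "free") {
    cv <- take((tt - 1L) * (tt - 2L) / 2L)
    m <- 0L
    for (a in 2:(tt - 1L)) for (b in (a + 1L):tt) {
      m <- m + 1L
      psi[a, b] <- psi[b, a] <- cv[m]
    }
  }
  theta <- if (identical(spec$residual, "constant")) rep(max(exp(take(1L)), floor), tt)
    else if (identical(spec$residual, "per_wave")) pmax(exp(take(tt)), floor)
    else rep(spec$residual, tt)
  list(mean_eta1 = mean_eta1, mean_deltas = mean_deltas, psi = psi,
       theta = theta)
}

#' @noRd
lcsm_start <- function(data, spec) {
  mu <- colMeans(data$y, na.rm = TRUE)
  vtot <- stats::var(as.vector(data$y), na.rm = TRUE)
  v <- c()
  tt <- spec$n_waves
  if (spec$free_mean_eta1) v <- c(v, mu[1L])
  if (spec$free_mean_deltas) v <- c(v, diff(mu))
  if (identical(spec$var_eta1, "free")) v <- c(v, log(vtot / 3))
  if (identical(spec$var_deltas, "free")) v <- c(v, rep(log(vtot / 6), tt - 1L))
  if (spec$cov_eta1_deltas == "free") v <- c(v, rep(0, tt - 1L))
  if (spec$cov_deltas == "free") v <- c(v, rep(0, (tt - 1L) * (tt - 2L) / 2L))
  if (identical(spec$residual, "constant")) v <- c(v, log(vtot / 2))
  if (identical(spec$residual, "per_wave")) v <- c(v, rep(log(vtot / 2), tt))
  unname(v)
}

# Saturated multivariate-normal model (free mean + free covariance) fitted
# to data with arbitrary missingness by the standard EM for the MVN.
#' @noRd
fit_saturated <- function(data, max_iter = 500L, tol = 1e-10) {
  Y <- data$y; obs <- data$observed
  n <- nrow(Y); tt <- ncol(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S)[diag(S) < 1e-6] <- 1e-6
  if (all(obs)) {
    Yc <- sweep(Y, 2L, mu)
    S <- crossprod(Yc) / n
    ll <- fiml_loglik(mu, S, data)
    return(list(mean = mu, cov = S, loglik = ll,
                n_params = tt + tt * (tt + 1) / 2))
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    EY <- Y; EYY <- array(0, c(n, tt, tt))
    pat <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
    for (p in unique(pat)) {
      rows <- which(pat == p)
      o <- which(obs[rows[1L], ]); m <- which(!obs[rows[1L], ])
      if (length(m)) {
        Soo <- S[o, o, drop = FALSE]
        B <- S[m, o, drop = FALSE] %*% solve(Soo)
        cond_cov <- S[m, m, drop = FALSE] - B %*% S[o, m, drop = FALSE]
        EY[rows, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          sweep(Y[rows, o, drop = FALSE], 2L, mu[o]) %*% t(B)
        for (r in rows) EYY[r, m, m] <- cond_cov
      }
    }
    mu_new <- colMeans(EY)
    Yc <- sweep(EY, 2L, mu_new)
    S_new <- crossprod(Yc) / n + apply(EYY, c(2, 3), mean)
    mu <- mu_new; S <- (S_new + t(S_new)) / 2
    ll <- fiml_loglik(mu, S, data)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(mean = mu, cov = S, loglik = ll, n_params = tt + tt * (tt + 1) / 2)
}

# Independence baseline: free per-wave means and variances, zero
# covariances. FIML factorizes by wave, so the MLE is closed form.
#' @noRd
fit_baseline <- function(data) {
  Y <- data$y
  n_t <- colSums(data$observed)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- colSums(sweep(Y, 2L, mu)^2, na.rm = TRUE) / n_t   # ML denominator
  ll <- sum(stats::dnorm(Y, matrix(mu, nrow(Y), ncol(Y), byrow = TRUE),
                         matrix(sqrt(v), nrow(Y), ncol(Y), byrow = TRUE),
                         log = TRUE), na.rm = TRUE)
  list(mean = mu, var = v, loglik = ll, n_params = 2L * ncol(Y))
}

# RMSEA confidence limit: invert the noncentral chi-square distribution in
# the noncentrality parameter by bisection (tolerance 1e-8).
#' @noRd
rmsea_ci_limit <- function(chi2, df, n, prob) {
  f <- function(ncp) stats::pchisq(chi2, df, ncp = ncp) - prob
  if (f(0) < 0) return(0)
  lo <- 0; hi <- max(chi2 * 2, 10)
  while (f(hi) > 0) hi <- hi * 2
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(max(0, lo / (df * (n - 1))))
}

#' Fit a latent change score model
#'
#' Maximizes the full-information Gaussian likelihood of the LCSM over the
#' free parameters declared in the spec (quasi-Newton optimization with
#' variances on the log scale). Fit indices are computed against a
#' saturated model (free mean vector and covariance matrix, fitted by EM
#' under the same missing-data likelihood) and an independence baseline
#' (free means and variances, zero covariances): chi-square, RMSEA with a
#' 90\% noncentral-chi-square confidence interval, CFI, TLI, SRMR (root mean
#' square standardized covariance residual), and AIC/BIC/aBIC.
#'
#' @param data a [panel_dataset].
#' @param spec an [lcsm_spec].
#' @param control list passed to [stats::nlminb()] (`iter.max`, `rel.tol`).
#' @return Object of class `fitted_lcsm`: `params`, `loglik`, `indices`,
#'   `spec`, `converged`, `boundary` (variances at the floor).
#' @export
fit_lcsm <- function(data, spec = lcsm_spec(), control = list()) {
  stopifnot(inherits(data, "panel_dataset"))
  if (spec$n_waves != data$n_waves) stopf("spec/data wave count mismatch")
  n <- data$n_subjects
  p_model <- lcsm_n_params(spec)
  if (n <= p_model) stopf("need n > number of free parameters (%d)", p_model)
  negll <- function(v) {
    par <- lcsm_unpack(v, spec)
    mom <- tryCatch(implied_moments(spec, par), error = function(e) NULL)
    if (is.null(mom)) return(1e10)
    ll <- tryCatch(fiml_loglik(mom$mean, mom$cov, data),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  v0 <- lcsm_start(data, spec)
  opt <- stats::nlminb(v0, negll,
                       control = utils::modifyList(
                         list(iter.max = 500L, rel.tol = 1e-10), control))
  if (opt$objective >= 1e10)
    stopf("LCSM optimization failed to find a finite likelihood")
  par <- lcsm_unpack(opt$par, spec)
  mom <- implied_moments(spec, par)
  ll <- -opt$objective
  sat <- fit_saturated(data)
  base <- fit_baseline(data)
  chi2 <- max(0, 2 * (sat$loglik - ll))
  df <- sat$n_params - p_model
  chi2_b <- max(0, 2 * (sat$loglik - base$loglik))
  df_b <- sat$n_params - base$n_params
  rmsea <- sqrt(max(0, (chi2 - df) / (df * (n - 1))))
  rmsea_lo <- rmsea_ci_limit(chi2, df, n, 0.95)
  rmsea_hi <- rmsea_ci_limit(chi2, df, n, 0.05)
  cfi <- 1 - max(chi2 - df, 0) / max(chi2 - df, chi2_b - df_b, 0 + 1e-300)
  cfi <- min(max(cfi, 0), 1)
  tli <- if (chi2_b / df_b - 1 > 0)
    min(1, ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)) else 1
  d_s <- sqrt(diag(sat$cov))
  res <- (sat$cov - mom$cov) / tcrossprod(d_s)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  ics <- information_criteria(ll, p_model, n)
  indices <- list(loglik = ll, chi2 = chi2, df = df,
                  p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                  rmsea = rmsea, rmsea_ci = c(lower = rmsea_lo,
                                              upper = rmsea_hi),
                  cfi = cfi, tli = tli, srmr = srmr,
                  aic = ics$aic, bic = ics$bic, abic = ics$abic,
                  baseline_chi2 = chi2_b, baseline_df = df_b)
  boundary <- any(par$theta <= 1e-4 + 1e-12)
  structure(list(params = par, implied = mom, loglik = ll, indices = indices,
                 spec = spec, n = n, n_params = p_model,
                 converged = opt$convergence == 0, boundary = boundary,
                 optimizer = opt[c("convergence", "message", "iterations")]),
            class = "fitted_lcsm")
}

#' @export
print.fitted_lcsm <- function(x, ...) {
  ix <- x$indices
  cat(sprintf("fitted_lcsm: %d waves, n = %d, logLik = %.2f (%d parameters)\n",
              x$spec$n_waves, x$n, x$loglik, x$n_params))
  cat(sprintf("  chi2(%d) = %.2f, p = %.3g\n", ix$df, ix$chi2, ix$p_value))
  cat(sprintf("  RMSEA = %.3f [%.3f, %.3f] | CFI = %.3f | TLI = %.3f | SRMR = %.3f\n",
              ix$rmsea, ix$rmsea_ci["lower"], ix$rmsea_ci["upper"],
              ix$cfi, ix$tli, ix$srmr))
  invisible(x)
}
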