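# Class-enumeration workflow: fit K = 1..Kmax with the full multi-start
# protocol and report the selection criteria side by side. The report
# never auto-selects a K: information criteria keep improving trivially in
# very large samples, so the scree (first differences), entropy, minimum
# class size, and log-likelihood replication are laid out for the analyst,
# with the "diminishing returns" elbow highlighted but not applied.

#' Enumerate candidate class counts
#'
#' Fits the trajectory mixture for each `K` in `1..Kmax`, each with the
#' full multi-start EM protocol, and tabulates log-likelihood (with
#' replication flag), AIC/BIC/aBIC, relative entropy (for K >= 2), the
#' smallest class proportion and size, and whether every class exceeds the
#' minimum-size threshold. Also computes IC first differences and the
#' smallest K after which every subsequent IC drop falls below
#' `elbow_fraction` of the largest drop.
#'
#' @param data a [panel_dataset].
#' @param Kmax largest class count to fit.
#' @param control an [em_control]; each K derives its start seed from
#'   `control$seed` so the whole report is reproducible bit-for-bit.
#' @param min_class_size minimum acceptable class proportion (default 5\%).
#' @param elbow_fraction fraction of the largest BIC drop below which
#'   further drops count as diminishing returns.
#' @return Object of class `enumeration_report`: `table` (one row per K),
#'   `scree` (IC first differences), `elbow_K`, `fits` (the
#'   `fitted_mixture` objects), `min_class_size`, `elbow_fraction`.
#' @export
enumerate_classes <- function(data, Kmax, control = em_control(),
                              min_class_size = 0.05,
                              elbow_fraction = 0.20) {
  stopifnot(inherits(data, "panel_dataset"))
  if (Kmax < 1L) stopf("Kmax must be >= 1")
  fits <- vector("list", Kmax)
  rows <- vector("list", Kmax)
  for (K in seq_len(Kmax)) {
    ctl <- control
    ctl$seed <- control$seed + K          # reproducible per-K start stream
    fit <- tryCatch(
      withCallingHandlers(em_fit(data, K, ctl),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[K]] <- data.frame(K = K, loglik = NA_real_, replicated = FALSE,
                              converged = FALSE, aic = NA_real_,
                              bic = NA_real_, abic = NA_real_,
                              entropy = NA_real_,
                              min_class_prop = NA_real_,
                              min_class_n = NA_integer_,
                              meets_min_size = FALSE)
      next
    }
    fits[[K]] <- fit
    prop <- fit$params$pi
    rows[[K]] <- data.frame(
      K = K, loglik = fit$loglik, replicated = fit$ll_replicated,
      converged = fit$converged, aic = fit$ic$aic, bic = fit$ic$bic,
      abic = fit$ic$abic, entropy = if (K >= 2L) fit$entropy else NA_real_,
      min_class_prop = min(prop),
      min_class_n = as.integer(round(min(prop) * fit$n)),
      meets_min_size = min(prop) >= min_class_size)
  }
  tab <- do.call(rbind, rows)
  scree <- if (Kmax > 1L)
    data.frame(from_K = seq_len(Kmax - 1L), to_K = 2:Kmax,
               d_aic = diff(tab$aic), d_bic = diff(tab$bic),
               d_abic = diff(tab$abic))
  else NULL
  elbow_K <- NA_integer_
  if (!is.null(scree) && any(is.finite(scree$d_bic))) {
    drops <- -scree$d_bic                 # positive = improvement
    largest <- max(drops, na.rm = TRUE)
    if (largest > 0) {
      # smallest K such that every later improvement is below the threshold
      for (K in seq_len(Kmax)) {
        later <- drops[scree$from_K >= K]
        if (length(later) == 0L || all(later < elbow_fraction * largest,
                                       na.rm = TRUE)) {
          elbow_K <- K
          break
        }
      }
    }
  }
  structure(list(table = tab, scree = scree, elbow_K = elbow_K,
                 fits = fits, min_class_size = min_class_size,
                 elbow_fraction = elbow_fraction),
            class = "enumeration_report")
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat("enumeration_report\n")
  tab <- x$table
  num <- c("loglik", "aic", "bic", "abic")
  tab[num] <- lapply(tab[num], round, 1)
  tab$entropy <- round(tab$entropy, 3)
  tab$min_class_prop <- round(tab$min_class_prop, 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$scree)) {
    cat("\nIC first differences (scree):\n")
    sc <- x$scree
    sc[c("d_aic", "d_bic", "d_abic")] <-
      lapply(sc[c("d_aic", "d_bic", "d_abic")], round, 1)
    print(sc, row.names = FALSE)
    if (!is.na(x$elbow_K))
      cat(sprintf("\ndiminishing returns (BIC drops < %.0f%% of largest) after K = %d; selection also requires substantive judgement\n",
                  100 * x$elbow_fraction, x$elbow_K))
  }
  invisible(x)
}
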