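# Internal numeric helpers shared across the package.

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp for a matrix (n x K), returns length-n vector.
#' @noRd
row_logsumexp <- function(lx) {
  m <- apply(lx, 1L, max)
  m + log(rowSums(exp(lx - m)))
}

#' @noRd
softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Central-difference Hessian of a scalar function; used for observed-
# information standard errors where no analytic Hessian is available.
#' @noRd
num_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x), 1) * eps
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Run an expression with a locally seeded RNG, restoring the caller's state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Row-wise first differences of a matrix (columns 2..T minus 1..T-1).
#' @noRd
row_diff <- function(m) m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
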