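# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# OLS by explicit normal equations: coefficient, SE and two-sided p for the
# predictor in column `j` of X (X includes the intercept).
oracle_ols <- function(y, X, j = 2) {
  XtX <- t(X) %*% X
  XtX_inv <- solve(XtX)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * XtX_inv[j, j])
  tt <- beta[j] / se
  list(beta = beta[j], se = se, t = tt, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- order(p[ok])
  adj <- p[ok][ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out[ok[ord]] <- pmin(adj, 1)
  out
}

# Greedy keep-if-below-threshold scan, written independently.
oracle_greedy_prune <- function(mat_cols, threshold) {
  kept <- integer(0)
  for (j in seq_len(ncol(mat_cols))) {
    if (var(mat_cols[, j]) == 0) next
    ok <- TRUE
    for (k in kept) {
      if (cor(mat_cols[, j], mat_cols[, k])^2 >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

# Upper orthant probability of a standard bivariate normal by a plain
# midpoint Riemann sum on a wide grid.
oracle_orthant <- function(h1, h2, rho, step = 0.005, lim = 8) {
  z <- seq(h1 + step / 2, lim, by = step)
  sum(dnorm(z) * pnorm((rho * z - h2) / sqrt(1 - rho^2))) * step
}

expit <- function(x) 1 / (1 + exp(-x))

# Small helper: clip and M-transform a simulated beta matrix.
to_m <- function(beta) {
  b <- pmin(pmax(beta, 0.001), 0.999)
  log2(b / (1 - b))
}
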