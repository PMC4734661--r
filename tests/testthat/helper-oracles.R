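# Independent oracles used across the suite.  They deliberately take the
# dense, textbook route (explicit normal equations, full n x n matrices)
# rather than the package's cached/low-rank paths.

# Least-squares fit of y on [X | s] via the normal equations; returns the
# marker coefficient, its standard error, t and two-sided P.
dense_marker_oracle <- function(X, y, s) {
  M <- cbind(X, s)
  XtX <- crossprod(M)
  if (rcond(XtX) < 1e-12) return(list(effect = NA_real_, se = NA_real_,
                                      t_stat = NA_real_, p_value = NA_real_))
  beta <- solve(XtX, crossprod(M, y))
  res <- y - M %*% beta
  df <- length(y) - ncol(M)
  s2 <- sum(res^2) / df
  covb <- s2 * solve(XtX)
  j <- ncol(M)
  se <- sqrt(covb[j, j])
  tv <- beta[j] / se
  list(effect = beta[j], se = se, t_stat = tv,
       p_value = 2 * pt(-abs(tv), df))
}

# Restricted log-likelihood of y = 1 mu + u + e, Var(u) = K2 * sigma_a^2,
# Var(e) = I sigma_e^2, profiled over (mu, sigma_a^2) at fixed
# delta = sigma_e^2 / sigma_a^2, computed with dense determinants.
dense_reml_oracle <- function(K2, y, delta) {
  n <- length(y)
  H <- K2 + delta * diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  xhx <- drop(crossprod(one, Hi %*% one))
  P <- Hi - (Hi %*% one %*% crossprod(one, Hi)) / xhx
  ypy <- drop(crossprod(y, P %*% y))
  sigma_a2 <- ypy / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(sigma_a2) + (n - 1) +
            determinant(H)$modulus[1] + log(xhx))
}

# Tiny genotype dataset straight from a matrix (one chromosome, unit-spaced
# positions unless a map is given).
toy_genotypes <- function(X, map = NULL) {
  colnames(X) <- paste0("m", seq_len(ncol(X)))
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  if (is.null(map))
    map <- data.frame(marker_id = colnames(X), chrom = "chr1",
                      pos = seq_len(ncol(X)) * 1000L)
  genotype_dataset(X, map)
}

# Random dosage matrix with independent markers.
random_dosages <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  X <- sapply(p, function(pp) rbinom(n, 2, pp))
  # guard against constant columns in tiny draws
  for (j in which(apply(X, 2, var) == 0)) X[1, j] <- 2 - X[1, j]
  X
}
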