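# Random-effect model used to score candidate pseudo-QTN sets:
#   y = 1*mu + u + e,  Var(u) = 2 K sigma_a^2,  Var(e) = I sigma_e^2,
# with K the genomic relationship built from the pseudo-QTN dosages only.
# Because K has rank <= t, the restricted likelihood is evaluated through
# the SVD of the centered pseudo-QTN matrix: only the t nonzero eigenvalues
# and the pooled orthogonal complement enter, so each evaluation is O(n)
# after one thin SVD.

#' Low-rank kinship factor from pseudo-QTN dosages
#'
#' Columns are centered at `2 * p_hat` (the VanRaden construction) and the
#' implied relationship matrix `K = Z Z' / norm` is rescaled so its mean
#' diagonal equals 1; only `Z` and its SVD are stored.
#'
#' @param genotypes aligned, imputed [genotype_dataset].
#' @param pseudo a [pseudo_qtn_set] (or character vector of marker ids).
#' @return object of class `kinship_factor` with elements `Z`, `u`
#'   (left singular vectors), `d` (singular values), `norm`.
#' @export
build_kinship_factor <- function(genotypes, pseudo) {
  ids <- if (inherits(pseudo, "pseudo_qtn_set")) pseudo$marker_ids else
    as.character(pseudo)
  if (length(ids) < 1) stop("pseudo-QTN set is empty")
  miss <- setdiff(ids, genotypes$map$marker_id)
  if (length(miss)) stop("pseudo QTNs absent from genotypes")
  Z <- genotypes$dosages[, ids, drop = FALSE]
  keep <- apply(Z, 2, function(x) stats::var(x) > 0)
  if (!any(keep)) stop("degenerate kinship: all pseudo-QTN columns constant")
  if (!all(keep)) {
    warning(sum(!keep), " constant pseudo-QTN column(s) dropped from kinship")
    Z <- Z[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  Z <- sweep(Z, 2, colMeans(Z))        # centering at 2*p_hat
  norm <- sum(Z^2) / nrow(Z)           # => mean(diag(ZZ'/norm)) == 1 exactly
  sv <- svd(Z, nu = min(dim(Z)), nv = 0)
  pos <- sv$d > sv$d[1] * 1e-12
  structure(list(Z = Z, ids = ids, u = sv$u[, pos, drop = FALSE],
                 d = sv$d[pos], norm = norm, n = nrow(Z)),
            class = "kinship_factor")
}

#' Dense relationship matrix implied by a kinship factor (for inspection and
#' oracles; the REML path never forms it).
#' @param factor a [build_kinship_factor] result.
#' @return n x n matrix with mean diagonal 1.
#' @export
kinship_matrix <- function(factor) {
  tcrossprod(factor$Z) / factor$norm
}

#' Restricted log-likelihood at a fixed variance ratio
#'
#' Profiles (mu, sigma_a^2) out of the restricted likelihood of
#' `y = 1 mu + u + e` at fixed `delta = sigma_e^2 / sigma_a^2`, using the
#' spectral identity for the rank-t kinship.  The value includes all
#' constants of the error-contrast likelihood, so it is comparable across
#' candidate sets (same `y`, same `n`).
#'
#' @param factor a [build_kinship_factor] result.
#' @param y aligned numeric phenotype vector.
#' @param delta positive variance ratio `sigma_e^2 / sigma_a^2`.
#' @return restricted log-likelihood (scalar).
#' @export
reml_criterion <- function(factor, y, delta) {
  stopifnot(delta > 0, length(y) == factor$n)
  if (any(!is.finite(y))) stop("non-finite phenotype")
  prof <- .reml_profile(factor, y, delta)
  if (!is.finite(prof$ll)) stop("non-finite restricted likelihood")
  prof$ll
}

# Shared spectral profile: eigenvalues of S K* S (K* = 2K) are
# lambda_i = 2 d_i^2 / norm for i <= r and 0 on the rest of the centered
# space; eta_i = u_i' y (u_i are centered already since Z columns are).
.reml_profile <- function(factor, y, delta) {
  n <- factor$n
  lambda <- 2 * factor$d^2 / factor$norm
  eta2 <- drop(crossprod(factor$u, y))^2
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  rest <- max(ssy - sum(eta2), 0)
  r <- length(lambda)
  R <- sum(eta2 / (lambda + delta)) + rest / delta
  logdet <- sum(log(lambda + delta)) + (n - 1 - r) * log(delta)
  sigma_a2 <- R / (n - 1)
  ll <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(sigma_a2) +
                  (n - 1) + log(n) + logdet)
  list(ll = ll, sigma_a2 = sigma_a2, sigma_e2 = delta * sigma_a2)
}

#' Estimate variance components by REML
#'
#' Maximizes the restricted log-likelihood over `delta` on a 100-point
#' log-spaced grid spanning `[1e-5, 1e5]`, refined by Brent search on
#' log(delta) in the bracketing interval.  A likelihood that is flat across
#' the grid (the zero-heritability pathology) is flagged `converged = FALSE`
#' so callers can fall back.
#'
#' @param factor a [build_kinship_factor] result.
#' @param y aligned numeric phenotype vector.
#' @param grid_points number of grid points (default 100).
#' @return list with `sigma_a2`, `sigma_e2`, `delta`, `loglik`, `converged`.
#' @export
estimate_variance_components <- function(factor, y, grid_points = 100L) {
  lg <- seq(log(1e-5), log(1e5), length.out = grid_points)
  ll <- vapply(lg, function(l) .reml_profile(factor, y, exp(l))$ll, 0)
  i <- which.max(ll)
  flat <- (max(ll) - min(ll)) < 1e-6 * max(1, abs(max(ll)))
  lo <- lg[max(i - 1L, 1L)]
  hi <- lg[min(i + 1L, grid_points)]
  opt <- stats::optimize(function(l) .reml_profile(factor, y, exp(l))$ll,
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  best_l <- if (opt$objective >= ll[i]) opt$maximum else lg[i]
  delta <- exp(best_l)
  prof <- .reml_profile(factor, y, delta)
  list(sigma_a2 = prof$sigma_a2, sigma_e2 = prof$sigma_e2, delta = delta,
       loglik = prof$ll, converged = !flat)
}
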