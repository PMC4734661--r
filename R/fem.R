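# Fixed-effect single-marker scan: each marker is tested by least squares in
# the model  y = intercept + covariates + pseudo-QTN dosages + marker, and the
# pseudo QTNs later receive a unified P value by substitution.  The design
# cross-products are factored once so the whole scan is O(n * m) for a fixed
# number of covariates.

#' Ordered set of pseudo QTNs
#'
#' @param marker_ids character vector of marker ids, most significant first.
#' @param p_values unified P values (same length), nondecreasing.
#' @param iteration iteration at which the set was formed.
#' @return object of class `pseudo_qtn_set`.
#' @export
pseudo_qtn_set <- function(marker_ids = character(), p_values = numeric(),
                           iteration = 0L) {
  stopifnot(length(marker_ids) == length(p_values))
  o <- order(p_values)
  structure(list(marker_ids = as.character(marker_ids)[o],
                 p_values = as.numeric(p_values)[o],
                 iteration = as.integer(iteration)),
            class = "pseudo_qtn_set")
}

#' @export
length.pseudo_qtn_set <- function(x) length(x$marker_ids)

#' @export
print.pseudo_qtn_set <- function(x, ...) {
  cat(sprintf("pseudo_qtn_set: %d marker(s) (iteration %d)\n",
              length(x), x$iteration))
  invisible(x)
}

# residual-norm tolerance (squared, relative) below which a column is
# declared linearly dependent on the current design
.collinear_tol <- 1e-8

#' Build the fixed design for the marker scan
#'
#' Assembles `[1 | covariates | pseudo-QTN dosages]`, drops linearly
#' dependent columns (covariates silently with a warning; a dependent pseudo
#' QTN should not survive pruning, but if one does the less significant of
#' the pair is dropped and reported), and caches the cross-product inverse
#' used by every marker test.
#'
#' @param covariates numeric matrix n x c or NULL.
#' @param pseudo a [pseudo_qtn_set] or NULL.
#' @param genotypes aligned, imputed [genotype_dataset].
#' @return object of class `design_context`.
#' @export
build_design <- function(covariates = NULL, pseudo = NULL, genotypes) {
  n <- nrow(genotypes$dosages)
  cols <- list(`(Intercept)` = rep(1, n))
  kind <- "intercept"
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows != sample count")
    if (anyNA(covariates)) stop("covariates contain missing values")
    cn <- colnames(covariates)
    if (is.null(cn)) cn <- paste0("covar", seq_len(ncol(covariates)))
    for (j in seq_len(ncol(covariates))) cols[[cn[j]]] <- covariates[, j]
    kind <- c(kind, rep("covariate", ncol(covariates)))
  }
  pseudo_ids <- character()
  if (!is.null(pseudo) && length(pseudo) > 0) {
    miss <- setdiff(pseudo$marker_ids, genotypes$map$marker_id)
    if (length(miss)) stop("pseudo QTNs absent from genotypes: ",
                           paste(miss, collapse = ", "))
    for (id in pseudo$marker_ids) cols[[id]] <- genotypes$dosages[, id]
    pseudo_ids <- pseudo$marker_ids
    kind <- c(kind, rep("pseudo", length(pseudo_ids)))
  }
  # greedy Gram-Schmidt sweep in priority order (intercept, covariates,
  # then pseudo QTNs by significance): keeps the design full rank while
  # guaranteeing that when two pseudo QTNs collide the less significant
  # one is the casualty.
  Q <- matrix(0, n, 0)
  keep <- logical(length(cols))
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    r <- if (ncol(Q)) v - Q %*% crossprod(Q, v) else v
    if (sum(r^2) > .collinear_tol * max(sum(v^2), .Machine$double.eps)) {
      keep[j] <- TRUE
      Q <- cbind(Q, r / sqrt(sum(r^2)))
    }
  }
  dropped <- names(cols)[!keep]
  if (length(dropped))
    warning("dropped linearly dependent design column(s): ",
            paste(dropped, collapse = ", "))
  X <- do.call(cbind, cols[keep])
  colnames(X) <- names(cols)[keep]
  p <- ncol(X)
  if (n <= p + 1)
    stop("no residual degrees of freedom: n = ", n, ", design columns = ", p)
  A <- chol2inv(chol(crossprod(X)))
  dimnames(A) <- list(colnames(X), colnames(X))
  structure(list(
    X = X, A = A, diagA = diag(A), n = n, p = p,
    pseudo_ids = intersect(pseudo_ids, colnames(X)),
    pseudo_cols = match(intersect(pseudo_ids, colnames(X)), colnames(X)),
    dropped = dropped),
    class = "design_context")
}

#' @export
print.design_context <- function(x, ...) {
  cat(sprintf("design_context: n = %d, %d column(s), %d pseudo QTN(s)\n",
              x$n, x$p, length(x$pseudo_ids)))
  invisible(x)
}

# P values are floored here on a perfect fit (se -> 0); the underlying model
# never reaches it but degenerate inputs can.
.p_floor <- 1e-300

#' Test one marker against the cached design
#'
#' @param context a [build_design] result.
#' @param y numeric phenotype vector, aligned.
#' @param marker_dosages numeric vector of length n.
#' @return list with `effect`, `se`, `t_stat`, `p_value`, `perfect_fit`;
#'   all-`NA` sentinel when the marker is collinear with the design.
#' @export
test_marker <- function(context, y, marker_dosages) {
  if (any(!is.finite(marker_dosages))) stop("non-finite marker dosages")
  res <- .scan_block(context, y,
                     matrix(marker_dosages, ncol = 1),
                     pseudo_stats = FALSE)
  list(effect = res$effect[1], se = res$se[1], t_stat = res$t_stat[1],
       p_value = res$p_value[1], perfect_fit = res$perfect_fit[1])
}

# Vectorized core: tests every column of S against the design.  Returns the
# marker statistics and (optionally) the pseudo-QTN coefficient P values for
# each test, computed from the rank-one update of the block inverse.
.scan_block <- function(context, y, S, pseudo_stats = TRUE) {
  X <- context$X; A <- context$A; n <- context$n; p <- context$p
  df <- n - p - 1
  xty <- crossprod(X, y)
  b0 <- drop(A %*% xty)
  ry <- y - drop(X %*% b0)
  rss0 <- sum(ry^2)

  U <- crossprod(X, S)                      # p x B
  V <- A %*% U
  ss <- colSums(S * S)
  sperp2 <- ss - colSums(U * V)
  collinear <- sperp2 <= .collinear_tol * pmax(ss, .Machine$double.eps)
  sperp2[collinear] <- NA_real_
  d <- drop(crossprod(S, ry)) / sperp2
  rss <- pmax(rss0 - d^2 * sperp2, 0)
  sigma2 <- rss / df
  perfect <- !collinear & sigma2 <= 1e-12 * max(mean(y^2), .Machine$double.eps)
  se <- sqrt(sigma2 / sperp2)
  tval <- d / se
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[perfect] <- .p_floor
  tval[perfect & !is.finite(tval)] <- Inf
  pval <- pmax(pval, .p_floor)
  out <- list(effect = d, se = se, t_stat = tval, p_value = pval,
              perfect_fit = perfect, collinear = collinear)

  k <- context$pseudo_cols
  if (pseudo_stats && length(k)) {
    # coefficient of pseudo QTN k in the model that also contains marker j:
    #   b_k(j) = b0[k] - d_j * V[k, j],  Var = sigma2_j * (A_kk + V[k,j]^2 / sperp2_j)
    Vk <- V[k, , drop = FALSE]
    bk <- b0[k] - Vk * rep(d, each = length(k))
    varb <- (context$diagA[k] + Vk^2 / rep(sperp2, each = length(k))) *
      rep(sigma2, each = length(k))
    tk <- bk / sqrt(varb)
    pk <- 2 * stats::pt(-abs(tk), df)
    pk[, collinear] <- NA_real_
    if (any(perfect)) pk[, perfect] <- .p_floor
    pk[is.nan(pk)] <- .p_floor
    pk <- pmax(pk, .p_floor)
    out$pseudo_p <- pk                      # t x B, NA where sentinel
  }
  out
}

#' Scan every marker in the genome
#'
#' Applies [test_marker] to all markers using cached cross-products, so cost
#' is linear in `n * m`.  Markers in the current pseudo-QTN set are collinear
#' with the design and carry the not-estimable sentinel until
#' [substitute_pvalues] is applied.  While scanning, the per-pseudo-QTN P
#' values from every marker test are accumulated streaming (running
#' min/max/sum), so the t x m matrix is only materialized when
#' `keep_pmatrix = TRUE` (needed for median substitution).
#'
#' @param context a [build_design] result.
#' @param y aligned numeric phenotype vector.
#' @param genotypes aligned, imputed [genotype_dataset].
#' @param keep_pmatrix keep the full t x m pseudo-QTN P matrix.
#' @param block_size markers per vectorized block.
#' @return data.frame of class `scan_result` with columns `marker_id`,
#'   `chrom`, `pos`, `effect`, `se`, `t_stat`, `p_value`, `is_pseudo_qtn`,
#'   `perfect_fit`; substitution inputs are carried in attributes.
#' @export
scan_genome <- function(context, y, genotypes, keep_pmatrix = FALSE,
                        block_size = 2048L) {
  S_all <- genotypes$dosages
  m <- ncol(S_all)
  t_ <- length(context$pseudo_ids)
  eff <- se <- tv <- pv <- rep(NA_real_, m)
  perfect <- logical(m)
  pmin_ <- rep(Inf, t_); pmax_ <- rep(-Inf, t_)
  psum <- rep(0, t_); pcnt <- rep(0L, t_)
  pmat <- if (keep_pmatrix && t_) matrix(NA_real_, t_, m) else NULL
  for (start in seq(1L, m, by = block_size)) {
    idx <- start:min(start + block_size - 1L, m)
    blk <- .scan_block(context, y, S_all[, idx, drop = FALSE],
                       pseudo_stats = t_ > 0)
    eff[idx] <- blk$effect; se[idx] <- blk$se
    tv[idx] <- blk$t_stat; pv[idx] <- blk$p_value
    perfect[idx] <- blk$perfect_fit
    if (t_ > 0) {
      pk <- blk$pseudo_p
      ok <- !blk$collinear
      if (any(ok)) {
        pok <- pk[, ok, drop = FALSE]
        pmin_ <- pmin(pmin_, apply(pok, 1, min))
        pmax_ <- pmax(pmax_, apply(pok, 1, max))
        psum <- psum + rowSums(pok)
        pcnt <- pcnt + sum(ok)
      }
      if (!is.null(pmat)) pmat[, idx] <- pk
    }
  }
  is_pseudo <- genotypes$map$marker_id %in% context$pseudo_ids
  # markers that are pseudo QTNs must be the sentinel entries
  eff[is_pseudo] <- se[is_pseudo] <- tv[is_pseudo] <- pv[is_pseudo] <- NA_real_
  res <- data.frame(marker_id = genotypes$map$marker_id,
                    chrom = genotypes$map$chrom,
                    pos = genotypes$map$pos,
                    effect = eff, se = se, t_stat = tv, p_value = pv,
                    is_pseudo_qtn = is_pseudo, perfect_fit = perfect,
                    stringsAsFactors = FALSE)
  class(res) <- c("scan_result", "data.frame")
  # onsite P values: fit of y on the design alone (no testing marker)
  onsite <- rep(NA_real_, t_)
  if (t_ > 0) {
    X <- context$X
    b0 <- drop(context$A %*% crossprod(X, y))
    rss0 <- sum((y - drop(X %*% b0))^2)
    df0 <- context$n - context$p
    s20 <- rss0 / df0
    k <- context$pseudo_cols
    t0 <- b0[k] / sqrt(s20 * context$diagA[k])
    onsite <- pmax(2 * stats::pt(-abs(t0), df0), .p_floor)
  }
  attr(res, "pseudo_stats") <- list(
    ids = context$pseudo_ids, min = pmin_, max = pmax_,
    mean = if (t_ && pcnt[1] > 0) psum / pcnt else rep(NA_real_, t_),
    count = pcnt, onsite = onsite, pmat = pmat)
  attr(res, "df") <- context$n - context$p - 1
  res
}

#' Unify pseudo-QTN P values by substitution
#'
#' Each pseudo QTN's sentinel P value is replaced by a summary of the P
#' values that pseudo QTN attained across all (non-sentinel) marker tests:
#' `min` (most significant, the default elsewhere), `mean`, `median`, `max`,
#' or `onsite` (the fit containing only the pseudo QTNs, no testing marker).
#'
#' @param scan a [scan_genome] result.
#' @param pseudo the [pseudo_qtn_set] used for the scan.
#' @param method substitution method.
#' @return the scan with pseudo-QTN P values filled in.
#' @export
substitute_pvalues <- function(scan, pseudo,
                               method = c("min", "mean", "median", "max",
                                          "onsite")) {
  method <- match.arg(method)
  st <- attr(scan, "pseudo_stats")
  if (is.null(st) || length(st$ids) == 0) return(scan)
  subs <- switch(method,
    min = st$min, max = st$max, mean = st$mean, onsite = st$onsite,
    median = {
      if (is.null(st$pmat))
        stop("median substitution requires scan_genome(keep_pmatrix = TRUE)")
      apply(st$pmat, 1, stats::median, na.rm = TRUE)
    })
  rows <- match(st$ids, scan$marker_id)
  scan$p_value[rows] <- subs
  attr(scan, "substitution") <- method
  scan
}
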