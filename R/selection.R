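# Pseudo-QTN selection: the genome is cut into fixed-length bins (restarting
# at every chromosome), each bin is represented by its most significant
# marker, and the (bin size, bin count) pair whose representative set gives
# the best restricted likelihood in the random-effect model wins.  The set is
# capped at n / log10(n) and pruned so no two pseudo QTNs are correlated
# above a threshold.

#' Default bin-optimization grid
#'
#' @param sizes bin sizes in base pairs (default 500 kb, 5 Mb, 50 Mb).
#' @param counts candidate numbers of top bins (default 10, 20, ..., 100).
#' @return list of class `bin_grid`.
#' @export
bin_grid <- function(sizes = c(5e5, 5e6, 5e7), counts = seq(10L, 100L, 10L)) {
  stopifnot(all(sizes > 0), all(counts > 0), !is.unsorted(counts))
  structure(list(sizes = sizes, counts = as.integer(counts)),
            class = "bin_grid")
}

#' Assign each marker to a genomic bin
#'
#' Bin label is `(chromosome, floor((pos - 1) / bin_size))`; bins never span
#' chromosomes.
#'
#' @param map marker map (columns `chrom`, `pos`), sorted within chromosome.
#' @param bin_size bin length in base pairs.
#' @return character vector of bin labels, one per marker.
#' @export
assign_bins <- function(map, bin_size) {
  if (bin_size <= 0) stop("bin size must be positive")
  paste(map$chrom, floor((map$pos - 1) / bin_size), sep = ":")
}

#' Most significant marker of every bin
#'
#' Ties on P value break toward smaller position, then lexicographic marker
#' id.  Candidates are returned sorted by P ascending.
#'
#' @param scan substituted scan result (no sentinels among candidates).
#' @param bins bin label per marker ([assign_bins]).
#' @return data.frame with columns `marker_id`, `chrom`, `pos`, `p_value`.
#' @export
select_bin_representatives <- function(scan, bins) {
  ok <- !is.na(scan$p_value)
  d <- data.frame(marker_id = scan$marker_id, chrom = scan$chrom,
                  pos = scan$pos, p_value = scan$p_value,
                  bin = bins, stringsAsFactors = FALSE)[ok, , drop = FALSE]
  d <- d[order(d$p_value, d$pos, d$marker_id), , drop = FALSE]
  d <- d[!duplicated(d$bin), , drop = FALSE]
  rownames(d) <- NULL
  d[, c("marker_id", "chrom", "pos", "p_value")]
}

#' Cap the candidate list at n / log10(n)
#'
#' @param candidates candidate data.frame sorted by P ascending.
#' @param n sample count (> 1).
#' @return truncated candidate list.
#' @export
enforce_qtn_cap <- function(candidates, n) {
  if (n <= 1) stop("sample count must exceed 1 for the n/log10(n) cap")
  cap <- floor(n / log10(n))
  utils::head(candidates, cap)
}

#' Greedy LD pruning of a candidate list
#'
#' Sweeping in significance order, a candidate is kept iff its dosage column
#' has absolute Pearson correlation at most `threshold` with every candidate
#' already kept.  Constant-dosage candidates carry no information and are
#' dropped.
#'
#' @param candidates candidate data.frame sorted by P ascending.
#' @param genotypes aligned [genotype_dataset].
#' @param threshold absolute correlation threshold (default 0.7).
#' @param iteration iteration stamp for the returned set.
#' @return a [pseudo_qtn_set].
#' @export
prune_correlated <- function(candidates, genotypes, threshold = 0.7,
                             iteration = 0L) {
  if (nrow(candidates) == 0)
    return(pseudo_qtn_set(iteration = iteration))
  X <- genotypes$dosages[, candidates$marker_id, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  keep_rows <- which(sds > 0)
  kept <- integer()
  for (j in keep_rows) {
    if (length(kept) == 0) { kept <- j; next }
    r <- suppressWarnings(abs(stats::cor(X[, j], X[, kept, drop = FALSE])))
    if (all(r <= threshold)) kept <- c(kept, j)
  }
  pseudo_qtn_set(candidates$marker_id[kept], candidates$p_value[kept],
                 iteration = iteration)
}

#' Optimize (bin size, bin count) by the REML criterion
#'
#' For every pair in the grid, the top-`count` bin representatives (after
#' the n/log10(n) cap and clamping to the available bins) define a kinship;
#' the pair whose optimized restricted log-likelihood is highest wins, and
#' its representative set is returned.  "Minimum REML value" is read as
#' minimum -2 * restricted log-likelihood, i.e. the maximum-likelihood set.
#'
#' @param scan substituted scan result.
#' @param genotypes aligned, imputed [genotype_dataset].
#' @param y aligned phenotype vector.
#' @param grid a [bin_grid].
#' @param qtn_threshold marginal P-value ceiling for pseudo-QTN candidacy
#'   (default 0.01).  Without it, noise markers entering the pseudo set are
#'   later branded significant by minimum substitution, inflating the null;
#'   admitting only markers already significant at this level keeps the
#'   substituted calls inside the type-I budget.  Set to 1 to disable.
#' @param iteration iteration stamp.
#' @return a [pseudo_qtn_set] (unpruned candidates, significance order) with
#'   attributes `bin_size`, `bin_count`, `loglik`, `converged`.
#' @export
optimize_bin_grid <- function(scan, genotypes, y, grid = bin_grid(),
                              qtn_threshold = 0.01, iteration = 0L) {
  n <- nrow(genotypes$dosages)
  cap <- floor(n / log10(n))
  best <- NULL
  any_converged <- FALSE
  for (size in grid$sizes) {
    bins <- assign_bins(genotypes$map, size)
    reps <- select_bin_representatives(scan, bins)
    reps <- reps[reps$p_value <= qtn_threshold, , drop = FALSE]
    seen <- integer()
    for (count in grid$counts) {
      k <- min(count, cap, nrow(reps))
      if (k < 1 || k %in% seen) next
      seen <- c(seen, k)
      cand <- utils::head(reps, k)
      vc <- tryCatch({
        fac <- suppressWarnings(build_kinship_factor(genotypes,
                                                     cand$marker_id))
        estimate_variance_components(fac, y)
      }, error = function(e) NULL)
      if (is.null(vc)) next
      any_converged <- any_converged || vc$converged
      if (is.null(best) || vc$loglik > best$loglik)
        best <- list(loglik = vc$loglik, cand = cand, size = size,
                     count = k, converged = vc$converged)
    }
  }
  if (is.null(best))
    stop("every candidate pseudo-QTN set was degenerate")
  out <- pseudo_qtn_set(best$cand$marker_id, best$cand$p_value,
                        iteration = iteration)
  attr(out, "bin_size") <- best$size
  attr(out, "bin_count") <- best$count
  attr(out, "loglik") <- best$loglik
  attr(out, "converged") <- any_converged
  out
}
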