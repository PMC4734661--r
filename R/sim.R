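# Phenotype simulator and evaluation machinery: synthetic LD-structured
# genotypes, additive phenotypes with geometric QTN effects and a target
# heritability, and scoring of scans by power, FDR, Type I error and
# candidate-gene enrichment.

#' Synthetic genotype fixture with block LD
#'
#' Dosages are sums of two haplotypes.  Within each LD block (fixed-length
#' windows of `ld_block_length` bp) every marker of a haplotype is copied
#' from one latent uniform draw per individual, then mutated independently
#' with probability `mutation_rate`; markers in different blocks are
#' independent, so within-block correlation exceeds cross-block correlation.
#' Positions are uniform within chromosomes.
#'
#' @param n,m samples and markers (>= 2 each).
#' @param chromosomes number of chromosomes (markers split evenly).
#' @param ld_block_length LD block length in bp (default 100 kb; use a value
#'   below the marker spacing for effectively independent markers).
#' @param maf_range allele-frequency range to draw per-marker frequencies
#'   from (default c(0.05, 0.5)).
#' @param chrom_length chromosome length in bp (default 10 kb per marker).
#' @param mutation_rate per-marker haplotype mutation probability (0.15).
#' @param seed random seed (required for reproducibility).
#' @return a [genotype_dataset].
#' @export
generate_fixture_genotypes <- function(n, m, chromosomes = 5L,
                                       ld_block_length = 1e5,
                                       maf_range = c(0.05, 0.5),
                                       chrom_length = NULL,
                                       mutation_rate = 0.15,
                                       seed = 1L) {
  stopifnot(n >= 2, m >= 2)
  set.seed(seed)
  per_chr <- diff(round(seq(0, m, length.out = chromosomes + 1)))
  if (is.null(chrom_length)) chrom_length <- max(per_chr) * 1e4
  map <- do.call(rbind, lapply(seq_len(chromosomes), function(cc) {
    k <- per_chr[cc]
    if (k == 0) return(NULL)
    pos <- sort(sample.int(chrom_length, k, replace = chrom_length < k))
    data.frame(marker_id = sprintf("chr%d_m%d", cc, seq_len(k)),
               chrom = paste0("chr", cc), pos = pos,
               stringsAsFactors = FALSE)
  }))
  freq <- stats::runif(nrow(map), maf_range[1], maf_range[2])
  X <- matrix(0, n, nrow(map))
  block <- paste(map$chrom, floor((map$pos - 1) / ld_block_length))
  for (b in unique(block)) {
    j <- which(block == b)
    pj <- freq[j]
    for (h in 1:2) {
      latent <- stats::runif(n)
      hap <- outer(latent, pj, "<") * 1
      flip <- matrix(stats::runif(n * length(j)) < mutation_rate,
                     n, length(j))
      redraw <- matrix(rep(pj, each = n), n, length(j))
      hap[flip] <- (matrix(stats::runif(n * length(j)), n,
                           length(j))[flip] < redraw[flip]) * 1
      X[, j] <- X[, j] + hap
    }
  }
  rownames(X) <- sprintf("s%04d", seq_len(n))
  colnames(X) <- map$marker_id
  genotype_dataset(X, map)
}

#' Simulation configuration
#'
#' @param n_qtn number of QTNs.
#' @param h2 narrow-sense heritability in (0, 1].
#' @param a geometric effect parameter in (0, 1]; the i-th QTN has additive
#'   effect `a^i` (a = 1 gives equal effects).
#' @param chrom_subset optional chromosome labels QTNs are restricted to.
#' @param exclude_qtns drop QTN columns from the returned genotype view.
#' @param seed random seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_qtn, h2, a = 0.9, chrom_subset = NULL,
                       exclude_qtns = FALSE, seed = NULL) {
  stopifnot(h2 > 0, h2 <= 1, a > 0, a <= 1, n_qtn >= 1)
  structure(list(n_qtn = as.integer(n_qtn), h2 = h2, a = a,
                 chrom_subset = chrom_subset, exclude_qtns = exclude_qtns,
                 seed = seed), class = "sim_config")
}

#' Simulate an additive phenotype with known QTNs
#'
#' QTNs are sampled uniformly without replacement (optionally restricted to
#' a chromosome subset); the i-th QTN has effect `a^i`; the additive value is
#' the QTN dosage submatrix times the effects; residuals are i.i.d. Gaussian
#' with `sigma_e^2 = (1 - h2) * sigma_a^2 / h2`, where `sigma_a^2` is the
#' empirical variance of the additive values, so realized heritability
#' concentrates at the target.
#'
#' @param genotypes a [genotype_dataset] (imputed).
#' @param config a [sim_config].
#' @return list with `phenotype` (named numeric vector), `truth` (list:
#'   `qtn_ids`, `qtn_map`, `effects`, `additive`, `sigma_a2`, `sigma_e2`,
#'   `h2`), and `genotypes` (the input, QTN columns removed when
#'   `exclude_qtns`).
#' @export
simulate_phenotype <- function(genotypes, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- genotypes$map
  pool <- seq_len(nrow(map))
  if (!is.null(config$chrom_subset))
    pool <- pool[map$chrom %in% config$chrom_subset]
  if (length(pool) < config$n_qtn)
    stop("fewer candidate markers than requested QTNs")
  for (attempt in seq_len(100L)) {
    qtn <- sample(pool, config$n_qtn)
    effects <- config$a^seq_len(config$n_qtn)
    additive <- drop(genotypes$dosages[, qtn, drop = FALSE] %*% effects)
    sigma_a2 <- stats::var(additive)
    if (sigma_a2 > 0) break
    if (attempt == 100L) stop("all sampled QTN sets were monomorphic")
  }
  sigma_e2 <- (1 - config$h2) * sigma_a2 / config$h2
  y <- additive + stats::rnorm(length(additive), 0, sqrt(sigma_e2))
  names(y) <- rownames(genotypes$dosages)
  truth <- list(qtn_ids = map$marker_id[qtn],
                qtn_map = map[qtn, c("marker_id", "chrom", "pos")],
                effects = effects, additive = additive,
                sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = config$h2)
  g <- genotypes
  if (isTRUE(config$exclude_qtns)) {
    g$dosages <- g$dosages[, -qtn, drop = FALSE]
    g$map <- g$map[-qtn, , drop = FALSE]
    rownames(g$map) <- NULL
  }
  list(phenotype = y, truth = truth, genotypes = g)
}

#' Add opposite mean shifts to two groups (structured non-genetic effect)
#'
#' One group is shifted by `+shift_fraction * sd(y)`, another by the same
#' amount downward; remaining groups are unchanged.
#'
#' @param phenotype named numeric vector.
#' @param groups group label per sample.
#' @param shift_fraction fraction of the phenotypic SD to shift by (0.5 in
#'   the structured-confounding experiments).
#' @param up,down labels of the raised / lowered groups (default: first two
#'   distinct labels).
#' @return shifted phenotype vector.
#' @export
add_group_shift <- function(phenotype, groups, shift_fraction,
                            up = NULL, down = NULL) {
  stopifnot(length(groups) == length(phenotype))
  labs <- unique(groups)
  if (length(labs) < 2) stop("need at least 2 groups")
  if (is.null(up)) up <- labs[1]
  if (is.null(down)) down <- labs[2]
  if (!all(c(up, down) %in% labs)) stop("unknown group label")
  s <- shift_fraction * stats::sd(phenotype)
  phenotype[groups == up] <- phenotype[groups == up] + s
  phenotype[groups == down] <- phenotype[groups == down] - s
  phenotype
}

#' Permute phenotype values (null phenotype), keeping sample ids fixed
#' @param phenotype named numeric vector.
#' @param seed random seed.
#' @return permuted phenotype with the original names.
#' @export
permute_phenotype <- function(phenotype, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- sample(as.numeric(phenotype))
  names(out) <- names(phenotype)
  out
}

#' Classify positives against simulated truth
#'
#' Positives are markers with `P <= threshold` (NA treated as not
#' significant).  A QTN counts as identified when some positive marker lies
#' within `window` bp of it (inclusive) on the same chromosome; positives
#' with no QTN within the window are false positives.  Type I error is
#' evaluated on markers outside every QTN window.
#'
#' @param scan substituted scan result.
#' @param truth truth list from [simulate_phenotype].
#' @param window matching window in bp (default 50,000).
#' @param threshold significance threshold on P.
#' @return list: `identified_qtns`, `false_positive_markers`, `n_positive`,
#'   `n_null_markers` (outside QTN windows), `n_null_positive`.
#' @export
classify_hits <- function(scan, truth, window = 5e4, threshold) {
  p <- scan$p_value
  pos_idx <- which(!is.na(p) & p <= threshold)
  qm <- truth$qtn_map
  near_qtn <- rep(FALSE, nrow(scan))
  identified <- character()
  for (i in seq_len(nrow(qm))) {
    same <- scan$chrom == qm$chrom[i] & abs(scan$pos - qm$pos[i]) <= window
    near_qtn <- near_qtn | same
    if (any(same[pos_idx])) identified <- c(identified, qm$marker_id[i])
  }
  fp <- scan$marker_id[setdiff(pos_idx, which(near_qtn))]
  null_markers <- which(!near_qtn)
  list(identified_qtns = identified,
       false_positive_markers = fp,
       n_positive = length(pos_idx),
       n_null_markers = length(null_markers),
       n_null_positive = sum(pos_idx %in% null_markers))
}

#' Power / FDR / Type I error across replicates and thresholds
#'
#' Power is the proportion of QTNs identified; FDR the proportion of
#' positives not within `window` of any QTN (0 when there are no
#' positives); Type I error the proportion of outside-window markers called
#' positive.  All averaged over replicates.
#'
#' @param scans list of substituted scan results (one per replicate).
#' @param truths list of matching truth objects.
#' @param window matching window in bp.
#' @param thresholds numeric vector of significance thresholds.
#' @return data.frame with columns `threshold`, `power`, `fdr`,
#'   `type1_error`.
#' @export
power_fdr_type1_curves <- function(scans, truths, window = 5e4,
                                   thresholds = 10^seq(-8, -2)) {
  stopifnot(length(scans) == length(truths))
  rows <- lapply(thresholds, function(th) {
    pw <- fdr <- t1 <- numeric(length(scans))
    for (r in seq_along(scans)) {
      cl <- classify_hits(scans[[r]], truths[[r]], window, th)
      pw[r] <- length(cl$identified_qtns) / nrow(truths[[r]]$qtn_map)
      fdr[r] <- if (cl$n_positive == 0) 0 else
        length(cl$false_positive_markers) / cl$n_positive
      t1[r] <- if (cl$n_null_markers == 0) 0 else
        cl$n_null_positive / cl$n_null_markers
    }
    data.frame(threshold = th, power = mean(pw), fdr = mean(fdr),
               type1_error = mean(t1))
  })
  do.call(rbind, rows)
}

#' Power at a matched empirical Type I error
#'
#' For each replicate the significance threshold is set to the empirical
#' quantile of the null (outside-window) P values that yields the requested
#' Type I error, and power is evaluated there; results are averaged.
#'
#' @param scans,truths replicate-aligned lists.
#' @param window matching window in bp.
#' @param type1 target Type I error (e.g. 1e-4).
#' @return mean power across replicates.
#' @export
power_at_type1 <- function(scans, truths, window = 5e4, type1 = 1e-4) {
  pw <- numeric(length(scans))
  for (r in seq_along(scans)) {
    scan <- scans[[r]]; truth <- truths[[r]]
    qm <- truth$qtn_map
    near <- rep(FALSE, nrow(scan))
    for (i in seq_len(nrow(qm)))
      near <- near | (scan$chrom == qm$chrom[i] &
                        abs(scan$pos - qm$pos[i]) <= window)
    pnull <- sort(scan$p_value[!near & !is.na(scan$p_value)])
    k <- max(1L, floor(type1 * length(pnull)))
    th <- pnull[k]
    cl <- classify_hits(scan, truth, window, th)
    pw[r] <- length(cl$identified_qtns) / nrow(qm)
  }
  mean(pw)
}

#' Candidate-gene enrichment coefficient
#'
#' Gene regions are the union of gene intervals extended by `extension` bp
#' on either side, clipped to the genome; the coefficient is the hit density
#' inside gene regions divided by the density outside.  `Inf` when all hits
#' are inside, `NaN` when there are no hits.
#'
#' @param hits data.frame with columns `chrom`, `pos` (associated SNPs).
#' @param gene_intervals data.frame `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @param genome_intervals data.frame `chrom`, `start`, `end` covering the
#'   genome.
#' @param extension bp added on either side of each gene (default 10,000).
#' @return the enrichment coefficient (scalar).
#' @export
enrichment_coefficient <- function(hits, gene_intervals, genome_intervals,
                                   extension = 1e4) {
  merge_len <- function(iv) {
    # union length of 1-based inclusive intervals, per chromosome
    tot <- 0
    ends <- list()
    for (cc in unique(iv$chrom)) {
      s <- iv[iv$chrom == cc, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      cur_s <- s$start[1]; cur_e <- s$end[1]
      merged <- list()
      for (i in seq_len(nrow(s))[-1]) {
        if (s$start[i] <= cur_e + 1) cur_e <- max(cur_e, s$end[i])
        else { merged[[length(merged) + 1]] <- c(cur_s, cur_e)
               cur_s <- s$start[i]; cur_e <- s$end[i] }
      }
      merged[[length(merged) + 1]] <- c(cur_s, cur_e)
      mm <- do.call(rbind, merged)
      tot <- tot + sum(mm[, 2] - mm[, 1] + 1)
      ends[[cc]] <- mm
    }
    list(length = tot, merged = ends)
  }
  # extend genes and clip to genome bounds
  g <- gene_intervals
  g$start <- g$start - extension
  g$end <- g$end + extension
  for (i in seq_len(nrow(g))) {
    gb <- genome_intervals[genome_intervals$chrom == g$chrom[i], ]
    if (nrow(gb) == 0) stop("gene interval outside the genome")
    g$start[i] <- max(g$start[i], min(gb$start))
    g$end[i] <- min(g$end[i], max(gb$end))
  }
  gene <- merge_len(g)
  total_len <- merge_len(genome_intervals)$length
  len_in <- gene$length
  len_out <- total_len - len_in
  if (len_in <= 0 || len_out <= 0)
    stop("degenerate region classes (zero length)")
  in_gene <- vapply(seq_len(nrow(hits)), function(i) {
    mm <- gene$merged[[hits$chrom[i]]]
    !is.null(mm) && any(hits$pos[i] >= mm[, 1] & hits$pos[i] <= mm[, 2])
  }, logical(1))
  h_in <- sum(in_gene); h_out <- nrow(hits) - h_in
  if (h_in + h_out == 0) return(NaN)
  if (h_out == 0) return(Inf)
  (h_in / len_in) / (h_out / len_out)
}
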