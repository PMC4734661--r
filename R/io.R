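#' Genotype dataset container
#'
#' Bundles an additive-dosage matrix (samples x markers, values in \[0, 2\],
#' `NA` for missing before imputation) with a marker map.  The map is kept
#' sorted by position within each chromosome; the original file column order
#' is preserved in the `orig_order` column of the map.
#'
#' @param dosages numeric matrix, n samples x m markers.  Row names are
#'   sample ids, column names marker ids.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based base pairs), one row per marker, in dosage column order.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosages` (matrix) and `map` (data.frame with an added `orig_order`).
#' @export
genotype_dataset <- function(dosages, map) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(map)))
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(dosages))
    stop("dimension mismatch: ", ncol(dosages), " genotype columns but ",
         nrow(map), " map records")
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids in map")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("s", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample ids")
  if (any(map$pos < 1L, na.rm = TRUE))
    stop("positions must be >= 1")
  if (is.null(map$orig_order)) map$orig_order <- seq_len(nrow(map))
  # enforce sort by (chrom, pos) so that binning can assume ordered maps
  o <- order(map$chrom, map$pos, map$marker_id)
  map <- map[o, , drop = FALSE]
  dosages <- dosages[, o, drop = FALSE]
  colnames(dosages) <- map$marker_id
  rownames(map) <- NULL
  ok <- range(dosages, na.rm = TRUE)
  if (is.finite(ok[1]) && (ok[1] < 0 || ok[2] > 2))
    stop("dosages must lie in [0, 2]")
  structure(list(dosages = dosages, map = map), class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers, %d chromosome(s), %d missing\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chrom)), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

sample_ids <- function(g) rownames(g$dosages)

#' Read genotypes and marker map from delimited text
#'
#' The genotype file has a header row of marker ids and the sample id in the
#' first column (one row per sample); `transposed = TRUE` accepts the
#' markers-as-rows layout instead.  The map file has columns
#' `marker_id`, `chrom`, `pos`.  Missing entries are flagged as `NA`,
#' not imputed.
#'
#' @param genotype_path path to the dosage table (TSV/CSV autodetected).
#' @param map_path path to the marker map.
#' @param missing_code string coding missing genotypes (default "NA").
#' @param transposed if TRUE the genotype file is markers x samples.
#' @return a [genotype_dataset].
#' @export
read_genotypes <- function(genotype_path, map_path, missing_code = "NA",
                           transposed = FALSE) {
  gt <- data.table::fread(genotype_path, header = TRUE,
                          na.strings = missing_code, data.table = FALSE)
  if (ncol(gt) < 2) stop("genotype file needs an id column plus markers")
  ids <- as.character(gt[[1]])
  mat <- as.matrix(gt[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  if (transposed) {
    mat <- t(mat)
    marker_ids <- ids
    ids <- colnames(gt)[-1]
    colnames(mat) <- marker_ids
  }
  rownames(mat) <- ids
  map <- data.table::fread(map_path, header = TRUE, data.table = FALSE)
  names(map)[1:3] <- c("marker_id", "chrom", "pos")
  if (!setequal(map$marker_id, colnames(mat)) ||
      nrow(map) != ncol(mat))
    stop("dimension mismatch between genotype matrix and map")
  # align map rows to genotype column order before construction
  map <- map[match(colnames(mat), map$marker_id), , drop = FALSE]
  genotype_dataset(mat, map)
}

#' Read a two-column phenotype table
#'
#' Column 1 is the sample id, column 2 the trait value.  Non-numeric values
#' become missing.
#'
#' @param path file path.
#' @return a data.frame with columns `sample_id`, `value` (class
#'   `phenotype`).
#' @export
read_phenotype <- function(path) {
  ph <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(ph) == 0 || ncol(ph) < 2) stop("empty or malformed phenotype file")
  out <- data.frame(sample_id = as.character(ph[[1]]),
                    value = suppressWarnings(as.numeric(ph[[2]])),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype", "data.frame")
  out
}

#' Read a covariate table (header row, sample id in first column)
#' @param path file path.
#' @return data.frame, first column `sample_id`, remaining columns numeric.
#' @export
read_covariates <- function(path) {
  cv <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(cv) < 2) stop("covariate file needs an id column plus covariates")
  out <- data.frame(sample_id = as.character(cv[[1]]), stringsAsFactors = FALSE)
  for (j in 2:ncol(cv)) out[[names(cv)[j]]] <- as.numeric(cv[[j]])
  out
}

#' Restrict genotypes, phenotype and covariates to shared samples
#'
#' The three inputs are restricted to the intersection of sample ids, in
#' genotype order; samples with a missing phenotype are dropped so that the
#' scan is a complete-case regression.
#'
#' @param genotypes a [genotype_dataset].
#' @param phenotype a phenotype data.frame from [read_phenotype].
#' @param covariates optional covariate data.frame (first column sample id).
#' @return list with elements `genotypes`, `y` (numeric vector) and
#'   `covariates` (numeric matrix or NULL), all aligned.
#' @export
align_samples <- function(genotypes, phenotype, covariates = NULL) {
  keep <- phenotype$sample_id[!is.na(phenotype$value)]
  ids <- sample_ids(genotypes)
  ids <- ids[ids %in% keep]
  if (!is.null(covariates)) ids <- ids[ids %in% covariates$sample_id]
  if (length(ids) < 2)
    stop("fewer than 2 samples shared across inputs")
  g <- genotypes
  g$dosages <- g$dosages[ids, , drop = FALSE]
  y <- phenotype$value[match(ids, phenotype$sample_id)]
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates[match(ids, covariates$sample_id), -1,
                               drop = FALSE])
    rownames(cv) <- ids
  }
  list(genotypes = g, y = stats::setNames(y, ids), covariates = cv)
}

#' Impute missing genotype dosages
#'
#' @param genotypes a [genotype_dataset].
#' @param strategy `"column_mean"` (per-marker mean dosage) or
#'   `"major_allele"` (most frequent observed dosage).
#' @return a [genotype_dataset] with no missing values; markers that are
#'   entirely missing are dropped with a warning.
#' @export
impute_missing <- function(genotypes, strategy = c("column_mean", "major_allele")) {
  strategy <- match.arg(strategy)
  X <- genotypes$dosages
  nmiss <- colSums(is.na(X))
  all_na <- nmiss == nrow(X)
  if (any(all_na)) {
    warning(sum(all_na), " marker(s) entirely missing; dropped")
    X <- X[, !all_na, drop = FALSE]
    genotypes$map <- genotypes$map[!all_na, , drop = FALSE]
    nmiss <- nmiss[!all_na]
  }
  for (j in which(nmiss > 0)) {
    x <- X[, j]
    fill <- if (strategy == "column_mean") mean(x, na.rm = TRUE) else {
      tab <- table(x[!is.na(x)])
      as.numeric(names(tab)[which.max(tab)])
    }
    x[is.na(x)] <- fill
    X[, j] <- x
  }
  genotypes$dosages <- X
  genotypes
}

#' Minor allele frequency per marker
#'
#' MAF is `min(p, 1 - p)` with `p = mean(dosage) / 2`.
#' @param genotypes imputed [genotype_dataset].
#' @return numeric vector, one entry per marker.
#' @export
marker_maf <- function(genotypes) {
  p <- colMeans(genotypes$dosages) / 2
  pmin(p, 1 - p)
}

#' Remove markers below a minor allele frequency threshold
#'
#' @param genotypes imputed [genotype_dataset].
#' @param threshold MAF threshold in \[0, 0.5\]; markers with MAF strictly
#'   below it are removed.
#' @return filtered [genotype_dataset].
#' @export
filter_by_maf <- function(genotypes, threshold) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  if (anyNA(genotypes$dosages)) stop("impute before MAF filtering")
  keep <- marker_maf(genotypes) >= threshold
  if (!any(keep)) stop("MAF filter removed every marker")
  genotypes$dosages <- genotypes$dosages[, keep, drop = FALSE]
  genotypes$map <- genotypes$map[keep, , drop = FALSE]
  rownames(genotypes$map) <- NULL
  genotypes
}

#' Write a scan result table
#'
#' Columns: `marker_id`, `chrom`, `pos`, `effect`, `se`, `t_stat`,
#' `p_value`, `is_pseudo_qtn`; not-estimable entries are written as `NA`.
#'
#' @param result scan result data.frame from [scan_genome] /
#'   [substitute_pvalues].
#' @param path output path (TSV).
#' @export
write_scan_result <- function(result, path) {
  cols <- c("marker_id", "chrom", "pos", "effect", "se", "t_stat",
            "p_value", "is_pseudo_qtn")
  stopifnot(all(cols %in% names(result)))
  data.table::fwrite(result[, cols], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write genotypes + map back to delimited text (round-trip partner of
#' [read_genotypes]).
#' @param genotypes a [genotype_dataset].
#' @param genotype_path,map_path output paths.
#' @export
write_genotypes <- function(genotypes, genotype_path, map_path) {
  df <- data.frame(sample = sample_ids(genotypes),
                   genotypes$dosages, check.names = FALSE)
  data.table::fwrite(df, genotype_path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(genotypes$map[, c("marker_id", "chrom", "pos")],
                     map_path, sep = "\t", quote = FALSE)
  invisible(genotype_path)
}
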