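# Orchestration of the iterative algorithm:
#   1. seed the pseudo-QTN set (empty unless prior candidates are supplied);
#   2. fixed-effect scan with pseudo QTNs as covariates;
#   3. substitution of pseudo-QTN P values;
#   4. stop unless some marker passes the Bonferroni-corrected threshold;
#   5. bin-grid pseudo-QTN reselection by the REML criterion;
#   6. LD pruning of the selected set;
#   7. stop when no new pseudo QTNs are added (or max iterations).

#' Run configuration
#'
#' @param threshold genome-wide significance level before Bonferroni
#'   correction (default 0.01).
#' @param max_iter maximum iterations (default 10).
#' @param substitution substitution method (default `"min"`).
#' @param grid a [bin_grid].
#' @param prune_threshold absolute-correlation pruning threshold (0.7).
#' @param qtn_threshold marginal P-value ceiling for pseudo-QTN candidacy
#'   (see [optimize_bin_grid]; default 0.01).
#' @param covariate_policy `"all_iterations"` keeps user covariates in every
#'   scan; `"first_iteration_only"` drops them once pseudo QTNs exist.
#' @param seed_qtns optional character vector of marker ids used as the
#'   initial pseudo-QTN set (prior knowledge).
#' @param strict_convergence if TRUE the loop stops only on set equality;
#'   default stops as soon as no NEW pseudo QTN is added.
#' @param seed optional random seed recorded in the trace (the core
#'   algorithm is deterministic; the seed matters to callers that simulate).
#' @return list of class `farm_config`.
#' @export
farm_config <- function(threshold = 0.01, max_iter = 10L,
                        substitution = "min", grid = bin_grid(),
                        prune_threshold = 0.7, qtn_threshold = 0.01,
                        covariate_policy = c("all_iterations",
                                             "first_iteration_only"),
                        seed_qtns = NULL, strict_convergence = FALSE,
                        seed = NULL) {
  stopifnot(threshold > 0, threshold < 1, max_iter >= 1)
  structure(list(threshold = threshold, max_iter = as.integer(max_iter),
                 substitution = substitution, grid = grid,
                 prune_threshold = prune_threshold,
                 qtn_threshold = qtn_threshold,
                 covariate_policy = match.arg(covariate_policy),
                 seed_qtns = seed_qtns,
                 strict_convergence = strict_convergence, seed = seed),
            class = "farm_config")
}

#' Bonferroni significance gate
#'
#' TRUE iff the smallest P value passes `threshold / m`.
#'
#' @param scan substituted scan result.
#' @param threshold uncorrected significance level.
#' @param m number of tests (defaults to the scan's marker count).
#' @return logical.
#' @export
significance_gate <- function(scan, threshold, m = nrow(scan)) {
  p <- scan$p_value
  if (all(is.na(p))) return(FALSE)
  min(p, na.rm = TRUE) <= threshold / m
}

#' Convergence check on pseudo-QTN sets
#'
#' Default reading: converged iff the current set adds no NEW marker, i.e.
#' it is a subset of the previous set.  `strict = TRUE` requires equality.
#'
#' @param previous,current [pseudo_qtn_set]s.
#' @param strict require set equality.
#' @return logical.
#' @export
converged <- function(previous, current, strict = FALSE) {
  if (strict)
    setequal(previous$marker_ids, current$marker_ids)
  else
    all(current$marker_ids %in% previous$marker_ids)
}

#' Run the full iterative scan
#'
#' @param genotypes aligned, imputed [genotype_dataset] (no missing values).
#' @param y aligned numeric phenotype vector.
#' @param covariates optional numeric matrix of user covariates.
#' @param config a [farm_config].
#' @return list of class `farm_fit`: `scan` (final substituted scan),
#'   `pseudo` (final [pseudo_qtn_set]), `trace` (per-iteration data.frame),
#'   `status` (`"converged"`, `"no_signal"`, `"max_iter"`, or
#'   `"rem_non_converged"`).
#' @export
run_farmcpu <- function(genotypes, y, covariates = NULL,
                        config = farm_config()) {
  if (anyNA(genotypes$dosages)) stop("impute genotypes before running")
  if (anyNA(y)) stop("phenotype contains missing values after alignment")
  m <- ncol(genotypes$dosages)
  pseudo <- pseudo_qtn_set(iteration = 0L)
  if (!is.null(config$seed_qtns) && length(config$seed_qtns)) {
    ids <- intersect(as.character(config$seed_qtns),
                     genotypes$map$marker_id)
    if (length(ids) == 0)
      warning("none of the seed pseudo QTNs are present; starting empty")
    # seeds have no P value yet; rank them in given order
    pseudo <- pseudo_qtn_set(ids, seq_along(ids) * .Machine$double.eps,
                             iteration = 0L)
  }
  trace <- list()
  scan <- NULL
  status <- "max_iter"
  keep_pmat <- identical(config$substitution, "median")
  for (iter in seq_len(config$max_iter)) {
    cv <- covariates
    if (!is.null(cv) && config$covariate_policy == "first_iteration_only" &&
        length(pseudo) > 0) cv <- NULL
    ctx <- suppressWarnings(build_design(cv, pseudo, genotypes))
    scan <- scan_genome(ctx, y, genotypes, keep_pmatrix = keep_pmat)
    scan <- substitute_pvalues(scan, pseudo, config$substitution)
    n_sig <- sum(scan$p_value <= config$threshold / m, na.rm = TRUE)
    rec <- data.frame(iteration = iter, n_pseudo = length(pseudo),
                      n_significant = n_sig, bin_size = NA_real_,
                      bin_count = NA_integer_, loglik = NA_real_,
                      stringsAsFactors = FALSE)
    rec$pseudo_ids <- I(list(pseudo$marker_ids))
    if (!significance_gate(scan, config$threshold, m)) {
      status <- if (iter == 1L) "no_signal" else "converged"
      trace[[iter]] <- rec
      break
    }
    sel <- tryCatch(
      optimize_bin_grid(scan, genotypes, y, config$grid,
                        qtn_threshold = config$qtn_threshold,
                        iteration = iter),
      error = function(e) NULL)
    if (is.null(sel) || !isTRUE(attr(sel, "converged"))) {
      # zero-heritability pathology in the REM: report the current scan
      status <- if (length(pseudo) == 0) "no_signal" else "rem_non_converged"
      trace[[iter]] <- rec
      break
    }
    cand_df <- data.frame(marker_id = sel$marker_ids,
                          p_value = sel$p_values,
                          stringsAsFactors = FALSE)
    new_set <- prune_correlated(cand_df, genotypes,
                                config$prune_threshold, iteration = iter)
    rec$bin_size <- attr(sel, "bin_size")
    rec$bin_count <- attr(sel, "bin_count")
    rec$loglik <- attr(sel, "loglik")
    rec$pseudo_ids <- I(list(new_set$marker_ids))
    trace[[iter]] <- rec
    if (converged(pseudo, new_set, config$strict_convergence)) {
      status <- "converged"
      break
    }
    pseudo <- new_set
  }
  structure(list(scan = scan, pseudo = pseudo,
                 trace = do.call(rbind, trace), status = status),
            class = "farm_fit")
}

#' @export
print.farm_fit <- function(x, ...) {
  cat(sprintf("farm_fit: %s after %d iteration(s); %d pseudo QTN(s); min P = %.3g\n",
              x$status, nrow(x$trace), length(x$pseudo),
              suppressWarnings(min(x$scan$p_value, na.rm = TRUE))))
  invisible(x)
}
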