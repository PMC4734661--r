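test_that("fixture genotypes are reproducible with block-local LD and the
           requested allele frequencies", {
  g1 <- generate_fixture_genotypes(80, 300, seed = 31)
  g2 <- generate_fixture_genotypes(80, 300, seed = 31)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$map, g2$map)

  # adjacent same-block |r| exceeds cross-block |r| on average
  blocks <- paste(g1$map$chrom, floor((g1$map$pos - 1) / 1e5))
  within <- cross <- numeric()
  for (j in seq_len(ncol(g1$dosages) - 1)) {
    r <- suppressWarnings(abs(cor(g1$dosages[, j], g1$dosages[, j + 1])))
    if (is.na(r)) next
    if (blocks[j] == blocks[j + 1]) within <- c(within, r)
    else cross <- c(cross, r)
  }
  expect_gt(mean(within), mean(cross) + 0.2)

  # per-marker allele frequency within the requested range (empirical slack)
  p <- colMeans(g1$dosages) / 2
  expect_true(all(p > 0.05 - 3 * sqrt(0.05 * 0.95 / 160)))
  expect_true(all(p < 0.5 + 3 * sqrt(0.25 / 160)))
})

test_that("phenotype simulation follows the additive model and the residual
           variance formula", {
  g <- generate_fixture_genotypes(200, 400, seed = 32)

  # h2 = 1: phenotype equals the additive values exactly
  sim1 <- simulate_phenotype(g, sim_config(10, 1, seed = 33))
  expect_equal(unname(sim1$phenotype), unname(sim1$truth$additive))
  expect_equal(sim1$truth$sigma_e2, 0)

  # geometric effects: a^i, consecutive ratio exactly a
  sim2 <- simulate_phenotype(g, sim_config(5, 0.5, a = 0.9, seed = 34))
  expect_equal(sim2$truth$effects[3], 0.729)
  expect_equal(sim2$truth$effects[-1] / sim2$truth$effects[-5],
               rep(0.9, 4))

  # residual variance formula: sigma_e2 = (1 - h2) sigma_a2 / h2
  expect_equal(sim2$truth$sigma_e2,
               0.5 * sim2$truth$sigma_a2 / 0.5)

  # QTN exclusion drops the QTN columns from the returned view
  sim3 <- simulate_phenotype(g, sim_config(8, 0.5, exclude_qtns = TRUE,
                                           seed = 35))
  expect_equal(ncol(sim3$genotypes$dosages), 392L)
  expect_false(any(sim3$truth$qtn_ids %in% sim3$genotypes$map$marker_id))

  # restricted placement
  sim4 <- simulate_phenotype(g, sim_config(6, 0.5,
                                           chrom_subset = c("chr1", "chr2"),
                                           seed = 36))
  expect_true(all(sim4$truth$qtn_map$chrom %in% c("chr1", "chr2")))

  # Monte-Carlo: mean realized heritability near the target (small scale;
  # the acceptance suite runs the full 200-replicate version)
  set.seed(37)
  h <- replicate(60, {
    s <- simulate_phenotype(g, sim_config(20, 0.5))
    var(s$truth$additive) / var(s$phenotype)
  })
  expect_equal(mean(h), 0.5, tolerance = 0.03)
})

test_that("group shifts move two groups by +/- the stated SD fraction", {
  set.seed(38)
  y <- rnorm(400)
  groups <- rep(c("g1", "g2"), each = 200)
  expect_identical(add_group_shift(y, groups, 0), y)
  ys <- add_group_shift(y, groups, 0.5)
  expect_equal(mean(ys[1:200]) - mean(ys[201:400]),
               mean(y[1:200]) - mean(y[201:400]) + 2 * 0.5 * sd(y))
  # two equal groups at +/- 0.5 sigma: between-group share c^2/(s^2+c^2) = 0.2
  set.seed(39)
  y2 <- rnorm(2e5)
  y2 <- y2 / sd(y2)
  ys2 <- add_group_shift(y2, rep(c("a", "b"), 1e5), 0.5)
  grand <- c(mean(ys2[seq(1, 2e5, 2)]), mean(ys2[seq(2, 2e5, 2)]))
  between <- var(rep(grand, each = 1e5)) * (2e5 - 1) / 2e5
  expect_equal(between / (var(ys2) * (2e5 - 1) / 2e5), 0.2, tolerance = 0.01)
  expect_error(add_group_shift(y, groups, 0.5, up = "zzz"), "unknown")
})

test_that("phenotype permutation preserves values and reproduces by seed", {
  y <- setNames(rnorm(50), paste0("s", 1:50))
  p1 <- permute_phenotype(y, seed = 40)
  expect_identical(sort(unname(p1)), sort(unname(y)))
  expect_identical(names(p1), names(y))
  expect_identical(p1, permute_phenotype(y, seed = 40))
  set.seed(41)
  r <- replicate(200, cor(y, permute_phenotype(y)))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("hit classification matches exhaustive enumeration", {
  map <- data.frame(marker_id = sprintf("m%03d", 1:100), chrom = "chr1",
                    pos = seq(1e4, 1e6, length.out = 100))
  scan <- data.frame(map, p_value = 1, is_pseudo_qtn = FALSE)
  truth <- list(qtn_ids = c("m010", "m050"),
                qtn_map = data.frame(marker_id = c("m010", "m050"),
                                     chrom = "chr1",
                                     pos = map$pos[c(10, 50)]))

  # no positives
  cl0 <- classify_hits(scan, truth, window = 5e4, threshold = 1e-4)
  expect_equal(length(cl0$identified_qtns), 0L)
  expect_equal(length(cl0$false_positive_markers), 0L)

  # marker exactly `window` away is inclusive
  scan2 <- scan
  scan2$p_value[11] <- 1e-9
  w <- abs(map$pos[11] - map$pos[10])
  cl1 <- classify_hits(scan2, truth, window = w, threshold = 1e-4)
  expect_true("m010" %in% cl1$identified_qtns)
  cl1b <- classify_hits(scan2, truth, window = w - 1, threshold = 1e-4)
  expect_false("m010" %in% cl1b$identified_qtns)

  # random assignment vs exhaustive enumeration
  set.seed(42)
  scan3 <- scan
  scan3$p_value <- runif(100)
  th <- 0.1; wd <- 4e4
  cl3 <- classify_hits(scan3, truth, window = wd, threshold = th)
  pos_idx <- which(scan3$p_value <= th)
  ident <- fp <- character()
  for (q in 1:2) {
    near <- abs(map$pos - truth$qtn_map$pos[q]) <= wd
    if (any(near[pos_idx])) ident <- c(ident, truth$qtn_ids[q])
  }
  for (i in pos_idx) {
    if (all(abs(truth$qtn_map$pos - map$pos[i]) > wd))
      fp <- c(fp, map$marker_id[i])
  }
  expect_setequal(cl3$identified_qtns, ident)
  expect_setequal(cl3$false_positive_markers, fp)
})

test_that("evaluation curves match hand computation and are monotone", {
  map <- data.frame(marker_id = paste0("m", 1:10), chrom = "c1",
                    pos = (1:10) * 1e5)
  mk_scan <- function(p) data.frame(map, p_value = p, is_pseudo_qtn = FALSE)
  truth <- list(qtn_ids = "m5",
                qtn_map = data.frame(marker_id = "m5", chrom = "c1",
                                     pos = 5e5))
  scans <- list(mk_scan(c(rep(0.5, 4), 1e-6, rep(0.5, 5))),
                mk_scan(c(1e-6, rep(0.5, 9))),
                mk_scan(rep(0.5, 10)))
  truths <- list(truth, truth, truth)
  cv <- power_fdr_type1_curves(scans, truths, window = 1e4,
                               thresholds = c(1e-4, 0.6))
  # threshold 1e-4: rep1 hits the QTN (power 1, fdr 0), rep2 one false
  # positive (fdr 1), rep3 nothing (fdr 0 by convention)
  expect_equal(cv$power, c(1 / 3, 1))
  expect_equal(cv$fdr[1], 1 / 3)
  # type I at 1e-4: rep2 has 1 of 9 null markers positive
  expect_equal(cv$type1_error[1], mean(c(0, 1 / 9, 0)))
  # all markers positive at 0.6 -> power 1, monotone in the threshold
  expect_true(all(diff(cv$power) >= 0))
  expect_true(all(diff(cv$type1_error) >= 0))

  # marker reordering leaves the curves unchanged
  perm <- sample(10)
  scans_p <- lapply(scans, function(s) s[perm, ])
  expect_equal(power_fdr_type1_curves(scans_p, truths, 1e4, c(1e-4, 0.6)),
               cv)
})

test_that("enrichment coefficient follows the density-ratio definition", {
  genome <- data.frame(chrom = "c1", start = 1, end = 1e6)
  genes <- data.frame(chrom = "c1", start = c(1e5, 5e5), end = c(15e4, 55e4))

  # equal density inside and out (extension 0 keeps arithmetic easy):
  # gene length 100,002 bp; place hits proportionally
  hits_eq <- data.frame(chrom = "c1",
                        pos = c(12e4, 52e4, 2e5, 3e5, 4e5, 6e5, 7e5, 8e5,
                                9e5, 95e4, 99e4, 25e4, 35e4, 45e4, 65e4,
                                75e4, 85e4, 15e4 + 1e4))
  inside <- c(12e4, 52e4)
  co <- enrichment_coefficient(hits_eq[hits_eq$pos %in% inside, , drop = FALSE],
                               genes, genome, extension = 0)
  expect_equal(co, Inf)  # all hits inside
  expect_true(is.nan(enrichment_coefficient(hits_eq[0, , drop = FALSE],
                                            genes, genome, extension = 0)))

  # exact density ratio on a constructed case: 2 hits in 100,002 bp vs
  # 16 hits in the remaining 899,998 bp
  co2 <- enrichment_coefficient(hits_eq, genes, genome, extension = 0)
  len_in <- (15e4 - 1e5 + 1) + (55e4 - 5e5 + 1)
  expect_equal(co2, (2 / len_in) / (16 / (1e6 - len_in)))

  expect_error(enrichment_coefficient(hits_eq, genes,
                                      data.frame(chrom = "c1", start = 1,
                                                 end = 15e4),
                                      extension = 0), "degenerate")
})
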