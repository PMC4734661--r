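---
title: "farmscan: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{farmscan: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Single-marker GWAS must control two confounders — population structure and
polygenic background — without absorbing the very signal it is testing.
Mixed linear models fit a kinship matrix that is constant across marker
tests, so markers in LD with the kinship lose power; stepwise multi-locus
models fit selected markers as covariates but leave the kinship fixed.
`farmscan` implements the FarmCPU strategy: split the problem into two
models used iteratively,

* a **fixed-effect model (FEM)** that tests markers one at a time,

  $$y_i = M_{i1} b_1 + \dots + M_{it} b_t + S_{ij} d_j + e_i,$$

  where the $M$ columns are the dosages of $t$ currently selected
  *pseudo QTNs* (associated markers standing in for unknown causal loci)
  and $d_j$ is the effect of the tested marker $j$; and

* a **random-effect model (REM)** used only to choose the pseudo QTNs,

  $$y_i = u_i + e_i, \qquad \operatorname{Var}(u) = 2K\sigma_a^2,$$

  where $K$ is a genomic relationship matrix built from the candidate
  pseudo-QTN dosages alone.  Candidate sets are compared by their REML
  value, so the number of free parameters stays at two regardless of how
  many pseudo QTNs are considered.

The loop: scan (FEM) → unify pseudo-QTN P values by substitution → stop if
nothing passes the Bonferroni gate → re-select pseudo QTNs from genomic
bins by REML → prune correlated selections → repeat until no new pseudo
QTN is added or the iteration cap is reached.

## Numerical route

The FEM design `[1 | covariates | pseudo QTNs]` is factored once per
iteration; each marker test is a rank-one update of the cached
cross-product inverse, so a scan costs $O(nm)$ for fixed design width.
Columns are checked for linear dependence with a relative squared-residual
tolerance of `1e-8`; a tested marker that fails it (e.g. a duplicate of a
pseudo QTN) gets the not-estimable sentinel.  Perfect fits (zero residual
variance) report the floor P value `1e-300` with a `perfect_fit` flag.
Tests are two-sided t tests on the marker coefficient.

During a scan every pseudo QTN also gets a coefficient P value in each
marker model, the $t \times m$ matrix behind **substitution**.  Running
min/mean/max summaries are accumulated streaming; the full matrix is
materialized only for median substitution.  The default substitution is
`min` (the most significant value), which the source experiments found the
most powerful; `onsite` (the fit without a testing marker) reproduces the
stepwise-regression convention.

The REM never forms $K$: the centered pseudo-QTN matrix $Z$ (VanRaden
centering at $2\hat p$, rescaled so $\operatorname{mean(diag}K) = 1$) is
decomposed by thin SVD, and the restricted likelihood at a variance ratio
$\delta = \sigma_e^2/\sigma_a^2$ uses only the $t$ nonzero eigenvalues plus
the pooled orthogonal complement — $O(n)$ per evaluation.  $\delta$ is
optimized on a 100-point log grid on $[10^{-5}, 10^5]$ refined by Brent
search; a likelihood flat across the grid is flagged non-converged (the
zero-heritability pathology) and the driver then reports the current scan
with a `no_signal` status instead of failing.  "Minimum REML value" is
read as minimum $-2\times$ restricted log-likelihood, i.e. maximum
restricted likelihood: a literal minimum would select the worst-fitting
candidate set.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| significance gate | 0.01 Bonferroni-corrected | Step-4 stop rule |
| bin sizes | 0.5, 5, 50 Mb | the documented grid |
| bin counts | 10..100 step 10 | the documented grid |
| pseudo-QTN cap | $\lfloor n/\log_{10} n\rfloor$ | detection capacity of the sample |
| prune threshold | abs Pearson r 0.7 | near-collinear covariates destabilize the FEM |
| substitution | min | most powerful variant in the source experiments |
| `qtn_threshold` | 0.01 | see below |
| matching window | 50 kb | power/FDR evaluation convention |
| enrichment extension | 10 kb | gene-region convention |

**Deviation — pseudo-QTN candidacy threshold.** The design we inherited
called for no P-value pre-filter on bin representatives (selection purely
likelihood-driven).  Implemented that way, markers with null-level P values
get selected as pseudo QTNs on truly empty chromosomes and are then branded
significant by min-substitution (which is an extreme order statistic over
all $m$ tests): the measured Type I error on QTN-free chromosomes doubled
at $\alpha = 0.01$.  We therefore gate candidacy at a marginal P value of
0.01 (the same level as the Step-4 gate, and what reference
implementations of this algorithm do): a marker may only become a pseudo
QTN if it was already inside the $\alpha = 0.01$ budget, so substitution
cannot create significance out of noise.  `qtn_threshold = 1` restores the
ungated behavior.

Correlation pruning uses |r| because negative LD is equally collinear; the
greedy sweep runs in significance order and keeps a candidate only if it is
below the threshold against every kept one.  Bins restart at chromosome
boundaries.  Convergence defaults to "no *new* pseudo QTN added" (a subset
of the previous set converges); `strict_convergence = TRUE` requires set
equality — both readings of the stop rule are defensible and both are
exposed.

## The simulator and what a green test establishes

Fixture genotypes are sums of two haplotypes; within fixed-length LD blocks
every marker of a haplotype is copied from one latent uniform draw per
individual, then mutated with probability 0.15, so within-block correlation
(~0.5–0.7) exceeds cross-block correlation (~0).  Per-marker allele
frequencies are uniform on [0.05, 0.5]; positions are uniform within
chromosomes (default five, 10 kb mean spacing).  This emulates block LD and
allele-frequency spectra, but **not** population structure, relatedness,
cross-chromosome LD, rare variants, or genotyping error — so a green null
test here shows the statistics are right, not that real-data confounding is
handled; structured confounding can be injected explicitly with
`add_group_shift()`.

Phenotypes: QTNs sampled uniformly without replacement, effect of the
$i$-th QTN $a^i$ (defaults $a \in \{0.9, 0.95, 1\}$; $a = 1$ is the
equal-effect model), additive values are the QTN dosage submatrix times the
effects, and the residual variance is
$\sigma_e^2 = (1 - h^2)\,\sigma_a^2 / h^2$ with $\sigma_a^2$ the *realized*
(empirical) additive variance, so realized heritability concentrates at the
target — the acceptance suite verifies a mean within ±0.02 of 0.5 and 0.30
over 200 replicates.

Null-calibration tests use `ld_block_length = 1` (effectively independent
markers) because the binomial and Kolmogorov–Smirnov reference
distributions assume independent tests; LD-rich fixtures are used wherever
binning and pruning are the point.

Evaluation conventions: a QTN counts as identified if a positive marker
lies within the window (inclusive, same chromosome); FDR is 0 when there
are no positives; Type I error is computed on markers outside every QTN
window; the enrichment coefficient is the hit density in extended gene
regions over the density outside, with +Inf / NaN sentinels for the
degenerate all-inside / no-hits cases.

## Known limitations

* **Substituted P values are order statistics.**  A pseudo QTN's reported
  P value is the minimum over all $m$ marker tests of a previous scan.  On
  empty chromosomes the pseudo set admits about $\alpha \cdot m_{null}$
  markers per scan even with the candidacy gate, and these stay below
  $\alpha$ in the final output *on top of* the final scan's own fresh
  $\alpha$ budget.  At desk scale ($m = 3{,}000$) this roughly doubles the
  pooled Type I error at $\alpha = 0.01$ — the acceptance suite leaves that
  check red deliberately — while at real-data marker counts ($10^5$–$10^6$)
  the same absolute excess is far inside the binomial interval.  Ordinary
  (non-pseudo) markers are calibrated to slightly conservative throughout.
* The REM carries no user covariates (the model as written has none); the
  FEM does.
* Binary traits, dominance/epistasis terms, VCF/PLINK parsing, and
  principal-component computation are out of scope; covariates such as PCs
  are supplied, not computed.
* With weak dense signal (e.g. 100 QTNs at $h^2 = 0.5$, $n = 300$) the
  pseudo-QTN set churns and runs typically end at the iteration cap rather
  than by convergence; results remain well-defined (the last scan is
  reported) but are less stable than in sparse-signal regimes.
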