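---
title: "Cross-trait pleiotropy with conditional FDR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait pleiotropy with conditional FDR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocfdr)
```

# The problem

Two complex traits — the motivating pair is late-onset Alzheimer's disease
(LOAD) and major depressive disorder (MDD) — can share causal variants even
when neither trait's GWAS is powered to reach genome-wide significance at
those variants. Given only the two studies' per-SNP summary statistics
(effect size, standard error, p-value), this package asks three questions:

1. **Is there polygenic overlap at all?** Stratified fold-enrichment and
   conditional quantile–quantile (Q–Q) curves show whether SNPs with strong
   evidence in trait B are enriched for association with trait A.
2. **Which SNPs?** A conditional false discovery rate (cFDR) re-ranks trait
   A's p-values using trait B's, and the conjunction cFDR bounds the
   probability that a SNP is null for *either* trait.
3. **Is the relationship causal?** Two-sample MR-Egger regression with
   trait-A instruments estimates the causal effect on trait B and tests for
   directional horizontal pleiotropy via its intercept.

# Harmonization and filtering

Both inputs are reduced to one internal schema (log-odds `beta`, `se`, `p`,
alleles, optional INFO and MAF). Odds ratios are log-transformed at load
time; the SE is assumed to be on the log-odds scale already, the convention
for logistic-regression GWAS output. Row validity rules: `p` in (0, 1]
(`p = 0` is clamped to the smallest positive double, because the cFDR grid
works on −log10 p), `se > 0`, `pos >= 1`, distinct alleles, unique rsIDs.

Allele harmonization joins on rsID and recognises four orientations of the
second table relative to the first — identity, swap (effect negated), strand
complement, complement+swap (negated) — and drops everything else. Effect
magnitudes are never changed, only signs and labels, and the fix is
idempotent. Strand-ambiguous (A/T, C/G) SNPs are dropped by default: without
allele-frequency comparison they cannot be oriented, and a frequency-based
rescue is deliberately out of scope. Rows with missing INFO or MAF pass the
respective filters with a warning, because the two consortium dialects
differ in which columns they report and a silent empty table is worse than
an unfiltered one. The INFO filter keeps the half-open interval
`0.6 <= INFO < 1.06`; the MAF filter is strict (`maf > 0.01`) after folding
frequencies onto (0, 0.5].

Region exclusion (used for the APOE analysis, hg19
chr19:45,111,942–45,711,941, available as `apoe_region()`) is inclusive on
both boundaries, matching 1-based inclusive coordinate quoting;
`exclude_region()`/`select_region()` partition the table exactly.

# LD operations

Pairwise LD comes from a reference dosage panel: `r^2` is the squared
Pearson correlation of dosage vectors; `D'` is |D| normalized by its
frequency-bound maximum, counted directly on phased panels and otherwise
estimated by the classical two-locus haplotype EM (50 iterations, tolerance
1e-10; non-convergence yields `NA`, never an error).

**Pruning** removes, within any pair closer than `window_kb` with
`r^2 > 0.2`, the member with the lower minor allele frequency
(summary-statistics MAF when present, else panel MAF; ties keep the smaller
primary p-value, then the lexicographically smaller rsID — no tie rule is
inherited, so one had to be chosen). Genome-wide all-pairs pruning is
quadratic, so pairs are only tested within a 1,000 kb window by default;
LD is local, and the test suite validates the windowed pass against an
unwindowed repeated-scan oracle on small data. The implementation processes
pairs in lexicographic (chrom, pos) order, which is provably identical to
repeatedly rescanning all pairs until none violates the threshold: the
result is a fixed point of the removal rule. SNPs missing from the panel
pass through (counted) — pruning should not silently discard data the panel
cannot vouch against.

**Clumping** (for MR instruments) is greedy by ascending p-value among SNPs
at `p <= 1e-8`: each surviving SNP becomes an index and discards candidates
within 10 kb or with `r^2 > 0.001` to it. Candidates missing from the panel
are dropped — the conservative choice in this role, since an unverifiable
candidate must not become an instrument. **Proxy search** returns SNPs
within a window with `r^2 > 0.9` and `D' = 1` (tolerance 1e-6), the common
criterion for substituting a missing SNP in eQTL lookups.

# Enrichment curves

For strata defined by secondary p-value thresholds `s` and grid points `t`
on −log10 p1:

$$FE_s(t) = \frac{\#\{p_2 \le s,\ p_1 \le 10^{-t}\}/\#\{p_2 \le s\}}
                 {\#\{p_1 \le 10^{-t}\}/N}.$$

The all-SNPs stratum (`s = 1`) is the baseline and equals 1 wherever
defined, whatever subset of SNPs is supplied. Default strata are
`p2 <= {1, 0.1, 0.01, 0.001}`, the four-curve convention of this analysis
family; empty cells are `NA` with a warning, never an error. Conditional
Q–Q curves pair observed −log10 p1 order statistics within each stratum
with uniform expectations `-log10(k/(n_s+1))`.

# Conditional FDR

The estimator is the empirical conditional-FDR lookup. For SNP `i`,

$$Q_i = \frac{p_{1i}}{\hat F(p_{1i} \mid p_2 \le p_{2i})},$$

with the conditional empirical CDF
$\hat F(p \mid p_2 \le s) = \#\{p_1 \le p, p_2 \le s\}/\#\{p_2 \le s\}$,
the null proportion fixed at 1 (a conservative upper bound — no null
proportion estimation procedure is inherited, and a Storey-style estimate
would only tighten results), values capped at 1, and a cumulative-minimum
pass along the p1 axis enforcing monotonicity within each conditioning
level. That last step is exactly what turns the raw Benjamini–Hochberg
ratio `p·N/rank` into the adjusted value, so with an uninformative
secondary trait (`p2 = 1` everywhere) the estimator reduces to
`stats::p.adjust(p, "BH")` — a property the tests verify to machine
precision.

Computation uses a 2-D lookup grid: 401 log-spaced p1 nodes down to 1e-20
by default (p-values beyond the smallest node are clamped onto it, never
dropped) crossed with conditioning levels −log10 p2 ∈ {0, 1, 2, 3},
extended one decade at a time while the conditioning subset keeps at least
`min_count` SNPs (default 100); empty levels are dropped with a warning.
Per-SNP values come from bilinear interpolation on the
(−log10 p1) × (−log10 p2) grid. Because the grid accepts arbitrary nodes,
placing one node at every observed data point makes the grid computation
*exactly* equal to the O(n²) direct-definition calculation — the test suite
exploits this to compare against an independent double-loop oracle at 1e-9.

Two numerical consequences worth knowing:

* **Conservativeness.** Since $\hat F \le 1$ and the interpolation is linear
  in −log10 p while $10^{-t}$ is convex, `Q >= p1` holds for every SNP.
* **No monotonicity across conditioning levels.** The empirical estimator
  does not guarantee that tightening the secondary threshold lowers Q; the
  cumulative minimum is applied along p1 only, as defined. The grid
  invariant tested is monotone non-decreasing FDR in p1 within each level.

Input order never matters: SNPs are sorted on (chrom, pos, rsID) before the
grid is built, and the module draws no random numbers.

The conjunction cFDR is the elementwise maximum of the two directional Q
values. Tier calls use inclusive thresholds — `genome_wide` at
`Q <= 5e-8`, `suggestive` at `Q <= 1e-5`, `significant` at `Q <= 0.05` —
and Manhattan reference lines sit at −log10(5e-8)/−log10(1e-5) for
conditional values and −log10(0.05)/−log10(0.1) for conjunction values.

# MR-Egger

Instruments are clumped trait-A SNPs at `p <= 1e-8` present in trait B,
oriented so every exposure effect is non-negative (without this convention
the Egger intercept is not identifiable). The fit is weighted least squares
of outcome effects on exposure effects with a free intercept and weights
`1/se_outcome^2`; standard errors come from the WLS covariance and
inference uses the t distribution with `n − 2` degrees of freedom (a
normal-approximation flag exists). This is the plain WLS estimator — no
rescaling of the standard error by a floor on the residual dispersion, and
no correction for exposure-side measurement error; both choices keep the
estimator exactly the textbook regression that the closed-form
normal-equations oracle reproduces to 1e-10. The intercept test reports
directional horizontal pleiotropy at a chosen alpha. The causal estimate is
reported on the odds-ratio scale as `exp(slope)` with an exp-transformed CI.

# The synthetic-data generator

The generator defines the study conditions every statistical claim is
tested under. It works at the summary level: simulating individual-level
phenotypes would be orders of magnitude slower and adds nothing for
statistics that only consume (beta, se, p) — the LD panel stays
individual-level where LD actually matters (pruning, clumping, proxies).

* **SNP grid**: 100,000 SNPs on 22 pseudo-chromosomes at 3 kb spacing, in
  LD blocks of mean 50 SNPs (1 + Poisson(49)).
* **Panel**: a founder-haplotype pool per block (200 founders). Founder
  alleles are serially correlated through a latent Gaussian AR(1)
  (correlation `exp(-d/50kb)` between adjacent SNPs) thresholded at each
  SNP's target frequency, and each individual haplotype is a founder mosaic
  with distance-dependent switch probability. Within-block r² therefore
  decays with distance; blocks are independent. Monomorphic SNPs are
  repaired by a single haplotype flip. Panels are phased, so D' needs no EM.
* **Effects**: each SNP is null / A-only / B-only / shared with
  probabilities (0.90, 0.025, 0.025, 0.05); causal effects are normal with
  SD 0.03 on the log-odds scale, shared effects bivariate with correlation
  0.8. These values give mid-single-digit fold enrichments and a handful of
  conditionally significant loci at the emulated sample sizes — the regime
  the method is designed for.
* **Sampling noise**: `se = 1/sqrt(2·maf·(1−maf)·n_eff)` with
  `n_eff = 4/(1/cases + 1/controls)`; defaults use the two consortium
  studies' sizes (21,982/41,944 and 59,851/113,154). Observed effects are
  true effects plus `N(0, se)`; p-values are two-sided Wald. Trait B is
  emitted with INFO ~ U(0.6, 1.05) and written to disk on the OR scale with
  a fraction of allele-swapped rows, so file round-trips exercise
  harmonization.
* **Dominant region**: `plant_apoe_like()` multiplies the trait-A effect SD
  of the *causal* SNPs inside a designated region by a factor (default 20),
  emulating a locus whose p-values sit far beyond the rest of the genome.
  Redrawing only causal SNPs makes factor 1 an exact distributional no-op,
  which pins down the operation's semantics in a testable way.

What the generator does **not** emulate: realistic human LD maps and allele
frequency spectra, population stratification, sample overlap between the
two GWAS, and LD-induced correlation of summary statistics between
neighbouring SNPs (true effects are drawn independently per SNP; noise is
independent too). Passing tests therefore demonstrate the statistical
machinery's correctness and calibration under clean conditions, not
robustness to confounded real data. Realized panel MAF scatters around the
nominal U(0.01, 0.5) spectrum by sampling noise.

Every generator is a pure function of (spec, seed); the seed is mandatory.

# Problem sizes and test design

The test and acceptance workloads are sized to what the statistics need,
not more: calibration uses 20 replicates of 50,000 independent null SNPs
(the false-discovery proportion under a global null is 0/1-valued per
replicate, so 20 replicates bound the family-wise call rate adequately);
enrichment properties use 20 replicates at the full default 100,000-SNP
grid without a panel (fold enrichment does not touch LD); MR coverage uses
500 replicates of 50 instruments; LD-heavy checks use panels of a few
hundred SNPs where exhaustive post-scans stay exact. Oracle comparisons
(cFDR double loop, pruning fixed point, clumping greedy order, WLS normal
equations) run on deliberately small inputs where the quadratic oracle is
itself trustworthy.

# Known limitations

* The cFDR estimator treats SNPs as exchangeable; no LD-score weighting or
  covariate adjustment is offered, and pruning is the only defence against
  LD-induced dependence (whether per-SNP tables should be computed on
  pruned or unpruned SNPs is genuinely ambiguous in this analysis family;
  the pipeline prunes for the curves and reports per-SNP values on the
  unpruned merge, and both stages are exposed directly).
* π0 = 1 is conservative; power is deliberately left on the table.
* MR-Egger here uses first-order weights and no NOME/I² diagnostics.
* Nearest-gene annotation ignores strand and regulatory context; reported
  gene lists are proximity statements, not causal claims.
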