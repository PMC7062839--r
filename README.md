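# pleiocfdr

Cross-trait pleiotropy analysis of GWAS summary statistics with
conditional false discovery rates.

## The problem

Two complex traits — the motivating pair is late-onset Alzheimer's disease
(LOAD) and major depressive disorder (MDD) — can share risk variants that
neither genome-wide association study detects on its own. Given only the two
studies' per-SNP summary statistics, `pleiocfdr`:

- **harmonizes** the two tables onto one allele orientation (OR → log-odds,
  swap/complement resolution, strand-ambiguous SNPs dropped);
- **prunes** correlated SNPs with a reference LD panel (the lower-MAF member
  of any pair with r² > 0.2 is removed);
- draws **stratified fold-enrichment** and **conditional Q–Q** curves:
  for strata `p₂ ≤ s` and grid points `t`,

  ```
  FE_s(t) = [#{p₂ ≤ s, p₁ ≤ 10⁻ᵗ} / #{p₂ ≤ s}] / [#{p₁ ≤ 10⁻ᵗ} / N]
  ```

- computes the per-SNP **conditional FDR** in both directions,

  ```
  Q(A|B)ᵢ = p₁ᵢ / F̂(p₁ᵢ | p₂ ≤ p₂ᵢ),   π₀ = 1, capped at 1,
  ```

  monotonized along p₁ by a cumulative minimum (the same step that turns
  `p·N/rank` into the Benjamini–Hochberg adjusted value), plus the
  **conjunction cFDR** `ccFDR = max(Q(A|B), Q(B|A))`;
- fits **two-sample MR-Egger** (WLS of outcome on exposure effects with a
  free intercept, weights 1/se², t inference with n−2 df) with the
  directional-pleiotropy intercept test, after instrument clumping at
  p ≤ 1e-8, r² 0.001, 10 kb;
- **annotates** significant SNPs with nearest genes and emits
  Manhattan/curve plot data and locus reports;
- ships a **synthetic-data generator** (block-LD panels, two-trait effect
  mixture with a tunable shared fraction, Wald-level summary statistics,
  a plantable APOE-like dominant region) so the whole pipeline is testable
  without any downloads.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and results have `autoplot()`/`plot_*()`
functions.

## Worked example

Simulate a two-trait study with 5% shared causal SNPs (effect correlation
0.8) and a dominant APOE-like region, then run the core analysis:

```r
library(pleiocfdr)

spec <- architecture_spec(n_snps = 20000, n_chrom = 4, seed = 2024,
                          apoe_like = list(chrom = "4", start = 2e6,
                                           end = 2.6e6, factor = 20))
study <- plant_apoe_like(simulate_sumstats(spec))
m     <- merge_study(study)

fold_enrichment(m, direction = "A|B") |> subset(t == 5)
#>  stratum t        fe n_stratum n_tail
#>    1.000 5  1.000000     20000    440
#>    0.100 5  4.497796      3052    302
#>    0.010 5 10.327214      1228    279
#>    0.001 5 13.007892       933    267
```

Fold enrichment at `-log10(p₁) = 5` rises from 1 (baseline) to ~13 as the
secondary-trait stratum tightens — the signature of pleiotropic enrichment.

```r
r_ab <- cfdr(m, "A|B")
table(call_significant(r_ab)$tier)
#>          ns significant  suggestive genome_wide
#>       19140         478         112         270
```

Of the SNPs reaching `Q ≤ 0.05`, 90% are truly causal for trait A in the
generator's truth table. MR-Egger on 50 simulated instruments with a true
causal odds ratio of 1.4:

```r
fit <- mr_egger(simulate_instruments(n_instruments = 50, seed = 2024))
fit
#> MR-Egger regression (50 instruments)
#>   slope        0.3164 (SE 0.0394), OR 1.372 [1.268, 1.485], p = 1.98e-10
#>   intercept    0.0079 (SE 0.0133), p = 0.555
mr_intercept_test(fit)$verdict
#> [1] "no significant directional pleiotropy"
```

The estimated OR of 1.372 [1.268, 1.485] covers the planted `exp(0.336) =
1.4`, and the intercept test finds no directional pleiotropy — as planted.

For file-based workflows, `run_pipeline()` executes the whole chain
(read → filter → harmonize → region exclusion → prune → curves → cFDR both
directions → conjunction → MR → annotation) from one YAML/list config and
writes tables, figures and a JSON manifest; `validate_config()` checks a
config without running it. `published_loci()` returns the bundled published
LOAD|MDD and MDD|LOAD conditional-FDR locus tables used by the reporting
tests.

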