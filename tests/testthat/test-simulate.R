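test_that("generators are pure functions of (spec, seed)", {
  spec <- architecture_spec(n_snps = 300, n_chrom = 2, seed = 41,
                            apoe_like = NULL)
  p1 <- simulate_panel(spec, n_individuals = 60)
  p2 <- simulate_panel(spec, n_individuals = 60)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$haplotypes, p2$haplotypes)
  s1 <- simulate_sumstats(spec)
  s2 <- simulate_sumstats(spec)
  expect_identical(s1$a, s2$a)
  expect_identical(s1$truth, s2$truth)
})

test_that("spec validation rejects bad mixtures, rho and maf bounds", {
  expect_error(architecture_spec(mixture = c(null = 0.5, a_only = 0.2,
                                             b_only = 0.2, shared = 0.2),
                                 seed = 1), "sum to 1")
  expect_error(architecture_spec(rho = 1.5, seed = 1), "\\[-1, 1\\]")
  expect_error(architecture_spec(maf_range = c(0, 0.5), seed = 1), "0 < lo")
  expect_error(architecture_spec(n_snps = 10), "seed")
})

test_that("single-SNP blocks give independent SNPs", {
  spec <- architecture_spec(n_snps = 200, n_chrom = 1, block_size_mean = 1,
                            apoe_like = NULL, seed = 42)
  pan <- simulate_panel(spec, n_individuals = 500)
  set.seed(1)
  pairs <- cbind(sample(200, 1000, replace = TRUE),
                 sample(200, 1000, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  r2 <- apply(pairs, 1, function(ij) {
    cor(pan$dosage[, ij[1]], pan$dosage[, ij[2]])^2
  })
  # under independence E[r2] ~ 1/(n-1); allow 3/n
  expect_lt(mean(r2, na.rm = TRUE), 3 / 500)
})

test_that("within-block LD exceeds between-block LD", {
  spec <- architecture_spec(n_snps = 300, n_chrom = 2, block_size_mean = 15,
                            apoe_like = NULL, seed = 43)
  pan <- simulate_panel(spec, n_individuals = 500)
  g <- pan$snps
  blocks <- pleiocfdr:::layout_snp_grid(spec)$block
  adj_same <- which(blocks[-1] == blocks[-length(blocks)])
  r2_within <- sapply(adj_same, function(i) {
    cor(pan$dosage[, i], pan$dosage[, i + 1])^2
  })
  set.seed(2)
  cross <- replicate(200, {
    ij <- sample(nrow(g), 2)
    if (blocks[ij[1]] == blocks[ij[2]]) NA
    else cor(pan$dosage[, ij[1]], pan$dosage[, ij[2]])^2
  })
  expect_gt(mean(r2_within, na.rm = TRUE), mean(cross, na.rm = TRUE))
})

test_that("emitted p-values are internally consistent with beta/se", {
  spec <- architecture_spec(n_snps = 2000, apoe_like = NULL, seed = 44)
  st <- simulate_sumstats(spec)
  for (t in list(st$a, st$b)) {
    z <- t$beta / t$se
    expect_lt(max(abs(t$p - pmax(2 * pnorm(-abs(z)), .Machine$double.xmin))),
              1e-12)
  }
})

test_that("emitted MAF equals the panel allele frequency", {
  spec <- architecture_spec(n_snps = 200, n_chrom = 2, apoe_like = NULL,
                            seed = 45)
  pan <- simulate_panel(spec, n_individuals = 100)
  st <- simulate_sumstats(spec, panel = pan)
  expect_equal(st$a$maf, pmin(pan$freq, 1 - pan$freq))
  expect_equal(st$a$maf, st$b$maf)
})

test_that("null p-values are uniform across seeded replicates", {
  crit_1pct <- 1.63 / sqrt(5000)  # asymptotic 1% KS critical value
  pass <- sapply(1:20, function(s) {
    spec <- architecture_spec(n_snps = 5000,
                              mixture = c(null = 1, a_only = 0, b_only = 0,
                                          shared = 0),
                              apoe_like = NULL, seed = 500 + s)
    st <- simulate_sumstats(spec)
    ks <- suppressWarnings(ks.test(st$a$p, "punif"))
    ks$statistic < crit_1pct
  })
  expect_gte(sum(pass), 18)
})

test_that("truth-table class counts follow the multinomial", {
  pvals <- sapply(1:5, function(s) {
    spec <- architecture_spec(n_snps = 20000, apoe_like = NULL, seed = 600 + s)
    st <- simulate_sumstats(spec)
    obs <- table(factor(st$truth$class,
                        levels = c("null", "a_only", "b_only", "shared")))
    suppressWarnings(chisq.test(obs, p = spec$mixture)$p.value)
  })
  expect_true(all(pvals > 0.001))
})

test_that("planting an extreme-effect region behaves as specified", {
  spec <- architecture_spec(n_snps = 20000, n_chrom = 4, seed = 46,
                            apoe_like = list(chrom = "2", start = 1e6,
                                             end = 1.6e6, factor = 20))
  st <- simulate_sumstats(spec)
  reg <- genomic_region("2", 1e6, 1.6e6)
  in_reg <- pleiocfdr:::in_region(st$a$chrom, st$a$pos, reg)
  expect_gt(sum(in_reg), 150)

  # factor 1 leaves the region distributionally indistinguishable
  st1 <- plant_apoe_like(st, region = list(chrom = "2", start = 1e6,
                                           end = 1.6e6, factor = 1))
  ks <- suppressWarnings(
    ks.test(abs(st1$a$beta[in_reg] / st1$a$se[in_reg]),
            abs(st1$a$beta[!in_reg] / st1$a$se[!in_reg])))
  expect_gt(ks$p.value, 0.01)

  # factor 20 produces extreme p-values inside the region
  st20 <- plant_apoe_like(st)
  expect_lt(min(st20$a$p[in_reg]), 1e-12)
  expect_gt(min(st20$a$p[in_reg]) / min(1, min(st$a$p[!in_reg])), 0)
  # truth updated: causal region SNPs carry inflated effects, classes intact
  causal <- in_reg & st$truth$class %in% c("a_only", "shared")
  expect_identical(st20$truth$class, st$truth$class)
  expect_gt(sd(st20$truth$beta_a[causal]), 3 * sd(st$truth$beta_a[causal]))
  expect_error(plant_apoe_like(st, region = list(chrom = "9", start = 1,
                                                 end = 2, factor = 2)),
               "no simulated SNPs")
})

test_that("extreme region p-values reach deep significance in most replicates", {
  hits <- sapply(1:20, function(s) {
    spec <- architecture_spec(n_snps = 5000, n_chrom = 2, seed = 700 + s,
                              apoe_like = list(chrom = "1", start = 1e6,
                                               end = 1.6e6, factor = 20))
    st <- plant_apoe_like(simulate_sumstats(spec))
    reg <- genomic_region("1", 1e6, 1.6e6)
    min(select_region(st$a, reg)$p) < 1e-12
  })
  expect_gte(sum(hits), 19)
})

test_that("written studies round-trip through the readers and harmonization", {
  spec <- architecture_spec(n_snps = 400, n_chrom = 2, seed = 47,
                            apoe_like = NULL, frac_b_swapped = 0.4)
  st <- simulate_sumstats(spec)
  genes <- simulate_genes(spec, genes_per_chrom = 5)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir, genes = genes)
  a <- read_sumstats(paths$a, schema_beta_dialect(), effect_scale = "beta")
  b <- read_sumstats(paths$b, schema_or_dialect(), effect_scale = "or")
  expect_equal(nrow(a), 400)
  # OR file re-converts to the original log-odds effects
  ord <- match(st$b$snp_id, b$snp_id)
  m <- harmonize(a, b)
  ordm <- match(m$snp_id, st$b$snp_id)
  # harmonization undoes the allele swap exactly
  expect_equal(m$beta2, st$b$beta[ordm], tolerance = 1e-12)
  g <- read_gene_intervals(paths$genes, format = "bed")
  expect_equal(nrow(g), 10)
  expect_equal(g$start, genes$start)
  expect_equal(g$end, genes$end)
})
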