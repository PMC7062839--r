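#' Specify a synthetic two-trait genetic architecture
#'
#' Collects every knob of the synthetic-data generator: the SNP grid (count,
#' pseudo-chromosomes, LD-block sizes, inter-SNP spacing), the allele
#' frequency spectrum, the four-component effect mixture (null / trait-A-only
#' / trait-B-only / shared), effect-size scales and the shared-effect
#' correlation, the two case-control sample sizes used for the Wald
#' standard-error approximation, and an optional extreme-effect region that
#' emulates a locus (like APOE in LOAD) strong enough to dominate
#' genome-wide statistics.
#'
#' Defaults emulate a down-scaled genome-wide study: 100,000 SNPs on 22
#' pseudo-chromosomes in LD blocks of ~50 SNPs, MAF uniform on (0.01, 0.5),
#' 5% shared causal SNPs with effect correlation 0.8, and the case/control
#' counts of the two consortium GWAS the package targets (21,982/41,944 and
#' 59,851/113,154).
#'
#' @param n_snps Total SNPs.
#' @param n_chrom Number of pseudo-chromosomes.
#' @param block_size_mean Mean LD-block size in SNPs (block sizes are
#'   1 + Poisson(mean - 1); use 1 for fully independent SNPs).
#' @param spacing_bp Base-pair spacing between adjacent grid SNPs.
#' @param maf_range Allele-frequency bounds (uniform draw).
#' @param mixture Named proportions `null`, `a_only`, `b_only`, `shared`;
#'   must be non-negative and sum to 1 within 1e-12.
#' @param sigma_a,sigma_b Effect-size SDs (log-odds scale) for causal SNPs.
#' @param rho Correlation of shared effects, in `[-1, 1]`.
#' @param n1_cases,n1_controls,n2_cases,n2_controls Sample sizes of the two
#'   studies.
#' @param apoe_like `NULL`, or a list `chrom`, `start`, `end`, `factor`
#'   describing the planted extreme-effect region (trait-A effect SD
#'   multiplied by `factor` inside the region).
#' @param frac_b_swapped Fraction of SNPs whose trait-B table is emitted with
#'   effect/other alleles swapped (and the effect negated), to exercise
#'   harmonization.
#' @param seed Mandatory integer seed; every stochastic operation derives
#'   from it.
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(n_snps = 1e5, n_chrom = 22, block_size_mean = 50,
                              spacing_bp = 3000,
                              maf_range = c(0.01, 0.5),
                              mixture = c(null = 0.90, a_only = 0.025,
                                          b_only = 0.025, shared = 0.05),
                              sigma_a = 0.03, sigma_b = 0.03, rho = 0.8,
                              n1_cases = 21982, n1_controls = 41944,
                              n2_cases = 59851, n2_controls = 113154,
                              apoe_like = list(chrom = "19", start = 6e6,
                                               end = 6.6e6, factor = 20),
                              frac_b_swapped = 0.25,
                              seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory for the generator.")
  stopifnot(length(mixture) == 4,
            all(c("null", "a_only", "b_only", "shared") %in% names(mixture)))
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-12) {
    abort("Mixture proportions must be non-negative and sum to 1 (within 1e-12).")
  }
  if (rho < -1 || rho > 1) abort("`rho` must lie in [-1, 1].")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] >= maf_range[2]) {
    abort("`maf_range` must satisfy 0 < lo < hi <= 0.5.")
  }
  structure(list(
    n_snps = as.integer(n_snps), n_chrom = as.integer(n_chrom),
    block_size_mean = block_size_mean, spacing_bp = spacing_bp,
    maf_range = maf_range,
    mixture = mixture[c("null", "a_only", "b_only", "shared")],
    sigma_a = sigma_a, sigma_b = sigma_b, rho = rho,
    n1_cases = n1_cases, n1_controls = n1_controls,
    n2_cases = n2_cases, n2_controls = n2_controls,
    apoe_like = apoe_like, frac_b_swapped = frac_b_swapped,
    seed = as.integer(seed)
  ), class = "architecture_spec")
}

n_eff <- function(cases, controls) 4 / (1 / cases + 1 / controls)

# deterministic SNP grid: ids, chromosomes, positions, LD-block assignment
layout_snp_grid <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_snps
  per_chrom <- rep(n %/% spec$n_chrom, spec$n_chrom)
  extra <- n - sum(per_chrom)
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(spec$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) seq_len(k) * spec$spacing_bp))
  # block sizes: 1 + Poisson(mean - 1), truncated at chromosome ends
  block <- integer(n)
  b <- 0L
  i <- 1L
  for (ch in seq_len(spec$n_chrom)) {
    left <- per_chrom[ch]
    while (left > 0) {
      b <- b + 1L
      size <- min(left, 1L + stats::rpois(1, max(spec$block_size_mean - 1, 0)))
      block[i:(i + size - 1L)] <- b
      i <- i + size
      left <- left - size
    }
  }
  tibble(snp_id = sprintf("rs%07d", seq_len(n)), chrom = chrom,
         pos = as.integer(pos), block = block)
}

#' Simulate a block-LD reference panel
#'
#' Genotypes come from a shared founder-haplotype pool per LD block. Founder
#' haplotypes carry serial allelic correlation within a block (a latent
#' Gaussian first-order autoregression with correlation `exp(-d / scale)`
#' between adjacent SNPs, thresholded at each SNP's target allele
#' frequency), and each individual haplotype is a mosaic of founders with a
#' distance-dependent switch probability. Adjacent-SNP r-squared therefore
#' declines with base-pair distance within a block, while SNPs in different
#' blocks are independent. Monomorphic SNPs are repaired by flipping a
#' single haplotype so LD is defined everywhere. The panel is phased
#' (haplotypes retained), so D' needs no EM.
#'
#' @param spec An [architecture_spec()].
#' @param n_individuals Panel size (>= 2).
#' @param n_founders Founder haplotypes per block.
#' @param ld_scale_bp Distance scale of both the founder allelic correlation
#'   and the mosaic switch probability.
#' @param seed Seed (defaults to `spec$seed`).
#' @return A [reference_panel()] (phased).
#' @export
simulate_panel <- function(spec, n_individuals = 500, n_founders = 200,
                           ld_scale_bp = 5e4, seed = spec$seed) {
  if (n_individuals < 2) abort("Need at least 2 individuals.")
  grid <- layout_snp_grid(spec)
  set.seed(seed + 1L)
  n <- nrow(grid)
  n_hap <- 2L * n_individuals
  haps <- matrix(0L, nrow = n_hap, ncol = n)
  for (bl in split(seq_len(n), grid$block)) {
    m <- length(bl)
    f <- runif(m, spec$maf_range[1], spec$maf_range[2])
    thr <- qnorm(f)
    # founder pool with serially correlated alleles (latent AR(1) copula)
    z <- matrix(rnorm(n_founders * m), n_founders, m)
    if (m > 1) {
      r <- exp(-diff(grid$pos[bl]) / ld_scale_bp)
      for (s in 2:m) z[, s] <- r[s - 1] * z[, s - 1] + sqrt(1 - r[s - 1]^2) * z[, s]
    }
    founders <- matrix(as.integer(z < rep(thr, each = n_founders)), n_founders, m)
    cur <- sample.int(n_founders, n_hap, replace = TRUE)
    haps[, bl[1]] <- founders[cbind(cur, 1L)]
    if (m > 1) {
      p_switch <- 1 - exp(-diff(grid$pos[bl]) / ld_scale_bp)
      for (s in 2:m) {
        switch_now <- runif(n_hap) < p_switch[s - 1]
        if (any(switch_now)) {
          cur[switch_now] <- sample.int(n_founders, sum(switch_now), replace = TRUE)
        }
        haps[, bl[s]] <- founders[cbind(cur, s)]
      }
    }
  }
  # repair monomorphic SNPs so pairwise LD is defined everywhere
  mono <- which(colSums(haps) %in% c(0L, n_hap))
  for (s in mono) {
    h <- sample.int(n_hap, 1)
    haps[h, s] <- 1L - haps[h, s]
  }
  dosage <- haps[seq(1, n_hap, by = 2), , drop = FALSE] +
    haps[seq(2, n_hap, by = 2), , drop = FALSE]
  reference_panel(grid[c("snp_id", "chrom", "pos")], dosage, haplotypes = haps)
}

#' Simulate two-trait GWAS summary statistics
#'
#' Works at the summary level: each SNP gets a true effect per trait from the
#' four-component mixture (shared effects bivariate normal with correlation
#' `rho`), a Wald standard error from the binary-trait approximation
#' `se = 1 / sqrt(2 maf (1 - maf) n_eff)` with
#' `n_eff = 4 / (1/cases + 1/controls)`, an observed effect
#' `beta = true + Normal(0, se)`, and a two-sided Wald p-value. Trait B
#' additionally carries an INFO score (Uniform(0.6, 1.05)); both tables share
#' the panel's allele frequencies when a panel is supplied, otherwise MAF is
#' drawn from the spec's bounds.
#'
#' @param spec An [architecture_spec()].
#' @param panel Optional [simulate_panel()] result consistent with `spec`;
#'   `NULL` draws MAF directly (no LD, faster).
#' @param seed Seed (defaults to `spec$seed`).
#' @return List of class `sim_study`: `a`, `b` (summary-statistics tibbles on
#'   the log-odds scale), `truth` (tibble `snp_id`, `class`, `beta_a`,
#'   `beta_b`), `grid` (SNP layout), `spec`.
#' @export
simulate_sumstats <- function(spec, panel = NULL, seed = spec$seed) {
  if (!is.null(panel)) {
    grid <- panel$snps
    maf <- fold_maf(panel$freq)
  } else {
    grid <- layout_snp_grid(spec)
    set.seed(seed + 2L)
    maf <- runif(nrow(grid), spec$maf_range[1], spec$maf_range[2])
  }
  set.seed(seed + 3L)
  n <- nrow(grid)
  cls <- sample(names(spec$mixture), n, replace = TRUE, prob = spec$mixture)

  beta_a <- numeric(n)
  beta_b <- numeric(n)
  ia <- cls == "a_only"; ib <- cls == "b_only"; is_sh <- cls == "shared"
  beta_a[ia] <- rnorm(sum(ia), 0, spec$sigma_a)
  beta_b[ib] <- rnorm(sum(ib), 0, spec$sigma_b)
  if (any(is_sh)) {
    z1 <- rnorm(sum(is_sh)); z2 <- rnorm(sum(is_sh))
    beta_a[is_sh] <- spec$sigma_a * z1
    beta_b[is_sh] <- spec$sigma_b * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
  }

  se_a <- 1 / sqrt(2 * maf * (1 - maf) * n_eff(spec$n1_cases, spec$n1_controls))
  se_b <- 1 / sqrt(2 * maf * (1 - maf) * n_eff(spec$n2_cases, spec$n2_controls))
  obs_a <- beta_a + rnorm(n, 0, se_a)
  obs_b <- beta_b + rnorm(n, 0, se_b)

  alleles <- sim_alleles(n)
  a <- tibble(snp_id = grid$snp_id, chrom = grid$chrom, pos = grid$pos,
              effect_allele = alleles$ea, other_allele = alleles$oa,
              beta = obs_a, se = se_a, p = wald_p(obs_a, se_a),
              info = NA_real_, maf = maf)
  b <- tibble(snp_id = grid$snp_id, chrom = grid$chrom, pos = grid$pos,
              effect_allele = alleles$ea, other_allele = alleles$oa,
              beta = obs_b, se = se_b, p = wald_p(obs_b, se_b),
              info = runif(n, 0.6, 1.05), maf = maf)
  truth <- tibble(snp_id = grid$snp_id, class = cls,
                  beta_a = beta_a, beta_b = beta_b)
  structure(list(a = a, b = b, truth = truth, grid = grid, spec = spec),
            class = "sim_study")
}

wald_p <- function(beta, se) {
  p <- 2 * pnorm(-abs(beta / se))
  pmax(p, .p_floor())
}

# non-strand-ambiguous allele pairs only
sim_alleles <- function(n) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  k <- sample.int(nrow(pairs), n, replace = TRUE)
  list(ea = pairs[k, 1], oa = pairs[k, 2])
}

#' Plant an extreme-effect region in a simulated study
#'
#' Redraws the trait-A true effects of the *causal* SNPs (classes `a_only`
#' and `shared`) inside the region with the effect SD multiplied by
#' `region$factor` (default from the spec), then regenerates the observed
#' effects and p-values there. With a large factor the region's p-values sit
#' orders of magnitude beyond the rest of the genome, emulating a dominant
#' locus that can mask other conditional signals; with `factor = 1` the
#' redraw comes from the generator's own effect distribution, so the region
#' stays distributionally indistinguishable from the background.
#'
#' @param study A `sim_study` from [simulate_sumstats()].
#' @param region List `chrom`, `start`, `end`, `factor` (default
#'   `study$spec$apoe_like`).
#' @param seed Seed (defaults to `spec$seed + 17`).
#' @return The modified `sim_study`.
#' @export
plant_apoe_like <- function(study, region = study$spec$apoe_like,
                            seed = study$spec$seed + 17L) {
  stopifnot(inherits(study, "sim_study"))
  if (is.null(region)) abort("No extreme-effect region specified.")
  reg <- genomic_region(region$chrom, region$start, region$end)
  in_reg <- in_region(study$a$chrom, study$a$pos, reg)
  if (!any(in_reg)) {
    abort("The requested region contains no simulated SNPs.")
  }
  idx <- which(in_reg & study$truth$class %in% c("a_only", "shared"))
  if (length(idx) == 0) return(study)
  set.seed(seed)
  sigma <- study$spec$sigma_a * region$factor
  new_true <- rnorm(length(idx), 0, sigma)
  se <- study$a$se[idx]
  obs <- new_true + rnorm(length(idx), 0, se)
  study$a$beta[idx] <- obs
  study$a$p[idx] <- wald_p(obs, se)
  study$truth$beta_a[idx] <- new_true
  study
}

#' Merge a simulated study without file round-tripping
#'
#' Convenience equivalent of writing the two tables and re-reading them
#' through [harmonize()]: joins trait A and B per SNP (they already share an
#' orientation in memory).
#'
#' @param study A `sim_study`.
#' @return Merged pair tibble as from [harmonize()].
#' @export
merge_study <- function(study) {
  harmonize(study$a, study$b, drop_ambiguous = FALSE)
}

#' Simulate a two-sample MR instrument set
#'
#' True exposure effects are uniform on `beta_exposure_range` (positive, the
#' Egger orientation convention); the true outcome effect of each instrument
#' is `intercept + slope * beta_exposure` (a nonzero `intercept` injects
#' directional pleiotropy). Observed effects add independent normal noise at
#' the stated standard errors.
#'
#' @param n_instruments Number of instruments.
#' @param slope True causal slope (default `log(1.4)`).
#' @param intercept True directional-pleiotropy intercept (default 0).
#' @param beta_exposure_range Range of true exposure effects.
#' @param se_exposure Exposure-side standard error (small: strong
#'   instruments).
#' @param se_outcome_range Outcome-side standard errors (uniform draw).
#' @param seed Mandatory seed.
#' @return Instrument tibble as from [select_instruments()].
#' @export
simulate_instruments <- function(n_instruments = 50, slope = log(1.4),
                                 intercept = 0,
                                 beta_exposure_range = c(0.1, 0.5),
                                 se_exposure = 0.01,
                                 se_outcome_range = c(0.02, 0.06), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  true_exp <- runif(n_instruments, beta_exposure_range[1], beta_exposure_range[2])
  se_out <- runif(n_instruments, se_outcome_range[1], se_outcome_range[2])
  obs_exp <- true_exp + rnorm(n_instruments, 0, se_exposure)
  obs_out <- intercept + slope * true_exp + rnorm(n_instruments, 0, se_out)
  tibble(snp_id = sprintf("iv%04d", seq_len(n_instruments)),
         beta_exposure = obs_exp, se_exposure = se_exposure,
         beta_outcome = obs_out, se_outcome = se_out,
         flipped = FALSE)
}

#' Simulate non-overlapping gene intervals for annotation tests
#'
#' Lays `genes_per_chrom` genes per pseudo-chromosome, alternating gene and
#' intergenic stretches, covering the SNP grid of `spec`.
#'
#' @param spec An [architecture_spec()].
#' @param genes_per_chrom Number of genes per chromosome.
#' @param seed Seed (defaults to `spec$seed`).
#' @return Gene-interval tibble (see [read_gene_intervals()]).
#' @export
simulate_genes <- function(spec, genes_per_chrom = 20, seed = spec$seed) {
  set.seed(seed + 5L)
  chrom_len <- ceiling(spec$n_snps / spec$n_chrom) * spec$spacing_bp
  rows <- purrr::map(seq_len(spec$n_chrom), function(ch) {
    bounds <- sort(sample.int(chrom_len, 2 * genes_per_chrom))
    tibble(name = sprintf("GENE%02d_%03d", ch, seq_len(genes_per_chrom)),
           chrom = as.character(ch),
           start = bounds[seq(1, length(bounds), by = 2)],
           end = bounds[seq(2, length(bounds), by = 2)],
           strand = NA_character_)
  })
  bind_rows(rows)
}

#' Write a simulated study in the file dialects the readers accept
#'
#' Trait A is written in a beta-scale dialect (`MarkerName`, `Chromosome`,
#' `Position`, `Effect_allele`, `Non_Effect_allele`, `Beta`, `SE`, `Pvalue`),
#' trait B in an OR-scale "daner"-like dialect (`SNP`, `CHR`, `BP`, `A1`,
#' `A2`, `OR`, `SE`, `P`, `INFO`, `FRQ`) with a fraction of SNPs emitted with
#' swapped alleles and inverted OR (per `spec$frac_b_swapped`) so that
#' reading the files exercises allele harmonization. Also writes the truth
#' table and a gene BED file.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @param genes Optional gene tibble to write as BED.
#' @param seed Seed for the swap draw (defaults to `spec$seed + 23`).
#' @return Named list of file paths.
#' @export
write_study <- function(study, dir, genes = NULL, seed = study$spec$seed + 23L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a_path <- file.path(dir, "trait_a.tsv")
  b_path <- file.path(dir, "trait_b.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(
    study$a |>
      select(MarkerName = "snp_id", Chromosome = "chrom", Position = "pos",
             Effect_allele = "effect_allele", Non_Effect_allele = "other_allele",
             Beta = "beta", SE = "se", Pvalue = "p"),
    a_path, progress = FALSE)
  set.seed(seed)
  swap <- runif(nrow(study$b)) < study$spec$frac_b_swapped
  b <- study$b
  ea <- ifelse(swap, b$other_allele, b$effect_allele)
  oa <- ifelse(swap, b$effect_allele, b$other_allele)
  or <- exp(ifelse(swap, -b$beta, b$beta))
  readr::write_tsv(
    tibble(SNP = b$snp_id, CHR = b$chrom, BP = b$pos, A1 = ea, A2 = oa,
           OR = or, SE = b$se, P = b$p, INFO = b$info, FRQ = b$maf),
    b_path, progress = FALSE)
  readr::write_tsv(study$truth, truth_path, progress = FALSE)
  out <- list(a = a_path, b = b_path, truth = truth_path)
  if (!is.null(genes)) {
    bed <- file.path(dir, "genes.bed")
    readr::write_tsv(
      tibble(chrom = genes$chrom, start = genes$start - 1L, end = genes$end,
             name = genes$name),
      bed, col_names = FALSE, progress = FALSE)
    out$genes <- bed
  }
  out
}

#' Column schemas for the two emitted summary-statistics dialects
#'
#' `schema_beta_dialect()` matches the beta-scale trait-A file written by
#' [write_study()] (and IGAP-style headers generally);
#' `schema_or_dialect()` matches the OR-scale "daner"-like trait-B file.
#'
#' @return Named character vector usable as the `schema` of
#'   [read_sumstats()].
#' @export
schema_beta_dialect <- function() {
  c(snp_id = "MarkerName", chrom = "Chromosome", pos = "Position",
    effect_allele = "Effect_allele", other_allele = "Non_Effect_allele",
    effect = "Beta", se = "SE", p = "Pvalue")
}

#' @rdname schema_beta_dialect
#' @export
schema_or_dialect <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
    other_allele = "A2", effect = "OR", se = "SE", p = "P",
    info = "INFO", maf = "FRQ")
}
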