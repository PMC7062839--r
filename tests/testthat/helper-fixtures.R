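# In-code fixture builders shared across test files.

toy_sumstats <- function(n = 10, seed = 1, chrom = "1") {
  set.seed(seed)
  tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = seq_len(n) * 10000L,
    effect_allele = rep(c("A", "T", "G", "C"), length.out = n),
    other_allele = rep(c("G", "C", "A", "T"), length.out = n),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.01, 0.05),
    p = runif(n),
    info = runif(n, 0.7, 1.0),
    maf = runif(n, 0.05, 0.5)
  )
}

toy_merged <- function(n = 10, seed = 1) {
  a <- toy_sumstats(n, seed)
  tibble::tibble(
    snp_id = a$snp_id, chrom = a$chrom, pos = a$pos,
    effect_allele = a$effect_allele, other_allele = a$other_allele,
    beta1 = a$beta, se1 = a$se, p1 = a$p,
    beta2 = rnorm(n, 0, 0.1), se2 = a$se, p2 = runif(n),
    maf = a$maf
  )
}

# panel built directly from a stated dosage matrix (individuals x SNPs)
toy_panel <- function(dosage, chrom = "1", pos = NULL, haplotypes = NULL) {
  n_snp <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(n_snp) * 10000L
  reference_panel(
    tibble::tibble(snp_id = sprintf("rs%03d", seq_len(n_snp)),
                   chrom = chrom, pos = as.integer(pos)),
    dosage, haplotypes = haplotypes
  )
}

# phased panel from explicit haplotype frequency counts for two SNPs:
# counts named c(AB=, Ab=, aB=, ab=) where A/B denote the counted allele
toy_phased_pair <- function(counts) {
  h1 <- c(rep(1, counts["AB"] + counts["Ab"]), rep(0, counts["aB"] + counts["ab"]))
  h2 <- c(rep(1, counts["AB"]), rep(0, counts["Ab"]),
          rep(1, counts["aB"]), rep(0, counts["ab"]))
  haps <- cbind(h1, h2)
  n_hap <- nrow(haps)
  stopifnot(n_hap %% 2 == 0)
  dosage <- haps[seq(1, n_hap, 2), ] + haps[seq(2, n_hap, 2), ]
  toy_panel(dosage, haplotypes = haps)
}

write_sumstats_file <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
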