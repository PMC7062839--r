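#' Bundled published conditional-FDR locus tables
#'
#' Per-SNP locus tables transcribed from a published pleiotropy analysis of
#' late-onset Alzheimer's disease (LOAD) and major depressive disorder (MDD):
#' the SNPs reaching conditional FDR Q <= 0.05 for LOAD conditional on MDD
#' (`"LOAD|MDD"`, 40 loci) and for MDD conditional on LOAD (`"MDD|LOAD"`,
#' 27 loci), with hg19 coordinates, nearest gene, minor allele and frequency,
#' the conditional Q value, and both traits' per-SNP association statistics
#' (LOAD on the beta scale, MDD as odds ratios).
#'
#' These tables are fixtures for the reporting layer: tier calling and
#' distinct-gene counting on them reproduce the published locus counts.
#'
#' @param direction `"LOAD|MDD"` or `"MDD|LOAD"`.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `gene`, `minor_allele`, `maf`,
#'   `q`, `beta1`, `se1`, `p1`, `or2`, `se2`, `p2`.
#' @export
published_loci <- function(direction = c("LOAD|MDD", "MDD|LOAD")) {
  direction <- match.arg(direction)
  f <- if (direction == "LOAD|MDD") "loci_load_given_mdd.tsv" else "loci_mdd_given_load.tsv"
  path <- system.file("extdata", f, package = "pleiocfdr", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    snp_id = "c", chrom = "c", pos = "i", gene = "c",
                    minor_allele = "c", .default = "d"))
}
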