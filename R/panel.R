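#' Construct a reference LD panel
#'
#' A reference panel holds per-SNP genotype dosages for a set of individuals,
#' from which pairwise LD (r-squared, D') is computed for pruning, clumping
#' and proxy search. Dosages count copies of the effect allele (0/1/2, or
#' fractional for imputed data).
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (one row per SNP,
#'   no duplicate identifiers), optionally `maf`.
#' @param dosage Numeric matrix, individuals x SNPs, values in `[0, 2]`;
#'   columns ordered as `snps`.
#' @param haplotypes Optional phased 0/1 matrix, (2 x individuals) x SNPs.
#'   When present, D' is computed from haplotype counts directly instead of
#'   by EM.
#' @return A list of class `reference_panel` with elements `snps`, `dosage`,
#'   `haplotypes`, `freq` (allele frequency of the counted allele).
#' @export
reference_panel <- function(snps, dosage, haplotypes = NULL) {
  snps <- as_tibble(snps)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (anyDuplicated(snps$snp_id)) abort("Panel has duplicate SNP identifiers.")
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(snps)) {
    abort("Dosage matrix must have one column per panel SNP.")
  }
  if (anyNA(dosage) || min(dosage) < 0 || max(dosage) > 2) {
    abort("Dosages must be non-missing and within [0, 2].")
  }
  colnames(dosage) <- snps$snp_id
  freq <- unname(colMeans(dosage)) / 2
  maf <- fold_maf(freq)
  if ("maf" %in% names(snps) && any(abs(snps$maf - maf) > 1e-12, na.rm = TRUE)) {
    abort("Stored panel MAF disagrees with MAF recomputed from dosages.")
  }
  snps$maf <- maf
  snps$chrom <- normalize_chrom(snps$chrom)
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    stopifnot(nrow(haplotypes) == 2 * nrow(dosage),
              ncol(haplotypes) == ncol(dosage),
              all(haplotypes %in% c(0, 1)))
    colnames(haplotypes) <- snps$snp_id
  }
  structure(list(snps = snps, dosage = dosage, haplotypes = haplotypes,
                 freq = freq),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d SNPs x %d individuals%s\n",
              nrow(x$snps), nrow(x$dosage),
              if (is.null(x$haplotypes)) " (unphased)" else " (phased)"))
  invisible(x)
}

panel_has <- function(panel, ids) ids %in% panel$snps$snp_id

panel_dosage <- function(panel, id) {
  j <- match(id, panel$snps$snp_id)
  if (is.na(j)) abort(sprintf("SNP '%s' is not in the reference panel.", id))
  panel$dosage[, j]
}

#' Read a reference panel from a plain-text dosage matrix
#'
#' Expected TSV layout: one row per SNP; columns `snp_id`, `chrom`, `pos`,
#' then one dosage column per individual.
#'
#' @param path TSV file path.
#' @return A [reference_panel()].
#' @export
read_panel_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("snp_id", "chrom", "pos")
  stopifnot(all(meta %in% names(raw)))
  dosage <- t(as.matrix(raw[setdiff(names(raw), meta)]))
  reference_panel(raw[meta], dosage)
}

#' Write a reference panel to the plain-text dosage format
#' @param panel A [reference_panel()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  d <- as.data.frame(t(panel$dosage))
  names(d) <- paste0("ind", seq_len(ncol(d)))
  out <- dplyr::bind_cols(panel$snps[c("snp_id", "chrom", "pos")], d)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a reference panel from a VCF
#'
#' Parses GT fields to dosages of the ALT allele; fully phased genotypes
#' (`|` separators throughout) also populate the haplotype matrix so D' can
#' be computed without EM. Requires the `vcfR` package.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [reference_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_panel_vcf() requires the 'vcfR' package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  alleles <- function(g) {
    a <- strsplit(g, "[|/]")
    vapply(a, function(x) sum(as.numeric(x)), numeric(1))
  }
  dosage <- t(apply(gt, 1, alleles))
  dosage <- t(dosage)  # individuals x SNPs
  phased <- all(grepl("\\|", gt))
  haplotypes <- NULL
  if (phased) {
    sp <- apply(gt, 1, function(g) {
      a <- strsplit(g, "\\|")
      as.numeric(unlist(a))
    })
    haplotypes <- as.matrix(sp)
  }
  snps <- tibble(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS))
  reference_panel(snps, dosage, haplotypes = haplotypes)
}
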