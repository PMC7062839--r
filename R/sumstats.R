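#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited file with a header line, maps its
#' columns onto the standard per-SNP schema used throughout the package, and
#' validates every row. Odds ratios are converted to log-odds effect sizes at
#' load time so all downstream arithmetic is on one scale; the standard error
#' is assumed to already be on the log-odds scale (the convention for
#' logistic-regression GWAS output).
#'
#' Rows failing validation (duplicated SNP identifier, p outside (0, 1],
#' non-positive standard error, position < 1, identical effect/other allele)
#' are dropped and counted; `p = 0` entries are clamped to the smallest
#' positive double rather than dropped, because log-scale grids downstream
#' need strictly positive p-values.
#'
#' @param path Path to the summary-statistics file.
#' @param schema Named character vector mapping logical column names to header
#'   names in the file. Required entries: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `effect`, `se`, `p`. Optional: `info`,
#'   `maf`.
#' @param effect_scale `"beta"` if the `effect` column is a log-odds (or
#'   linear) coefficient, `"or"` if it is an odds ratio to be log-transformed.
#' @param build Genome-build label carried as metadata (default GRCh37/hg19).
#' @param n_cases,n_controls Optional study sample sizes, carried as metadata.
#'
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`, `info`, `maf`, with attributes
#'   `n_rejected`, `n_p_clamped`, `build`, `n_cases`, `n_controls`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tOR\tSE\tP",
#'              "rs1\t1\t100\tA\tG\t1.25\t0.1\t0.02"), tf)
#' ss <- read_sumstats(tf, schema = c(snp_id = "SNP", chrom = "CHR",
#'   pos = "BP", effect_allele = "A1", other_allele = "A2", effect = "OR",
#'   se = "SE", p = "P"), effect_scale = "or")
#' ss$beta  # log(1.25)
read_sumstats <- function(path, schema, effect_scale = c("beta", "or"),
                          build = "GRCh37/hg19",
                          n_cases = NA_integer_, n_controls = NA_integer_) {
  effect_scale <- match.arg(effect_scale)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read summary statistics: file '%s' does not exist.", path))
  }
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "effect", "se", "p")
  missing_map <- setdiff(required, names(schema))
  if (length(missing_map) > 0) {
    abort(sprintf("Schema is missing required logical columns: %s.",
                  paste(missing_map, collapse = ", ")))
  }

  first_line <- readLines(path, n = 1L)
  raw <- if (grepl("\t", first_line)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }

  missing_cols <- setdiff(unname(schema[required]), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("File '%s' lacks column(s) named in the schema: %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }

  t <- tibble(
    snp_id = as.character(raw[[schema[["snp_id"]]]]),
    chrom = normalize_chrom(raw[[schema[["chrom"]]]]),
    pos = as.integer(raw[[schema[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[schema[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[schema[["other_allele"]]]])),
    beta = as.numeric(raw[[schema[["effect"]]]]),
    se = as.numeric(raw[[schema[["se"]]]]),
    p = as.numeric(raw[[schema[["p"]]]]),
    info = if ("info" %in% names(schema)) as.numeric(raw[[schema[["info"]]]]) else NA_real_,
    maf = if ("maf" %in% names(schema)) as.numeric(raw[[schema[["maf"]]]]) else NA_real_
  )
  if (effect_scale == "or") {
    bad_or <- !is.na(t$beta) & t$beta <= 0
    t$beta[bad_or] <- NA_real_
    t$beta <- log(t$beta)
  }
  validate_sumstats(t, n_input = nrow(t), build = build,
                    n_cases = n_cases, n_controls = n_controls)
}

normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

#' Validate a summary-statistics tibble
#'
#' Applies the row-level validity rules (see [read_sumstats()]) to an
#' in-memory table, dropping and counting offending rows and clamping p = 0.
#'
#' @param t Tibble with the standard summary-statistics columns.
#' @param n_input Number of rows before any upstream filtering, for reporting.
#' @param build,n_cases,n_controls Metadata carried on the result.
#' @return The validated tibble (see [read_sumstats()] for attributes).
#' @export
validate_sumstats <- function(t, n_input = nrow(t), build = "GRCh37/hg19",
                              n_cases = NA_integer_, n_controls = NA_integer_) {
  n_clamped <- sum(!is.na(t$p) & t$p == 0)
  t$p[!is.na(t$p) & t$p == 0] <- .p_floor()

  ok <- !is.na(t$snp_id) & !is.na(t$p) & t$p > 0 & t$p <= 1 &
    !is.na(t$se) & t$se > 0 &
    !is.na(t$pos) & t$pos >= 1 &
    !is.na(t$beta) &
    !is.na(t$effect_allele) & !is.na(t$other_allele) &
    t$effect_allele != t$other_allele
  ok[is.na(ok)] <- FALSE
  t <- t[ok, , drop = FALSE]
  t <- t[!duplicated(t$snp_id), , drop = FALSE]

  n_rejected <- n_input - nrow(t)
  if (nrow(t) == 0) {
    abort("All rows failed validation: the summary-statistics table is empty.")
  }
  if (n_rejected > 0) {
    inform(sprintf("Dropped %d invalid summary-statistics row(s).", n_rejected))
  }
  if (n_clamped > 0) {
    warn(sprintf("%d p-value(s) of exactly 0 clamped to %.3g.",
                 n_clamped, .p_floor()))
  }
  structure(as_tibble(t),
            n_rejected = n_rejected, n_p_clamped = n_clamped,
            build = build, n_cases = n_cases, n_controls = n_controls)
}

#' Filter on imputation quality (INFO)
#'
#' Retains rows with `lo <= info < hi` (half-open interval). Rows with
#' missing INFO pass: the two consortium file formats differ in whether INFO
#' is reported, and dropping missing values would silently empty one input.
#'
#' @param t Summary-statistics tibble.
#' @param lo,hi Interval bounds; defaults keep `0.6 <= INFO < 1.06`.
#' @return Filtered tibble.
#' @export
filter_info <- function(t, lo = 0.6, hi = 1.06) {
  stopifnot_scalar_number(lo, "lo")
  stopifnot_scalar_number(hi, "hi")
  if (lo >= hi) abort("`lo` must be strictly less than `hi`.")
  if (all(is.na(t$info))) {
    warn("All INFO values are missing; filter_info() left the table unchanged.")
    return(t)
  }
  t[is.na(t$info) | (t$info >= lo & t$info < hi), , drop = FALSE]
}

#' Filter on minor allele frequency
#'
#' Retains rows with `maf > min_maf` (strict inequality; frequencies above
#' 0.5 are folded first). Rows with missing MAF pass with a warning — some
#' summary-statistics dialects do not report frequency, and the filter must
#' not silently empty such an input.
#'
#' @param t Summary-statistics tibble with a `maf` column.
#' @param min_maf Threshold in `[0, 0.5)`; default 0.01.
#' @return Filtered tibble.
#' @export
filter_maf <- function(t, min_maf = 0.01) {
  stopifnot_scalar_number(min_maf, "min_maf")
  if (min_maf < 0 || min_maf >= 0.5) abort("`min_maf` must lie in [0, 0.5).")
  if (!"maf" %in% names(t)) abort("Table has no `maf` column.")
  if (anyNA(t$maf)) {
    warn(sprintf("%d row(s) with missing MAF pass filter_maf() unfiltered.",
                 sum(is.na(t$maf))))
  }
  t[is.na(t$maf) | fold_maf(t$maf) > min_maf, , drop = FALSE]
}

#' Harmonize two summary-statistics tables onto a shared allele orientation
#'
#' Inner-joins two tables on SNP identifier and reorients table `b`'s effect
#' onto table `a`'s allele coding. Four orientations are recognised: identity,
#' allele swap (effect for `a`'s other allele: `beta2` is negated), strand
#' complement, and complement+swap (negated). SNPs whose alleles fit none of
#' the four cases are dropped and counted. Strand-ambiguous (A/T, C/G) SNPs
#' cannot be oriented without allele-frequency information and are dropped by
#' default.
#'
#' @param a,b Validated summary-statistics tibbles (phenotype A and B).
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default `TRUE`).
#' @return Merged tibble with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta1`, `se1`, `p1`, `beta2`, `se2`,
#'   `p2`, `maf`, and attributes `n_dropped_ambiguous`, `n_dropped_mismatch`,
#'   `n_flipped`.
#' @export
harmonize <- function(a, b, drop_ambiguous = TRUE) {
  m <- inner_join(
    a |> select("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                beta1 = "beta", se1 = "se", p1 = "p", maf_a = "maf"),
    b |> select("snp_id", ea2 = "effect_allele", oa2 = "other_allele",
                beta2 = "beta", se2 = "se", p2 = "p", maf_b = "maf"),
    by = "snp_id"
  )
  if (nrow(m) == 0) abort("Harmonization failed: the two tables share no SNP identifiers.")

  n_ambiguous <- 0L
  if (drop_ambiguous) {
    amb <- is_strand_ambiguous(m$effect_allele, m$other_allele)
    n_ambiguous <- sum(amb)
    m <- m[!amb, , drop = FALSE]
  }

  same <- m$ea2 == m$effect_allele & m$oa2 == m$other_allele
  swap <- m$ea2 == m$other_allele & m$oa2 == m$effect_allele
  comp <- complement_allele(m$ea2) == m$effect_allele &
    complement_allele(m$oa2) == m$other_allele
  comp_swap <- complement_allele(m$ea2) == m$other_allele &
    complement_allele(m$oa2) == m$effect_allele

  keep_as_is <- same | (comp & !same & !swap)
  flip <- (swap | comp_swap) & !keep_as_is
  matched <- keep_as_is | flip
  n_mismatch <- sum(!matched)

  m$beta2[flip] <- -m$beta2[flip]
  m <- m[matched, , drop = FALSE]
  if (nrow(m) == 0) abort("Harmonization dropped every SNP: no allele orientations matched.")

  out <- m |>
    mutate(maf = dplyr::coalesce(.data$maf_a, .data$maf_b)) |>
    select("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta1", "se1", "p1", "beta2", "se2", "p2", "maf") |>
    arrange(.data$chrom, .data$pos, .data$snp_id)
  if (n_ambiguous + n_mismatch > 0) {
    inform(sprintf(
      "harmonize(): dropped %d strand-ambiguous and %d allele-mismatch SNP(s); flipped %d.",
      n_ambiguous, n_mismatch, sum(flip)))
  }
  structure(out, n_dropped_ambiguous = n_ambiguous,
            n_dropped_mismatch = n_mismatch, n_flipped = sum(flip))
}

#' Define a genomic region
#'
#' 1-based coordinates, inclusive on both ends (matching hg19 coordinate
#' conventions for region exclusion).
#'
#' @param chrom Chromosome label (any `chr` prefix is stripped).
#' @param start,end Inclusive 1-based bounds, `start <= end`.
#' @return A list of class `genomic_region`.
#' @export
genomic_region <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    abort("Invalid region: need integer start <= end.")
  }
  structure(list(chrom = normalize_chrom(chrom), start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> chr%s:%s-%s\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ",")))
  invisible(x)
}

#' The APOE exclusion region
#'
#' The chr19 interval spanning +/- 300 kb around the APOE epsilon coding
#' SNPs (hg19: chr19:45,111,942-45,711,941), the region whose uniquely strong
#' LOAD association can mask other conditional signals.
#'
#' @return A `genomic_region`.
#' @export
apoe_region <- function() genomic_region("19", 45111942L, 45711941L)

in_region <- function(chrom, pos, region) {
  chrom == region$chrom & pos >= region$start & pos <= region$end
}

#' Exclude (or select) SNPs inside a genomic region
#'
#' `exclude_region()` removes SNPs with `chrom == region$chrom` and
#' `region$start <= pos <= region$end` (both boundaries inclusive);
#' `select_region()` keeps exactly those SNPs. Together they partition the
#' input.
#'
#' @param m Merged (or single-trait) tibble with `chrom` and `pos` columns.
#' @param region A [genomic_region()].
#' @return Filtered tibble.
#' @export
exclude_region <- function(m, region) {
  stopifnot(inherits(region, "genomic_region"))
  m[!in_region(m$chrom, m$pos, region), , drop = FALSE]
}

#' @rdname exclude_region
#' @export
select_region <- function(m, region) {
  stopifnot(inherits(region, "genomic_region"))
  m[in_region(m$chrom, m$pos, region), , drop = FALSE]
}

#' Write a merged pair table to TSV
#'
#' Fixed column order: snp_id, chrom, pos, ea, oa, beta1, se1, p1, beta2,
#' se2, p2, maf.
#'
#' @param m Merged tibble from [harmonize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_merged <- function(m, path) {
  out <- m |>
    select("snp_id", "chrom", "pos", ea = "effect_allele",
           oa = "other_allele", "beta1", "se1", "p1", "beta2", "se2", "p2", "maf")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
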