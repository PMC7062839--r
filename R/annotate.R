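#' Read gene intervals
#'
#' Either BED (0-based, half-open; converted internally to 1-based inclusive
#' coordinates) or a headered 4+ column TSV with `name`, `chrom`, `start`,
#' `end` already 1-based inclusive.
#'
#' @param path File path.
#' @param format `"bed"` or `"tsv"`.
#' @return Tibble: `name`, `chrom`, `start`, `end`, `strand` (NA if absent).
#' @export
read_gene_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
    if (ncol(raw) < 4) abort("BED gene file needs at least 4 columns (chrom, start, end, name).")
    g <- tibble(name = as.character(raw[[4]]),
                chrom = normalize_chrom(raw[[1]]),
                start = as.integer(raw[[2]]) + 1L,
                end = as.integer(raw[[3]]),
                strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else NA_character_)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("name", "chrom", "start", "end") %in% names(raw)))
    g <- tibble(name = as.character(raw$name),
                chrom = normalize_chrom(raw$chrom),
                start = as.integer(raw$start), end = as.integer(raw$end),
                strand = if ("strand" %in% names(raw)) as.character(raw$strand) else NA_character_)
  }
  if (any(g$start > g$end)) abort("Gene intervals must satisfy start <= end.")
  if (anyDuplicated(g[c("name", "chrom")])) {
    abort("Gene names must be unique within a chromosome.")
  }
  g
}

#' Nearest gene for each SNP
#'
#' Distance is measured to the nearest interval edge and is 0 for SNPs inside
#' a gene; strand is ignored. Equidistant ties are broken alphabetically and
#' flagged. SNPs with no gene on their chromosome within `max_distance_kb`
#' (when given) are flagged intergenic with `gene = NA`.
#'
#' @param snps Tibble with `chrom` and `pos` (other columns are preserved).
#' @param genes Gene-interval tibble (see [read_gene_intervals()]).
#' @param max_distance_kb Optional cap on the annotation distance.
#' @return `snps` with added columns `gene`, `distance_bp`, `gene_tie`,
#'   `intergenic`.
#' @export
nearest_gene <- function(snps, genes, max_distance_kb = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  if (nrow(snps) == 0) {
    return(dplyr::bind_cols(snps,
                            tibble(gene = character(), distance_bp = numeric(),
                                   gene_tie = logical(), intergenic = logical())))
  }
  max_bp <- if (is.null(max_distance_kb)) Inf else max_distance_kb * 1000
  res <- purrr::pmap(list(snps$chrom, snps$pos), function(ch, p) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) {
      return(tibble(gene = NA_character_, distance_bp = NA_real_,
                    gene_tie = FALSE, intergenic = TRUE))
    }
    d <- ifelse(p < g$start, g$start - p, ifelse(p > g$end, p - g$end, 0))
    dmin <- min(d)
    if (dmin > max_bp) {
      return(tibble(gene = NA_character_, distance_bp = dmin,
                    gene_tie = FALSE, intergenic = TRUE))
    }
    hits <- sort(g$name[d == dmin])
    tibble(gene = hits[1], distance_bp = dmin,
           gene_tie = length(hits) > 1, intergenic = FALSE)
  })
  dplyr::bind_cols(snps, bind_rows(res))
}

#' Build a locus report of significant SNPs
#'
#' One row per SNP whose conditional FDR meets `q_threshold`, carrying the
#' nearest gene, the reported minor allele and frequency, and both traits'
#' association statistics; the secondary (OR-scale) trait's effect is
#' re-exponentiated. Rows are sorted by nearest-gene name. The report is a
#' deterministic function of its inputs.
#'
#' @param r A `cfdr_result` (or conjunction tibble; pick the column with
#'   `value`).
#' @param m Merged pair tibble aligned with `r` (same SNP ids).
#' @param genes Gene intervals, see [read_gene_intervals()].
#' @param q_threshold Inclusion threshold on Q (default 0.05, `<=`).
#' @param value Q column name when `r` is a tibble.
#' @param or_scale_trait2 Report trait 2 as an odds ratio (default `TRUE`).
#' @return Tibble: `snp_id`, `chrom`, `pos`, `gene`, `distance_bp`,
#'   `minor_allele`, `maf`, `q`, `beta1`, `se1`, `p1`, `or2`/`beta2`, `se2`,
#'   `p2`, plus tie/intergenic flags.
#' @export
build_locus_report <- function(r, m, genes, q_threshold = 0.05, value = "q",
                               or_scale_trait2 = TRUE) {
  t <- if (inherits(r, "cfdr_result")) r$snps else as_tibble(r)
  if (!value %in% names(t)) abort(sprintf("No column '%s' in the result.", value))
  sig <- t[t[[value]] <= q_threshold, , drop = FALSE]
  out <- sig |>
    select("snp_id", q = dplyr::all_of(value)) |>
    inner_join(m, by = "snp_id")
  if (nrow(out) != nrow(sig)) {
    abort("Result and merged table are not aligned: some significant SNPs are missing from `m`.")
  }
  out <- nearest_gene(out, genes)
  out <- out |>
    mutate(minor_allele = .data$effect_allele,
           or2 = if (or_scale_trait2) exp(.data$beta2) else .data$beta2) |>
    select("snp_id", "chrom", "pos", "gene", "distance_bp", "minor_allele",
           "maf", "q", "beta1", "se1", "p1", "or2", "se2", "p2",
           "gene_tie", "intergenic") |>
    arrange(.data$gene, .data$snp_id)
  if (!or_scale_trait2) out <- rename(out, beta2 = "or2")
  out
}

#' Format a locus report at publication precision
#'
#' Effect sizes and odds ratios to 3 decimals, p-values and Q values in
#' scientific notation with 2 mantissa digits.
#'
#' @param report A [build_locus_report()] tibble.
#' @return Tibble of character columns.
#' @export
format_locus_report <- function(report) {
  fmt_p <- function(x) toupper(sprintf("%.2e", x))
  fmt_3 <- function(x) sprintf("%.3f", x)
  report |>
    mutate(across(dplyr::any_of(c("beta1", "se1", "or2", "beta2", "se2", "maf")), fmt_3),
           across(dplyr::any_of(c("q", "p1", "p2")), fmt_p),
           across(dplyr::everything(), as.character))
}

#' Manhattan plot data for conditional and conjunction FDR values
#'
#' Computes a cumulative genome coordinate (chromosomes laid end to end in
#' natural order), the -log10 of the chosen FDR column, and an alternating
#' chromosome colour index. Reference lines: -log10(5e-8) and -log10(1e-5)
#' for conditional values, -log10(0.05) and -log10(0.1) for conjunction
#' values.
#'
#' @param r A `cfdr_result` or a tibble with `chrom`, `pos` and the value
#'   column.
#' @param value Column to plot: `"q"`, `"q_ab"`, `"q_ba"` or `"cc"`.
#' @return Tibble `snp_id`, `chrom`, `pos`, `coord`, `neg_log10`,
#'   `chrom_index`, with attributes `ref_lines` (named numeric) and
#'   `chrom_centers` (for axis labelling).
#' @export
manhattan_data <- function(r, value = "q") {
  t <- if (inherits(r, "cfdr_result")) r$snps else as_tibble(r)
  if (!value %in% names(t)) abort(sprintf("No column '%s' in the result.", value))
  chrom_order <- function(ch) {
    suppressWarnings(n <- as.numeric(ch))
    ifelse(is.na(n), match(toupper(ch), c("X", "Y", "MT", "M")) + 100, n)
  }
  t <- t |>
    mutate(.ord = chrom_order(.data$chrom)) |>
    arrange(.data$.ord, .data$pos, .data$snp_id)
  sizes <- t |>
    group_by(.data$.ord, .data$chrom) |>
    summarise(max_pos = max(.data$pos), .groups = "drop") |>
    arrange(.data$.ord) |>
    mutate(offset = cumsum(dplyr::lag(.data$max_pos, default = 0)))
  t <- t |>
    left_join(sizes |> select("chrom", "offset"), by = "chrom") |>
    mutate(coord = .data$pos + .data$offset,
           neg_log10 = -log10(.data[[value]]),
           chrom_index = as.integer(factor(.data$.ord)) %% 2L) |>
    select(dplyr::any_of("snp_id"), "chrom", "pos", "coord", "neg_log10",
           "chrom_index")
  ref <- if (value == "cc") {
    c(genome_wide = -log10(0.05), suggestive = -log10(0.1))
  } else {
    c(genome_wide = -log10(5e-8), suggestive = -log10(1e-5))
  }
  centers <- sizes |>
    mutate(center = .data$offset + .data$max_pos / 2) |>
    select("chrom", "center")
  structure(t, ref_lines = ref, chrom_centers = centers)
}
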