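test_that("odds ratios are log-transformed on load and invalid rows are counted", {
  tf <- write_sumstats_file(c(
    "SNP\tCHR\tBP\tA1\tA2\tOR\tSE\tP",
    "rs1\t1\t100\tA\tG\t1.0\t0.1\t0.5",
    "rs2\t1\t200\tT\tG\t1.25\t0.1\t0.01",
    "rs3\t1\t300\tC\tA\t0.8\t0.1\t0.02",
    "rs4\t1\t400\tC\tT\t1.1\t0.1\t1.5"))
  schema <- c(snp_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
              other_allele = "A2", effect = "OR", se = "SE", p = "P")
  expect_message(ss <- read_sumstats(tf, schema, effect_scale = "or"),
                 "Dropped 1 invalid")
  expect_equal(ss$beta, c(0, log(1.25), log(0.8)))
  # reciprocal ORs give equal-magnitude opposite-sign effects
  expect_equal(abs(ss$beta[2]), abs(log(1 / 1.25)))
  expect_equal(attr(ss, "n_rejected"), 1L)
  expect_false("rs4" %in% ss$snp_id)
})

test_that("OR-dialect schema with INFO populates the info column", {
  tf <- write_sumstats_file(c(
    "SNP\tCHR\tBP\tA1\tA2\tOR\tSE\tP\tINFO\tFRQ",
    "rs1\t2\t100\tA\tG\t1.05\t0.02\t0.3\t0.91\t0.25"))
  ss <- read_sumstats(tf, schema_or_dialect(), effect_scale = "or")
  expect_equal(ss$info, 0.91)
  expect_equal(ss$maf, 0.25)
})

test_that("missing schema entries and unreadable files raise informative errors", {
  expect_error(read_sumstats(tempfile(), schema_or_dialect()), "does not exist")
  tf <- write_sumstats_file(c("SNP\tP", "rs1\t0.5"))
  expect_error(read_sumstats(tf, c(snp_id = "SNP", p = "P")), "missing required")
})

test_that("p = 0 is clamped to the smallest positive double, not dropped", {
  tf <- write_sumstats_file(c(
    "SNP\tCHR\tBP\tA1\tA2\tOR\tSE\tP",
    "rs1\t1\t100\tA\tG\t1.5\t0.1\t0"))
  expect_warning(ss <- read_sumstats(tf, schema_or_dialect()[1:8],
                                     effect_scale = "or"),
                 "clamped")
  expect_gt(ss$p, 0)
  expect_equal(attr(ss, "n_p_clamped"), 1L)
})

test_that("INFO filter keeps the half-open interval and passes missing values", {
  t <- toy_sumstats(4)
  t$info <- c(0.5, 0.6, 1.0, 1.06)
  kept <- filter_info(t)
  expect_setequal(kept$info, c(0.6, 1.0))
  t$info <- NA_real_
  expect_warning(out <- filter_info(t), "unchanged")
  expect_equal(nrow(out), 4)
  expect_equal(nrow(filter_info(toy_sumstats(5), lo = 0, hi = 2)), 5)
  expect_error(filter_info(t, lo = 1, hi = 0.5), "strictly less")
})

test_that("MAF filter is strict and folds frequencies above one half", {
  t <- toy_sumstats(3)
  t$maf <- c(0.005, 0.01, 0.02)
  expect_equal(filter_maf(t)$maf, 0.02)
  t$maf <- c(0.995, 0.6, 0.98)  # folded: 0.005, 0.4, 0.02
  expect_equal(filter_maf(t)$maf, c(0.6, 0.98))
  t$maf <- c(0.3, 0.4, 0.5)
  expect_equal(nrow(filter_maf(t, min_maf = 0)), 3)
  expect_equal(nrow(filter_maf(t[0, ])), 0)
  expect_error(filter_maf(t, min_maf = 0.6), "0, 0.5")
})

test_that("harmonization matches the exhaustive orientation oracle on a toy table", {
  a <- tibble::tibble(
    snp_id = sprintf("rs%d", 1:6), chrom = "1", pos = 1:6 * 1000L,
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "G", "G"),
    beta = rep(0.1, 6), se = rep(0.02, 6), p = rep(0.01, 6),
    info = NA_real_, maf = rep(0.2, 6))
  b <- a
  b$effect_allele <- c("A", "G", "T", "C", "A", "C")
  b$other_allele <-  c("G", "A", "C", "T", "C", "G")
  b$beta <- rep(0.12, 6)
  expect_message(m <- harmonize(a, b), "mismatch")
  for (i in seq_len(nrow(a))) {
    case <- harmonize_case_oracle(a$effect_allele[i], a$other_allele[i],
                                  b$effect_allele[i], b$other_allele[i])
    row <- m[m$snp_id == a$snp_id[i], ]
    if (case == "mismatch") {
      expect_equal(nrow(row), 0)
    } else {
      expected <- if (case %in% c("swap", "comp_swap")) -0.12 else 0.12
      expect_equal(row$beta2, expected)
    }
  }
  expect_equal(attr(m, "n_dropped_mismatch"), 2L)
})

test_that("harmonization preserves |beta2|, is idempotent, and drops ambiguous SNPs", {
  set.seed(42)
  n <- 30
  a <- toy_sumstats(n)
  b <- a
  b$beta <- rnorm(n, 0, 0.1)
  flip <- seq(1, n, by = 3)
  tmp <- b$effect_allele[flip]
  b$effect_allele[flip] <- b$other_allele[flip]
  b$other_allele[flip] <- tmp
  b$beta[flip] <- -b$beta[flip]
  m <- harmonize(a, b)
  expect_equal(nrow(m), n)
  expect_equal(sort(abs(m$beta2)), sort(abs(b$beta)))
  # re-applying the orientation fix to its own output changes nothing
  a2 <- m |> dplyr::transmute(snp_id, chrom, pos, effect_allele, other_allele,
                              beta = beta1, se = se1, p = p1, info = NA_real_, maf)
  b2 <- m |> dplyr::transmute(snp_id, chrom, pos, effect_allele, other_allele,
                              beta = beta2, se = se2, p = p2, info = NA_real_, maf)
  m2 <- harmonize(a2, b2)
  expect_equal(m2$beta2, m$beta2)
  expect_equal(m2$effect_allele, m$effect_allele)

  amb <- a
  amb$effect_allele[1] <- "A"; amb$other_allele[1] <- "T"
  expect_message(m3 <- harmonize(amb, amb), "ambiguous")
  expect_equal(attr(m3, "n_dropped_ambiguous"), 1L)
  expect_false(amb$snp_id[1] %in% m3$snp_id)
})

test_that("row filters commute", {
  t <- toy_sumstats(50, seed = 9)
  t$info[c(3, 7)] <- c(0.2, 1.2)
  t$maf[c(5, 11)] <- 0.004
  ab <- filter_maf(filter_info(t))
  ba <- filter_info(filter_maf(t))
  expect_equal(ab, ba)
})

test_that("region exclusion is inclusive on both boundaries and partitions the table", {
  m <- toy_merged(5)
  m$chrom <- c("19", "19", "19", "18", "19")
  m$pos <- c(45111942L, 45500000L, 45711941L, 45500000L, 45711942L)
  reg <- apoe_region()
  ex <- exclude_region(m, reg)
  expect_setequal(ex$snp_id, m$snp_id[4:5])   # wrong chrom and past the end kept
  sel <- select_region(m, reg)
  expect_setequal(sel$snp_id, m$snp_id[1:3])  # both boundaries removed
  expect_setequal(c(ex$snp_id, sel$snp_id), m$snp_id)
  expect_equal(nrow(ex) + nrow(sel), nrow(m))
})

test_that("merged tables round-trip through the fixed-column TSV writer", {
  m <- toy_merged(8)
  tf <- tempfile(fileext = ".tsv")
  write_merged(m, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(names(back), c("snp_id", "chrom", "pos", "ea", "oa", "beta1",
                              "se1", "p1", "beta2", "se2", "p2", "maf"))
  expect_equal(back$beta1, m$beta1)
})
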