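test_that("reference panel validation catches bad dosages and duplicate ids", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)
  p <- toy_panel(d)
  expect_s3_class(p, "reference_panel")
  expect_equal(p$snps$maf, c(0.5, 0.5))
  expect_error(toy_panel(matrix(c(0, 1, 3), nrow = 3)), "within \\[0, 2\\]")
  snps <- tibble::tibble(snp_id = c("a", "a"), chrom = "1", pos = c(1L, 2L))
  expect_error(reference_panel(snps, matrix(0:1, nrow = 1, ncol = 2)),
               "duplicate")
  snps2 <- tibble::tibble(snp_id = c("a", "b"), chrom = "1", pos = c(1L, 2L),
                          maf = c(0.9, 0.1))
  expect_error(reference_panel(snps2, matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)),
               "disagrees")
})

test_that("r-squared equals the squared Pearson correlation of dosages", {
  d <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 1, 2, 2, 1, 0), c(2, 1, 0, 0, 1, 2),
             c(0, 2, 0, 2, 0, 2))
  p <- toy_panel(d)
  expect_equal(ld_r2(p, "rs001", "rs002"), 1.0)       # identical vectors
  expect_equal(ld_r2(p, "rs001", "rs003"), 1.0)       # coding swap, same info
  expect_equal(ld_r2(p, "rs001", "rs004"), 0.0)       # zero covariance
  # hand-computed toy pair
  x <- c(0, 1, 2, 1, 0, 2); y <- c(1, 1, 2, 0, 0, 2)
  p2 <- toy_panel(cbind(x, y))
  expect_equal(ld_r2(p2, "rs001", "rs002"), cor(x, y)^2)
  # symmetry
  expect_equal(ld_r2(p2, "rs001", "rs002"), ld_r2(p2, "rs002", "rs001"))
  # zero variance errors
  p3 <- toy_panel(cbind(c(1, 1, 1), c(0, 1, 2)))
  expect_error(ld_r2(p3, "rs001", "rs002"), "zero-variance")
})

test_that("D' matches the closed form on stated haplotype counts", {
  # worked example: counts AB 40, Ab 10, aB 10, ab 40
  p <- toy_phased_pair(c(AB = 40, Ab = 10, aB = 10, ab = 40))
  p11 <- 0.4; pA <- 0.5; pB <- 0.5
  D <- p11 - pA * pB
  d_max <- min(pA * (1 - pB), (1 - pA) * pB)
  expect_equal(ld_d_prime(p, "rs001", "rs002"), D / d_max)  # 0.6
  # perfect coupling
  p_c <- toy_phased_pair(c(AB = 30, Ab = 0, aB = 0, ab = 30))
  expect_equal(ld_d_prime(p_c, "rs001", "rs002"), 1.0)
  # independence: p11 = pA * pB exactly
  p_i <- toy_phased_pair(c(AB = 25, Ab = 25, aB = 25, ab = 25))
  expect_equal(ld_d_prime(p_i, "rs001", "rs002"), 0.0)
  # D' = 1 whenever one haplotype class is absent
  for (zero in c("Ab", "aB")) {
    counts <- c(AB = 20, Ab = 16, aB = 10, ab = 26)
    counts[zero] <- 0
    pz <- toy_phased_pair(counts)
    expect_equal(ld_d_prime(pz, "rs001", "rs002"), 1.0)
  }
})

test_that("unphased EM recovers D' from genotypes when phase is informative", {
  p <- toy_phased_pair(c(AB = 80, Ab = 5, aB = 5, ab = 80))
  phased <- ld_d_prime(p, "rs001", "rs002")
  p_unphased <- p
  p_unphased$haplotypes <- NULL
  em <- ld_d_prime(p_unphased, "rs001", "rs002")
  expect_lt(abs(em - phased), 0.05)
  expect_true(em >= 0 && em <= 1)
})

test_that("pruning removes the lower-MAF member and matches the fixed-point oracle", {
  # two SNPs in strong LD with stated MAFs: lower-MAF one must go
  set.seed(3)
  base <- rbinom(200, 2, 0.4)
  noisy <- ifelse(runif(200) < 0.9, base, rbinom(200, 2, 0.4))
  d <- cbind(base, noisy)
  pan <- toy_panel(d, pos = c(100L, 200L))
  m <- tibble::tibble(snp_id = c("rs001", "rs002"), chrom = "1",
                      pos = c(100L, 200L), p1 = c(0.5, 0.5),
                      maf = c(0.4, 0.1))
  stopifnot(ld_r2(pan, "rs001", "rs002") > 0.2)
  out <- ld_prune(m, pan)
  expect_equal(out$snp_id, "rs001")

  # nothing above the threshold: output identical to input
  set.seed(4)
  d_ind <- sapply(1:4, function(i) rbinom(300, 2, 0.3))
  pan_i <- toy_panel(d_ind)
  m_i <- tibble::tibble(snp_id = sprintf("rs%03d", 1:4), chrom = "1",
                        pos = 1:4 * 10000L, p1 = runif(4), maf = rep(0.3, 4))
  expect_equal(ld_prune(m_i, pan_i)$snp_id, m_i$snp_id)

  # 5-SNP chains with mixed r2: equality with the repeated-scan oracle
  for (seed in 1:5) {
    set.seed(seed)
    anchor <- rbinom(300, 2, 0.45)
    chain <- sapply(1:5, function(i) {
      keep <- runif(300) < c(0.95, 0.6, 0.95, 0.3, 0.9)[i]
      ifelse(keep, anchor, rbinom(300, 2, 0.45))
    })
    pan_c <- toy_panel(chain, pos = 1:5 * 5000L)
    m_c <- tibble::tibble(snp_id = sprintf("rs%03d", 1:5), chrom = "1",
                          pos = 1:5 * 5000L, p1 = runif(5),
                          maf = runif(5, 0.1, 0.5))
    out_c <- ld_prune(m_c, pan_c, 0.2, window_kb = 100)
    oracle <- prune_fixed_point_oracle(
      m_c, function(i, j) ld_r2(pan_c, i, j),
      maf = m_c$maf, window_bp = 1e5, p1 = m_c$p1)
    expect_equal(sort(out_c$snp_id), sort(oracle))
    # fixed point: re-pruning changes nothing, output is a subset of input
    expect_equal(ld_prune(out_c, pan_c, 0.2, window_kb = 100)$snp_id,
                 out_c$snp_id)
    expect_true(all(out_c$snp_id %in% m_c$snp_id))
  }
})

test_that("no retained pair within the window exceeds the pruning threshold", {
  spec <- architecture_spec(n_snps = 300, n_chrom = 2, block_size_mean = 15,
                            apoe_like = NULL, seed = 21)
  pan <- simulate_panel(spec, n_individuals = 250)
  st <- simulate_sumstats(spec, panel = pan)
  m <- merge_study(st)
  out <- ld_prune(m, pan, 0.2, window_kb = 500)
  ids <- out$snp_id
  for (i in seq_len(nrow(out) - 1)) {
    for (j in (i + 1):nrow(out)) {
      if (out$chrom[i] == out$chrom[j] &&
          abs(out$pos[j] - out$pos[i]) <= 5e5) {
        expect_lte(ld_r2(pan, ids[i], ids[j]), 0.2)
      }
    }
  }
})

test_that("SNPs absent from the panel pass through pruning and are counted", {
  set.seed(5)
  d <- cbind(rbinom(100, 2, 0.3), rbinom(100, 2, 0.3))
  pan <- toy_panel(d)
  m <- toy_merged(3)
  m$snp_id <- c("rs001", "rs002", "missing1")
  out <- ld_prune(m, pan)
  expect_true("missing1" %in% out$snp_id)
  expect_equal(attr(out, "n_uncovered"), 1L)
})

test_that("clumping keeps the most significant SNP per locus", {
  set.seed(6)
  d <- sapply(1:2, function(i) rbinom(200, 2, 0.3))
  pan <- toy_panel(d, pos = c(1000L, 6000L))
  t <- tibble::tibble(snp_id = c("rs001", "rs002"), chrom = "1",
                      pos = c(1000L, 6000L), p = c(1e-12, 1e-10))
  out <- ld_clump(t, pan, p_threshold = 1e-8, r2_threshold = 0.001,
                  distance_kb = 10)
  expect_equal(out$snp_id, "rs001")  # 5 kb apart: distance rule removes rs002

  # single qualifying SNP passes through
  t1 <- t[1, ]
  expect_equal(ld_clump(t1, pan)$snp_id, "rs001")

  # no qualifying SNPs
  t0 <- t; t0$p <- c(0.5, 0.9)
  expect_equal(nrow(ld_clump(t0, pan)), 0)
})

test_that("clumping equals the greedy-order oracle on an 8-SNP toy", {
  set.seed(7)
  anchor <- rbinom(400, 2, 0.4)
  d <- sapply(1:8, function(i) {
    if (i %in% c(2, 5)) ifelse(runif(400) < 0.9, anchor, rbinom(400, 2, 0.4))
    else rbinom(400, 2, 0.4)
  })
  d[, 1] <- anchor
  pos <- c(1000L, 40000L, 52000L, 90000L, 130000L, 135000L, 200000L, 500000L)
  pan <- toy_panel(d, pos = pos)
  t <- tibble::tibble(snp_id = sprintf("rs%03d", 1:8), chrom = "1", pos = pos,
                      p = c(1e-12, 3e-11, 5e-10, 2e-9, 1e-13, 4e-9, 0.2, 8e-9))
  out <- ld_clump(t, pan, p_threshold = 1e-8, r2_threshold = 0.1,
                  distance_kb = 10)
  oracle <- clump_greedy_oracle(t, function(i, j) ld_r2(pan, i, j),
                                p_threshold = 1e-8, r2_threshold = 0.1,
                                dist_bp = 1e4)
  expect_equal(out$snp_id, oracle)
  report <- attr(out, "clump_report")
  expect_equal(sum(report$n_removed) + nrow(out), sum(t$p <= 1e-8))
})

test_that("clump candidates absent from the panel are dropped and counted", {
  set.seed(8)
  pan <- toy_panel(cbind(rbinom(100, 2, 0.3)))
  t <- tibble::tibble(snp_id = c("rs001", "ghost"), chrom = "1",
                      pos = c(10000L, 500000L), p = c(1e-10, 1e-12))
  expect_message(out <- ld_clump(t, pan), "absent from the panel")
  expect_equal(out$snp_id, "rs001")
  expect_equal(attr(out, "n_uncovered"), 1L)
})

test_that("proxy search matches a brute-force scan and excludes the index", {
  # 10-SNP block: SNP 1 duplicated at SNP 2 (perfect LD), others varying
  set.seed(9)
  base <- rep(c(0L, 1L), each = 40)
  haps <- cbind(base, base,
                sapply(3:10, function(i) {
                  ifelse(runif(80) < 0.85, base, rbinom(80, 1, 0.5))
                }))
  dosage <- haps[seq(1, 79, 2), ] + haps[seq(2, 80, 2), ]
  pan <- toy_panel(dosage, pos = 1:10 * 2000L, haplotypes = haps)
  pro <- find_proxies(pan, "rs001", window_kb = 50)
  # brute force over all other SNPs
  ids <- pan$snps$snp_id[-1]
  brute <- Filter(function(id) {
    ld_r2(pan, "rs001", id) > 0.9 &&
      abs(ld_d_prime(pan, "rs001", id) - 1) <= 1e-6
  }, ids)
  expect_setequal(pro$snp_j, brute)
  expect_false("rs001" %in% pro$snp_j)
  expect_true("rs002" %in% pro$snp_j)
  expect_equal(pro$r2[pro$snp_j == "rs002"], 1.0)
  expect_equal(pro$r2, sort(pro$r2, decreasing = TRUE))
  expect_error(find_proxies(pan, "nope"), "not in the reference panel")
})
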