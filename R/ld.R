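#' Pairwise LD r-squared from a reference panel
#'
#' Squared Pearson correlation of the two SNPs' dosage vectors. Invariant to
#' swapping an allele coding (dosage -> 2 - dosage) and symmetric in its
#' arguments.
#'
#' @param panel A [reference_panel()].
#' @param i,j SNP identifiers.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(panel, i, j) {
  di <- panel_dosage(panel, i)
  dj <- panel_dosage(panel, j)
  if (stats::var(di) == 0 || stats::var(dj) == 0) {
    abort("LD is undefined for a zero-variance (monomorphic) SNP.")
  }
  min(stats::cor(di, dj)^2, 1)
}

# r^2 of SNP j0 against a set of columns, vectorized
ld_r2_vec <- function(dosage, j0, js) {
  x <- dosage[, j0]
  y <- dosage[, js, drop = FALSE]
  vx <- stats::var(x)
  vy <- apply(y, 2, stats::var)
  r2 <- rep(NA_real_, length(js))
  ok <- vx > 0 & vy > 0
  if (any(ok)) {
    r2[ok] <- as.numeric(stats::cor(x, y[, ok, drop = FALSE]))^2
  }
  pmin(r2, 1)
}

#' Pairwise LD D' from a reference panel
#'
#' `|D|` normalized by its maximum given the allele frequencies. With a
#' phased panel, haplotype frequencies are counted directly; with unphased
#' dosages they are estimated by the two-locus haplotype-frequency EM
#' (at most `max_iter` iterations, convergence tolerance `tol`). If the EM
#' fails to converge the value is returned as `NA` with a warning rather
#' than an error.
#'
#' @param panel A [reference_panel()].
#' @param i,j SNP identifiers.
#' @param max_iter,tol EM controls.
#' @return D' in `[0, 1]`, or `NA` on EM non-convergence.
#' @export
ld_d_prime <- function(panel, i, j, max_iter = 50, tol = 1e-10) {
  if (!is.null(panel$haplotypes)) {
    hi <- panel$haplotypes[, match(i, panel$snps$snp_id)]
    hj <- panel$haplotypes[, match(j, panel$snps$snp_id)]
    p11 <- mean(hi == 1 & hj == 1)
    pA <- mean(hi); pB <- mean(hj)
    return(d_prime_from_freqs(p11, pA, pB))
  }
  di <- round(panel_dosage(panel, i))
  dj <- round(panel_dosage(panel, j))
  em <- haplotype_em(di, dj, max_iter = max_iter, tol = tol)
  if (!em$converged) {
    warn(sprintf("Haplotype EM did not converge for pair (%s, %s); D' set to NA.", i, j))
    return(NA_real_)
  }
  d_prime_from_freqs(em$p11, em$pA, em$pB)
}

d_prime_from_freqs <- function(p11, pA, pB) {
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    abort("D' is undefined for a monomorphic SNP.")
  }
  D <- p11 - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  if (d_max == 0) return(0)
  min(abs(D) / d_max, 1)
}

# two-locus haplotype-frequency EM from unphased 0/1/2 genotype vectors;
# only the double heterozygote is phase-ambiguous
haplotype_em <- function(g1, g2, max_iter = 50, tol = 1e-10) {
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  # every genotype pair except the double heterozygote decomposes uniquely
  # into two haplotypes; double hets are split in the E step
  dh <- g1 == 1 & g2 == 1
  n_dh <- sum(dh)
  a1 <- g1[!dh]; a2 <- g2[!dh]
  n11 <- sum(ifelse(a1 == 2 & a2 == 2, 2,
             ifelse((a1 == 2 & a2 == 1) | (a1 == 1 & a2 == 2), 1, 0)))
  n10 <- sum(ifelse(a1 == 2 & a2 == 0, 2,
             ifelse(a1 == 2 & a2 == 1, 1,
             ifelse(a1 == 1 & a2 == 0, 1, 0))))
  n01 <- sum(ifelse(a1 == 0 & a2 == 2, 2,
             ifelse(a1 == 1 & a2 == 2, 1,
             ifelse(a1 == 0 & a2 == 1, 1, 0))))
  n00 <- sum(ifelse(a1 == 0 & a2 == 0, 2,
             ifelse(a1 == 1 & a2 == 0, 1,
             ifelse(a1 == 0 & a2 == 1, 1, 0))))
  p11 <- pA * pB; p10 <- pA * (1 - pB); p01 <- (1 - pA) * pB; p00 <- (1 - pA) * (1 - pB)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E step: split double hets between coupling (11/00) and repulsion (10/01)
    denom <- p11 * p00 + p10 * p01
    w_coupling <- if (denom == 0) 0.5 else p11 * p00 / denom
    e11 <- n11 + n_dh * w_coupling
    e00 <- n00 + n_dh * w_coupling
    e10 <- n10 + n_dh * (1 - w_coupling)
    e01 <- n01 + n_dh * (1 - w_coupling)
    tot <- e11 + e10 + e01 + e00
    new <- c(e11, e10, e01, e00) / tot
    delta <- max(abs(new - c(p11, p10, p01, p00)))
    p11 <- new[1]; p10 <- new[2]; p01 <- new[3]; p00 <- new[4]
    if (delta < tol) { converged <- TRUE; break }
  }
  list(p11 = p11, p10 = p10, p01 = p01, p00 = p00,
       pA = p11 + p10, pB = p11 + p01, converged = converged)
}

#' LD-prune a merged pair table
#'
#' Among any two retained SNPs within `window_kb` whose panel r-squared
#' exceeds `r2_threshold`, the member with the lower minor allele frequency
#' is removed. SNPs are processed in (chrom, pos, snp_id) order, and pairs in
#' lexicographic order, which makes the result identical to repeatedly
#' scanning all within-window pairs and applying the removal rule until none
#' exceeds the threshold. The MAF used is the summary-statistics MAF where
#' present (folded onto (0, 0.5]), otherwise the panel MAF; exact MAF ties
#' keep the SNP with the smaller primary p-value, then the lexicographically
#' smaller identifier. SNPs absent from the panel pass through untouched and
#' are counted.
#'
#' @param m Merged tibble (needs `snp_id`, `chrom`, `pos`; uses `maf` and
#'   `p1` if present).
#' @param panel A [reference_panel()].
#' @param r2_threshold Removal threshold, in `(0, 1]`; default 0.2.
#' @param window_kb Only pairs within this many kb are tested (default 1000).
#' @return Pruned tibble with attributes `n_removed`, `n_uncovered`.
#' @export
ld_prune <- function(m, panel, r2_threshold = 0.2, window_kb = 1000) {
  stopifnot_scalar_number(r2_threshold, "r2_threshold")
  if (r2_threshold <= 0 || r2_threshold > 1) {
    abort("`r2_threshold` must lie in (0, 1].")
  }
  m <- arrange(m, .data$chrom, .data$pos, .data$snp_id)
  covered <- panel_has(panel, m$snp_id)
  col <- match(m$snp_id, panel$snps$snp_id)
  maf_rule <- if ("maf" %in% names(m)) fold_maf(m$maf) else rep(NA_real_, nrow(m))
  maf_rule[is.na(maf_rule)] <- panel$snps$maf[col[is.na(maf_rule)]]
  p1 <- if ("p1" %in% names(m)) m$p1 else rep(NA_real_, nrow(m))

  keep <- rep(TRUE, nrow(m))
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(m))) {
    if (!keep[i] || !covered[i]) next
    j <- i + 1L
    while (j <= nrow(m) && m$chrom[j] == m$chrom[i] &&
           m$pos[j] - m$pos[i] <= window_bp) {
      if (keep[j] && covered[j]) {
        r2 <- stats::cor(panel$dosage[, col[i]], panel$dosage[, col[j]])^2
        if (!is.na(r2) && r2 > r2_threshold) {
          loser <- prune_loser(i, j, maf_rule, p1, m$snp_id)
          keep[loser] <- FALSE
          if (loser == i) break
        }
      }
      j <- j + 1L
    }
  }
  out <- m[keep, , drop = FALSE]
  structure(out, n_removed = sum(!keep), n_uncovered = sum(!covered))
}

# index of the pair member the pruning rule removes
prune_loser <- function(i, j, maf, p1, ids) {
  if (maf[i] < maf[j]) return(i)
  if (maf[j] < maf[i]) return(j)
  if (!is.na(p1[i]) && !is.na(p1[j]) && p1[i] != p1[j]) {
    return(if (p1[i] < p1[j]) j else i)
  }
  if (ids[i] <= ids[j]) j else i
}

#' Greedy LD clumping
#'
#' Considers only SNPs with `p <= p_threshold`; in ascending order of p, each
#' surviving SNP becomes an index SNP and all remaining candidates within
#' `distance_kb` (same chromosome) or with panel r-squared above
#' `r2_threshold` to it are discarded. Candidates absent from the panel
#' cannot pass the LD test and are dropped (counted).
#'
#' @param t Summary-statistics tibble with columns `snp_id`, `chrom`, `pos`,
#'   `p`.
#' @param panel A [reference_panel()].
#' @param p_threshold Candidate p-value threshold.
#' @param r2_threshold Discard threshold on r-squared.
#' @param distance_kb Discard distance in kb.
#' @return Tibble of index SNPs (rows of `t`), with attributes `n_uncovered`
#'   and `clump_report` (tibble: index snp_id, n_removed).
#' @export
ld_clump <- function(t, panel, p_threshold = 1e-8, r2_threshold = 0.001,
                     distance_kb = 10) {
  stopifnot(all(c("snp_id", "chrom", "pos", "p") %in% names(t)))
  cand <- t |> filter(.data$p <= p_threshold)
  uncovered <- !panel_has(panel, cand$snp_id)
  n_uncovered <- sum(uncovered)
  cand <- cand[!uncovered, , drop = FALSE]
  cand <- arrange(cand, .data$p, .data$snp_id)
  col <- match(cand$snp_id, panel$snps$snp_id)

  kept <- integer(0)
  removed_by <- integer(0)
  alive <- rep(TRUE, nrow(cand))
  dist_bp <- distance_kb * 1000
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    later <- which(alive)
    later <- later[later > i]
    if (length(later) > 0) {
      near <- cand$chrom[later] == cand$chrom[i] &
        abs(cand$pos[later] - cand$pos[i]) <= dist_bp
      r2 <- ld_r2_vec(panel$dosage, col[i], col[later])
      drop <- near | (!is.na(r2) & r2 > r2_threshold)
      alive[later[drop]] <- FALSE
      removed_by <- c(removed_by, sum(drop))
    } else {
      removed_by <- c(removed_by, 0L)
    }
  }
  out <- cand[kept, , drop = FALSE]
  report <- tibble(snp_id = cand$snp_id[kept], n_removed = removed_by)
  if (n_uncovered > 0) {
    inform(sprintf("ld_clump(): dropped %d candidate SNP(s) absent from the panel.",
                   n_uncovered))
  }
  structure(out, n_uncovered = n_uncovered, clump_report = report)
}

#' Find proxy SNPs for an index SNP
#'
#' SNPs within `window_kb` of the index (same chromosome) with r-squared
#' above `r2_min` and D' equal to `d_prime_eq` within 1e-6, sorted by
#' descending r-squared. The index SNP itself is excluded.
#'
#' @param panel A [reference_panel()].
#' @param index Index SNP identifier (must be in the panel).
#' @param r2_min Minimum r-squared (strict), default 0.9.
#' @param d_prime_eq Required D' value, default 1.
#' @param window_kb Search window, default 500.
#' @return Tibble: `snp_i` (index), `snp_j`, `r2`, `d_prime`.
#' @export
find_proxies <- function(panel, index, r2_min = 0.9, d_prime_eq = 1.0,
                         window_kb = 500) {
  j0 <- match(index, panel$snps$snp_id)
  if (is.na(j0)) abort(sprintf("Index SNP '%s' is not in the reference panel.", index))
  s <- panel$snps
  near <- which(s$chrom == s$chrom[j0] &
                  abs(s$pos - s$pos[j0]) <= window_kb * 1000 &
                  s$snp_id != index)
  if (length(near) == 0) {
    return(tibble(snp_i = character(), snp_j = character(),
                  r2 = numeric(), d_prime = numeric()))
  }
  r2 <- ld_r2_vec(panel$dosage, j0, near)
  hits <- which(!is.na(r2) & r2 > r2_min)
  dp <- vapply(hits, function(k) {
    ld_d_prime(panel, index, s$snp_id[near[k]])
  }, numeric(1))
  ok <- !is.na(dp) & abs(dp - d_prime_eq) <= 1e-6
  out <- tibble(snp_i = index, snp_j = s$snp_id[near[hits[ok]]],
                r2 = r2[hits[ok]], d_prime = dp[ok])
  arrange(out, dplyr::desc(.data$r2))
}
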