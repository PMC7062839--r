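# Independent oracles, each a direct transcription of the defining rule,
# deliberately O(n^2) or iterate-to-fixed-point rather than sharing code
# with the implementations they check.

# conditional FDR by the definition: Q_i = p1_i / F(p1_i | p2 <= p2_i),
# pi0 = 1, capped at 1, monotone in p1 via minimum over all p1_j >= p1_i
cfdr_direct_oracle <- function(p1, p2) {
  n <- length(p1)
  q <- numeric(n)
  for (i in seq_len(n)) {
    sel <- p2 <= p2[i]
    n_i <- sum(sel)
    js <- which(p1 >= p1[i])
    vals <- vapply(js, function(j) {
      c_ij <- sum(p1 <= p1[j] & sel)
      min(1, p1[j] * n_i / c_ij)
    }, numeric(1))
    q[i] <- min(vals)
  }
  q
}

# fold enrichment by direct counting
fe_counting_oracle <- function(p1, p2, s, t) {
  n <- length(p1)
  in_s <- p2 <= s
  num <- sum(in_s & p1 <= 10^-t) / sum(in_s)
  den <- sum(p1 <= 10^-t) / n
  num / den
}

# pruning: repeatedly scan all within-window pairs in (chrom, pos) order and
# remove the lower-MAF member of the first violating pair, until none violates
prune_fixed_point_oracle <- function(m, r2_lookup, maf, window_bp, p1 = NULL) {
  ord <- order(m$chrom, m$pos, m$snp_id)
  m <- m[ord, ]; maf <- maf[ord]
  if (!is.null(p1)) p1 <- p1[ord]
  alive <- rep(TRUE, nrow(m))
  repeat {
    found <- FALSE
    idx <- which(alive)
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      for (j in idx[-seq_len(ai)]) {
        if (m$chrom[j] != m$chrom[i] || m$pos[j] - m$pos[i] > window_bp) next
        r2 <- r2_lookup(m$snp_id[i], m$snp_id[j])
        if (!is.na(r2) && r2 > 0.2) {
          loser <- if (maf[i] < maf[j]) i
            else if (maf[j] < maf[i]) j
            else if (!is.null(p1) && p1[i] != p1[j]) { if (p1[i] < p1[j]) j else i }
            else if (m$snp_id[i] <= m$snp_id[j]) j else i
          alive[loser] <- FALSE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
  }
  m$snp_id[alive]
}

# greedy clumping by explicit enumeration of the p-value order
clump_greedy_oracle <- function(t, r2_lookup, p_threshold, r2_threshold, dist_bp) {
  cand <- t[t$p <= p_threshold, ]
  cand <- cand[order(cand$p, cand$snp_id), ]
  kept <- character(0)
  discarded <- character(0)
  for (i in seq_len(nrow(cand))) {
    id <- cand$snp_id[i]
    if (id %in% discarded) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(cand))) {
      jd <- cand$snp_id[j]
      if (jd == id || jd %in% kept || jd %in% discarded) next
      near <- cand$chrom[j] == cand$chrom[i] &&
        abs(cand$pos[j] - cand$pos[i]) <= dist_bp
      r2 <- r2_lookup(id, jd)
      if (near || (!is.na(r2) && r2 > r2_threshold)) discarded <- c(discarded, jd)
    }
  }
  kept
}

# weighted least squares via the normal equations
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  b <- solve(XtWX, t(X) %*% (w * y))
  res <- y - X %*% b
  s2 <- sum(w * res^2) / (length(y) - 2)
  V <- s2 * solve(XtWX)
  list(intercept = b[1], slope = b[2],
       se_intercept = sqrt(V[1, 1]), se_slope = sqrt(V[2, 2]))
}

# orientation fix by exhaustive enumeration of the four recognised cases
harmonize_case_oracle <- function(ea1, oa1, ea2, oa2) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  if (ea2 == ea1 && oa2 == oa1) return("same")
  if (ea2 == oa1 && oa2 == ea1) return("swap")
  if (comp(ea2) == ea1 && comp(oa2) == oa1) return("comp")
  if (comp(ea2) == oa1 && comp(oa2) == ea1) return("comp_swap")
  "mismatch"
}
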