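#' Stratified fold-enrichment curves
#'
#' For each secondary-phenotype stratum `p2 <= s` and each grid point `t` on
#' the -log10(p) axis, the fold enrichment is
#'
#' \deqn{FE_s(t) = \frac{\#\{p_2 \le s,\ p_1 \le 10^{-t}\} / \#\{p_2 \le s\}}
#'                     {\#\{p_1 \le 10^{-t}\} / N}}
#'
#' i.e. the tail proportion of primary-trait significance inside the stratum,
#' relative to the same proportion among all SNPs. Pleiotropic enrichment
#' shows as curves that rise with increasingly stringent strata. Cells with
#' an empty numerator or denominator are `NA` (with a warning for entirely
#' empty strata, not an error).
#'
#' @param m Merged pair tibble (typically LD-pruned) with `p1`, `p2`.
#' @param strata Secondary p-value thresholds; must include the trivial
#'   stratum 1 (all SNPs), which is the baseline where FE is identically 1.
#' @param t_grid Ascending -log10(p1) evaluation points.
#' @param direction `"A|B"` (enrichment of trait A conditional on B) or
#'   `"B|A"` (roles swapped).
#' @return Tibble of class `stratified_curves`: `stratum`, `t`, `fe`,
#'   `n_stratum`, `n_tail`.
#' @export
fold_enrichment <- function(m, strata = c(1, 0.1, 0.01, 0.001),
                            t_grid = seq(0, 10, by = 0.25),
                            direction = c("A|B", "B|A")) {
  direction <- match.arg(direction)
  if (nrow(m) == 0) abort("fold_enrichment() needs a nonempty table.")
  if (!any(strata == 1)) {
    warn("Adding the trivial stratum (all SNPs, p2 <= 1) to `strata`.")
    strata <- c(1, strata)
  }
  strata <- sort(unique(strata), decreasing = TRUE)
  pp <- direction_p(m, direction)
  n <- length(pp$p1)
  t1 <- -log10(pp$p1)

  base_tail <- vapply(t_grid, function(t) sum(t1 >= t), numeric(1))
  rows <- purrr::map(strata, function(s) {
    in_s <- pp$p2 <= s
    n_s <- sum(in_s)
    if (n_s == 0) {
      warn(sprintf("Stratum p2 <= %g is empty; its curve is all NA.", s))
      return(tibble(stratum = s, t = t_grid, fe = NA_real_,
                    n_stratum = 0L, n_tail = 0L))
    }
    tail_s <- vapply(t_grid, function(t) sum(t1[in_s] >= t), numeric(1))
    fe <- ifelse(base_tail > 0, (tail_s / n_s) / (base_tail / n), NA_real_)
    tibble(stratum = s, t = t_grid, fe = fe,
           n_stratum = n_s, n_tail = as.integer(tail_s))
  })
  out <- bind_rows(rows)
  structure(out, class = c("stratified_curves", class(out)),
            curve_type = "fold_enrichment", direction = direction)
}

direction_p <- function(m, direction) {
  if (direction == "A|B") list(p1 = m$p1, p2 = m$p2) else list(p1 = m$p2, p2 = m$p1)
}

#' Conditional quantile-quantile curves
#'
#' For each stratum `p2 <= s`, pairs the observed order statistics of
#' -log10(p1) inside the stratum with the expected -log10 quantiles of the
#' uniform distribution, `-log10(k / (n_s + 1))`. Leftward deflections
#' (observed above expected in the tail) that grow with stratum stringency
#' indicate pleiotropic enrichment.
#'
#' @inheritParams fold_enrichment
#' @param min_count Strata with fewer SNPs are flagged `low_count`.
#' @return Tibble of class `stratified_curves`: `stratum`, `expected`,
#'   `observed`, `n_stratum`, `low_count`.
#' @export
conditional_qq <- function(m, strata = c(1, 0.1, 0.01, 0.001),
                           direction = c("A|B", "B|A"), min_count = 10) {
  direction <- match.arg(direction)
  if (nrow(m) == 0) abort("conditional_qq() needs a nonempty table.")
  strata <- sort(unique(c(1, strata)), decreasing = TRUE)
  pp <- direction_p(m, direction)
  rows <- purrr::map(strata, function(s) {
    obs <- sort(-log10(pp$p1[pp$p2 <= s]), decreasing = TRUE)
    n_s <- length(obs)
    if (n_s == 0) {
      warn(sprintf("Stratum p2 <= %g is empty; its curve is omitted.", s))
      return(NULL)
    }
    tibble(stratum = s,
           expected = -log10(seq_len(n_s) / (n_s + 1)),
           observed = obs,
           n_stratum = n_s,
           low_count = n_s < min_count)
  })
  out <- bind_rows(rows)
  structure(out, class = c("stratified_curves", class(out)),
            curve_type = "conditional_qq", direction = direction)
}

#' Per-SNP conditional false discovery rate
#'
#' Computes, for every SNP, the conditional FDR
#' \deqn{Q_i = p_{1i} / \hat F(p_{1i} \mid p_2 \le p_{2i})}
#' where \eqn{\hat F} is the empirical CDF of the primary p-value among SNPs
#' whose secondary p-value is at most \eqn{p_{2i}}. The null proportion is
#' treated as 1 (a conservative upper bound), values are capped at 1, and a
#' cumulative-minimum pass along the p1 axis of the lookup grid enforces
#' monotonicity in p1 within each conditioning level — the same step that
#' turns the raw Benjamini-Hochberg ratio into an adjusted value. Per-SNP
#' values are assigned by bilinear interpolation on the
#' (-log10 p1) x (-log10 p2-threshold) grid.
#'
#' @param m Merged pair tibble with `snp_id`, `chrom`, `pos`, `p1`, `p2`.
#' @param direction `"A|B"` (Q for trait A conditional on B) or `"B|A"`.
#' @param p1_grid p-value nodes of the p1 axis. `NULL` for the default 401
#'   log-spaced nodes from 1 down to 1e-20, or `"data"` to place one node at
#'   every observed p1 (exact, used for oracle comparisons).
#' @param p2_levels Conditioning thresholds on p2. `NULL` for the default
#'   `10^-(0:3)` extended one decade at a time while at least `min_count`
#'   SNPs remain in the conditioning subset, or `"data"` for one level per
#'   observed p2.
#' @param min_count Minimum conditioning-subset size used by the data-driven
#'   level refinement; levels with fewer SNPs are dropped with a warning.
#' @return Object of class `cfdr_result`: list with `snps` (tibble `snp_id`,
#'   `chrom`, `pos`, `p1`, `p2`, `q`), `grid` (list `t_nodes`, `p_nodes`,
#'   `levels`, `fdr` matrix nodes x levels, `n_level`), `direction`.
#' @export
cfdr <- function(m, direction = c("A|B", "B|A"), p1_grid = NULL,
                 p2_levels = NULL, min_count = 100) {
  direction <- match.arg(direction)
  stopifnot(all(c("snp_id", "chrom", "pos", "p1", "p2") %in% names(m)))
  m <- arrange(m, .data$chrom, .data$pos, .data$snp_id)
  pp <- direction_p(m, direction)
  if (any(pp$p1 <= 0 | pp$p1 > 1 | pp$p2 <= 0 | pp$p2 > 1)) {
    abort("p-values must lie in (0, 1].")
  }

  p_nodes <- if (is.null(p1_grid)) {
    10^(-seq(0, 20, length.out = 401))
  } else if (identical(p1_grid, "data")) {
    sort(unique(pp$p1), decreasing = TRUE)
  } else sort(unique(as.numeric(p1_grid)), decreasing = TRUE)
  t_nodes <- -log10(p_nodes)  # ascending

  t2 <- -log10(pp$p2)
  levels <- if (is.null(p2_levels)) {
    s <- 0:3
    while (sum(t2 >= max(s) + 1) >= min_count) s <- c(s, max(s) + 1)
    s
  } else if (identical(p2_levels, "data")) {
    sort(unique(t2))
  } else sort(unique(-log10(as.numeric(p2_levels))))

  n_level <- vapply(levels, function(s) sum(t2 >= s), integer(1))
  if (any(n_level == 0)) {
    warn("Dropping conditioning level(s) with no SNPs.")
    levels <- levels[n_level > 0]
    n_level <- n_level[n_level > 0]
  }
  if (length(levels) == 0) abort("No usable conditioning levels.")

  # clamp p1 below the smallest grid node onto that node
  t1 <- pmin(-log10(pp$p1), max(t_nodes))

  fdr <- matrix(NA_real_, nrow = length(t_nodes), ncol = length(levels))
  for (k in seq_along(levels)) {
    sub <- sort(t1[t2 >= levels[k]])
    n_k <- length(sub)
    # count of subset SNPs with t1 >= node  (p1 <= p_node)
    cnt <- n_k - findInterval(t_nodes, sub, left.open = TRUE)
    raw <- ifelse(cnt > 0, pmin(1, p_nodes * n_k / cnt), Inf)
    fdr[, k] <- cummin(raw)
  }
  fdr[!is.finite(fdr)] <- NA_real_

  q <- interp_grid(t_nodes, levels, fdr, t1, pmin(pmax(t2, min(levels)), max(levels)))
  snps <- tibble(snp_id = m$snp_id, chrom = m$chrom, pos = m$pos,
                 p1 = pp$p1, p2 = pp$p2, q = q)
  structure(list(snps = snps,
                 grid = list(t_nodes = t_nodes, p_nodes = p_nodes,
                             levels = levels, fdr = fdr, n_level = n_level),
                 direction = direction),
            class = "cfdr_result")
}

# bilinear interpolation on an ascending (t_nodes x levels) grid
interp_grid <- function(t_nodes, levels, M, t1, t2) {
  it <- findInterval(t1, t_nodes, all.inside = TRUE)
  wt <- (t1 - t_nodes[it]) / (t_nodes[it + 1] - t_nodes[it])
  wt <- pmin(pmax(wt, 0), 1)
  if (length(levels) == 1) {
    col <- M[, 1]
    return((1 - wt) * col[it] + wt * col[it + 1])
  }
  is <- findInterval(t2, levels, all.inside = TRUE)
  ws <- (t2 - levels[is]) / (levels[is + 1] - levels[is])
  ws <- pmin(pmax(ws, 0), 1)
  lo <- (1 - wt) * M[cbind(it, is)] + wt * M[cbind(it + 1, is)]
  hi <- (1 - wt) * M[cbind(it, is + 1)] + wt * M[cbind(it + 1, is + 1)]
  (1 - ws) * lo + ws * hi
}

#' @export
print.cfdr_result <- function(x, ...) {
  cat(sprintf("<cfdr_result> Q(%s): %d SNPs, grid %d x %d\n",
              x$direction, nrow(x$snps), length(x$grid$t_nodes),
              length(x$grid$levels)))
  print(utils::head(x$snps, 5))
  invisible(x)
}

#' @export
#' @rdname cfdr
#' @param x A `cfdr_result`.
#' @param ... Unused.
tidy.cfdr_result <- function(x, ...) x$snps

#' @export
#' @rdname cfdr
glance.cfdr_result <- function(x, ...) {
  tibble(direction = x$direction, n_snps = nrow(x$snps),
         n_grid_nodes = length(x$grid$t_nodes),
         n_levels = length(x$grid$levels),
         n_q_below_0.05 = sum(x$snps$q <= 0.05))
}

#' Conjunction conditional FDR
#'
#' The conjunction FDR for a SNP is the maximum of its two directional
#' conditional FDR values, an upper bound on the probability that the SNP is
#' null for either phenotype.
#'
#' @param q_ab `cfdr_result` for direction A|B.
#' @param q_ba `cfdr_result` for direction B|A.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `p1`, `p2`, `q_ab`, `q_ba`, `cc`.
#' @export
cfdr_conjunction <- function(q_ab, q_ba) {
  a <- if (inherits(q_ab, "cfdr_result")) q_ab$snps else as_tibble(q_ab)
  b <- if (inherits(q_ba, "cfdr_result")) q_ba$snps else as_tibble(q_ba)
  if (!setequal(a$snp_id, b$snp_id) || nrow(a) != nrow(b)) {
    abort("Conjunction requires the same SNP universe in both directions.")
  }
  a |>
    select("snp_id", "chrom", "pos", p1 = "p1", q_ab = "q") |>
    inner_join(b |> select("snp_id", p2 = "p1", q_ba = "q"), by = "snp_id") |>
    mutate(cc = pmax(.data$q_ab, .data$q_ba)) |>
    arrange(.data$chrom, .data$pos, .data$snp_id)
}

#' Tier significant SNPs by conditional FDR
#'
#' Labels each SNP with the smallest threshold its Q value meets, using `<=`
#' comparisons at every boundary: `genome_wide` (Q <= 5e-8), `suggestive`
#' (Q <= 1e-5), `significant` (Q <= 0.05), otherwise `ns`.
#'
#' @param r A `cfdr_result`, or a tibble containing the Q column.
#' @param value Name of the Q column when `r` is a tibble (default `"q"`;
#'   use `"cc"` for conjunction results).
#' @param q_threshold,suggestive,genome_wide Tier thresholds, which must be
#'   monotone: `genome_wide <= suggestive <= q_threshold`.
#' @return The per-SNP tibble with an added ordered factor column `tier`.
#' @export
call_significant <- function(r, q_threshold = 0.05, suggestive = 1e-5,
                             genome_wide = 5e-8, value = "q") {
  if (!(genome_wide <= suggestive && suggestive <= q_threshold)) {
    abort("Thresholds must satisfy genome_wide <= suggestive <= q_threshold.")
  }
  t <- if (inherits(r, "cfdr_result")) r$snps else as_tibble(r)
  if (!value %in% names(t)) abort(sprintf("No column '%s' in the result.", value))
  q <- t[[value]]
  tier <- dplyr::case_when(
    q <= genome_wide ~ "genome_wide",
    q <= suggestive ~ "suggestive",
    q <= q_threshold ~ "significant",
    TRUE ~ "ns"
  )
  t$tier <- factor(tier, levels = c("ns", "significant", "suggestive",
                                    "genome_wide"), ordered = TRUE)
  t
}
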