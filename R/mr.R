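#' Select MR instruments from harmonized summary statistics
#'
#' Clumps the exposure GWAS (greedy by p-value; see [ld_clump()]) at the
#' instrument threshold, intersects the surviving index SNPs with the outcome
#' GWAS, and orients every instrument so its exposure effect is non-negative
#' (the standard Egger convention, without which the intercept is not
#' identifiable).
#'
#' @param exposure,outcome Summary-statistics tibbles sharing an allele
#'   orientation (e.g. the two sides of [harmonize()]); need `snp_id`,
#'   `chrom`, `pos`, `beta`, `se`, `p`.
#' @param panel A [reference_panel()] for the clumping LD test.
#' @param p_threshold Instrument p-value threshold (default 1e-8).
#' @param clump_r2 Clumping r-squared threshold (default 0.001).
#' @param clump_kb Clumping distance in kb (default 10).
#' @return Tibble: `snp_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `flipped` (orientation flag).
#' @export
select_instruments <- function(exposure, outcome, panel, p_threshold = 1e-8,
                               clump_r2 = 0.001, clump_kb = 10) {
  idx <- ld_clump(exposure, panel, p_threshold = p_threshold,
                  r2_threshold = clump_r2, distance_kb = clump_kb)
  inst <- idx |>
    select("snp_id", beta_exposure = "beta", se_exposure = "se") |>
    inner_join(outcome |> select("snp_id", beta_outcome = "beta",
                                 se_outcome = "se"),
               by = "snp_id")
  if (nrow(inst) < 3) {
    abort(sprintf(
      "Insufficient instruments: %d survive clumping and outcome lookup (need >= 3).",
      nrow(inst)))
  }
  flip <- inst$beta_exposure < 0
  inst$beta_exposure[flip] <- -inst$beta_exposure[flip]
  inst$beta_outcome[flip] <- -inst$beta_outcome[flip]
  inst$flipped <- flip
  inst
}

#' MR-Egger regression
#'
#' Weighted least squares of the instruments' outcome effects on their
#' exposure effects with a free intercept, weights `1 / se_outcome^2`. The
#' slope estimates the causal effect (log-odds outcome per log-odds
#' exposure); a nonzero intercept indicates directional horizontal
#' pleiotropy. Standard errors come from the WLS covariance; confidence
#' intervals and p-values use the t distribution with `n - 2` degrees of
#' freedom (set `normal = TRUE` for the normal approximation).
#'
#' @param inst Instrument tibble from [select_instruments()] (or any tibble
#'   with `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @param normal Use normal rather than t reference distribution.
#' @return Object of class `mr_egger_fit` with slope/intercept estimates,
#'   SEs, CI, p-values, the OR-scale slope, and the fitted `lm`.
#' @export
mr_egger <- function(inst, conf_level = 0.95, normal = FALSE) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(inst)))
  n <- nrow(inst)
  if (n < 3) abort(sprintf("MR-Egger needs >= 3 instruments, got %d.", n))
  if (any(inst$se_outcome <= 0)) abort("Outcome standard errors must be positive.")
  if (stats::var(inst$beta_exposure) == 0) {
    abort("Degenerate design: all exposure effects are identical.")
  }
  fit <- lm(beta_outcome ~ beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  est <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  df <- n - 2L
  crit <- if (normal) qnorm(1 - (1 - conf_level) / 2) else stats::qt(1 - (1 - conf_level) / 2, df)
  pfun <- function(z) {
    if (normal) 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), df)
  }
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  structure(list(
    slope = unname(est[2]), slope_se = unname(se[2]),
    slope_ci = unname(est[2] + c(-1, 1) * crit * se[2]),
    slope_p = unname(pfun(tval[2])),
    intercept = unname(est[1]), intercept_se = unname(se[1]),
    intercept_p = unname(pfun(tval[1])),
    or = exp(unname(est[2])),
    or_ci = exp(unname(est[2] + c(-1, 1) * crit * se[2])),
    n_instruments = n, df = df, conf_level = conf_level, normal = normal,
    fit = fit
  ), class = "mr_egger_fit")
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat("MR-Egger regression (", x$n_instruments, " instruments)\n", sep = "")
  cat(sprintf("  slope      %8.4f (SE %.4f), OR %.3f [%.3f, %.3f], p = %.3g\n",
              x$slope, x$slope_se, x$or, x$or_ci[1], x$or_ci[2], x$slope_p))
  cat(sprintf("  intercept  %8.4f (SE %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
#' @rdname mr_egger
#' @param x An `mr_egger_fit`.
#' @param ... Unused.
tidy.mr_egger_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se),
         p.value = c(x$intercept_p, x$slope_p),
         conf.low = c(NA, x$slope_ci[1]),
         conf.high = c(NA, x$slope_ci[2]))
}

#' @export
#' @rdname mr_egger
glance.mr_egger_fit <- function(x, ...) {
  tibble(or = x$or, or_ci_low = x$or_ci[1], or_ci_high = x$or_ci[2],
         slope_p = x$slope_p, intercept_p = x$intercept_p,
         n_instruments = x$n_instruments, df = x$df)
}

#' Directional horizontal pleiotropy test
#'
#' Reports the Egger intercept, its p-value, and a verdict at `alpha`: a
#' significant intercept indicates that instruments influence the outcome
#' through pathways other than the exposure.
#'
#' @param fit An [mr_egger()] result.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `intercept`, `intercept_se`, `intercept_p`,
#'   `alpha`, `significant`, `verdict`.
#' @export
mr_intercept_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mr_egger_fit"))
  sig <- fit$intercept_p <= alpha
  tibble(intercept = fit$intercept, intercept_se = fit$intercept_se,
         intercept_p = fit$intercept_p, alpha = alpha, significant = sig,
         verdict = if (sig) "directional pleiotropy detected"
                   else "no significant directional pleiotropy")
}
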