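#' @importFrom rlang %||% abort warn inform .data
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows
#'   group_by ungroup summarise n row_number distinct across pull rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm rnorm runif rbinom setNames coef lm pt
#' @importFrom utils head tail
NULL

# complement of a (possibly multi-base) allele string; non-ACGT bases pass through
complement_allele <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

is_strand_ambiguous <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# minor allele frequency folded onto (0, 0.5]
fold_maf <- function(f) pmin(f, 1 - f)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# smallest positive double; used to clamp p = 0 before any log-scale work
.p_floor <- function() .Machine$double.xmin
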