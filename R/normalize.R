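#' Per-gene Z-score normalization
#'
#' Transforms every row to `(x - mean) / sd` using the population standard
#' deviation (divisor T, not T-1). Genes with zero variance across the series
#' cannot be scaled; they are mapped to all-zero rows and recorded in the
#' `"flagged_genes"` attribute rather than producing NaNs, so downstream KS
#' samples stay complete.
#'
#' @param m an [expression_matrix] with at least 2 time points.
#' @return an [expression_matrix] with `scale_tag = "zscore"`; constant genes
#'   listed in `attr(, "flagged_genes")`.
#' @export
#' @examples
#' m <- expression_matrix(rbind(gA = c(1, 2, 3), gB = c(5, 5, 5)),
#'                        times = c(0, 1, 2))
#' z <- zscore_rows(m)
#' z$values
#' attr(z, "flagged_genes")
zscore_rows <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  T <- length(m$times)
  if (T < 2L) stop("Z-scoring needs at least 2 time points (sd undefined)")
  mu <- rowMeans(m$values)
  centered <- m$values - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  flagged <- m$gene_ids[sd_pop == 0]
  sd_safe <- ifelse(sd_pop == 0, 1, sd_pop)
  z <- centered / sd_safe
  out <- expression_matrix(z, gene_ids = m$gene_ids, times = m$times,
                           scale_tag = "zscore")
  attr(out, "flagged_genes") <- flagged
  out
}

# Map one column onto the reference distribution by within-column rank.
# Ties (exactly equal values) receive the mean of the reference values over
# the tied rank range.
qn_map_column <- function(x, ref) {
  out <- numeric(length(x))
  out[order(x)] <- ref
  stats::ave(out, x, FUN = mean)
}

#' Quantile normalization across time points
#'
#' Forces every column (time point) to share one reference distribution: the
#' per-rank arithmetic mean of the column-sorted values (the standard
#' expression-array construction). Each value is replaced by the reference
#' value at its within-column rank; tied values receive the mean of the
#' reference over the tied rank range. The transform preserves within-column
#' rank order and is idempotent.
#'
#' @param m an [expression_matrix].
#' @param ref_fun function combining sorted columns into the reference at
#'   each rank; `mean` (default, the convention) or e.g. `median`.
#' @return an [expression_matrix] with `scale_tag = "qn"` (or `"zqn"` if the
#'   input was Z-scored).
#' @export
#' @examples
#' m <- expression_matrix(cbind(`0` = c(2, 4, 6), `10` = c(5, 1, 3)),
#'                        gene_ids = c("g1", "g2", "g3"))
#' quantile_normalize(m)$values  # reference is (1.5, 3.5, 5.5)
quantile_normalize <- function(m, ref_fun = mean) {
  stopifnot(inherits(m, "expression_matrix"))
  sorted <- apply(m$values, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = 1L)
  ref <- apply(sorted, 1L, ref_fun)
  out <- apply(m$values, 2L, qn_map_column, ref = ref)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
  tag <- if (m$scale_tag %in% c("zscore", "zqn")) "zqn" else "qn"
  res <- expression_matrix(out, gene_ids = m$gene_ids, times = m$times,
                           scale_tag = tag)
  attr(res, "flagged_genes") <- attr(m, "flagged_genes")
  res
}

#' Z-score quantile normalization
#'
#' The composition [quantile_normalize()] applied to [zscore_rows()] output.
#' Whereas plain quantile normalization acts on the raw scale before any
#' Z-scoring, here the per-gene Z-scores themselves are distribution-matched
#' across time points -- the order of operations is the only difference, and
#' it matters for bimodal anomalies, which survive raw-scale quantile
#' normalization (ranks within the anomalous column are reshuffled, not
#' restored) but not Z-score quantile normalization.
#'
#' @param m a raw-scale [expression_matrix].
#' @inheritParams quantile_normalize
#' @return an [expression_matrix] with `scale_tag = "zqn"`.
#' @export
zscore_quantile_normalize <- function(m, ref_fun = mean) {
  stopifnot(inherits(m, "expression_matrix"))
  quantile_normalize(zscore_rows(m), ref_fun = ref_fun)
}
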