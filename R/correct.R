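#' Reconstruct anomalous time points by monotone piecewise-cubic
#' interpolation
#'
#' Per gene, the STRIPE columns are dropped and a shape-preserving piecewise
#' cubic Hermite interpolant (PCHIP, Fritsch-Carlson node derivatives: zero
#' at interior local extrema, weighted harmonic mean of the adjacent secant
#' slopes otherwise, shape-preserving one-sided formula at the ends) is fit
#' through the remaining (time, value) nodes and evaluated at the dropped
#' times. The interpolant is local and never overshoots the bracketing node
#' values on monotone segments. Non-STRIPE columns are returned bit-
#' unchanged. None of the information inside the anomalous columns is used.
#'
#' A STRIPE at the first or last time point cannot be interpolated (there is
#' no bracketing node); such points are filled with the value of the nearest
#' remaining column and a prominent warning is raised -- terminal anomalies
#' are better dropped or corrected by a normalization scheme.
#'
#' @param m an [expression_matrix].
#' @param stripe_times numeric time labels to drop and reconstruct; must be
#'   a subset of `m$times`, leaving at least 2 columns.
#' @return an [expression_matrix] on the same scale as the input.
#' @export
#' @examples
#' m <- expression_matrix(rbind(g = c(1, 2, 9, 4, 5)),
#'                        times = c(0, 10, 20, 30, 40))
#' interpolate_stripes(m, 20)$values  # the spike at t=20 becomes 3
interpolate_stripes <- function(m, stripe_times) {
  stopifnot(inherits(m, "expression_matrix"))
  if (length(stripe_times) == 0L) return(m)
  idx <- match(stripe_times, m$times)
  if (anyNA(idx))
    stop("stripe time(s) not in the matrix: ",
         paste(stripe_times[is.na(idx)], collapse = ", "))
  keep <- setdiff(seq_along(m$times), idx)
  if (length(keep) < 2L)
    stop("interpolation needs at least 2 remaining non-STRIPE time points")
  tk <- m$times[keep]
  ts <- m$times[idx]
  interior <- ts > min(tk) & ts < max(tk)
  if (any(!interior))
    warning("STRIPE at a terminal time point (",
            paste(format(ts[!interior], trim = TRUE), collapse = ", "),
            "): filled with the nearest remaining column's values, NOT ",
            "interpolated; consider dropping it or using a normalization ",
            "correction", call. = FALSE)
  out <- m$values
  G <- nrow(out)
  for (g in seq_len(G)) {
    yk <- m$values[g, keep]
    if (any(interior))
      out[g, idx[interior]] <- pracma::pchip(tk, yk, ts[interior])
    if (any(!interior)) {
      for (s in which(!interior)) {
        nearest <- keep[which.min(abs(tk - ts[s]))]
        out[g, idx[s]] <- m$values[g, nearest]
      }
    }
  }
  res <- expression_matrix(out, gene_ids = m$gene_ids, times = m$times,
                           scale_tag = m$scale_tag)
  attr(res, "flagged_genes") <- attr(m, "flagged_genes")
  res
}

#' Detect, correct, and verify STRIPEs in one step
#'
#' Runs [detect_stripes()], applies the chosen correction, then re-runs the
#' detector on the corrected matrix at the same threshold. A STRIPE time
#' point counts as corrected when it is no longer detected at that
#' threshold; points still flagged are reported as residual.
#'
#' Correction methods:
#' \describe{
#'   \item{`interpolation`}{drops the detected (or user-supplied) STRIPE
#'     columns and reconstructs them with [interpolate_stripes()]; acts on
#'     the input scale and touches only the anomalous columns.}
#'   \item{`qn`}{[quantile_normalize()] of the whole matrix on its input
#'     (raw) scale, before any Z-scoring.}
#'   \item{`zqn`}{[zscore_quantile_normalize()]: Z-score first, then
#'     quantile normalize. Unlike `qn`, this also removes bimodal anomalies,
#'     because the STRIPE definition rests on the Z-score distributions and
#'     `zqn` matches exactly those.}
#' }
#'
#' Verification preprocessing is chosen to be consistent with each method's
#' output scale: after `interpolation` or `qn` the corrected matrix is
#' re-Z-scored for re-detection; after `zqn` the output is already the
#' distribution-matched Z-score scale, so re-detection runs with
#' `preprocess = "none"`.
#'
#' @inheritParams detect_stripes
#' @param method `"interpolation"`, `"qn"` or `"zqn"`.
#' @param stripe_times optional explicit list of time labels to correct
#'   (interpolation only); overrides the detected set, e.g. to exclude
#'   points suspected to be biological. The before/after bookkeeping still
#'   refers to the detected set.
#' @return an object of class `"stripe_correction"`: list with `corrected`
#'   (the corrected [expression_matrix]), `method`, `calls_before`,
#'   `calls_after`, `corrected_timepoints` (labels that went 1 to 0) and
#'   `residual_timepoints` (labels still 1).
#' @export
correct_stripes <- function(m, method = c("interpolation", "qn", "zqn"),
                            threshold = 0.3,
                            preprocess = c("zscore", "none"),
                            max_consecutive = 5L, stripe_times = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  preprocess <- match.arg(preprocess)
  threshold <- as_threshold_spec(threshold)

  before <- detect_stripes(m, threshold, preprocess = preprocess,
                           max_consecutive = max_consecutive)
  detected <- before$time[before$label == 1L]
  to_fix <- if (is.null(stripe_times)) detected else stripe_times

  corrected <- switch(method,
    interpolation = interpolate_stripes(m, to_fix),
    qn = quantile_normalize(m),
    zqn = zscore_quantile_normalize(m))

  after_pre <- if (method == "zqn") "none" else preprocess
  after <- detect_stripes(corrected, threshold, preprocess = after_pre,
                          max_consecutive = max_consecutive)
  after_label <- after$label[match(detected, after$time)]
  structure(list(corrected = corrected, method = method,
                 calls_before = before, calls_after = after,
                 corrected_timepoints = detected[after_label == 0L],
                 residual_timepoints = detected[after_label == 1L]),
            class = "stripe_correction")
}

#' @export
print.stripe_correction <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(format(v, trim = TRUE),
                                          collapse = " ") else "none"
  cat(sprintf("<stripe_correction> method = %s\n", x$method))
  cat("  STRIPEs before:", fmt(stripe_times(x$calls_before)), "\n")
  cat("  corrected:     ", fmt(x$corrected_timepoints), "\n")
  cat("  residual:      ", fmt(x$residual_timepoints), "\n")
  invisible(x)
}
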