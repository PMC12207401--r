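#' Specify a detection threshold
#'
#' The detector labels a time point a STRIPE when its KS metric against the
#' current anchor crosses the threshold: strictly `D > value` in distance
#' mode, strictly `p < value` in p-value mode (exact equality is
#' non-STRIPE).
#'
#' @param value numeric threshold: a KS distance in (0, 1) or a p-value in
#'   (0, 1).
#' @param metric `"distance"` (default) or `"pvalue"`.
#' @return an object of class `"threshold_spec"`.
#' @export
threshold_spec <- function(value, metric = c("distance", "pvalue")) {
  metric <- match.arg(metric)
  value <- as.numeric(value)
  if (length(value) != 1L || is.na(value) || value <= 0 || value >= 1)
    stop("threshold value must be a single number strictly inside (0, 1)")
  structure(list(metric = metric, value = value), class = "threshold_spec")
}

as_threshold_spec <- function(x) {
  if (inherits(x, "threshold_spec")) x else threshold_spec(x)
}

# Asymptotic two-sided Kolmogorov distribution tail Q(lambda).
kolmogorov_tail <- function(lambda) {
  if (lambda < 1e-10) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Two-sample Kolmogorov-Smirnov distance and p-value
#'
#' The distance is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs. The p-value is the two-sided
#' asymptotic Kolmogorov distribution evaluated at
#' `D * sqrt(n1 * n2 / (n1 + n2))`, clamped to (0, 1]; at transcriptome
#' sample sizes (thousands of genes per time point) the asymptotic form is
#' accurate and tie-robust, so no exact small-sample p is computed.
#'
#' @param a,b non-empty numeric samples.
#' @return a list with elements `D` (in \[0, 1\]) and `p` (in (0, 1\]).
#' @export
#' @examples
#' ks_two_sample(c(1, 2), c(1, 3))  # D = 0.5
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  w <- c(a, b)
  o <- order(w)
  # step +1/n1 for points of a, -1/n2 for points of b, cumulated in sorted
  # order gives F_a - F_b; at ties only the value at the end of the tie
  # group is an evaluation of the ECDF difference at a pooled point.
  steps <- ifelse(o <= n1, 1 / n1, -1 / n2)
  z <- cumsum(steps)
  ws <- w[o]
  at_point <- c(diff(ws) != 0, TRUE)
  D <- max(abs(z[at_point]))
  D <- min(max(D, 0), 1)
  lambda <- D * sqrt(n1 * n2 / (n1 + n2))
  list(D = D, p = kolmogorov_tail(lambda))
}

crosses_threshold <- function(ks, threshold) {
  if (threshold$metric == "distance") ks$D > threshold$value
  else ks$p < threshold$value
}

# One sequential pass over the columns of X.
# order_idx: candidate columns in scan order; start_idx: the assumed
# non-STRIPE starting anchor. Returns labels/D/p/anchor per column, or
# budget_exhausted = TRUE if max_consecutive consecutive STRIPEs occur.
stripe_pass <- function(X, times, start_idx, order_idx, threshold,
                        max_consecutive) {
  T <- ncol(X)
  labels <- rep(NA_integer_, T)
  D <- rep(NA_real_, T); P <- rep(NA_real_, T)
  anchor_time <- rep(NA_real_, T)
  labels[start_idx] <- 0L
  D[start_idx] <- 0; P[start_idx] <- 1
  anchor_time[start_idx] <- times[start_idx]
  anchor <- start_idx
  consec <- 0L
  for (t in order_idx) {
    ks <- ks_two_sample(X[, t], X[, anchor])
    D[t] <- ks$D; P[t] <- ks$p
    anchor_time[t] <- times[anchor]
    if (crosses_threshold(ks, threshold)) {
      labels[t] <- 1L
      consec <- consec + 1L
      if (consec >= max_consecutive)
        return(list(budget_exhausted = TRUE))
    } else {
      labels[t] <- 0L
      anchor <- t
      consec <- 0L
    }
  }
  list(budget_exhausted = FALSE, labels = labels, D = D, P = P,
       anchor_time = anchor_time)
}

ambiguous_condition <- function(max_consecutive) {
  errorCondition(
    sprintf(paste0(
      "ambiguous: both scan directions hit %d consecutive STRIPEs; ",
      "STRIPE identity cannot be established sequentially -- inspect ",
      "pairwise_distance_matrix() or drop time points"), max_consecutive),
    class = c("stripe_ambiguous", "error"))
}

#' Sequential STRIPE detection
#'
#' Labels each time point STRIPE (1) or non-STRIPE (0) by comparing its
#' transcript-level distribution to the most recent non-STRIPE neighbor with
#' a two-sample KS test. The procedure first compares time points 1 and 2.
#' If that metric does not cross the threshold, a forward pass runs anchored
#' at point 1: each subsequent point is compared to the most recent point
#' labeled 0, labeled 1 if the metric crosses the threshold, and otherwise
#' labeled 0 and made the new anchor. If the initial pair crosses the
#' threshold (so the front of the series cannot be trusted as a non-STRIPE
#' reference), or if `max_consecutive` consecutive STRIPEs accumulate during
#' the forward pass, the scan is repeated in the reverse direction anchored
#' at the last time point. If the reverse pass also exhausts the consecutive
#' budget, detection aborts with an error of class `"stripe_ambiguous"`
#' directing the user to the all-by-all distance matrix.
#'
#' The procedure assumes the series starts (or, in reverse, ends) with a
#' non-STRIPE point; the anchor point therefore always carries label 0 with
#' a self-anchor, D = 0 and p = 1.
#'
#' @param m an [expression_matrix] with at least 3 time points.
#' @param threshold a [threshold_spec], or a bare number interpreted as a KS
#'   distance threshold. Default 0.3 (distance) -- a tool default; always
#'   review [suggest_threshold()] output for your dataset.
#' @param preprocess `"zscore"` (default; the STRIPE definition rests on
#'   per-gene Z-score distributions) or `"none"` for data that are already
#'   on a common distributional scale.
#' @param max_consecutive consecutive-STRIPE budget per direction before the
#'   scan direction is abandoned; default 5.
#' @return an object of class `"stripe_calls"`: a data frame with columns
#'   `time`, `label`, `ks_distance`, `p_value`, `anchor_time`, plus
#'   attributes `direction` (`"forward"` or `"reverse"`), `threshold`,
#'   `max_consecutive` and `preprocess`.
#' @seealso [pairwise_distance_matrix()], [suggest_threshold()],
#'   [correct_stripes()]
#' @export
detect_stripes <- function(m, threshold = 0.3,
                           preprocess = c("zscore", "none"),
                           max_consecutive = 5L) {
  stopifnot(inherits(m, "expression_matrix"))
  preprocess <- match.arg(preprocess)
  threshold <- as_threshold_spec(threshold)
  max_consecutive <- as.integer(max_consecutive)
  if (max_consecutive < 1L) stop("max_consecutive must be >= 1")
  T <- length(m$times)
  if (T < 3L) stop("sequential detection needs at least 3 time points")
  X <- if (preprocess == "zscore") zscore_rows(m)$values else m$values

  initial <- ks_two_sample(X[, 1L], X[, 2L])
  direction <- "forward"
  res <- NULL
  if (!crosses_threshold(initial, threshold)) {
    res <- stripe_pass(X, m$times, start_idx = 1L, order_idx = 2:T,
                       threshold = threshold,
                       max_consecutive = max_consecutive)
    if (res$budget_exhausted) res <- NULL
  }
  if (is.null(res)) {
    direction <- "reverse"
    res <- stripe_pass(X, m$times, start_idx = T,
                       order_idx = rev(seq_len(T - 1L)),
                       threshold = threshold,
                       max_consecutive = max_consecutive)
    if (res$budget_exhausted) stop(ambiguous_condition(max_consecutive))
  }
  out <- data.frame(time = m$times, label = res$labels,
                    ks_distance = res$D, p_value = res$P,
                    anchor_time = res$anchor_time)
  structure(out, class = c("stripe_calls", "data.frame"),
            direction = direction, threshold = threshold,
            max_consecutive = max_consecutive, preprocess = preprocess)
}

#' @export
print.stripe_calls <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf(
    "<stripe_calls> %d time points, %d STRIPE(s); %s pass, %s threshold %g\n",
    nrow(x), sum(x$label), attr(x, "direction"), thr$metric, thr$value))
  if (any(x$label == 1L))
    cat("  STRIPE times:",
        paste(format(x$time[x$label == 1L], trim = TRUE), collapse = " "),
        "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' STRIPE time labels from a call set
#' @param calls a `stripe_calls` object.
#' @return numeric vector of time labels with label 1.
#' @export
stripe_times <- function(calls) {
  stopifnot(inherits(calls, "stripe_calls"))
  calls$time[calls$label == 1L]
}

#' All-by-all pairwise KS distance matrix
#'
#' Compares every pair of time points with a two-sample KS test, the
#' fallback view when sequential detection is ambiguous and a direct display
#' of anomaly structure.
#'
#' @inheritParams detect_stripes
#' @return an object of class `"ks_distance_matrix"`: list with `times`, the
#'   symmetric zero-diagonal `D` matrix and the p-value matrix `P`.
#' @export
pairwise_distance_matrix <- function(m, preprocess = c("zscore", "none")) {
  stopifnot(inherits(m, "expression_matrix"))
  preprocess <- match.arg(preprocess)
  T <- length(m$times)
  if (T < 2L) stop("need at least 2 time points")
  X <- if (preprocess == "zscore") zscore_rows(m)$values else m$values
  D <- matrix(0, T, T); P <- matrix(1, T, T)
  for (i in seq_len(T - 1L)) for (j in (i + 1L):T) {
    ks <- ks_two_sample(X[, i], X[, j])
    D[i, j] <- D[j, i] <- ks$D
    P[i, j] <- P[j, i] <- ks$p
  }
  lab <- format(m$times, trim = TRUE, digits = 15)
  dimnames(D) <- dimnames(P) <- list(lab, lab)
  structure(list(times = m$times, D = D, P = P),
            class = "ks_distance_matrix")
}

#' @export
print.ks_distance_matrix <- function(x, ...) {
  cat(sprintf("<ks_distance_matrix> %d x %d time points\n",
              length(x$times), length(x$times)))
  print(round(x$D, 3))
  invisible(x)
}

# Robust outlier flags for a vector of distances: |d - median| / mad(d) with
# the consistency constant 1.4826 folded into stats::mad.
robust_outliers <- function(d, fence = 3.5) {
  med <- stats::median(d)
  s <- stats::mad(d)
  if (s == 0) {
    warning("all neighbor distances (essentially) identical; ",
            "no outliers can be flagged")
    return(list(flag = rep(FALSE, length(d)), fence_value = NA_real_,
                robust_z = rep(NA_real_, length(d))))
  }
  z <- abs(d - med) / s
  list(flag = z > fence, fence_value = med + fence * s, robust_z = z)
}

#' Suggest a detection threshold from neighbor-distance outliers
#'
#' Computes the KS distance between each time point and its immediate
#' predecessor, then flags comparisons whose distance is a robust outlier:
#' `|d - median| / (1.4826 * MAD) > fence` (default fence 3.5). Anomalous
#' time points sit far from their neighbors, so their comparisons stand out
#' from the bulk of biological point-to-point variation. The suggestion is
#' advisory only -- it is never applied automatically, mirroring the practice
#' of picking the threshold from the distance distribution by inspection.
#'
#' @inheritParams detect_stripes
#' @param fence robust z-score cutoff, default 3.5.
#' @return an object of class `"threshold_report"`: list with
#'   `neighbor_distances` (data frame `from`, `to`, `ks_distance`,
#'   `robust_z`, `outlier`), `suggested_outliers` (time labels of the later
#'   point in each flagged comparison) and `fence` (the numeric distance
#'   cutoff implied by the rule, NA when the MAD is zero).
#' @export
suggest_threshold <- function(m, preprocess = c("zscore", "none"),
                              fence = 3.5) {
  stopifnot(inherits(m, "expression_matrix"))
  preprocess <- match.arg(preprocess)
  T <- length(m$times)
  if (T < 4L) stop("threshold suggestion needs at least 4 time points")
  X <- if (preprocess == "zscore") zscore_rows(m)$values else m$values
  d <- vapply(2:T, function(i) ks_two_sample(X[, i - 1L], X[, i])$D,
              numeric(1))
  ro <- robust_outliers(d, fence)
  nd <- data.frame(from = m$times[-T], to = m$times[-1L], ks_distance = d,
                   robust_z = ro$robust_z, outlier = ro$flag)
  structure(list(neighbor_distances = nd,
                 suggested_outliers = nd$to[nd$outlier],
                 fence = ro$fence_value),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report> consecutive-neighbor KS distances\n")
  print(x$neighbor_distances)
  if (length(x$suggested_outliers))
    cat("suggested outlier time point(s):",
        paste(format(x$suggested_outliers, trim = TRUE), collapse = " "),
        sprintf("(fence %.4g)\n", x$fence))
  else cat("no outlying comparisons flagged\n")
  invisible(x)
}
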