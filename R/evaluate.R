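#' Rank genes by cosinor periodicity score
#'
#' Fits, per gene, the single-harmonic linear model
#' `x(t) ~ b0 + b1*cos(2*pi*t/period) + b2*sin(2*pi*t/period)` by least
#' squares and scores it with the coefficient of determination R^2. This is
#' a deliberately simple stand-in for dedicated periodicity tools
#' (JTK_CYCLE, Lomb-Scargle, ...): any external ranking can be supplied
#' instead via [as_periodicity_ranking()] or [read_ranking()] everywhere a
#' ranking is consumed.
#'
#' Constant genes (zero variance, R^2 formally 0/0) score 0. Ties are broken
#' by gene ID so the ranking is deterministic.
#'
#' @param m an [expression_matrix] with at least 4 time points.
#' @param period the period to test, in the unit of `m$times`.
#' @return an object of class `"periodicity_ranking"`: a data frame with
#'   columns `gene_id` and `score` (R^2 in \[0, 1\]) sorted by descending
#'   score, with the period as attribute.
#' @export
rank_periodicity <- function(m, period) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("period must be a single positive number")
  if (length(m$times) < 4L)
    stop("cosinor ranking needs at least 4 time points")
  w <- 2 * pi * m$times / period
  X <- cbind(1, cos(w), sin(w))
  Y <- m$values                       # G x T
  # one QR factorization serves every gene
  B <- qr.solve(X, t(Y))              # 3 x G
  fitted <- t(X %*% B)                # G x T
  rss <- rowSums((Y - fitted)^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  score <- ifelse(tss == 0, 0, 1 - rss / tss)
  score <- pmin(pmax(score, 0), 1)
  as_periodicity_ranking(
    data.frame(gene_id = m$gene_ids, score = score,
               stringsAsFactors = FALSE),
    period = period)
}

#' Coerce a gene/score table to a periodicity ranking
#'
#' @param df data frame with columns `gene_id` and `score` (one row per
#'   gene), e.g. from an external periodicity tool.
#' @param period optional period the scores refer to.
#' @return a `periodicity_ranking` sorted by descending score, ties broken
#'   by gene ID.
#' @export
as_periodicity_ranking <- function(df, period = NA_real_) {
  if (inherits(df, "periodicity_ranking")) return(df)
  stopifnot(is.data.frame(df), all(c("gene_id", "score") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene IDs in ranking")
  df <- df[order(-df$score, df$gene_id), c("gene_id", "score")]
  rownames(df) <- NULL
  structure(df, class = c("periodicity_ranking", "data.frame"),
            period = period)
}

#' @export
print.periodicity_ranking <- function(x, ...) {
  cat(sprintf("<periodicity_ranking> %d genes, period %s\n", nrow(x),
              format(attr(x, "period"))))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Peak/trough alignment of top periodic genes with STRIPE time points
#'
#' Among the `top_n` highest-ranked genes, counts the fraction whose
#' expression maximum or minimum over the search window falls exactly on a
#' STRIPE time point, and compares it to the uniform expectation `k / mp`
#' (`k` STRIPE times among `mp` window time points). Anomalies manufacture
#' false peaks and troughs, so an aligned fraction well above the
#' expectation quantifies how strongly the anomaly biases periodicity
#' analysis.
#'
#' The default window is the first full period from the first time point,
#' matching the convention of ordering periodic genes on their first-period
#' peak; `"full-series"` searches every time point. Note the expectation is
#' a single-extremum uniform argument while alignment counts peak OR trough;
#' both quantities are reported so the convention is explicit.
#'
#' @param m an [expression_matrix].
#' @param stripe_times numeric STRIPE time labels (subset of `m$times`); may
#'   be empty, in which case both fractions are 0.
#' @param ranking a `periodicity_ranking`; computed with
#'   [rank_periodicity()] when `NULL`.
#' @param top_n number of top-ranked genes to examine (<= number of genes).
#' @param period period used for the default window and ranking.
#' @param window `"first-period"` (default) or `"full-series"`.
#' @return an object of class `"alignment_report"`: list with `top_n`,
#'   `aligned_fraction`, `expected_fraction`, `stripe_times`, `window` and
#'   `n_window_points`.
#' @export
stripe_alignment_fraction <- function(m, stripe_times, ranking = NULL,
                                      top_n, period,
                                      window = c("first-period",
                                                 "full-series")) {
  stopifnot(inherits(m, "expression_matrix"))
  window <- match.arg(window)
  if (top_n < 1L || top_n > length(m$gene_ids))
    stop("top_n must be between 1 and the number of genes")
  if (length(stripe_times) && !all(stripe_times %in% m$times))
    stop("stripe_times must be a subset of the matrix time points")
  if (is.null(ranking)) ranking <- rank_periodicity(m, period)
  stopifnot(inherits(ranking, "periodicity_ranking"))

  widx <- if (window == "first-period")
    which(m$times < m$times[1] + period) else seq_along(m$times)
  if (length(widx) < 3L)
    stop("search window contains fewer than 3 time points")
  wt <- m$times[widx]

  top <- utils::head(ranking$gene_id, top_n)
  gi <- match(top, m$gene_ids)
  if (anyNA(gi)) stop("ranking contains gene IDs absent from the matrix")

  if (length(stripe_times) == 0L) {
    aligned <- 0; expected <- 0
  } else {
    V <- m$values[gi, widx, drop = FALSE]
    peak <- wt[max.col(V, ties.method = "first")]
    trough <- wt[max.col(-V, ties.method = "first")]
    aligned <- mean(peak %in% stripe_times | trough %in% stripe_times)
    expected <- sum(stripe_times %in% wt) / length(wt)
  }
  structure(list(top_n = as.integer(top_n), aligned_fraction = aligned,
                 expected_fraction = expected, stripe_times = stripe_times,
                 window = window, n_window_points = length(widx)),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<alignment_report> top %d genes, %s window (%d points)\n",
    "  aligned with STRIPE peak/trough: %.1f%% (uniform expectation %.1f%%)\n"),
    x$top_n, x$window, x$n_window_points, 100 * x$aligned_fraction,
    100 * x$expected_fraction))
  invisible(x)
}

#' Overlap of top-N gene sets between periodicity rankings
#'
#' Exact set-intersection counts of the top-`n` gene-ID sets of 2 or 3
#' rankings over the same gene universe: 3 regions for a pair, the full
#' 7-region decomposition for a triple (the numbers a Venn diagram would
#' display). Region counts always sum to the size of the union.
#'
#' @param rankings named list of 2 or 3 `periodicity_ranking` objects (or
#'   data frames coercible by [as_periodicity_ranking()]); unnamed lists get
#'   names A, B, C.
#' @param top_n size of each top set.
#' @return named integer vector of disjoint region counts, e.g.
#'   `A_only, B_only, A_B` or `A_only, ..., A_B_C`, with attribute `top_n`.
#' @export
topn_overlap <- function(rankings, top_n) {
  stopifnot(is.list(rankings), length(rankings) %in% c(2L, 3L))
  rankings <- lapply(rankings, as_periodicity_ranking)
  if (is.null(names(rankings)) || any(names(rankings) == ""))
    names(rankings) <- LETTERS[seq_along(rankings)]
  universes <- lapply(rankings, function(r) sort(r$gene_id))
  for (i in seq_along(universes)[-1])
    if (!identical(universes[[1]], universes[[i]]))
      stop("rankings must cover the same gene universe")
  if (top_n < 1L || top_n > length(universes[[1]]))
    stop("top_n must be between 1 and the universe size")
  tops <- lapply(rankings, function(r) utils::head(r$gene_id, top_n))
  nm <- names(rankings)
  if (length(tops) == 2L) {
    ab <- intersect(tops[[1]], tops[[2]])
    out <- c(length(setdiff(tops[[1]], tops[[2]])),
             length(setdiff(tops[[2]], tops[[1]])),
             length(ab))
    names(out) <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                    paste(nm, collapse = "_"))
  } else {
    inA <- function(g, i) g %in% tops[[i]]
    u <- unique(unlist(tops))
    member <- vapply(1:3, function(i) u %in% tops[[i]], logical(length(u)))
    key <- member %*% c(1, 2, 4)
    cnt <- function(k) sum(key == k)
    out <- c(cnt(1), cnt(2), cnt(4), cnt(3), cnt(5), cnt(6), cnt(7))
    names(out) <- c(paste0(nm, "_only"),
                    paste(nm[c(1, 2)], collapse = "_"),
                    paste(nm[c(1, 3)], collapse = "_"),
                    paste(nm[c(2, 3)], collapse = "_"),
                    paste(nm, collapse = "_"))
  }
  structure(as.integer(out), names = names(out), top_n = as.integer(top_n))
}

#' Detector sensitivity to time-point subsampling
#'
#' Re-runs the STRIPE detector on reduced versions of the series -- dropping
#' one time point at a time (`"leave-one-out"`) or keeping every k-th point
#' (`"keep-every-k"`) -- to probe how robust the calls are to sampling
#' density. Omitted points are reported as `"absent"`, never as non-STRIPE;
#' an ambiguous detector outcome is recorded per subsample rather than
#' raised.
#'
#' @inheritParams detect_stripes
#' @param mode `"leave-one-out"` or `"keep-every-k"`.
#' @param k keep-every-k stride (ignored for leave-one-out), default 2.
#' @return an object of class `"subsample_calls"`: a list of per-subsample
#'   records, each with `name`, `kept_times`, `status` (`"ok"` or
#'   `"ambiguous"`) and `labels` -- a data frame over the ORIGINAL time axis
#'   with character labels `"0"`, `"1"` or `"absent"`.
#' @export
sampling_sensitivity <- function(m, threshold = 0.3,
                                 mode = c("leave-one-out", "keep-every-k"),
                                 k = 2L, preprocess = c("zscore", "none"),
                                 max_consecutive = 5L) {
  stopifnot(inherits(m, "expression_matrix"))
  mode <- match.arg(mode)
  preprocess <- match.arg(preprocess)
  T <- length(m$times)
  subsets <- if (mode == "leave-one-out") {
    lapply(seq_len(T), function(i) {
      list(name = paste0("drop_", format(m$times[i], trim = TRUE)),
           keep = setdiff(seq_len(T), i))
    })
  } else {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    list(list(name = paste0("every_", k), keep = seq(1L, T, by = k)))
  }
  out <- lapply(subsets, function(s) {
    if (length(s$keep) < 3L)
      stop("subsample ", s$name, " keeps fewer than 3 time points")
    sub <- expression_matrix(m$values[, s$keep, drop = FALSE],
                             gene_ids = m$gene_ids,
                             times = m$times[s$keep],
                             scale_tag = m$scale_tag)
    labels <- rep("absent", T)
    status <- "ok"
    calls <- tryCatch(
      detect_stripes(sub, threshold, preprocess = preprocess,
                     max_consecutive = max_consecutive),
      stripe_ambiguous = function(e) NULL)
    if (is.null(calls)) {
      status <- "ambiguous"
      labels[s$keep] <- NA_character_
    } else {
      labels[s$keep] <- as.character(calls$label)
    }
    list(name = s$name, kept_times = m$times[s$keep], status = status,
         labels = data.frame(time = m$times, label = labels,
                             stringsAsFactors = FALSE))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  structure(out, class = "subsample_calls", mode = mode,
            threshold = as_threshold_spec(threshold))
}

#' @export
print.subsample_calls <- function(x, ...) {
  cat(sprintf("<subsample_calls> mode %s, %d subsample(s)\n",
              attr(x, "mode"), length(x)))
  for (s in x) {
    stripes <- s$labels$time[s$labels$label == "1"]
    cat(sprintf("  %s [%s]: STRIPEs %s\n", s$name, s$status,
                if (length(stripes))
                  paste(format(stripes, trim = TRUE), collapse = " ")
                else "none"))
  }
  invisible(x)
}
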