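#' Construct an expression matrix object
#'
#' The central container of the package: a genes x time-points matrix of
#' transcript levels (TPM/FPKM scale, or Z-scores after normalization) with
#' unique gene identifiers and strictly increasing numeric time labels.
#'
#' @param values numeric matrix, genes in rows, time points in columns. All
#'   entries must be finite; on the `"raw"` scale they must also be
#'   non-negative.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param times strictly increasing numeric vector of time labels (minutes,
#'   hours -- unit-agnostic), one per column. Defaults to
#'   `as.numeric(colnames(values))`.
#' @param scale_tag one of `"raw"`, `"zscore"`, `"qn"`, `"zqn"`, recording
#'   which normalizations have been applied.
#'
#' @return an object of class `"expression_matrix"`: a list with elements
#'   `gene_ids`, `times`, `values` (with dimnames set) and `scale_tag`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, nrow = 2, byrow = TRUE),
#'                        gene_ids = c("gA", "gB"), times = c(0, 10, 20))
#' m
expression_matrix <- function(values, gene_ids = rownames(values),
                              times = as.numeric(colnames(values)),
                              scale_tag = c("raw", "zscore", "qn", "zqn")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required (no rownames on values)")
  gene_ids <- as.character(gene_ids)
  times <- as.numeric(times)
  if (nrow(values) < 1L) stop("expression matrix needs at least one gene")
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(times) != ncol(values))
    stop("length(times) must equal ncol(values)")
  if (anyNA(times)) stop("time labels must be numeric (got NA after coercion)")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("time labels must be strictly increasing")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (scale_tag == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  dimnames(values) <- list(gene_ids, format(times, trim = TRUE, digits = 15))
  structure(list(gene_ids = gene_ids, times = times, values = values,
                 scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d time points [%s scale]\n",
              length(x$gene_ids), length(x$times), x$scale_tag))
  cat("  times:", paste(format(utils::head(x$times, 8), trim = TRUE),
                        collapse = " "),
      if (length(x$times) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Delimiter from file extension, unless given explicitly.
infer_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from a delimited text file
#'
#' Expects gene identifiers in the first column and numeric time labels as
#' the remaining header cells. The pipeline has no missing-value semantics,
#' so empty or non-numeric cells are rejected with the offending row and
#' column named.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator; by default inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @param scale_tag scale of the stored values, default `"raw"`.
#' @return an [expression_matrix] with column order preserved.
#' @export
read_expression_matrix <- function(path, delimiter = NULL,
                                   scale_tag = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  delimiter <- infer_delim(path, delimiter)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected a gene-ID column plus >=1 time column")
  hdr <- colnames(df)[-1]
  times <- suppressWarnings(as.numeric(hdr))
  if (anyNA(times))
    stop("non-numeric time label(s) in header: ",
         paste(hdr[is.na(times)], collapse = ", "))
  gene_ids <- df[[1]]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(times))
  for (j in seq_along(times)) {
    cell <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(cell))
    bad <- is.na(v) | cell == ""
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "cannot parse value %s at row %d (gene %s), column %s",
        dQuote(cell[i]), i, gene_ids[i], hdr[j]))
    }
    vals[, j] <- v
  }
  expression_matrix(vals, gene_ids = gene_ids, times = times,
                    scale_tag = scale_tag)
}

#' Write an expression matrix to a delimited text file
#'
#' Values are rendered with 15 significant digits so a write/read round trip
#' reproduces the matrix to floating precision.
#'
#' @param m an [expression_matrix].
#' @param path output path.
#' @param delimiter field separator; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delimiter = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  delimiter <- infer_delim(path, delimiter)
  df <- data.frame(gene = m$gene_ids,
                   format(m$values, trim = TRUE, digits = 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", format(m$times, trim = TRUE, digits = 15))
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write a STRIPE call set to a TSV file
#'
#' Columns: `time`, `label` (0 = non-STRIPE, 1 = STRIPE), `ks_distance`,
#' `p_value`, `anchor_time`, `direction`.
#'
#' @param calls a `stripe_calls` object from [detect_stripes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stripe_calls <- function(calls, path) {
  stopifnot(inherits(calls, "stripe_calls"))
  df <- as.data.frame(calls)
  df$direction <- attr(calls, "direction")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pairwise KS distance matrix to a TSV file
#'
#' @param dm a `ks_distance_matrix` from [pairwise_distance_matrix()].
#' @param path output path.
#' @param what `"distance"` (default) writes the D matrix, `"pvalue"` the
#'   p-value matrix.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, what = c("distance", "pvalue")) {
  stopifnot(inherits(dm, "ks_distance_matrix"))
  what <- match.arg(what)
  M <- if (what == "distance") dm$D else dm$P
  lab <- format(dm$times, trim = TRUE, digits = 15)
  df <- data.frame(time = lab, format(M, trim = TRUE, digits = 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("time", lab)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a periodicity ranking table
#'
#' Two-column table (`gene_id`, `score`), e.g. exported from an external
#' periodicity tool such as JTK_CYCLE, for use anywhere a built-in cosinor
#' ranking is accepted.
#'
#' @param path path to a TSV/CSV file with a header.
#' @param delimiter field separator; inferred from the extension by default.
#' @return a `periodicity_ranking` (see [rank_periodicity()]).
#' @export
read_ranking <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = infer_delim(path, delimiter),
                          header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ranking table needs columns gene_id and score")
  as_periodicity_ranking(stats::setNames(df[1:2], c("gene_id", "score")))
}

#' Write a periodicity ranking table
#' @param ranking a `periodicity_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "periodicity_ranking"))
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
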