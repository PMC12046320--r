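#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric gene x sample matrix carrying a
#' normalization tag (`raw_counts`, `log2cpm`, `zscaled` or `activity`) and a
#' species label. All pipeline stages consume and produce this container so
#' that units are explicit at every hand-off.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to colnames of `values`).
#' @param normalization one of `"raw_counts"`, `"log2cpm"`, `"zscaled"`,
#'   `"activity"`.
#' @param species free-text species label (e.g. `"human"`, `"mouse"`).
#' @return an object of class `expr_mat`: the matrix with dimnames set and
#'   `normalization` / `species` attributes.
#' @export
expr_mat <- function(values, gene_ids = rownames(values),
                     sample_ids = colnames(values),
                     normalization = c("raw_counts", "log2cpm", "zscaled",
                                       "activity"),
                     species = "unspecified") {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (rownames/colnames or explicit)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (normalization != "raw_counts" && any(!is.finite(values)))
    stop("non-finite values in a normalized matrix")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, normalization = normalization, species = species,
            class = c("expr_mat", "matrix", "array"))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expr_mat: %d genes x %d samples [%s, species=%s]\n",
              nrow(x), ncol(x), attr(x, "normalization"), attr(x, "species")))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

#' Subsetting keeps the tags
#' @param x an `expr_mat`.
#' @param i,j row/column indices.
#' @param drop drop dimensions as for matrices (default `FALSE`, keeping the
#'   container); with `drop = TRUE` a plain vector is returned.
#' @param ... unused.
#' @export
`[.expr_mat` <- function(x, i, j, ..., drop = FALSE) {
  y <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(y)) return(y)
  expr_mat(y, normalization = attr(x, "normalization"),
           species = attr(x, "species"))
}

#' Log2 counts-per-million normalization
#'
#' `value = log2(count / column_sum * 1e6 + pseudocount)`. Samples that share
#' the same count composition map to identical columns, so doubling every
#' count of a sample leaves its normalized column unchanged.
#'
#' @param counts an `expr_mat` with `normalization = "raw_counts"` and
#'   nonnegative entries.
#' @param pseudocount nonnegative offset added on the CPM scale before the
#'   log; default 1 keeps zero counts finite.
#' @return an `expr_mat` tagged `log2cpm`.
#' @examples
#' m <- expr_mat(matrix(c(8, 2), 2, 1, dimnames = list(c("A", "B"), "s1")),
#'               normalization = "raw_counts")
#' log2cpm(m, pseudocount = 0)
#' @export
log2cpm <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "expr_mat"))
  if (attr(counts, "normalization") != "raw_counts")
    stop("log2cpm() expects a matrix tagged 'raw_counts'")
  if (any(counts < 0)) stop("negative counts")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("'pseudocount' must be a single nonnegative number")
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  cpm <- sweep(unclass(counts), 2, libsize, "/") * 1e6
  expr_mat(log2(cpm + pseudocount), normalization = "log2cpm",
           species = attr(counts, "species"))
}

#' Z-scale each gene across samples
#'
#' Rows with zero variance become all-zero rather than NaN.
#'
#' @param expr an `expr_mat`.
#' @return an `expr_mat` tagged `zscaled`.
#' @export
zscale_genes <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  m <- unclass(expr)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  expr_mat(z, normalization = "zscaled", species = attr(expr, "species"))
}

#' Poisson-thinning count export
#'
#' Converts a log2-CPM matrix back to an integer count matrix by drawing
#' Poisson counts with mean `2^value / 1e6 * lib_size` per sample. Intended
#' for exercising the raw-count entry point of the pipeline with synthetic
#' data; uses the current RNG state.
#'
#' @param expr an `expr_mat` tagged `log2cpm`.
#' @param lib_size target library size per sample (scalar or per-sample
#'   vector).
#' @return an `expr_mat` tagged `raw_counts`.
#' @export
as_counts <- function(expr, lib_size = 1e6) {
  stopifnot(inherits(expr, "expr_mat"))
  if (attr(expr, "normalization") != "log2cpm")
    stop("as_counts() expects a 'log2cpm' matrix")
  lib_size <- rep_len(lib_size, ncol(expr))
  lam <- sweep(2^unclass(expr) / 1e6, 2, lib_size, "*")
  cnt <- matrix(stats::rpois(length(lam), lam), nrow(expr), ncol(expr),
                dimnames = dimnames(expr))
  expr_mat(cnt, normalization = "raw_counts", species = attr(expr, "species"))
}
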