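# Plain-text formats: expression TSV/CSV and MatrixMarket triplets (with
# rows/cols sidecars), sample annotation TSV, DE tables, network edge TSV,
# GMT gene sets, and JSON truth/report sidecars.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
         stop("cannot guess format from extension '.", ext, "'"))
}

mtx_sidecars <- function(path) {
  base <- sub("\\.mtx$", "", path)
  list(rows = paste0(base, "_rows.txt"), cols = paste0(base, "_cols.txt"))
}

#' Read an expression matrix
#'
#' TSV/CSV files carry gene ids in the first column and sample ids in the
#' header. MatrixMarket files (`.mtx`) need `<base>_rows.txt` and
#' `<base>_cols.txt` sidecars holding the gene and sample identifiers, one
#' per line.
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension by
#'   default.
#' @param normalization tag to attach (default `"log2cpm"`).
#' @param species species label.
#' @return an `expr_mat`. Duplicate identifiers are rejected.
#' @export
read_expression <- function(path, format = guess_format(path),
                            normalization = "log2cpm",
                            species = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    sc <- mtx_sidecars(path)
    for (f in c(sc$rows, sc$cols))
      if (!file.exists(f)) stop("missing MTX sidecar file: ", f)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(sc$rows)
    cn <- readLines(sc$cols)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar length does not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                        row.names = NULL, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate gene ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    rownames(m) <- ids
  }
  expr_mat(m, normalization = normalization, species = species)
}

#' Write an expression matrix
#'
#' @param expr an `expr_mat`.
#' @param path output path; for `"mtx"` the rows/cols sidecars are written
#'   next to it.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = guess_format(path)) {
  stopifnot(inherits(expr, "expr_mat"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(expr), sparse = TRUE), path)
    sc <- mtx_sidecars(path)
    writeLines(rownames(expr), sc$rows)
    writeLines(colnames(expr), sc$cols)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(expr), unclass(expr),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a two-column sample annotation table
#'
#' @param path TSV path with header columns `sample` and `group`.
#' @return named character vector (sample -> group).
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation needs (sample, group) columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_annotation
#' @param groups named character vector (sample -> group).
#' @export
write_annotation <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a differential table
#'
#' Columns: `gene`, `log2FC`, `t`, `p`, `z`, `ave_expr`.
#' @param path TSV path.
#' @return a `de_table`.
#' @export
read_de <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "log2FC", "t", "p", "z", "ave_expr")
  if (!all(need %in% names(df)))
    stop("DE table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"constant" %in% names(df)) df$constant <- FALSE
  structure(df, class = c("de_table", "data.frame"))
}

#' @rdname read_de
#' @param de a `de_table`.
#' @export
write_de <- function(de, path) {
  utils::write.table(
    de[, c("gene", "log2FC", "t", "p", "z", "ave_expr")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a network edge table
#'
#' One edge per row, columns `source`, `target`, `mi`, `spearman`, `sign`,
#' `support`. Reading reassembles an `interactome` keyed by `source`.
#'
#' @param interactome an `interactome`.
#' @param path TSV path.
#' @export
write_network <- function(interactome, path) {
  rows <- lapply(names(interactome$regulons), function(d) {
    r <- interactome$regulons[[d]]
    if (nrow(r) == 0) return(NULL)
    data.frame(source = d, target = r$target, mi = r$mi,
               spearman = r$spearman, sign = r$sign, support = r$support,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(source = character(0), target = character(0),
                     mi = numeric(0), spearman = numeric(0),
                     sign = numeric(0), support = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("source", "target", "mi", "spearman", "sign", "support")
  if (!all(need %in% names(df)))
    stop("network table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  regs <- split(df[, c("target", "mi", "spearman", "sign", "support")],
                df$source)
  regs <- lapply(regs, function(r) { rownames(r) <- NULL; r })
  as_interactome(regs)
}

#' Read / write GMT gene sets
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export regulons as signed GMT sets
#'
#' Each regulon becomes two sets, `<driver>_pos` and `<driver>_neg`, holding
#' its positive and negative targets (empty partitions are skipped).
#'
#' @param interactome an `interactome`.
#' @param path GMT path.
#' @export
regulons_to_gmt <- function(interactome, path) {
  sets <- list()
  for (d in names(interactome$regulons)) {
    r <- interactome$regulons[[d]]
    if (any(r$sign > 0)) sets[[paste0(d, "_pos")]] <- r$target[r$sign > 0]
    if (any(r$sign < 0)) sets[[paste0(d, "_neg")]] <- r$target[r$sign < 0]
  }
  write_gmt(sets, path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}
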