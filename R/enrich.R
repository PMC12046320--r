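# Running-sum gene-set enrichment against a ranked statistic, with a
# permutation null and a Kolmogorov-Smirnov p-value, plus unsigned gene-set
# activity scoring.

#' Gene-set enrichment by weighted running sum
#'
#' Genes are sorted by the statistic (descending). Walking down the list,
#' the running sum rises by `|stat|^weight_exponent` (normalized over set
#' members) at each set hit and falls by `1/(N - n_set)` at each miss; the
#' enrichment score ES is the extremum of the running sum. With
#' `weight_exponent = 0` the statistic enters only through the ordering and
#' the ES reduces to the (signed) KS statistic between in-set and out-set
#' rank positions.
#'
#' The null is a gene-label permutation: set membership is reassigned
#' uniformly at random `n_perm` times. NES is ES divided by the mean |ES| of
#' same-sign permutations and `p_perm` is the one-sided permutation p among
#' same-sign permutations. `p_ks` is the two-sided two-sample KS test
#' between in-set and out-set rank positions and is available even with
#' `n_perm = 0`.
#'
#' @param ranked named numeric vector: gene -> ranking statistic.
#' @param set character vector of set member genes (see [gene_set()]), or a
#'   `gene_set`.
#' @param weight_exponent hit-weight exponent on `|stat|` (default 1; 0
#'   gives the unweighted KS form).
#' @param n_perm gene-label permutations (default 1000; 0 skips the
#'   permutation null, leaving `nes`/`p_perm` as `NA`).
#' @return an `enrichment_result`: `es`, `nes`, `p_perm`, `p_ks`,
#'   `leading_edge`, `n_set`, `n_total`.
#' @export
gsea <- function(ranked, set, weight_exponent = 1, n_perm = 1000) {
  if (inherits(set, "gene_set")) set <- set$members
  if (is.null(names(ranked))) stop("'ranked' must be a named vector")
  if (any(!is.finite(ranked))) stop("ranking statistics must be finite")
  set <- unique(as.character(set))
  hits0 <- names(ranked) %in% set
  if (!any(hits0)) stop("gene set does not intersect the ranked genes")
  if (all(hits0)) stop("gene set covers every ranked gene")

  ord <- order(-ranked, names(ranked))
  stat <- ranked[ord]
  hits <- hits0[ord]
  N <- length(stat)

  es_of <- function(hits) {
    w <- abs(stat)^weight_exponent
    wh <- w * hits
    sw <- sum(wh)
    if (sw == 0) wh <- hits / sum(hits) else wh <- wh / sw
    run <- cumsum(wh - (!hits) / (N - sum(hits)))
    unname(run[which.max(abs(run))])
  }
  es <- es_of(hits)

  peak <- {
    w <- abs(stat)^weight_exponent
    wh <- w * hits
    sw <- sum(wh)
    if (sw == 0) wh <- hits / sum(hits) else wh <- wh / sw
    run <- cumsum(wh - (!hits) / (N - sum(hits)))
    which.max(abs(run))
  }
  leading_edge <- if (es >= 0) names(stat)[seq_len(peak)][hits[seq_len(peak)]]
                  else names(stat)[peak:N][hits[peak:N]]

  nes <- NA_real_; p_perm <- NA_real_
  if (n_perm > 0) {
    k <- sum(hits)
    es_perm <- vapply(seq_len(n_perm), function(i) {
      h <- logical(N)
      h[sample.int(N, k)] <- TRUE
      es_of(h)
    }, numeric(1))
    same <- es_perm * sign(es) >= 0
    if (any(same)) {
      nes <- es / mean(abs(es_perm[same]))
      p_perm <- (1 + sum(same & abs(es_perm) >= abs(es))) / (1 + sum(same))
    }
  }

  pos_in <- which(hits)
  pos_out <- which(!hits)
  p_ks <- suppressWarnings(stats::ks.test(pos_in, pos_out)$p.value)

  structure(list(es = es, nes = nes, p_perm = p_perm, p_ks = p_ks,
                 leading_edge = leading_edge, n_set = sum(hits),
                 n_total = N, weight_exponent = weight_exponent),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES = %.4f (NES = %.4f), p_perm = %.4g, p_ks = %.4g [%d/%d genes]\n",
              x$es, x$nes, x$p_perm, x$p_ks, x$n_set, x$n_total))
  invisible(x)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param members unique gene ids (nonempty).
#' @param sign optional per-member +1/-1 partition (positive/negative
#'   targets).
#' @return a `gene_set` list.
#' @export
gene_set <- function(name, members, sign = NULL) {
  members <- as.character(members)
  if (length(members) == 0) stop("empty gene set")
  if (anyDuplicated(members)) stop("duplicate members in gene set")
  if (!is.null(sign)) {
    sign <- rep_len(sign, length(members))
    if (!all(sign %in% c(-1, 1))) stop("sign must be -1/+1")
  }
  structure(list(name = name, members = members, sign = sign),
            class = "gene_set")
}

#' Signed-regulon enrichment
#'
#' Runs [gsea()] separately on a regulon's positive and negative targets.
#' For a driver whose activity is higher in the cases that top the ranking,
#' positive targets enrich at the top (ES > 0) and negative targets at the
#' bottom (ES < 0).
#'
#' @param ranked named statistic vector (e.g. a Stouffer combined ranking).
#' @param reg a regulon target table (from an `interactome` or [regulon()]),
#'   with columns `target` and `sign`.
#' @inheritParams gsea
#' @return list with `positive` and `negative` `enrichment_result`s (either
#'   is `NULL` when that partition is empty or absent from the ranking).
#' @export
signed_regulon_gsea <- function(ranked, reg, weight_exponent = 1,
                                n_perm = 1000) {
  pos <- reg$target[reg$sign > 0]
  neg <- reg$target[reg$sign < 0]
  if (length(intersect(c(pos, neg), names(ranked))) == 0)
    stop("regulon has no targets in the ranking")
  run <- function(tg) {
    if (length(intersect(tg, names(ranked))) == 0) return(NULL)
    gsea(ranked, tg, weight_exponent = weight_exponent, n_perm = n_perm)
  }
  list(positive = run(pos), negative = run(neg))
}

#' Unsigned gene-set activity
#'
#' Per-sample set activity is the unweighted mean of z-scaled expression of
#' the member genes present in the matrix -- suitable for scoring, e.g.,
#' inflammatory (M1) versus anti-inflammatory (M2) macrophage signatures,
#' after which [differential_activity()] compares groups.
#'
#' @param expr an `expr_mat`.
#' @param sets a named list of character vectors or of `gene_set` objects.
#' @return an `expr_mat` tagged `activity` (sets x samples); sets with no
#'   member in the matrix are skipped with a warning.
#' @export
geneset_activity <- function(expr, sets) {
  stopifnot(inherits(expr, "expr_mat"))
  if (inherits(sets, "gene_set")) sets <- stats::setNames(list(sets),
                                                          sets$name)
  members <- lapply(sets, function(s)
    if (inherits(s, "gene_set")) s$members else as.character(s))
  if (is.null(names(members)) || any(names(members) == ""))
    stop("'sets' must be named")
  z <- unclass(zscale_genes(expr))
  rows <- list()
  for (nm in names(members)) {
    present <- intersect(members[[nm]], rownames(z))
    if (length(present) == 0) {
      warning("gene set ", nm, " has no member in the matrix; skipped")
      next
    }
    rows[[nm]] <- colMeans(z[present, , drop = FALSE])
  }
  if (length(rows) == 0) stop("no gene set intersects the matrix")
  act <- do.call(rbind, rows)
  colnames(act) <- colnames(expr)
  expr_mat(act, normalization = "activity", species = attr(expr, "species"))
}
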