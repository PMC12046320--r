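# Cross-species integration: ortholog merge, response-signature (anchor)
# selection, overlap significance, joint PCA response score, ROC evaluation
# and Stouffer combined ranking.

#' Merge two species' differential-expression tables over orthologs
#'
#' By default genes are matched by case-insensitive symbol identity and only
#' 1:1 matches are kept: symbols that collide within a species after
#' uppercasing are ambiguous and dropped with a message. An explicit
#' two-column ortholog map (human symbol, mouse symbol) overrides the
#' default matching; many-to-many rows of the map are likewise dropped.
#'
#' @param de_h,de_m `de_table` results for the two species.
#' @param ortholog_map optional data.frame whose first two columns give
#'   (human, mouse) symbol pairs.
#' @return a `merged_de` data.frame with columns `gene` (human-cased
#'   symbol), `z_h`, `log2FC_h`, `z_m`, `log2FC_m`, `combined_z` (Stouffer),
#'   plus attribute `dropped` listing ambiguous symbols.
#' @export
merge_orthologs <- function(de_h, de_m, ortholog_map = NULL) {
  if (nrow(de_h) == 0 || nrow(de_m) == 0) stop("empty DE table")
  dropped <- character(0)

  if (is.null(ortholog_map)) {
    key_h <- toupper(de_h$gene)
    key_m <- toupper(de_m$gene)
    dup_h <- unique(key_h[duplicated(key_h)])
    dup_m <- unique(key_m[duplicated(key_m)])
    dropped <- union(dup_h, dup_m)
    h <- de_h[!key_h %in% dropped, ]
    m <- de_m[!key_m %in% dropped, ]
    h$key <- toupper(h$gene)
    m$key <- toupper(m$gene)
  } else {
    map <- data.frame(h = as.character(ortholog_map[[1]]),
                      m = as.character(ortholog_map[[2]]),
                      stringsAsFactors = FALSE)
    bad <- map$h %in% map$h[duplicated(map$h)] |
           map$m %in% map$m[duplicated(map$m)]
    dropped <- unique(c(map$h[bad], map$m[bad]))
    map <- map[!bad, ]
    h <- de_h[de_h$gene %in% map$h, ]
    m <- de_m[de_m$gene %in% map$m, ]
    h$key <- h$gene
    m$key <- map$h[match(m$gene, map$m)]
  }
  if (length(dropped))
    message("merge_orthologs: dropped ", length(dropped),
            " ambiguous symbol(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")

  shared <- intersect(h$key, m$key)
  if (length(shared) == 0) stop("zero shared genes after ortholog matching")
  ih <- match(shared, h$key)
  im <- match(shared, m$key)
  out <- data.frame(gene = h$gene[ih],
                    z_h = h$z[ih], log2FC_h = h$log2FC[ih],
                    z_m = m$z[im], log2FC_m = m$log2FC[im],
                    stringsAsFactors = FALSE)
  out$combined_z <- (out$z_h + out$z_m) / sqrt(2)
  structure(out, dropped = dropped, class = c("merged_de", "data.frame"))
}

#' Select per-species response signatures and cross-species anchors
#'
#' Three-step anchor selection on a merged table: (1) per species, keep
#' genes with `|z| > z_thresh` (these per-species directional lists are the
#' response signatures); (2) within each species' list, keep genes whose
#' log2 fold-change sign agrees between the species; (3) equalize the two
#' lists to the smaller size by ranking on `|log2FC|` within each species
#' (ties at the cutoff go to the lexicographically smaller symbol). The
#' shared signature is the sign-consistent intersection of the two
#' per-species lists.
#'
#' @param merged a `merged_de` table.
#' @param z_thresh absolute signed-Z cutoff (default 1.96).
#' @return a `signature_set`: `species_sets` (per-species signature tables
#'   with direction), `shared` (sign-consistent intersection table),
#'   `anchors_h`/`anchors_m` (equalized per-species anchor tables),
#'   `anchors` (union of anchor gene symbols, used for the joint PCA),
#'   `universe_size` (merged gene count).
#' @export
select_anchors <- function(merged, z_thresh = 1.96) {
  if (nrow(merged) == 0) stop("empty merged table")
  sig_h <- merged[abs(merged$z_h) > z_thresh, ]
  sig_m <- merged[abs(merged$z_m) > z_thresh, ]
  consistent <- sign(merged$log2FC_h) == sign(merged$log2FC_m)
  names(consistent) <- merged$gene

  cand_h <- sig_h[consistent[sig_h$gene], ]
  cand_m <- sig_m[consistent[sig_m$gene], ]
  k <- min(nrow(cand_h), nrow(cand_m))
  if (k == 0)
    warning("no anchors pass |z| > ", z_thresh,
            " with consistent direction; empty signature set")

  top_k <- function(df, fc_col, k) {
    if (k == 0) return(df[0, ])
    ord <- order(-abs(df[[fc_col]]), df$gene)
    df[ord[seq_len(k)], ]
  }
  anchors_h <- top_k(cand_h, "log2FC_h", k)
  anchors_m <- top_k(cand_m, "log2FC_m", k)

  shared <- merged[merged$gene %in% intersect(sig_h$gene, sig_m$gene) &
                     consistent[merged$gene], ]
  add_dir <- function(df, fc_col) {
    df$direction <- sign(df[[fc_col]])
    rownames(df) <- NULL
    df
  }
  structure(list(
    species_sets = list(human = add_dir(sig_h, "log2FC_h"),
                        mouse = add_dir(sig_m, "log2FC_m")),
    shared = add_dir(shared, "log2FC_h"),
    anchors_h = add_dir(anchors_h, "log2FC_h"),
    anchors_m = add_dir(anchors_m, "log2FC_m"),
    anchors = sort(union(anchors_h$gene, anchors_m$gene)),
    universe_size = nrow(merged),
    z_thresh = z_thresh
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(paste0("signature_set: human %d / mouse %d genes at |z| > %g; ",
                     "%d shared, %d anchors per species (union %d) of %d ",
                     "merged genes\n"),
              nrow(x$species_sets$human), nrow(x$species_sets$mouse),
              x$z_thresh, nrow(x$shared), nrow(x$anchors_h),
              length(x$anchors), x$universe_size))
  invisible(x)
}

#' Two-tailed Fisher exact test of gene-set overlap
#'
#' Builds the 2x2 membership table of two gene sets over a stated universe
#' and returns the two-tailed Fisher exact p-value (the sum of
#' hypergeometric probabilities of tables at most as probable as the
#' observed one).
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe universe size (count), at least `|set_a U set_b|`.
#' @return list with `overlap`, `p`, `odds_ratio` and the 2x2 `table`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  n_union <- length(union(set_a, set_b))
  if (universe < n_union)
    stop("universe (", universe, ") smaller than |set_a U set_b| (",
         n_union, ")")
  k <- length(intersect(set_a, set_b))
  a <- length(set_a); b <- length(set_b)
  tab <- matrix(c(k, a - k, b - k, universe - a - b + k), 2, 2,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(overlap = k, p = ft$p.value,
       odds_ratio = unname(ft$estimate), table = tab)
}

#' Joint cross-species PCA response score
#'
#' Subsets both expression matrices to the anchor genes, z-scales each gene
#' within its species (removing species location and scale, the only batch
#' handling applied), column-concatenates the samples and runs PCA. The PC1
#' score is the per-sample response score. PC1's sign is fixed so that the
#' anchor gene with the largest absolute loading has a positive loading.
#'
#' @param expr_h,expr_m `expr_mat` matrices (log2cpm) for the two species;
#'   mouse genes are matched to anchor symbols case-insensitively.
#' @param anchors a `signature_set` or a character vector of (human-cased)
#'   anchor symbols.
#' @return data.frame with `sample`, `species`, `score` (PC1), plus
#'   attributes `loadings` and `var_explained`.
#' @export
joint_pca_score <- function(expr_h, expr_m, anchors) {
  if (inherits(anchors, "signature_set")) anchors <- anchors$anchors
  anchors <- unique(as.character(anchors))
  if (length(anchors) < 2) stop("need at least 2 anchor genes")

  pick <- function(expr, species) {
    key <- toupper(rownames(expr))
    idx <- match(toupper(anchors), key)
    if (anyNA(idx))
      stop("anchor gene(s) missing from ", species, " matrix: ",
           paste(anchors[is.na(idx)], collapse = ", "))
    sub <- expr[idx, ]
    rownames(sub) <- anchors
    unclass(zscale_genes(sub))
  }
  zh <- pick(expr_h, "human")
  zm <- pick(expr_m, "mouse")
  combined <- cbind(zh, zm)

  pc <- stats::prcomp(t(combined), center = TRUE, scale. = FALSE)
  loadings <- pc$rotation[, 1]
  flip <- sign(loadings[which.max(abs(loadings))])
  if (flip == 0) flip <- 1
  scores <- pc$x[, 1] * flip
  loadings <- loadings * flip

  out <- data.frame(
    sample = colnames(combined),
    species = rep(c(attr(expr_h, "species"), attr(expr_m, "species")),
                  c(ncol(zh), ncol(zm))),
    score = unname(scores), stringsAsFactors = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(out, loadings = loadings, var_explained = ve[1])
}

#' ROC curve summary with bootstrap confidence interval
#'
#' AUC computed as the Mann-Whitney U statistic over positive/negative score
#' pairs (ties count 0.5), with a stratified bootstrap percentile CI.
#' Accuracy at the Youden-optimal threshold is reported alongside.
#'
#' @param scores numeric per-sample scores.
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is "positive").
#' @param n_boot bootstrap replicates for the CI (default 2000).
#' @param conf confidence level (default 0.95).
#' @return a `roc_result`: `auc`, `ci_low`, `ci_high`, `accuracy`,
#'   `threshold`, `n_pos`, `n_neg`, and the `(score, label)` table.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, conf = 0.95) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (!any(labels) || all(labels)) stop("both label classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]

  auc_of <- function(pos, neg) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  auc <- auc_of(pos, neg)

  boots <- replicate(n_boot, auc_of(pos[sample.int(length(pos),
                                                   replace = TRUE)],
                                    neg[sample.int(length(neg),
                                                   replace = TRUE)]))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)

  # Youden threshold on the midpoints of adjacent distinct scores
  cuts <- sort(unique(scores))
  cuts <- c(-Inf, (cuts[-1] + cuts[-length(cuts)]) / 2, Inf)
  youden <- vapply(cuts, function(th) {
    mean(pos > th) + mean(neg <= th) - 1
  }, numeric(1))
  th <- cuts[which.max(youden)]
  acc <- (sum(pos > th) + sum(neg <= th)) / length(scores)

  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 conf = conf, accuracy = acc, threshold = th,
                 n_pos = length(pos), n_neg = length(neg),
                 data = data.frame(score = scores, label = labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%.0f%% CI %.4f-%.4f), n = %d pos / %d neg\n",
              x$auc, 100 * x$conf, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("accuracy at Youden threshold (%.4g) = %.4f\n",
              x$threshold, x$accuracy))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly 2 levels")
  f == levels(f)[2]
}

#' Stouffer combined gene ranking
#'
#' Combines the two species' signed Z-scores as `(z_h + z_m) / sqrt(2)` and
#' ranks genes by the combined statistic, descending; ties are broken by
#' gene symbol, so the ordering is fully deterministic. Plotted against
#' rank, the combined statistic traces the S-curve used to read off top
#' drivers at both extremes.
#'
#' @param merged a `merged_de` table.
#' @return the table sorted by `combined_z` (descending) with a `rank`
#'   column prepended.
#' @export
stouffer_rank <- function(merged) {
  if (!all(is.finite(merged$z_h)) || !all(is.finite(merged$z_m)))
    stop("non-finite Z-scores")
  merged$combined_z <- (merged$z_h + merged$z_m) / sqrt(2)
  ord <- order(-merged$combined_z, merged$gene)
  out <- merged[ord, ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
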