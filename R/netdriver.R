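# Mutual-information regulon inference and activity scoring.
#
# Desk-scale ARACNe-family machinery: plug-in MI on equal-frequency bins,
# per-bootstrap permutation-null edge thresholding, data-processing-
# inequality (DPI) pruning of the weakest edge in every fully connected
# triangle, and a binomial consensus over bootstraps. Regulon activity is
# the weighted mean of signed, z-scaled target expression.

# Equal-frequency bin indices from ranks; exactly balanced when n is a
# multiple of n_bins. Ties are broken by position ("first"), which makes the
# estimator invariant under strictly monotone transforms of either vector.
mi_bins <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n) + 1L)
}

default_n_bins <- function(n) max(2L, as.integer(floor(sqrt(n) / 2)))

mi_from_bins <- function(bx, by, n_bins) {
  n <- length(bx)
  joint <- tabulate(bx + n_bins * (by - 1L), nbins = n_bins * n_bins) / n
  px <- tabulate(bx, nbins = n_bins) / n
  py <- tabulate(by, nbins = n_bins) / n
  pxy <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pxy[nz]))
}

#' Plug-in mutual information on equal-frequency bins
#'
#' Both vectors are discretized into `n_bins` equal-frequency (quantile)
#' bins; MI is the plug-in estimate (natural log) from the joint bin table.
#' The estimator is symmetric, nonnegative, and -- because binning is
#' rank-based -- invariant under strictly monotone transforms, so
#' `mi(x, -x) = mi(x, x) = log(n_bins)` when `n` is divisible by `n_bins`.
#' A constant vector carries no information and returns 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @param n_bins bins per axis; default `max(2, floor(sqrt(n)/2))`.
#' @return nonnegative MI in nats.
#' @export
mutual_information <- function(x, y, n_bins = default_n_bins(length(x))) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 8) stop("need at least 8 observations")
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: MI set to 0")
    return(0)
  }
  mi_from_bins(mi_bins(x, n_bins), mi_bins(y, n_bins), as.integer(n_bins))
}

# DPI pruning on a symmetric weighted edge list. edges: data.frame with
# integer node columns a, b (a < b) and weight mi. Removes every edge that
# is the strict minimum of some triangle by more than `tolerance`.
dpi_prune <- function(edges, tolerance = 0) {
  if (nrow(edges) < 3) return(edges)
  key <- paste(edges$a, edges$b)
  w <- stats::setNames(edges$mi, key)
  nodes <- sort(unique(c(edges$a, edges$b)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))))
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- edges$a[e]; j <- edges$b[e]
    common <- intersect(adj[[as.character(i)]], adj[[as.character(j)]])
    for (k in common) {
      wik <- w[paste(min(i, k), max(i, k))]
      wjk <- w[paste(min(j, k), max(j, k))]
      if (edges$mi[e] < min(wik, wjk) - tolerance) {
        drop[e] <- TRUE
        break
      }
    }
  }
  edges[!drop, , drop = FALSE]
}

#' Infer a driver-centred mutual-information interactome
#'
#' For each bootstrap resample of samples: compute driver-vs-gene MI on
#' equal-frequency bins, keep pairs exceeding a permutation-null MI
#' threshold held at family-wise level `alpha` across the candidate pairs
#' (`n_null` permuted pairs per bootstrap; the permutation preserves the
#' duplicate-column coupling of the resample, and the far tail is read off
#' a moment-matched gamma extrapolation of the null), and prune indirect
#' edges by the
#' data-processing inequality within every fully connected triangle. Edges
#' are then kept when their bootstrap support count beats a binomial null
#' (support rate `alpha / n_pairs`, the per-pair pass rate under the
#' family-wise screen) at `consensus_p` after Bonferroni correction across
#' candidate edges. Final
#' edge weight is the mean MI over supporting bootstraps; edge sign is the
#' sign of the Spearman correlation on the full data.
#'
#' With `n_bootstraps = 1` and `consensus_p = NULL` the result is a single
#' deterministic MI-threshold + DPI pass (the oracle mode used in tests).
#'
#' @param expr an `expr_mat`.
#' @param driver_ids candidate driver gene ids (must appear in `expr`).
#' @param n_bootstraps bootstrap resamples (default 100).
#' @param consensus_p binomial-tail significance for bootstrap support
#'   (default 0.01); `NULL` disables the consensus step and keeps any edge
#'   ever supported.
#' @param dpi_tolerance additive DPI tolerance (default 0, strict pruning).
#' @param alpha per-bootstrap family-wise edge significance vs the
#'   permutation null.
#' @param n_null permuted pairs drawn for the null MI distribution per
#'   bootstrap.
#' @param n_bins bins for the MI estimator; default from the sample count.
#' @return an `interactome`: list of regulons (`driver`, `targets`
#'   data.frame with `target`, `mi`, `spearman`, `sign`, `support`) plus the
#'   provenance parameters. Uses the current RNG state.
#' @export
infer_network <- function(expr, driver_ids, n_bootstraps = 100,
                          consensus_p = 0.01, dpi_tolerance = 0,
                          alpha = 0.05, n_null = 100,
                          n_bins = default_n_bins(ncol(expr))) {
  stopifnot(inherits(expr, "expr_mat"))
  genes <- rownames(expr)
  drivers <- intersect(driver_ids, genes)
  if (length(drivers) == 0) stop("no driver ids found in expression matrix")
  ns <- ncol(expr)
  if (ns < 30)
    warning("fewer than 30 samples; MI estimates will be unstable")
  n_bins <- as.integer(n_bins)

  m <- unclass(expr)
  didx <- match(drivers, genes)
  ng <- nrow(m)

  # candidate pairs: driver x every other gene, deduplicated symmetrically
  pairs <- do.call(rbind, lapply(didx, function(d) {
    others <- setdiff(seq_len(ng), d)
    cbind(a = pmin(d, others), b = pmax(d, others))
  }))
  pairs <- unique(as.data.frame(pairs))

  support <- numeric(nrow(pairs))
  mi_sum <- numeric(nrow(pairs))

  for (b in seq_len(n_bootstraps)) {
    cols <- if (n_bootstraps == 1) seq_len(ns)
            else sample.int(ns, replace = TRUE)
    bm <- m[, cols, drop = FALSE]
    bins <- t(apply(bm, 1, mi_bins, n_bins = n_bins))

    mi_b <- vapply(seq_len(nrow(pairs)), function(e)
      mi_from_bins(bins[pairs$a[e], ], bins[pairs$b[e], ], n_bins),
      numeric(1))

    # permutation null: the driver row is permuted in the original sample
    # space and then passed through the same bootstrap indices, so the
    # duplicate-column coupling induced by resampling is preserved while
    # any true dependence is destroyed
    null_mi <- vapply(seq_len(n_null), function(i) {
      d <- didx[sample.int(length(didx), 1)]
      g <- sample.int(ng, 1)
      pd <- m[d, sample.int(ns)][cols]
      mi_from_bins(mi_bins(pd, n_bins), bins[g, ], n_bins)
    }, numeric(1))
    # family-wise level alpha across the candidate pairs: a per-pair level
    # would persistently admit the upper tail of chance dependencies in the
    # realized data, which no support-count consensus can later remove; the
    # far tail is read off a moment-matched gamma extrapolation of the
    # permutation null (the plug-in MI null is approximately scaled
    # chi-square)
    mu0 <- mean(null_mi)
    v0 <- stats::var(null_mi)
    thresh <- if (v0 > 0)
      stats::qgamma(1 - alpha / nrow(pairs), shape = mu0^2 / v0,
                    rate = mu0 / v0)
    else mu0

    kept <- which(mi_b > thresh)
    if (length(kept) == 0) next
    kept_edges <- data.frame(a = pairs$a[kept], b = pairs$b[kept],
                             mi = mi_b[kept])
    kept_edges <- dpi_prune(kept_edges, dpi_tolerance)
    ke <- match(paste(kept_edges$a, kept_edges$b), paste(pairs$a, pairs$b))
    support[ke] <- support[ke] + 1
    mi_sum[ke] <- mi_sum[ke] + kept_edges$mi
  }

  cand <- which(support > 0)
  if (!is.null(consensus_p) && n_bootstraps > 1) {
    p0 <- alpha / nrow(pairs)  # null per-pair pass rate under the screen
    p_edge <- stats::pbinom(support[cand] - 1, n_bootstraps, p0,
                            lower.tail = FALSE)
    keep <- cand[p_edge * length(cand) < consensus_p]
  } else {
    keep <- cand
  }

  edges <- data.frame(a = pairs$a[keep], b = pairs$b[keep],
                      mi = mi_sum[keep] / support[keep],
                      support = support[keep])
  if (nrow(edges) > 0) {
    edges$spearman <- vapply(seq_len(nrow(edges)), function(e)
      stats::cor(m[edges$a[e], ], m[edges$b[e], ], method = "spearman"),
      numeric(1))
    edges$sign <- ifelse(edges$spearman < 0, -1, 1)
  } else {
    edges$spearman <- numeric(0)
    edges$sign <- numeric(0)
  }

  regulons <- lapply(stats::setNames(didx, drivers), function(d) {
    sel <- (edges$a == d | edges$b == d)
    tg <- ifelse(edges$a[sel] == d, edges$b[sel], edges$a[sel])
    data.frame(target = genes[tg], mi = edges$mi[sel],
               spearman = edges$spearman[sel], sign = edges$sign[sel],
               support = edges$support[sel], stringsAsFactors = FALSE)
  })

  structure(list(
    regulons = regulons,
    n_nodes = length(unique(c(edges$a, edges$b))),
    n_edges = nrow(edges),
    params = list(n_bootstraps = n_bootstraps, consensus_p = consensus_p,
                  dpi_tolerance = dpi_tolerance, alpha = alpha,
                  n_null = n_null, n_bins = n_bins)
  ), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d regulons, %d nodes, %d edges\n",
              length(x$regulons), x$n_nodes, x$n_edges))
  p <- x$params
  cat(sprintf("  bootstraps=%d, consensus_p=%s, dpi_tolerance=%g, alpha=%g, bins=%d\n",
              p$n_bootstraps,
              if (is.null(p$consensus_p)) "off" else format(p$consensus_p),
              p$dpi_tolerance, p$alpha, p$n_bins))
  for (d in names(x$regulons)) {
    r <- x$regulons[[d]]
    cat(sprintf("  %s: %d targets (%d+/%d-)\n", d, nrow(r),
                sum(r$sign > 0), sum(r$sign < 0)))
  }
  invisible(x)
}

#' Build a regulon object by hand
#'
#' @param driver driver gene id.
#' @param targets character vector of target ids.
#' @param mi nonnegative MI weights (recycled).
#' @param sign +1/-1 signs (recycled).
#' @return a single-regulon `interactome`-compatible list entry.
#' @export
regulon <- function(driver, targets, mi = 1, sign = 1) {
  targets <- as.character(targets)
  if (anyDuplicated(targets)) stop("duplicate targets")
  if (driver %in% targets) stop("driver cannot be its own target")
  mi <- rep_len(mi, length(targets))
  if (any(mi < 0)) stop("mi weights must be nonnegative")
  sign <- rep_len(sign, length(targets))
  if (!all(sign %in% c(-1, 1))) stop("signs must be -1 or +1")
  data.frame(target = targets, mi = mi, spearman = sign, sign = sign,
             support = NA_real_, stringsAsFactors = FALSE)
}

#' Regulon list helper
#'
#' Wraps a named list of regulon target tables (as from [regulon()]) into an
#' `interactome` so it can be fed to [compute_activity()].
#'
#' @param regulons named list (driver id -> target table).
#' @return an `interactome`.
#' @export
as_interactome <- function(regulons) {
  structure(list(regulons = regulons,
                 n_nodes = length(unique(c(names(regulons),
                   unlist(lapply(regulons, `[[`, "target"))))),
                 n_edges = sum(vapply(regulons, nrow, integer(1))),
                 params = list(n_bootstraps = NA, consensus_p = NA,
                               dpi_tolerance = NA, alpha = NA, n_null = NA,
                               n_bins = NA)),
            class = "interactome")
}

#' Weighted-mean regulon activity
#'
#' Genes are z-scaled across samples; the activity of a driver in a sample
#' is the MI-weighted mean of its signed target z-scores:
#' `sum(sign_t * w_t * z_ts) / sum(w_t)`. Targets absent from the
#' expression matrix are dropped (logged); a regulon with no present target
#' is omitted with a warning.
#'
#' @param expr an `expr_mat`.
#' @param interactome an `interactome`.
#' @return an `expr_mat` tagged `activity` (drivers x samples).
#' @export
compute_activity <- function(expr, interactome) {
  stopifnot(inherits(expr, "expr_mat"), inherits(interactome, "interactome"))
  z <- unclass(zscale_genes(expr))
  rows <- list()
  for (d in names(interactome$regulons)) {
    r <- interactome$regulons[[d]]
    present <- r$target %in% rownames(z)
    if (!all(present))
      message("compute_activity: ", d, ": dropped ", sum(!present),
              " absent target(s)")
    r <- r[present, , drop = FALSE]
    if (nrow(r) == 0) {
      warning("regulon ", d, " has no targets in the matrix; omitted")
      next
    }
    w <- r$mi
    if (sum(w) == 0) w <- rep(1, nrow(r))
    rows[[d]] <- colSums(z[r$target, , drop = FALSE] * (r$sign * w)) / sum(w)
  }
  if (length(rows) == 0) stop("no regulon has any target in the matrix")
  act <- do.call(rbind, rows)
  colnames(act) <- colnames(expr)
  expr_mat(act, normalization = "activity", species = attr(expr, "species"))
}

#' Differential activity between two sample groups
#'
#' Applies the same moderated two-group machinery as differential expression
#' to a driver x sample activity matrix.
#'
#' @inheritParams moderated_two_group
#' @param activity an `expr_mat` tagged `activity`.
#' @return a `de_table` (one row per driver).
#' @export
differential_activity <- function(activity, groups, case = "case",
                                  control = "control", d0 = NULL) {
  stopifnot(inherits(activity, "expr_mat"))
  if (attr(activity, "normalization") != "activity")
    stop("expected an activity matrix")
  moderated_two_group(activity, groups, case = case, control = control,
                      d0 = d0)
}

#' Hidden-driver filter
#'
#' Keeps drivers whose differential activity is significant while their own
#' differential expression is not elevated: `z_DA > z_da_thresh` and
#' `z_DE < z_de_max`. The result is ranked by `z_DA` descending; an
#' alternative ordering by mean activity is provided as `rank_by_activity`.
#'
#' @param da `de_table` from [differential_activity()] (drivers).
#' @param de `de_table` from [moderated_two_group()] on expression, indexed
#'   by the same driver identifiers.
#' @param z_da_thresh minimum differential-activity Z (default 1.96).
#' @param z_de_max maximum differential-expression Z (default 0).
#' @return data.frame of retained drivers: `driver`, `z_da`, `z_de`,
#'   `mean_activity`, `rank_by_activity`, sorted by `z_da` descending.
#' @export
hidden_drivers <- function(da, de, z_da_thresh = 1.96, z_de_max = 0) {
  shared <- intersect(da$gene, de$gene)
  if (length(shared) == 0)
    stop("no shared driver identifiers between DA and DE tables")
  ia <- match(shared, da$gene)
  ie <- match(shared, de$gene)
  out <- data.frame(driver = shared,
                    z_da = da$z[ia], z_de = de$z[ie],
                    mean_activity = da$ave_expr[ia],
                    stringsAsFactors = FALSE)
  out <- out[out$z_da > z_da_thresh & out$z_de < z_de_max, , drop = FALSE]
  out <- out[order(-out$z_da, out$driver), , drop = FALSE]
  out$rank_by_activity <- rank(-out$mean_activity, ties.method = "first")
  rownames(out) <- NULL
  out
}
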