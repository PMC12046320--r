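# Moderated two-group differential expression.
#
# The statistic is the classic empirical-Bayes moderated t: per-gene pooled
# residual variance s_g^2 on d_g df is shrunk toward a common prior value
# s0^2 with prior df d0,
#     stilde_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g),
# and t_mod = log2FC / (stilde_g * sqrt(1/n1 + 1/n2)) is referred to a t
# distribution on d0 + d_g df. (d0, s0^2) are estimated by method of moments
# on log s_g^2.

#' Cap used when converting p-values to signed Z-scores
#'
#' `qnorm(1 - p/2)` saturates near the double-precision limit of the normal
#' quantile; |Z| is capped at 8.21 so that downstream Stouffer combinations
#' stay finite.
#' @keywords internal
Z_CAP <- 8.21

#' Signed Z-score from a two-sided p-value
#'
#' `z = sign * qnorm(1 - p/2)`, with |z| capped at 8.21 to guard against
#' p-value underflow.
#'
#' @param p two-sided p-value(s) in (0, 1].
#' @param direction_sign -1, 0 or +1 (vectorized; usually `sign(log2FC)`).
#' @return signed Z-score(s).
#' @examples
#' z_from_p(0.05, +1)  # ~ 1.96
#' @export
z_from_p <- function(p, direction_sign) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (!all(direction_sign %in% c(-1, 0, 1)))
    stop("direction_sign must be -1, 0 or +1")
  z <- stats::qnorm(1 - p / 2)
  direction_sign * pmin(z, Z_CAP)
}

# Newton solve of trigamma(y) = x, on the log scale for stability.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Method-of-moments fit of the scaled inverse-chi-square prior for gene
# variances: match mean and variance of log(s^2) against the theoretical
# log-F distribution. Returns list(d0, s0sq); d0 may be Inf when the
# observed spread of log-variances is no wider than sampling noise alone.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  if (length(s2) < 2) return(list(d0 = Inf, s0sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(ebar)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated two-group differential expression
#'
#' Gene-wise two-group comparison with empirical-Bayes variance moderation:
#' log2 fold change is the mean difference (case - control), the pooled
#' per-gene variance is shrunk toward a method-of-moments prior, and the
#' moderated t is converted to a two-sided p-value and a signed Z-score
#' (`sign(z) = sign(log2FC)`, |z| capped at 8.21).
#'
#' @param expr an `expr_mat` (typically `log2cpm` expression or an `activity`
#'   matrix).
#' @param groups named character/factor vector mapping every sample id of
#'   `expr` to a group label, or a two-column data.frame `(sample, group)`.
#' @param case,control the two group labels being compared; every sample must
#'   belong to one of them and each side needs at least two samples.
#' @param d0 optional override of the prior degrees of freedom: `0` disables
#'   moderation (ordinary pooled t), `Inf` fully shrinks every variance to
#'   the prior value. Default `NULL` estimates d0 from the data.
#' @param min_mean optional expression filter: genes with
#'   `ave_expr < min_mean` are dropped before testing (default: no filter).
#' @return a `de_table` data.frame with columns `gene`, `log2FC`, `t`, `p`,
#'   `z`, `ave_expr`, `constant` (logical flag for genes with no variance
#'   anywhere, reported with p = 1, z = 0), plus attributes `d0`, `s0sq`,
#'   `df_residual`.
#' @export
moderated_two_group <- function(expr, groups, case = "case",
                                control = "control", d0 = NULL,
                                min_mean = NULL) {
  stopifnot(inherits(expr, "expr_mat"))
  groups <- as_group_vector(groups, colnames(expr))
  if (!all(groups %in% c(case, control)) ||
      !all(c(case, control) %in% groups))
    stop("groups must partition samples into '", case, "' and '", control, "'")
  i1 <- which(groups == case)
  i2 <- which(groups == control)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples (got ", n1, " and ", n2, ")")

  m <- unclass(expr)
  if (!is.null(min_mean)) {
    keep <- rowMeans(m) >= min_mean
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0) stop("no genes left after min_mean filter")
  }

  mu1 <- rowMeans(m[, i1, drop = FALSE])
  mu2 <- rowMeans(m[, i2, drop = FALSE])
  fc <- mu1 - mu2
  ss1 <- rowSums((m[, i1, drop = FALSE] - mu1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - mu2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg

  constant <- s2 <= 0 & abs(fc) < .Machine$double.eps^0.5

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2[!constant & s2 > 0], dg)
    d0 <- prior$d0
    s0sq <- prior$s0sq
  } else {
    if (length(d0) != 1 || is.na(d0) || d0 < 0) stop("'d0' must be >= 0")
    s0sq <- if (d0 > 0) fit_variance_prior(s2[!constant & s2 > 0], dg)$s0sq
            else 0
  }

  if (is.infinite(d0)) {
    stilde2 <- rep(s0sq, length(s2))
    df_total <- Inf
  } else {
    stilde2 <- (d0 * s0sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }

  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tmod <- fc / se
  tmod[se == 0 & fc == 0] <- 0
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  p <- pmax(pmin(p, 1), 1e-320)
  z <- z_from_p(p, sign(fc))

  p[constant] <- 1
  z[constant] <- 0
  tmod[constant] <- 0

  out <- data.frame(gene = rownames(m), log2FC = fc, t = tmod, p = p, z = z,
                    ave_expr = rowMeans(m), constant = constant,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, d0 = d0, s0sq = s0sq, df_residual = dg,
            class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table: %d genes (d0 = %.4g, s0^2 = %.4g, residual df = %d)\n",
              nrow(x), attr(x, "d0"), attr(x, "s0sq"), attr(x, "df_residual")))
  ord <- order(-abs(x$z))
  print.data.frame(utils::head(x[ord, ], 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# Accept groups as a named vector or a (sample, group) data.frame and align
# them to the matrix's sample order.
as_group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2) stop("group data.frame needs (sample, group) columns")
    v <- as.character(groups[[2]])
    names(v) <- as.character(groups[[1]])
    groups <- v
  }
  if (is.null(names(groups)))
    stop("'groups' must be named by sample id")
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  as.character(groups[sample_ids])
}
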