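test_that("ortholog merge matches case-insensitively and 1:1 only", {
  de_h <- mk_de(c("GPR65", "FOXO1"), c(2, 1), c(1, 1))
  de_m <- mk_de(c("Gpr65", "Vegfa"), c(2.5, 1), c(1, 1))
  merged <- merge_orthologs(de_h, de_m)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$gene, "GPR65")
  expect_equal(merged$combined_z, 4.5 / sqrt(2))

  expect_error(merge_orthologs(mk_de("A", 1, 1), mk_de("B", 1, 1)),
               "zero shared genes")

  # 2:1 collision: human GENE1/Gene1 both uppercase to GENE1 -> dropped
  de_h2 <- mk_de(c(sprintf("G%02d", 1:14), "g01"), rep(1, 15), rep(1, 15))
  de_m2 <- mk_de(sprintf("g%02d", 1:12), rep(1, 12), rep(1, 12))
  expect_message(merged2 <- merge_orthologs(de_h2, de_m2), "ambiguous")
  expect_equal(nrow(merged2), 11)  # 12 shared minus the collided symbol
  expect_equal(attr(merged2, "dropped"), "G01")
})

test_that("explicit ortholog maps override symbol matching", {
  de_h <- mk_de(c("A", "B", "C"), c(1, 2, 3), c(1, 1, 1))
  de_m <- mk_de(c("x", "y", "z"), c(3, 2, 1), c(1, 1, 1))
  map <- data.frame(human = c("A", "B"), mouse = c("y", "z"))
  merged <- merge_orthologs(de_h, de_m, map)
  expect_equal(merged$gene, c("A", "B"))
  expect_equal(merged$z_m, c(2, 1))
})

test_that("anchor selection applies the three steps (enumeration oracle)", {
  # 8 genes with fixed z and fold changes
  genes <- sprintf("G%d", 1:8)
  z_h <- c(2.5, 2.5, 2.2, 3.0, 1.0, -2.4, -2.1, 0.5)
  z_m <- c(2.5, 2.5, 2.1, 1.2, 2.8, -2.6, 2.3, 0.2)
  fc_h <- c(1.0, 1.1, 0.8, 2.0, 0.3, -1.5, -0.9, 0.1)
  fc_m <- c(0.9, -1.0, 0.7, 0.4, 1.1, -1.2, 1.0, 0.05)
  merged <- merge_orthologs(mk_de(genes, z_h, fc_h), mk_de(genes, z_m, fc_m))

  # brute-force application of the three steps
  s_h <- genes[abs(z_h) > 1.96]
  s_m <- genes[abs(z_m) > 1.96]
  consistent <- genes[sign(fc_h) == sign(fc_m)]
  c_h <- intersect(s_h, consistent)     # G1 G3 G4 G6
  c_m <- intersect(s_m, consistent)     # G1 G3 G5 G6
  k <- min(length(c_h), length(c_m))
  top_h <- c_h[order(-abs(fc_h[match(c_h, genes)]), c_h)][1:k]
  top_m <- c_m[order(-abs(fc_m[match(c_m, genes)]), c_m)][1:k]

  sig <- select_anchors(merged)
  expect_setequal(sig$species_sets$human$gene, s_h)
  expect_setequal(sig$species_sets$mouse$gene, s_m)
  expect_equal(sig$anchors_h$gene, top_h)
  expect_equal(sig$anchors_m$gene, top_m)
  expect_setequal(sig$shared$gene, intersect(intersect(s_h, s_m), consistent))
  expect_equal(sig$universe_size, 8)
  # directions consistent between species for every anchor
  expect_equal(sign(sig$anchors_h$log2FC_h), sign(sig$anchors_h$log2FC_m))

  # invariant to row order
  sig2 <- select_anchors(merged[sample.int(8), ])
  expect_equal(sig2$anchors_h$gene, sig$anchors_h$gene)

  # opposite-sign gene dropped even with large z in both species
  expect_false("G2" %in% sig$anchors_h$gene)
  expect_true("G1" %in% sig$anchors_h$gene)
})

test_that("empty anchor sets warn but return a valid object", {
  merged <- merge_orthologs(mk_de(c("A", "B"), c(0.1, 0.2), c(1, 1)),
                            mk_de(c("A", "B"), c(0.1, 0.2), c(1, 1)))
  expect_warning(sig <- select_anchors(merged), "empty")
  expect_equal(length(sig$anchors), 0)
})

test_that("overlap test equals hypergeometric enumeration for small universes", {
  enum_p <- function(k, a, b, n) {
    ks <- max(0, a + b - n):min(a, b)
    probs <- dhyper(ks, a, n - a, b)
    sum(probs[probs <= dhyper(k, a, n - a, b) * (1 + 1e-7)])
  }
  for (n in c(10, 20)) {
    univ <- sprintf("u%02d", 1:n)
    set.seed(n)
    for (i in 1:25) {
      a <- sample(1:n, 1); b <- sample(1:n, 1)
      sa <- sample(univ, a); sb <- sample(univ, b)
      got <- overlap_test(sa, sb, n)
      expect_equal(got$overlap, length(intersect(sa, sb)))
      expect_equal(got$p, enum_p(got$overlap, a, b, n), tolerance = 1e-9)
    }
  }
  # perfect overlap of the full universe is certain
  expect_equal(overlap_test(sprintf("u%d", 1:20), sprintf("u%d", 1:20), 20)$p, 1)
  # spec toy: identical 5-gene sets in a 20-gene universe
  s <- sprintf("u%d", 1:5)
  expect_equal(overlap_test(s, s, 20)$p, 1 / choose(20, 5), tolerance = 1e-6)
  expect_error(overlap_test(sprintf("u%d", 1:5), sprintf("u%d", 6:10), 8),
               "universe")
})

test_that("joint PCA score recovers a planted rank-1 structure", {
  set.seed(7)
  s_true <- rnorm(40)                     # per-sample factor
  w <- rnorm(15)                          # gene loadings
  m <- outer(w, s_true) + matrix(rnorm(15 * 40, sd = 0.01), 15, 40)
  genes <- sprintf("A%02d", 1:15)
  mh <- m[, 1:20]; mm <- m[, 21:40]
  dimnames(mh) <- list(genes, sprintf("h%02d", 1:20))
  dimnames(mm) <- list(tolower(genes), sprintf("m%02d", 1:20))
  eh <- expr_mat(mh, normalization = "log2cpm", species = "human")
  em <- expr_mat(mm, normalization = "log2cpm", species = "mouse")
  sc <- joint_pca_score(eh, em, genes)
  # genes are z-scaled within species, so the recoverable factor is the
  # within-species standardized one
  s_std <- c(scale(s_true[1:20]), scale(s_true[21:40]))
  expect_gt(abs(cor(sc$score, s_std)), 0.999)
  # shifting a gene by a constant within a species changes nothing
  mh2 <- mh; mh2[3, ] <- mh2[3, ] + 100
  sc2 <- joint_pca_score(expr_mat(mh2, normalization = "log2cpm",
                                  species = "human"), em, genes)
  expect_equal(sc2$score, sc$score, tolerance = 1e-8)
  expect_error(joint_pca_score(eh, em, c(genes, "MISSING")), "MISSING")
})

test_that("roc_auc equals concordant-pair counting and handles ties", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0), n_boot = 50)
  expect_equal(r$auc, 0.75)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  # all-equal scores: AUC = 0.5 by the tie rule
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0), n_boot = 10)$auc, 0.5)
  # label flip maps AUC to 1 - AUC
  set.seed(8)
  sc <- rnorm(30); lab <- rep(c(1, 0), 15)
  expect_equal(roc_auc(sc, lab, n_boot = 10)$auc,
               1 - roc_auc(sc, 1 - lab, n_boot = 10)$auc)
  expect_error(roc_auc(sc, rep(1, 30), n_boot = 10), "both label classes")
})

test_that("roc_auc agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:20) {
    sc <- round(rnorm(40), 1)  # rounding induces ties
    lab <- rbinom(40, 1, 0.5)
    if (length(unique(lab)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(lab, sc,
                                                 direction = "<")))
    expect_equal(roc_auc(sc, lab, n_boot = 2)$auc, ref, tolerance = 1e-12)
  }
})

test_that("stouffer ranking follows the closed form and is antisymmetric", {
  merged <- merge_orthologs(mk_de(c("A", "B", "C"), c(1.5, 0, -1), c(1, 1, -1)),
                            mk_de(c("a", "b", "c"), c(2.5, 0, -2), c(1, 1, -1)))
  rk <- stouffer_rank(merged)
  expect_equal(rk$combined_z[rk$gene == "A"], 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(rk$combined_z[rk$gene == "A"], 2.8284, tolerance = 1e-4)
  expect_equal(rk$combined_z[rk$gene == "B"], 0)
  expect_equal(rk$gene, c("A", "B", "C"))
  # global sign flip reverses the ranking exactly
  flipped <- merged
  flipped$z_h <- -flipped$z_h; flipped$z_m <- -flipped$z_m
  rk2 <- stouffer_rank(flipped)
  expect_equal(rk2$combined_z, -rev(rk$combined_z))
})
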