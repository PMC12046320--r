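test_that("mutual information: exact self-MI, symmetry, monotone invariance", {
  set.seed(1)
  x <- runif(1000); y <- runif(1000)
  # n divisible by bins: plug-in MI of a vector with itself is log(n_bins)
  for (nb in c(2, 5, 10))
    expect_equal(mutual_information(x, x, nb), log(nb))
  expect_equal(mutual_information(x, y, 8), mutual_information(y, x, 8))
  # invariance under strictly monotone transforms (quantile binning)
  expect_equal(mutual_information(x, y, 6),
               mutual_information(exp(3 * x), y^3, 6))
  expect_equal(mutual_information(x, -x, 5), mutual_information(x, x, 5))
  expect_gte(mutual_information(x, y, 10), 0)
  expect_warning(mi0 <- mutual_information(rep(1, 100), y[1:100]), "constant")
  expect_equal(mi0, 0)
  expect_error(mutual_information(x[1:4], y[1:4]), "at least 8")
})

test_that("independent vectors give near-zero MI at large n", {
  set.seed(2)
  expect_lt(mutual_information(runif(10000), runif(10000), 10), 0.02)
})

test_that("single-pass inference equals a brute-force MI threshold + DPI", {
  set.seed(3)
  n <- 120; ng <- 20
  a <- rnorm(n)
  m <- matrix(rnorm(ng * n), ng, n)
  m[2, ] <- a + rnorm(n, sd = 0.4)       # target of driver 1
  m[1, ] <- a + rnorm(n, sd = 0.4)       # driver 1
  m[3, ] <- m[2, ] + rnorm(n, sd = 0.4)  # chain: 1 -> 2 -> 3
  dimnames(m) <- list(sprintf("g%02d", 1:ng), sprintf("s%03d", 1:n))
  em <- expr_mat(m, normalization = "log2cpm")
  drivers <- c("g01", "g02")

  set.seed(10)
  net <- infer_network(em, drivers, n_bootstraps = 1, consensus_p = NULL,
                       n_bins = 5, n_null = 400)

  # brute force: same threshold construction, exhaustive triangle DPI
  set.seed(10)
  pairs <- unique(do.call(rbind, lapply(1:2, function(d)
    data.frame(a = pmin(d, setdiff(1:ng, d)),
               b = pmax(d, setdiff(1:ng, d))))))
  mi <- apply(pairs, 1, function(pr)
    mutual_information(m[pr[1], ], m[pr[2], ], 5))
  null_mi <- replicate(400, {
    d <- sample(1:2, 1); g <- sample(1:ng, 1)
    mutual_information(m[d, sample(n)], m[g, ], 5)
  })
  mu0 <- mean(null_mi); v0 <- var(null_mi)
  thr <- qgamma(1 - 0.05 / nrow(pairs), shape = mu0^2 / v0, rate = mu0 / v0)
  keep <- which(mi > thr)
  kept <- cbind(pairs[keep, ], mi = mi[keep])
  # exhaustive DPI over all triangles
  drop <- rep(FALSE, nrow(kept))
  for (e in seq_len(nrow(kept))) {
    for (f in seq_len(nrow(kept))) {
      for (g in seq_len(nrow(kept))) {
        nodes <- c(kept$a[e], kept$b[e], kept$a[f], kept$b[f],
                   kept$a[g], kept$b[g])
        if (e < f && f < g && length(unique(nodes)) == 3) {
          w <- c(kept$mi[e], kept$mi[f], kept$mi[g])
          drop[c(e, f, g)[which.min(w)]] <-
            drop[c(e, f, g)[which.min(w)]] || (min(w) < min(w[-which.min(w)]))
        }
      }
    }
  }
  oracle <- kept[!drop, ]
  got <- do.call(rbind, lapply(names(net$regulons), function(d) {
    r <- net$regulons[[d]]
    di <- match(d, rownames(m))
    ti <- match(r$target, rownames(m))
    data.frame(a = pmin(di, ti), b = pmax(di, ti), mi = r$mi)
  }))
  got <- unique(got)
  expect_setequal(paste(got$a, got$b), paste(oracle$a, oracle$b))
  expect_equal(sort(got$mi), sort(oracle$mi), tolerance = 1e-12)
})

test_that("DPI removes the indirect edge of a chain", {
  removed <- vapply(1:30, function(s) {
    set.seed(s)
    n <- 300
    X <- rnorm(n); Y <- X + rnorm(n, sd = 0.3); Z <- Y + rnorm(n, sd = 0.3)
    m <- rbind(X = X, Y = Y, Z = Z)
    colnames(m) <- paste0("s", 1:n)
    net <- infer_network(expr_mat(m, normalization = "log2cpm"), c("X", "Y"),
                         n_bootstraps = 1, consensus_p = NULL)
    xt <- net$regulons[["X"]]$target
    ("Y" %in% xt) && !("Z" %in% xt) && ("Z" %in% net$regulons[["Y"]]$target)
  }, logical(1))
  expect_gte(mean(removed), 0.95)
})

test_that("negative dependence yields sign -1", {
  set.seed(4)
  n <- 200
  a <- rnorm(n)
  m <- rbind(D = a + rnorm(n, sd = 0.2), Tpos = a + rnorm(n, sd = 0.2),
             Tneg = -a + rnorm(n, sd = 0.2))
  colnames(m) <- paste0("s", 1:n)
  net <- infer_network(expr_mat(m, normalization = "log2cpm"), "D",
                       n_bootstraps = 1, consensus_p = NULL)
  r <- net$regulons[["D"]]
  expect_equal(r$sign[r$target == "Tpos"], 1)
  expect_equal(r$sign[r$target == "Tneg"], -1)
})

test_that("network recovery on a small planted-regulon instance", {
  rs <- simulate_regulon_population(regulon_config(n_genes = 150,
                                                   n_samples_per_group_per_species = 150,
                                                   seed = 6))
  set.seed(7)
  net <- infer_network(rs$expr, rs$truth$driver_genes, n_bootstraps = 40)
  truth_targets <- unlist(lapply(rs$truth$driver_regulons, `[[`, "target"))
  inferred <- unlist(lapply(net$regulons, `[[`, "target"))
  expect_gte(mean(truth_targets %in% inferred), 0.9)
  ok <- unlist(lapply(names(net$regulons), function(d)
    net$regulons[[d]]$target %in%
      c(rs$truth$driver_regulons[[d]]$target, rs$truth$driver_genes)))
  expect_gte(mean(ok), 0.9)
  expect_error(infer_network(rs$expr, "NOT_A_GENE"), "no driver ids")
})

test_that("activity is the weighted mean of signed z-scaled targets", {
  set.seed(8)
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(c("D", "t1", "t2", "t3", "t4"),
                              sprintf("s%02d", 1:12)))
  em <- expr_mat(m, normalization = "log2cpm")
  z <- unclass(zscale_genes(em))
  # single positive target: activity equals that target's z-scores
  net1 <- as_interactome(list(D = regulon("D", "t1", mi = 0.7)))
  a1 <- compute_activity(em, net1)
  expect_equal(unname(a1["D", , drop = TRUE]), unname(z["t1", ]))
  # two equal-weight targets with signs +1/-1: (z1 - z2) / 2
  net2 <- as_interactome(list(D = regulon("D", c("t1", "t2"), mi = 0.5,
                                          sign = c(1, -1))))
  a2 <- compute_activity(em, net2)
  expect_equal(unname(a2["D", , drop = TRUE]), unname((z["t1", ] - z["t2", ]) / 2))
  # invariance under uniform rescaling of the MI weights
  net3 <- as_interactome(list(D = regulon("D", c("t1", "t3"),
                                          mi = c(0.2, 0.8))))
  net4 <- as_interactome(list(D = regulon("D", c("t1", "t3"),
                                          mi = c(2, 8))))
  expect_equal(unclass(compute_activity(em, net3)),
               unclass(compute_activity(em, net4)))
  # missing targets dropped; fully absent regulon omitted with warning
  net5 <- as_interactome(list(D = regulon("D", c("t1", "nope")),
                              E = regulon("E", "missing")))
  expect_warning(suppressMessages(a5 <- compute_activity(em, net5)),
                 "omitted")
  expect_equal(rownames(a5), "D")
  expect_equal(unname(a5["D", , drop = TRUE]), unname(z["t1", ]))
})

test_that("differential activity is antisymmetric under label swap", {
  rs <- simulate_regulon_population(small_regulon(seed = 9))
  truth_net <- as_interactome(lapply(rs$truth$driver_regulons, function(r)
    regulon(".d", r$target, sign = r$sign)))
  act <- compute_activity(rs$expr, truth_net)
  grp <- rs$truth$group_labels[colnames(act)]
  da1 <- differential_activity(act, grp, case = "hi", control = "lo")
  da2 <- differential_activity(act, grp, case = "lo", control = "hi")
  expect_equal(da1$z, -da2$z)
  expect_equal(da1$p, da2$p)
  # planted driver has the strongest differential activity
  expect_equal(da1$gene[which.max(abs(da1$z))], rs$truth$hidden_driver)
  expect_gt(da1$z[da1$gene == rs$truth$hidden_driver], 1.96)
})

test_that("hidden-driver filter keeps DA-up, DE-down drivers only", {
  da <- mk_de(c("A", "B", "C", "D"), c(2.5, 2.5, 1.0, 3.5), c(1, 1, 1, 1))
  da$ave_expr <- c(0.5, 0.9, 0.1, 0.2)
  de <- mk_de(c("A", "B", "C", "D"), c(-0.5, 0.5, -2.0, -1.0),
              c(-1, 1, -1, -1))
  hd <- hidden_drivers(da, de)
  expect_equal(hd$driver, c("D", "A"))  # sorted by z_da, B fails z_de, C z_da
  expect_equal(hd$rank_by_activity, c(2, 1))  # B excluded; A outranks D
  expect_error(hidden_drivers(da, mk_de("X", 1, 1)), "no shared driver")
})
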