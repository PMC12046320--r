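# Synthetic cohorts with planted ground truth.
#
# Two generators back the whole test surface of the package:
#   * simulate_cross_species_cohort(): paired human-like / mouse-like
#     responder vs nonresponder bulk cohorts sharing a planted response
#     signature headed by a single top driver gene;
#   * simulate_regulon_population(): a single-population matrix whose
#     structure is a set of planted signed regulons driven by latent
#     activities, with one hidden driver whose activity (not mRNA) separates
#     the two sample groups.
# Expression is simulated directly on the log2-CPM scale (Gaussian on log2
# scale, i.e. log-normal expression), matching what the differential
# expression stage consumes; as_counts() exports Poisson-thinned raw counts
# when the raw-count entry point needs exercising.

#' Configuration for the cross-species cohort generator
#'
#' Defaults describe the simulated study conditions used throughout the
#' package: 2,000 genes of which 40 form a shared response signature headed
#' by one designated driver gene, 20 samples per group per species, a log2
#' effect of 3 for the driver (secondary signature genes carry 30% of it),
#' a species batch offset of 2 and per-gene noise SD of 0.5.
#'
#' @param n_genes total genes per species.
#' @param n_signature number of true shared response genes (including the
#'   driver).
#' @param n_samples_per_group_per_species samples per (group, species) cell.
#' @param effect_size log2-scale shift of the designated driver gene in
#'   responders; the remaining signature genes carry
#'   `secondary_frac * effect_size` with random sign.
#' @param secondary_frac fraction of `effect_size` carried by non-driver
#'   signature genes (default 0.3).
#' @param batch_shift species-level log2 offset applied to the mouse-like
#'   matrix.
#' @param noise_sd per-gene log2-scale standard deviation (> 0).
#' @param n_drivers,targets_per_driver,frac_negative_targets,driver_effect
#'   regulon-layer parameters, used by [simulate_regulon_population()].
#' @param seed integer seed; each emitted matrix uses a fixed offset from it
#'   so artifacts are independently reproducible.
#' @return a `sim_config` list.
#' @export
cohort_config <- function(n_genes = 2000, n_signature = 40,
                          n_samples_per_group_per_species = 20,
                          effect_size = 3, secondary_frac = 0.3,
                          batch_shift = 2, noise_sd = 0.5,
                          n_drivers = 2, targets_per_driver = 20,
                          frac_negative_targets = 0.4, driver_effect = 2,
                          seed = 1) {
  cfg <- list(n_genes = n_genes, n_signature = n_signature,
              n_samples_per_group_per_species = n_samples_per_group_per_species,
              effect_size = effect_size, secondary_frac = secondary_frac,
              batch_shift = batch_shift, noise_sd = noise_sd,
              n_drivers = n_drivers, targets_per_driver = targets_per_driver,
              frac_negative_targets = frac_negative_targets,
              driver_effect = driver_effect, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Configuration for the regulon population generator
#'
#' Same fields as [cohort_config()], with defaults matched to the
#' single-population regulon study conditions: 500 genes, 2 drivers with 20
#' targets each (40% negative, echoing a 30-positive / 20-negative regulon
#' split), 250 samples per group, target noise SD 0.3, and a latent activity
#' shift of 2 between groups for the first (hidden) driver.
#'
#' @inheritParams cohort_config
#' @param n_samples_per_group_per_species samples per group (one species).
#' @return a `sim_config` list.
#' @export
regulon_config <- function(n_genes = 500, n_signature = 40,
                           n_samples_per_group_per_species = 250,
                           effect_size = 3, secondary_frac = 0.3,
                           batch_shift = 2, noise_sd = 0.3,
                           n_drivers = 2, targets_per_driver = 20,
                           frac_negative_targets = 0.4, driver_effect = 2,
                           seed = 1) {
  cohort_config(n_genes = n_genes, n_signature = n_signature,
                n_samples_per_group_per_species =
                  n_samples_per_group_per_species,
                effect_size = effect_size, secondary_frac = secondary_frac,
                batch_shift = batch_shift, noise_sd = noise_sd,
                n_drivers = n_drivers, targets_per_driver = targets_per_driver,
                frac_negative_targets = frac_negative_targets,
                driver_effect = driver_effect, seed = seed)
}

validate_sim_config <- function(cfg) {
  need_count <- c("n_genes", "n_signature", "n_samples_per_group_per_species",
                  "n_drivers", "targets_per_driver")
  for (f in need_count) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v))
      stop("invalid config field '", f, "': must be an integer >= 1")
  }
  if (cfg$n_signature > cfg$n_genes)
    stop("invalid config field 'n_signature': exceeds n_genes")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("invalid config field 'noise_sd': must be > 0")
  if (!is.numeric(cfg$frac_negative_targets) ||
      cfg$frac_negative_targets < 0 || cfg$frac_negative_targets > 1)
    stop("invalid config field 'frac_negative_targets': must lie in [0, 1]")
  for (f in c("effect_size", "batch_shift", "driver_effect",
              "secondary_frac")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
        !is.finite(cfg[[f]]))
      stop("invalid config field '", f, "': must be a finite number")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed))
    stop("invalid config field 'seed': must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (f in names(x)) cat(sprintf("  %-34s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Gene identifiers: human symbols uppercase, mouse symbols capitalized-only,
# so the case-insensitive ortholog matching path is exercised.
sim_gene_ids <- function(n, species = c("human", "mouse")) {
  species <- match.arg(species)
  base <- sprintf("gene%05d", seq_len(n))
  if (species == "human") toupper(base)
  else paste0("Gene", substring(base, 5))
}

#' Simulate a paired two-species responder/nonresponder cohort
#'
#' Generates human-like and mouse-like log2-CPM matrices from a common
#' planted structure: per-gene baselines shared across species, a response
#' signature whose genes are shifted in responders (one designated driver
#' gene carries the full `effect_size`, the rest carry
#' `secondary_frac * effect_size` with random sign), a constant species
#' batch offset on the mouse-like matrix, and i.i.d. Gaussian log2 noise.
#'
#' @param config a `sim_config` from [cohort_config()].
#' @return a list with `human` and `mouse` (`expr_mat`, tag `log2cpm`) and
#'   `truth` (`sim_truth`): signature gene table (human-cased ids, direction,
#'   effect), the driver gene id, and group/species labels per sample.
#' @export
simulate_cross_species_cohort <- function(config = cohort_config()) {
  validate_sim_config(config)
  n <- config$n_samples_per_group_per_species
  ng <- config$n_genes

  # substream 0: shared structure
  set.seed(config$seed)
  baseline <- stats::runif(ng, 3, 9)
  sig_idx <- sort(sample.int(ng, config$n_signature))
  direction <- sample(c(-1, 1), config$n_signature, replace = TRUE)
  direction[1] <- 1  # driver gene planted as up-in-responders
  effect <- rep(config$secondary_frac * config$effect_size,
                config$n_signature)
  effect[1] <- config$effect_size
  driver_idx <- sig_idx[1]

  genes_h <- sim_gene_ids(ng, "human")
  genes_m <- sim_gene_ids(ng, "mouse")

  groups <- rep(c("responder", "nonresponder"), each = n)
  shift <- numeric(ng)
  shift[sig_idx] <- direction * effect

  make_matrix <- function(genes, samples, batch, sub_seed) {
    set.seed(sub_seed)
    mu <- baseline + batch
    m <- matrix(stats::rnorm(ng * 2 * n, mean = mu, sd = config$noise_sd),
                ng, 2 * n, dimnames = list(genes, samples))
    m[, groups == "responder"] <- m[, groups == "responder"] + shift
    m
  }

  samples_h <- sprintf("h_%s_%02d", rep(c("R", "NR"), each = n),
                       rep(seq_len(n), 2))
  samples_m <- sprintf("m_%s_%02d", rep(c("R", "NR"), each = n),
                       rep(seq_len(n), 2))
  # substreams 1/2: one per emitted matrix
  mh <- make_matrix(genes_h, samples_h, 0, config$seed + 1L)
  mm <- make_matrix(genes_m, samples_m, config$batch_shift, config$seed + 2L)

  truth <- structure(list(
    signature_genes = data.frame(gene = genes_h[sig_idx],
                                 direction = direction, effect = effect,
                                 stringsAsFactors = FALSE),
    driver_gene = genes_h[driver_idx],
    group_labels = stats::setNames(rep(groups, 2), c(samples_h, samples_m)),
    species_labels = stats::setNames(rep(c("human", "mouse"), each = 2 * n),
                                     c(samples_h, samples_m))
  ), class = "sim_truth")

  list(human = expr_mat(mh, normalization = "log2cpm", species = "human"),
       mouse = expr_mat(mm, normalization = "log2cpm", species = "mouse"),
       truth = truth)
}

#' Simulate a regulon-structured single population
#'
#' Each driver gets a latent per-sample activity `a ~ N(0, 1)`; positive
#' targets read `+a` plus Gaussian noise (`noise_sd`), negative targets
#' `-a` plus noise, and off-regulon genes are independent noise. The first
#' driver is planted as a hidden driver: its latent activity is shifted by
#' `driver_effect` in the second sample group while its own mRNA tracks only
#' the within-group activity fluctuation and carries a small *negative*
#' group shift (`-0.15 * driver_effect`), i.e. differential activity without
#' raised expression. Any additional drivers act as decoys: unshifted
#' activity with a mildly *raised* mRNA (`+0.15 * driver_effect`) in the
#' second group.
#'
#' @param config a `sim_config` from [regulon_config()].
#' @return a list with `expr` (`expr_mat`, tag `log2cpm`) and `truth`
#'   (`sim_truth`): per-driver regulon tables `(target, sign)`, latent
#'   activity matrix, and the group labels.
#' @export
simulate_regulon_population <- function(config = regulon_config()) {
  validate_sim_config(config)
  ng <- config$n_genes
  nd <- config$n_drivers
  tpd <- config$targets_per_driver
  if (nd * (tpd + 1) > ng)
    stop("n_drivers * (targets_per_driver + 1) exceeds n_genes")
  n <- config$n_samples_per_group_per_species
  ns <- 2L * n

  set.seed(config$seed)
  genes <- sim_gene_ids(ng, "human")
  baseline <- stats::runif(ng, 3, 9)
  samples <- sprintf("c_%s_%03d", rep(c("lo", "hi"), each = n),
                     rep(seq_len(n), 2))
  groups <- rep(c("lo", "hi"), each = n)

  idx <- sample.int(ng, nd * (tpd + 1))
  driver_idx <- idx[seq_len(nd)]
  target_idx <- matrix(idx[-seq_len(nd)], nrow = nd)  # nd x tpd

  n_neg <- round(config$frac_negative_targets * tpd)
  signs <- t(vapply(seq_len(nd), function(d) {
    s <- c(rep(-1, n_neg), rep(1, tpd - n_neg))
    s[sample.int(tpd)]
  }, numeric(tpd)))
  if (tpd == 1L) signs <- matrix(as.vector(signs), nd, 1L)

  set.seed(config$seed + 1L)
  # latent activity: within-group fluctuation eps plus group shift (driver 1)
  eps <- matrix(stats::rnorm(nd * ns), nd, ns)
  activity <- eps
  activity[1, groups == "hi"] <- activity[1, groups == "hi"] +
    config$driver_effect

  m <- matrix(stats::rnorm(ng * ns, mean = baseline, sd = 1), ng, ns,
              dimnames = list(genes, samples))
  for (d in seq_len(nd)) {
    tgt <- target_idx[d, ]
    noise <- matrix(stats::rnorm(tpd * ns, sd = config$noise_sd), tpd, ns)
    m[tgt, ] <- baseline[tgt] + outer(signs[d, ], activity[d, ]) + noise
  }
  # driver mRNA: tracks within-group activity fluctuation; hidden driver 1
  # gets a small negative group shift, decoy drivers a small positive one.
  mshift <- c(-0.15, rep(0.15, nd - 1)) * config$driver_effect
  for (d in seq_len(nd)) {
    m[driver_idx[d], ] <- baseline[driver_idx[d]] + eps[d, ] +
      mshift[d] * (groups == "hi") +
      stats::rnorm(ns, sd = config$noise_sd)
  }

  regulons <- stats::setNames(lapply(seq_len(nd), function(d)
    data.frame(target = genes[target_idx[d, ]], sign = signs[d, ],
               stringsAsFactors = FALSE)), genes[driver_idx])

  truth <- structure(list(
    driver_regulons = regulons,
    driver_genes = genes[driver_idx],
    hidden_driver = genes[driver_idx[1]],
    activity = matrix(activity, nd, ns,
                      dimnames = list(genes[driver_idx], samples)),
    group_labels = stats::setNames(groups, samples)
  ), class = "sim_truth")

  list(expr = expr_mat(m, normalization = "log2cpm", species = "human"),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:\n")
  if (!is.null(x$signature_genes))
    cat(sprintf("  %d signature genes (driver: %s)\n",
                nrow(x$signature_genes), x$driver_gene))
  if (!is.null(x$driver_regulons))
    cat(sprintf("  %d planted regulons (hidden driver: %s)\n",
                length(x$driver_regulons), x$hidden_driver))
  cat(sprintf("  %d samples\n", length(x$group_labels)))
  invisible(x)
}
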