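# End-to-end pipeline driver: synthetic cohort -> per-species DE ->
# cross-species integration -> regulon network -> activity -> differential
# activity -> hidden drivers -> signed-regulon enrichment, with every stage
# output written to disk and a JSON summary.

#' Pipeline configuration
#'
#' Collects the thresholds, seeds and simulation settings for
#' [run_pipeline()]. Can also be read from a YAML document whose keys match
#' the argument names ([read_pipeline_config()]).
#'
#' @param cohort a `sim_config` for the cross-species stage (default
#'   [cohort_config()]).
#' @param regulon a `sim_config` for the regulon stage (default
#'   [regulon_config()]); `NULL` skips the network/activity/driver stages.
#' @param z_thresh anchor |Z| cutoff (default 1.96).
#' @param consensus_p,dpi_tolerance network-inference settings (see
#'   [infer_network()]).
#' @param n_bootstraps bootstrap resamples for network inference.
#' @param z_da,z_de hidden-driver filter thresholds (defaults 1.96 and 0).
#' @param n_perm GSEA permutations.
#' @param seed master seed; stages derive fixed offsets from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), regulon = regulon_config(),
                            z_thresh = 1.96, consensus_p = 0.01,
                            dpi_tolerance = 0, n_bootstraps = 100,
                            z_da = 1.96, z_de = 0, n_perm = 1000, seed = 1) {
  stopifnot(is.numeric(z_thresh), z_thresh >= 0,
            is.numeric(dpi_tolerance), dpi_tolerance >= 0,
            is.numeric(n_perm), n_perm >= 0)
  if (!is.null(consensus_p) &&
      (consensus_p <= 0 || consensus_p > 1))
    stop("consensus_p must lie in (0, 1]")
  cohort$seed <- seed
  if (!is.null(regulon)) regulon$seed <- seed + 1000L
  structure(list(cohort = cohort, regulon = regulon, z_thresh = z_thresh,
                 consensus_p = consensus_p, dpi_tolerance = dpi_tolerance,
                 n_bootstraps = n_bootstraps, z_da = z_da, z_de = z_de,
                 n_perm = n_perm, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file; top-level keys `cohort` and `regulon` hold
#'   simulation fields, the rest are passed straight through.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  reg <- if (isFALSE(y$regulon)) NULL
         else do.call(regulon_config, y$regulon %||% list())
  rest <- y[setdiff(names(y), c("cohort", "regulon"))]
  do.call(pipeline_config, c(list(cohort = cohort, regulon = reg), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort driver-discovery pipeline
#'
#' Stages: simulate the paired cross-species cohort; per-species moderated
#' DE; ortholog merge; anchor selection; Fisher overlap of the two species'
#' anchor sets over the merged universe; joint PCA response score and ROC
#' against the true labels; Stouffer combined ranking. If a regulon config
#' is present: simulate the regulon population, infer the MI network over
#' the true driver ids, compute weighted-mean activity, differential
#' activity and expression between the two groups, apply the hidden-driver
#' filter, and run signed-regulon GSEA of the planted regulon against the
#' group-difference ranking. Every stage writes its table under `out_dir`
#' and the run ends with a `summary.json`.
#'
#' If no gene passes the anchor filter the integration stage stops the run
#' with a warning and the summary records the empty signature.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if absent).
#' @return a `carsx_report` list (also serialized as `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("carsx_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 thresholds = list(z_thresh = config$z_thresh,
                                   consensus_p = config$consensus_p,
                                   dpi_tolerance = config$dpi_tolerance,
                                   z_da = config$z_da, z_de = config$z_de))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- cross-species arm ---------------------------------------------------
  sim <- stage("simulate", simulate_cross_species_cohort(config$cohort))
  write_expression(sim$human, file.path(out_dir, "expr_human.tsv"))
  write_expression(sim$mouse, file.path(out_dir, "expr_mouse.tsv"))
  write_annotation(sim$truth$group_labels,
                   file.path(out_dir, "annotation.tsv"))

  grp <- sim$truth$group_labels
  de_h <- stage("de_human",
                moderated_two_group(sim$human, grp[colnames(sim$human)],
                                    case = "responder",
                                    control = "nonresponder"))
  de_m <- stage("de_mouse",
                moderated_two_group(sim$mouse, grp[colnames(sim$mouse)],
                                    case = "responder",
                                    control = "nonresponder"))
  write_de(de_h, file.path(out_dir, "de_human.tsv"))
  write_de(de_m, file.path(out_dir, "de_mouse.tsv"))

  merged <- stage("integrate", merge_orthologs(de_h, de_m))
  sig <- stage("integrate", select_anchors(merged, config$z_thresh))
  report$n_merged_genes <- nrow(merged)
  report$anchor_counts <- list(human = nrow(sig$species_sets$human),
                               mouse = nrow(sig$species_sets$mouse),
                               shared = nrow(sig$shared),
                               anchors = length(sig$anchors))

  ranking <- stage("ranking", stouffer_rank(merged))
  utils::write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$top10_combined <- ranking$gene[seq_len(min(10, nrow(ranking)))]
  report$planted_driver <- sim$truth$driver_gene
  report$planted_driver_rank <-
    ranking$rank[match(sim$truth$driver_gene, ranking$gene)]

  if (length(sig$anchors) == 0) {
    warning("empty anchor set; stopping after integration")
    report$status <- "empty_anchor_set"
    write_json_report(report, file.path(out_dir, "summary.json"))
    return(structure(report, class = "carsx_report"))
  }

  utils::write.table(
    data.frame(gene = sig$anchors_h$gene, direction = sig$anchors_h$direction,
               z_h = sig$anchors_h$z_h, z_m = sig$anchors_h$z_m),
    file.path(out_dir, "anchors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_gmt(list(anchors_human = sig$anchors_h$gene,
                 anchors_mouse = sig$anchors_m$gene,
                 shared_signature = sig$shared$gene),
            file.path(out_dir, "signatures.gmt"))

  ov <- stage("overlap", overlap_test(sig$anchors_h$gene, sig$anchors_m$gene,
                                      sig$universe_size))
  report$overlap <- list(overlap = ov$overlap, p = ov$p)
  write_json_report(report$overlap, file.path(out_dir, "overlap.json"))

  scores <- stage("score", joint_pca_score(sim$human, sim$mouse, sig))
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  set.seed(config$seed + 10L)
  roc <- stage("roc", roc_auc(scores$score,
                              grp[scores$sample] == "responder"))
  report$roc <- list(auc = roc$auc, ci_low = roc$ci_low,
                     ci_high = roc$ci_high, accuracy = roc$accuracy)
  write_json_report(report$roc, file.path(out_dir, "roc.json"))

  ## -- regulon arm ---------------------------------------------------------
  if (!is.null(config$regulon)) {
    rsim <- stage("simulate_regulon",
                  simulate_regulon_population(config$regulon))
    write_expression(rsim$expr, file.path(out_dir, "expr_population.tsv"))

    set.seed(config$seed + 20L)
    net <- stage("network",
                 infer_network(rsim$expr, rsim$truth$driver_genes,
                               n_bootstraps = config$n_bootstraps,
                               consensus_p = config$consensus_p,
                               dpi_tolerance = config$dpi_tolerance))
    write_network(net, file.path(out_dir, "network.tsv"))
    regulons_to_gmt(net, file.path(out_dir, "regulons.gmt"))
    report$network <- list(n_nodes = net$n_nodes, n_edges = net$n_edges)

    act <- stage("activity", compute_activity(rsim$expr, net))
    rgrp <- rsim$truth$group_labels
    da <- stage("da", differential_activity(act, rgrp[colnames(act)],
                                            case = "hi", control = "lo"))
    de_pop <- stage("de_population",
                    moderated_two_group(rsim$expr, rgrp[colnames(rsim$expr)],
                                        case = "hi", control = "lo"))
    write_de(da, file.path(out_dir, "da_drivers.tsv"))
    hd <- stage("drivers", hidden_drivers(da, de_pop,
                                          z_da_thresh = config$z_da,
                                          z_de_max = config$z_de))
    utils::write.table(hd, file.path(out_dir, "hidden_drivers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$top10_hidden_drivers <-
      hd$driver[seq_len(min(10, nrow(hd)))]
    report$hidden_driver_recovered <-
      identical(hd$driver[1], rsim$truth$hidden_driver)

    # signed enrichment of the planted regulon in the group-difference
    # ranking of the population
    ranked <- stats::setNames(de_pop$z, de_pop$gene)
    set.seed(config$seed + 30L)
    sg <- stage("gsea",
                signed_regulon_gsea(
                  ranked,
                  rsim$truth$driver_regulons[[rsim$truth$hidden_driver]],
                  n_perm = config$n_perm))
    report$regulon_gsea <- list(
      es_pos = if (is.null(sg$positive)) NA else sg$positive$es,
      p_pos = if (is.null(sg$positive)) NA else sg$positive$p_perm,
      es_neg = if (is.null(sg$negative)) NA else sg$negative$es,
      p_neg = if (is.null(sg$negative)) NA else sg$negative$p_perm)
  }

  report$status <- "ok"
  write_json_report(report, file.path(out_dir, "summary.json"))
  structure(report, out_dir = out_dir, class = "carsx_report")
}

#' @export
print.carsx_report <- function(x, ...) {
  cat("carsx pipeline report (seed", x$seed, ")\n")
  cat("  status:", x$status, "\n")
  if (!is.null(x$planted_driver_rank))
    cat(sprintf("  planted driver %s: combined rank %d of %d\n",
                x$planted_driver, x$planted_driver_rank, x$n_merged_genes))
  if (!is.null(x$overlap))
    cat(sprintf("  anchor overlap: %d genes, Fisher p = %.3g\n",
                x$overlap$overlap, x$overlap$p))
  if (!is.null(x$roc))
    cat(sprintf("  response score AUC = %.3f (%.3f-%.3f)\n",
                x$roc$auc, x$roc$ci_low, x$roc$ci_high))
  if (!is.null(x$hidden_driver_recovered))
    cat("  hidden driver recovered as top driver:",
        x$hidden_driver_recovered, "\n")
  invisible(x)
}
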