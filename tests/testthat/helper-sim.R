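# Shared helpers: small matrices and configs built in code.

toy_expr <- function(values, genes = NULL, samples = NULL,
                     normalization = "log2cpm") {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_mat(values, normalization = normalization)
}

# tiny two-group matrix with known per-gene rows
two_group_expr <- function(rows) {
  m <- do.call(rbind, rows)
  toy_expr(m, genes = names(rows))
}

small_cohort <- function(seed = 1, n_genes = 300, ...) {
  cohort_config(n_genes = n_genes, n_signature = 12,
                n_samples_per_group_per_species = 10, seed = seed, ...)
}

mk_de <- function(genes, z, fc) {
  structure(data.frame(gene = genes, log2FC = fc, t = z, p = 0.5, z = z,
                       ave_expr = 1, constant = FALSE,
                       stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

small_regulon <- function(seed = 1, n_samples_per_group_per_species = 100,
                          ...) {
  regulon_config(n_genes = 80, n_drivers = 2, targets_per_driver = 8,
                 n_samples_per_group_per_species =
                   n_samples_per_group_per_species, seed = seed, ...)
}
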