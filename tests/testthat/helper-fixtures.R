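# Shared fixture builders. All fixtures are generated in code.

# Small expression matrix with explicit values (genes x samples), labelled
# mut/wt in two halves unless labels given.
toy_expression <- function(values, labels = NULL, genes = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (is.null(genes)) genes <- sprintf("GENE%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  if (is.null(labels))
    labels <- rep(c("KRAS_mut", "KRAS_wt"), length.out = ncol(values))
  expression_matrix(values, stats::setNames(labels, samples))
}

# Random two-group matrix with optional planted effect in the mut half.
random_expression <- function(n_genes, n_per_group, seed, effect_rows = integer(),
                              effect = 0, noise_sd = 0.5, baseline = 7,
                              heteroscedastic = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_group
  sds <- if (heteroscedastic) sqrt(noise_sd^2 * 4 / rchisq(n_genes, 4))
         else rep(noise_sd, n_genes)
  vals <- matrix(rnorm(n_genes * n), n_genes, n) * sds + baseline
  if (length(effect_rows))
    vals[effect_rows, seq_len(n_per_group)] <-
      vals[effect_rows, seq_len(n_per_group)] + effect
  toy_expression(vals,
                 labels = rep(c("KRAS_mut", "KRAS_wt"), each = n_per_group),
                 genes = sprintf("G%05d", seq_len(n_genes)))
}

# A DEResult-shaped data frame for testing selection rules directly.
fake_de <- function(genes, log2fc, b_stat) {
  structure(data.frame(gene = genes, log2fc = log2fc,
                       t_mod = NA_real_, df_total = NA_real_,
                       p_value = NA_real_, b_stat = b_stat),
            class = c("DEResult", "data.frame"))
}

# Brute-force weighted KS enrichment score: O(N * |S|) literal evaluation
# of P_hit and P_miss at every rank. Independent oracle for
# enrichment_score().
brute_force_es <- function(genes, metric, gene_set, weight_p = 1) {
  o <- order(-metric, genes)
  genes <- genes[o]; metric <- metric[o]
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  nr <- sum(abs(metric[hit])^weight_p)
  dev <- numeric(n)
  for (i in seq_len(n)) {
    idx <- seq_len(i)
    p_hit <- sum(abs(metric[idx][hit[idx]])^weight_p) / nr
    p_miss <- sum(!hit[idx]) / (n - nh)
    dev[i] <- p_hit - p_miss
  }
  if (max(dev) >= -min(dev)) max(dev) else min(dev)
}
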