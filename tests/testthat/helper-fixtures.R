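# Small builders shared across test files.

# Gene x sample matrix with named dims.
named_matrix <- function(vals, genes, samples) {
  matrix(vals, length(genes), length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# A tiny normalized expr_matrix built directly from values (rows assumed
# already standardized by the caller, or scale overridden).
make_em <- function(vals, scale = "log2_absolute", groups = NULL) {
  expr_matrix(vals, scale = scale, groups = groups)
}

# Minimal two-module planted scenario, small enough for fast tests.
small_scenario <- function(seed = 1, noise_sd = 0.3, latent_sd = 1,
                           n_genes = 300, module_size = 30,
                           beta_a = 1, beta_b = -1,
                           loading = c(KDM5A = 1, EZH2 = -1),
                           groups = c(hi = 10, mid = 10, lo = 10),
                           means = c(hi = 2, mid = 0, lo = -2)) {
  synthetic_scenario(
    n_genes = n_genes, groups = groups, group_latent_mean = means,
    latent_sd = latent_sd,
    modules = list(modA = list(size = module_size, beta = beta_a),
                   modB = list(size = module_size, beta = beta_b)),
    enzymes = loading, noise_sd = noise_sd, probe_noise_sd = 0.1,
    seed = seed)
}

# A hand-built qPCR plate: one reference gene at fixed Ct, target genes with
# prescribed delta-Ct per sample.
manual_plate <- function(dct, ref_ct = 18, reference = "B2M") {
  samples <- colnames(dct)
  genes <- rownames(dct)
  rows <- expand.grid(sample_id = samples, gene = c(reference, genes),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$ct <- ifelse(rows$gene == reference, ref_ct,
                    ref_ct + dct[cbind(match(rows$gene, genes),
                                       match(rows$sample_id, samples))])
  data.frame(plate_id = "p1", sample_id = rows$sample_id, gene = rows$gene,
             ct = rows$ct, melt_ok = TRUE)
}
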