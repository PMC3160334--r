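#!/usr/bin/env Rscript
# Step 4: unsupervised hierarchical clustering of samples (Manhattan
# distance, average linkage) on the module genes, scored against the
# planted activity groups.

suppressPackageStartupMessages(library(modscore))
out <- "results/04_clustering"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

norm <- read_matrix("results/02_enrichment/expression_gene_normalized.tsv",
                    scale = "gene_normalized")
modules <- read_gmt("results/01_simulated_data/modules.gmt")
truth <- read.delim("results/01_simulated_data/truth.tsv")
groups <- with(subset(truth, kind == "sample"), setNames(value, id))

cl <- cluster_samples(norm,
                      gene_subset = unlist(lapply(modules, `[[`, "genes"),
                                           use.names = FALSE),
                      linkage_method = "average", k = 3)
write_clustering(cl, file.path(out, "sample_tree.nwk"),
                 file.path(out, "sample_clusters.tsv"))

print(cl)
tab <- table(cluster = cl$flat_labels, group = groups[names(cl$flat_labels)])
print(tab)
ari <- mclust::adjustedRandIndex(cl$flat_labels, groups[names(cl$flat_labels)])
cat(sprintf("Adjusted Rand Index vs planted groups: %.3f\n", ari))
cat("The three activity groups differ only in mean latent activity (-2/0/+2)\n")
cat("with within-group spread 1, so the distributions overlap: clustering\n")
cat("separates the extremes but blends boundary samples of the middle group.\n")
cat("With well-separated groups (means -3/0/+3, spread 0.5) recovery is\n")
cat("essentially perfect — that setting is exercised by the test suite and\n")
cat("scripts/acceptance.R.\n")
cat("Wrote", out, "\n")
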