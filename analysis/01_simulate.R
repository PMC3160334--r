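#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# One expression dataset with a planted "enzyme activity" axis — a
# demethylase-like enzyme (KDM5A, loading +1) whose target module follows it
# (beta +1) and a repressive methyltransferase-like module (EZH2 targets,
# beta -1) — across 60 samples in three activity groups, plus a qPCR plate
# with known fold changes, some dropout wells and some irregular melt peaks.
# Everything downstream (steps 02-05) runs from the files written here.

suppressPackageStartupMessages(library(modscore))
out <- "results/01_simulated_data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- synthetic_scenario(n_probes_per_gene = c(1L, 3L), seed = 20260919L)
sim <- simulate_expression(scenario)
write_matrix(sim$probes, file.path(out, "probe_matrix.tsv"))
write_gmt(truth_modules(sim$truth), file.path(out, "modules.gmt"))
write_truth(sim$truth, file.path(out, "truth.tsv"))

set.seed(20260920L)
panel <- c("KDM5A", "KDM5B", "BRD8", "EZH2", "MLL1", "SMYD3")
folds <- matrix(2^rnorm(length(panel) * 12, sd = 1.2), length(panel), 12,
                dimnames = list(panel, NULL))
plate <- simulate_qpcr_plate(12, c("B2M", panel),
                             fold_changes = folds, dropout_rate = 0.05,
                             melt_fail_rate = 0.05, noise_sd = 0,
                             seed = 20260921L)
write_qpcr_plate(plate, file.path(out, "qpcr_plate.tsv"))
write.table(data.frame(gene = rep(rownames(attr(plate, "truth")),
                                  ncol(attr(plate, "truth"))),
                       sample_id = rep(colnames(attr(plate, "truth")),
                                       each = nrow(attr(plate, "truth"))),
                       true_fold = as.vector(attr(plate, "truth"))),
            file.path(out, "qpcr_truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf(
  "Simulated %d probes (%d genes) x %d samples in groups: %s\n",
  nrow(sim$probes$values), scenario$n_genes, ncol(sim$probes$values),
  paste(sprintf("%s (n=%d)", names(scenario$groups), scenario$groups),
        collapse = ", ")))
cat(sprintf("Planted modules: %s\n",
            paste(sprintf("%s (size %d, beta %+g)", names(scenario$modules),
                          vapply(scenario$modules, `[[`, 0, "size"),
                          vapply(scenario$modules, `[[`, 0, "beta")),
                  collapse = "; ")))
cat(sprintf("qPCR plate: %d wells, %d no-product, %d melt-failed\n",
            nrow(plate), sum(is.na(plate$ct)), sum(!plate$melt_ok)))
cat("Wrote", out, "\n")
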