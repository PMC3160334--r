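#' Run the expression-module-signature workflow
#'
#' Composes the full analysis chain on one expression dataset: read (or
#' accept) the probe matrix, filter and collapse probes, gene-normalize,
#' score every module in every sample against the random-module null,
#' correlate enzyme expression with module z-profiles, compute pairwise
#' gene correlations within each sample group, and cluster samples on a
#' gene subset under the Manhattan distance. All artifacts are written as
#' TSV/Newick under `out_dir` together with a JSON run manifest (seeds,
#' options, per-stage dimensions), so a run is fully reproducible from the
#' manifest alone.
#'
#' @param matrix_input a [probe_matrix()], [expr_matrix()], or path to a
#'   matrix TSV.
#' @param modules list of [gene_module()] objects, or path to a GMT file.
#' @param enzymes character vector of enzyme gene ids to correlate against
#'   the module profiles.
#' @param cluster_genes genes to cluster samples on (default: the enzymes).
#' @param k flat clusters to extract (default 3).
#' @param linkage linkage method for clustering (default `"average"`).
#' @param n_draws Monte-Carlo draws per module x sample (default 10000).
#' @param seed integer seed for the enrichment null.
#' @param min_interprobe_pcc probe-filter threshold (default 0.5).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the normalized matrix, the enrichment
#'   profile, the correlation matrices, the clustering result and the
#'   manifest.
#' @export
run_signature_workflow <- function(matrix_input, modules, enzymes,
                                   cluster_genes = NULL, k = 3L,
                                   linkage = "average", n_draws = 10000,
                                   seed = 1L, min_interprobe_pcc = 0.5,
                                   out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(matrix_input)) matrix_input <- read_matrix(matrix_input)
  if (is.character(modules)) modules <- read_gmt(modules)
  if (inherits(matrix_input, "probe_matrix")) {
    pm <- filter_probes(matrix_input, min_interprobe_pcc = min_interprobe_pcc)
    em <- collapse_probes(pm)
  } else {
    em <- matrix_input
  }
  norm <- gene_normalize(em)
  write_matrix(norm, file.path(out_dir, "expression_gene_normalized.tsv"))

  profile <- enrichment_matrix(norm, modules, n_draws = n_draws, seed = seed)
  write_enrichment(profile, file.path(out_dir, "module_zscores.tsv"),
                   file.path(out_dir, "module_calls.tsv"))

  cm <- module_enzyme_correlation(profile, norm, enzymes)
  write_cor_matrix(cm, file.path(out_dir, "module_enzyme_pcc.tsv"),
                   file.path(out_dir, "module_enzyme_pcc_n.tsv"))
  cm_med <- module_enzyme_correlation(profile, norm, enzymes,
                                      use_median_expression = TRUE,
                                      modules = modules)
  write_cor_matrix(cm_med, file.path(out_dir, "module_enzyme_pcc_median_expr.tsv"))

  gene_cors <- list()
  if (!is.null(norm$groups)) {
    for (g in unique(norm$groups)) {
      ids <- names(norm$groups)[norm$groups == g]
      if (length(ids) < 3L) next
      gc <- pairwise_gene_correlation(norm, enzymes, ids)
      gc$subset_label <- g
      write_cor_matrix(gc, file.path(out_dir, paste0("gene_pcc_", g, ".tsv")))
      gene_cors[[g]] <- gc
    }
  }

  cluster_genes <- cluster_genes %||% enzymes
  cl <- cluster_samples(norm, gene_subset = cluster_genes,
                        linkage_method = linkage, k = k)
  write_clustering(cl, file.path(out_dir, "sample_tree.nwk"),
                   file.path(out_dir, "sample_clusters.tsv"))

  manifest <- list(
    workflow = "signature",
    seed = seed, n_draws = n_draws, k = k, linkage = linkage,
    min_interprobe_pcc = min_interprobe_pcc,
    n_genes = nrow(norm$values), n_samples = ncol(norm$values),
    modules = setNames(lapply(modules, function(m) length(m$genes)),
                       vapply(modules, `[[`, "", "name")),
    effective_module_sizes = as.list(profile$effective_size),
    enzymes = enzymes, cluster_genes = cluster_genes,
    package_version = as.character(utils::packageVersion("modscore")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(normalized = norm, profile = profile,
                 module_enzyme = cm, module_enzyme_median = cm_med,
                 gene_correlations = gene_cors, clustering = cl,
                 manifest = manifest))
}

#' Run the qPCR panel workflow
#'
#' Composes the qPCR chain: well-level QC (melt-peak removal, cap
#' assignment), relative quantification against the reference gene, and the
#' clipped heatmap scale. Writes the per-well QC audit, the quantification
#' table and the clipped folds under `out_dir` with a JSON manifest.
#'
#' @param plate a `qpcr_plate` or path to a plate TSV.
#' @param reference_gene reference gene name (e.g. `"B2M"`).
#' @param ct_cap,assigned_value QC parameters (defaults 35, 40).
#' @param exclude_assigned see [relative_quantification()].
#' @param out_dir output directory.
#' @return Invisibly, list with the QC'd wells, the `qpcr_result`, and the
#'   manifest. If no wells survive QC the result is empty and the manifest
#'   records `no_data_after_qc = TRUE`.
#' @export
run_qpcr_workflow <- function(plate, reference_gene, ct_cap = 35,
                              assigned_value = 40, exclude_assigned = FALSE,
                              out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(plate)) plate <- read_qpcr_plate(plate)
  qc <- apply_well_qc(plate, ct_cap = ct_cap, assigned_value = assigned_value)
  write.table(qc, file.path(out_dir, "well_qc_audit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res <- relative_quantification(qc, reference_gene,
                                 exclude_assigned = exclude_assigned)
  write.table(res, file.path(out_dir, "qpcr_quantification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  clipped <- res
  if (nrow(res)) clipped$fold_change <- heatmap_scale(res$fold_change)
  write.table(clipped[, intersect(c("sample_id", "gene", "fold_change"),
                                  names(clipped))],
              file.path(out_dir, "fold_change_heatmap_scale.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(workflow = "qpcr", reference_gene = reference_gene,
                   ct_cap = ct_cap, assigned_value = assigned_value,
                   exclude_assigned = exclude_assigned,
                   n_wells = nrow(plate),
                   n_removed_melt = sum(qc$qc_status == "removed_melt"),
                   n_assigned = sum(qc$qc_status == "assigned_40"),
                   no_data_after_qc = nrow(res) == 0L,
                   package_version = as.character(utils::packageVersion("modscore")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(wells = qc, result = res, manifest = manifest))
}
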