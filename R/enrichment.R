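#' Per-sample module enrichment z-score against a random-module null
#'
#' Compares the median expression of a module's genes in one sample with the
#' distribution of medians of random gene sets of the same size drawn
#' without replacement from that sample's values:
#' `z = (observed_median - null_mean) / null_sd`, where the null moments use
#' the population s.d. of the sampled medians. Values are expected to come
#' from a gene-normalized matrix so medians are comparable between genes.
#' Positive z indicates preferential expression of the module in the sample,
#' negative z underexpression; `|z| > 1.96` is the significance threshold.
#'
#' Module genes absent from `sample_values` are dropped with a warning and
#' the effective size recorded. When the null is degenerate (`null_sd == 0`,
#' e.g. the module is the whole universe or the sample is constant) the
#' z-score is 0 if the observed median equals the null mean and undefined
#' (`NA`, call "ns") otherwise.
#'
#' @param sample_values named numeric vector: one sample's (gene-normalized)
#'   expression, names are gene symbols.
#' @param module a [gene_module()] (or character vector of genes).
#' @param n_draws number of Monte-Carlo null draws (default 10000).
#' @param seed integer RNG seed; the same seed reproduces the z exactly.
#' @param exact if `TRUE`, use the exhaustive null ([exact_null()]) instead
#'   of Monte Carlo (only feasible for small universes).
#' @return A list with `z`, `observed_median`, `null_mean`, `null_sd`,
#'   `effective_size`, `call` (`"over"`, `"under"` or `"ns"`) and
#'   `exact_flag`.
#' @export
module_zscore <- function(sample_values, module, n_draws = 10000, seed = 1,
                          exact = FALSE) {
  genes <- if (inherits(module, "gene_module")) module$genes else as.character(module)
  stopifnot(!is.null(names(sample_values)))
  vals <- sample_values[!is.na(sample_values)]
  present <- intersect(genes, names(vals))
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " module genes absent from the sample; effective size ",
            length(present))
  m <- length(present)
  if (m == 0L) stop("effective module size 0: no module genes in the sample")
  obs <- median(vals[present])
  if (exact) {
    nm <- exact_null(vals, m)
    null_mean <- nm$null_mean; null_sd <- nm$null_sd
  } else {
    meds <- withr::with_seed(seed, .null_medians_mc(unname(vals), m, n_draws))
    null_mean <- mean(meds); null_sd <- pop_sd(meds)
  }
  z <- if (null_sd > 0) (obs - null_mean) / null_sd
       else if (isTRUE(all.equal(obs, null_mean))) 0 else NA_real_
  call <- if (is.na(z)) "ns" else if (z > 1.96) "over" else if (z < -1.96) "under" else "ns"
  list(z = z, observed_median = obs, null_mean = null_mean, null_sd = null_sd,
       effective_size = m, call = call, exact_flag = exact,
       degenerate = null_sd == 0)
}

#' Exhaustive random-module null
#'
#' Enumerates every gene set of the requested size in the sample and returns
#' the mean and population s.d. of the set medians. Serves as the exact
#' reference for the Monte-Carlo null; refuses when the number of
#' combinations exceeds `cap` (callers then fall back to Monte Carlo).
#'
#' @param sample_values named or unnamed numeric vector of one sample's
#'   values (missing entries dropped).
#' @param module_size gene-set size to enumerate.
#' @param cap maximum number of combinations to enumerate (default 200000).
#' @return list with `null_mean`, `null_sd` and `n_sets`.
#' @export
exact_null <- function(sample_values, module_size, cap = 200000) {
  vals <- unname(sample_values[!is.na(sample_values)])
  n <- length(vals)
  stopifnot(module_size >= 1L, module_size <= n)
  n_sets <- choose(n, module_size)
  if (n_sets > cap)
    stop("exact_null: C(", n, ", ", module_size, ") = ", n_sets,
         " exceeds cap ", cap)
  meds <- combn(vals, module_size, median)
  list(null_mean = mean(meds), null_sd = pop_sd(meds), n_sets = n_sets)
}

#' Module x sample enrichment matrix
#'
#' Applies [module_zscore()] to every (module, sample) pair of a
#' gene-normalized expression matrix. Per-pair RNG seeds are derived from
#' `seed` and the module/sample indices, so results do not depend on
#' iteration order. Calls use the `|z| > 1.96` thresholds; an optional
#' Benjamini-Hochberg adjustment across samples (per module, on the normal
#' two-sided p-values) is available behind `bh_adjust` but is off by
#' default.
#'
#' @param em a gene-normalized [expr_matrix()].
#' @param modules list of [gene_module()] objects.
#' @param n_draws Monte-Carlo draws per pair (default 10000).
#' @param seed base integer seed.
#' @param bh_adjust apply BH correction across samples before calling
#'   over/under (default FALSE, matching the raw-threshold convention).
#' @param alpha significance level used with `bh_adjust` (default 0.05).
#' @return An `enrichment_profile`: list of module x sample matrices `z`,
#'   `observed_median`, `null_mean`, `null_sd`, a character `call` matrix,
#'   `effective_size`, plus `n_draws` and `seed`.
#' @export
enrichment_matrix <- function(em, modules, n_draws = 10000, seed = 1,
                              bh_adjust = FALSE, alpha = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "gene_normalized")
    stop("enrichment_matrix expects a gene-normalized matrix")
  if (inherits(modules, "gene_module")) modules <- list(modules)
  mod_names <- unname(vapply(modules, function(m) m$name, character(1)))
  samples <- colnames(em$values)
  dims <- list(mod_names, samples)
  z <- obs <- nmu <- nsd <- matrix(NA_real_, length(modules), length(samples),
                                   dimnames = dims)
  call <- matrix("ns", length(modules), length(samples), dimnames = dims)
  eff <- setNames(integer(length(modules)), mod_names)
  for (i in seq_along(modules)) {
    genes <- modules[[i]]$genes
    absent <- setdiff(genes, rownames(em$values))
    if (length(absent))
      msg("module '%s': %d of %d genes absent from matrix", mod_names[i],
          length(absent), length(genes))
    for (j in seq_along(samples)) {
      sv <- setNames(em$values[, j], rownames(em$values))
      res <- suppressWarnings(
        module_zscore(sv, modules[[i]], n_draws = n_draws,
                      seed = derive_seed(seed, mod_names[i], samples[j])))
      z[i, j] <- res$z; obs[i, j] <- res$observed_median
      nmu[i, j] <- res$null_mean; nsd[i, j] <- res$null_sd
      call[i, j] <- res$call
      eff[i] <- res$effective_size
    }
  }
  if (bh_adjust) {
    for (i in seq_along(modules)) {
      p <- 2 * stats::pnorm(-abs(z[i, ]))
      padj <- stats::p.adjust(p, method = "BH")
      sig <- !is.na(padj) & padj < alpha
      call[i, ] <- ifelse(sig & z[i, ] > 0, "over",
                          ifelse(sig & z[i, ] < 0, "under", "ns"))
    }
  }
  structure(list(z = z, observed_median = obs, null_mean = nmu, null_sd = nsd,
                 call = call, effective_size = eff, n_draws = n_draws,
                 seed = seed, groups = em$groups),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("enrichment_profile: %d modules x %d samples (%d draws, seed %d)\n",
              nrow(x$z), ncol(x$z), x$n_draws, x$seed))
  tab <- table(factor(x$call, c("over", "under", "ns")))
  cat(sprintf("  calls: %d over, %d under, %d ns\n", tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Export an enrichment profile as TSV
#'
#' Writes the z matrix and the over/under/ns call matrix as module x sample
#' TSV files consumed by the correlation stage and external heatmap tools.
#'
#' @param profile an `enrichment_profile`.
#' @param z_path,calls_path output paths.
#' @export
write_enrichment <- function(profile, z_path, calls_path = NULL) {
  write_named_matrix(profile$z, z_path)
  if (!is.null(calls_path)) write_named_matrix(profile$call, calls_path)
  invisible(z_path)
}

write_named_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
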