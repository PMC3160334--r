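#' Define a synthetic expression scenario with planted module structure
#'
#' The generator emulates the structure the module-signature pipeline is
#' designed to detect: a latent per-sample "enzyme activity" factor `a_s`
#' drives coordinated over/under-expression of whole gene modules, with the
#' enzyme genes themselves loading on the same factor. Gene `g` in module
#' `m` gets log2 value `baseline_g + beta_m * a_s + noise`; enzyme gene `e`
#' gets `baseline_e + loading_e * a_s + noise`; all other genes are
#' baseline + noise. Samples fall into groups (emulating tissues or cancer
#' types) that differ in the latent-factor mean. Each gene may be expanded
#' into several probes by adding independent probe-level Gaussian noise.
#'
#' Defaults plant the axis the method targets: a demethylase-like enzyme
#' (loading +1) whose target module follows it (beta +1) and a repressive
#' methyltransferase-like module moving oppositely (beta -1), across 60
#' samples in three groups of latent mean -2 / 0 / +2, with residual noise
#' s.d. 0.5 and probe noise s.d. 0.1 on the log2 scale.
#'
#' @param n_genes size of the gene universe (module and enzyme genes
#'   included).
#' @param groups named integer vector of group sizes.
#' @param group_latent_mean named numeric vector (same names as `groups`):
#'   latent-factor mean per group.
#' @param latent_sd per-sample s.d. of the latent factor around its group
#'   mean.
#' @param modules named list: each element `list(size =, beta =)` gives a
#'   module's size and its signed effect (log2 units per unit latent
#'   activity).
#' @param enzymes named numeric vector: enzyme gene name -> signed loading
#'   on the latent factor.
#' @param n_probes_per_gene single count, or length-2 range from which each
#'   gene's probe count is drawn uniformly.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param noise_sd residual log2 s.d. per gene x sample.
#' @param probe_noise_sd probe-level log2 s.d. around the gene value.
#' @param seed integer seed; the same scenario and seed reproduce
#'   bit-identical output.
#' @return A `synthetic_scenario` list, validated.
#' @export
synthetic_scenario <- function(n_genes = 2000,
                               groups = c(act_high = 20, act_mid = 20, act_low = 20),
                               group_latent_mean = c(act_high = 2, act_mid = 0, act_low = -2),
                               latent_sd = 1,
                               modules = list(
                                 KDM5A_targets = list(size = 100, beta = 1),
                                 EZH2_targets = list(size = 100, beta = -1)),
                               enzymes = c(KDM5A = 1, EZH2 = -1),
                               n_probes_per_gene = 1L,
                               baseline_mean = 7, baseline_sd = 1.5,
                               noise_sd = 0.5, probe_noise_sd = 0.1,
                               seed = 1L) {
  stopifnot(n_genes >= 1, all(groups >= 1), latent_sd >= 0, noise_sd >= 0,
            probe_noise_sd >= 0, baseline_sd >= 0)
  if (!setequal(names(groups), names(group_latent_mean)))
    stop("groups and group_latent_mean must share names")
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  if (any(sizes < 1)) stop("module sizes must be positive")
  if (sum(sizes) + length(enzymes) > n_genes)
    stop("module sizes plus enzyme genes (", sum(sizes) + length(enzymes),
         ") exceed the gene universe (", n_genes, ")")
  if (length(n_probes_per_gene) == 2L) {
    stopifnot(n_probes_per_gene[1] >= 1, diff(n_probes_per_gene) >= 0)
  } else stopifnot(length(n_probes_per_gene) == 1L, n_probes_per_gene >= 1)
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 group_latent_mean = group_latent_mean, latent_sd = latent_sd,
                 modules = modules, enzymes = enzymes,
                 n_probes_per_gene = as.integer(n_probes_per_gene),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, probe_noise_sd = probe_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate a probe-level expression matrix with known truth
#'
#' Draws the scenario of [synthetic_scenario()]: module membership, per-gene
#' baselines, per-sample latent activities, residual and probe-level noise.
#' The RNG stream is partitioned by purpose (membership, baseline, latent,
#' noise, probe noise), so changing e.g. the noise level does not perturb
#' the planted membership or latent factors.
#'
#' @param scenario a `synthetic_scenario`.
#' @return A list with `probes` (a [probe_matrix()] on the log2 scale, with
#'   group annotations) and `truth`: `latent_activity` (named per-sample),
#'   `module_membership` (gene -> module), `expected_direction` (module ->
#'   sign of beta), `group_assignment` (sample -> group), `baseline`
#'   (per-gene), and the noise-free gene x sample `signal` matrix.
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  enzyme_names <- names(sc$enzymes) %||% character()
  n_other <- sc$n_genes - length(enzyme_names)
  gene_ids <- c(enzyme_names, sprintf("G%05d", seq_len(n_other)))
  samples <- sprintf("S%03d", seq_len(sum(sc$groups)))
  group_of <- setNames(rep(names(sc$groups), sc$groups), samples)

  # stream 0: module membership (enzyme genes excluded from modules)
  membership <- withr::with_seed(derive_seed(sc$seed, 0L), {
    pool <- setdiff(gene_ids, enzyme_names)
    mm <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
    for (mn in names(sc$modules)) {
      picked <- sample(pool, sc$modules[[mn]]$size)
      mm[picked] <- mn
      pool <- setdiff(pool, picked)
    }
    mm
  })
  # stream 1: baselines; stream 2: latent activities
  baseline <- withr::with_seed(derive_seed(sc$seed, 1L),
    setNames(rnorm(length(gene_ids), sc$baseline_mean, sc$baseline_sd), gene_ids))
  latent <- withr::with_seed(derive_seed(sc$seed, 2L),
    setNames(sc$group_latent_mean[group_of] +
               rnorm(length(samples), 0, sc$latent_sd), samples))

  effect <- setNames(numeric(length(gene_ids)), gene_ids)
  for (mn in names(sc$modules))
    effect[!is.na(membership) & membership == mn] <- sc$modules[[mn]]$beta
  effect[enzyme_names] <- sc$enzymes

  signal <- baseline + outer(effect, latent)
  dimnames(signal) <- list(gene_ids, samples)
  noise <- withr::with_seed(derive_seed(sc$seed, 3L),
    matrix(rnorm(length(signal), 0, sc$noise_sd), nrow(signal), ncol(signal)))
  gene_vals <- signal + noise

  # probe expansion (stream 4)
  probes_per_gene <- withr::with_seed(derive_seed(sc$seed, 4L), {
    if (length(sc$n_probes_per_gene) == 2L)
      sample(seq(sc$n_probes_per_gene[1], sc$n_probes_per_gene[2]),
             length(gene_ids), replace = TRUE)
    else rep(sc$n_probes_per_gene, length(gene_ids))
  })
  probe_gene <- rep(gene_ids, probes_per_gene)
  probe_ids <- paste0(probe_gene, "_p",
                      unlist(lapply(probes_per_gene, seq_len), use.names = FALSE))
  pvals <- gene_vals[probe_gene, , drop = FALSE]
  pnoise <- withr::with_seed(derive_seed(sc$seed, 5L),
    matrix(rnorm(length(pvals), 0, sc$probe_noise_sd), nrow(pvals), ncol(pvals)))
  pvals <- pvals + pnoise
  rownames(pvals) <- probe_ids

  truth <- list(latent_activity = latent,
                module_membership = membership[!is.na(membership)],
                expected_direction = vapply(sc$modules, function(m)
                  sign(m$beta), numeric(1)),
                group_assignment = group_of,
                baseline = baseline, signal = signal)
  list(probes = probe_matrix(pvals, setNames(probe_gene, probe_ids),
                             scale = "log2", groups = group_of),
       truth = truth)
}

#' Gene modules of a synthetic scenario
#'
#' Convenience accessor: turns the planted membership of
#' [simulate_expression()] truth into [gene_module()] objects.
#'
#' @param truth the `truth` element returned by [simulate_expression()].
#' @return named list of [gene_module()] objects.
#' @export
truth_modules <- function(truth) {
  mm <- truth$module_membership
  mods <- lapply(unique(mm), function(mn)
    gene_module(mn, names(mm)[mm == mn], note = "synthetic planted module"))
  setNames(mods, unique(mm))
}

#' Write the planted truth as a sidecar TSV
#'
#' One row per sample (group, latent activity) plus one row per module gene
#' (module, expected direction), in a single long-format table.
#'
#' @param truth the `truth` element of [simulate_expression()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  rows <- rbind(
    data.frame(kind = "sample", id = names(truth$latent_activity),
               value = unname(truth$group_assignment),
               numeric = unname(truth$latent_activity)),
    data.frame(kind = "module_gene", id = names(truth$module_membership),
               value = unname(truth$module_membership),
               numeric = unname(truth$expected_direction[truth$module_membership])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a qPCR plate with planted fold changes
#'
#' Constructs Ct values so that the 2^-ddCt pipeline recovers the planted
#' fold changes in the noise-free case: for gene `g` and sample `s`,
#' `Ct(s, g) = base_g + shift_s - log2(fold(g, s))`, where `shift_s` is a
#' per-sample loading shift common to all wells of the sample (it cancels in
#' dCt) and the reference gene carries fold 1 everywhere. Because ddCt is
#' centred on each gene's mean dCt across samples, only folds with per-gene
#' geometric mean 1 are identifiable; requested folds are renormalized
#' accordingly and the renormalized matrix is recorded as the truth.
#' Dropout wells are emitted with the no-product flag, and a configurable
#' fraction of wells gets an irregular melt peak.
#'
#' @param n_samples number of samples.
#' @param genes character vector of assayed genes (reference included).
#' @param fold_changes genes-less-reference x samples numeric matrix of
#'   planted fold changes (default: all 1), or a named list of per-gene
#'   vectors.
#' @param reference_gene the stable reference (default `"B2M"`).
#' @param dropout_rate fraction of wells that produce no product.
#' @param melt_fail_rate fraction of wells with irregular melt peaks.
#' @param noise_sd Gaussian Ct noise s.d. (default 0, the exactly
#'   recoverable case).
#' @param sample_shift_sd s.d. of the per-sample global Ct shift
#'   (default 0.5; cancels in dCt).
#' @param seed integer seed.
#' @return A `qpcr_plate` data frame with attribute `truth` (the
#'   geometric-mean-1 fold matrix actually planted).
#' @export
simulate_qpcr_plate <- function(n_samples, genes, fold_changes = NULL,
                                reference_gene = "B2M", dropout_rate = 0,
                                melt_fail_rate = 0, noise_sd = 0,
                                sample_shift_sd = 0.5, seed = 1L) {
  if (!(reference_gene %in% genes))
    stop("reference gene '", reference_gene, "' not in the assayed genes")
  stopifnot(dropout_rate >= 0, dropout_rate <= 1,
            melt_fail_rate >= 0, melt_fail_rate <= 1, noise_sd >= 0)
  targets <- setdiff(genes, reference_gene)
  samples <- sprintf("S%03d", seq_len(n_samples))
  if (is.null(fold_changes))
    fold_changes <- matrix(1, length(targets), n_samples,
                           dimnames = list(targets, samples))
  if (is.list(fold_changes))
    fold_changes <- do.call(rbind, fold_changes)[targets, , drop = FALSE]
  stopifnot(nrow(fold_changes) == length(targets),
            ncol(fold_changes) == n_samples, all(fold_changes > 0))
  dimnames(fold_changes) <- list(targets, samples)
  # identifiability: centre log2 folds per gene (geometric mean 1)
  lf <- log2(fold_changes)
  lf <- lf - rowMeans(lf)
  truth <- 2^lf

  base_g <- withr::with_seed(derive_seed(seed, 1L),
    setNames(runif(length(targets), 22, 30), targets))
  shift_s <- withr::with_seed(derive_seed(seed, 2L),
    setNames(rnorm(n_samples, 0, sample_shift_sd), samples))
  ref_base <- 18

  wells <- expand.grid(sample_id = samples, gene = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ct <- ifelse(wells$gene == reference_gene,
               ref_base + shift_s[wells$sample_id],
               base_g[wells$gene] + shift_s[wells$sample_id] -
                 lf[cbind(match(wells$gene, targets),
                          match(wells$sample_id, samples))])
  if (noise_sd > 0)
    ct <- ct + withr::with_seed(derive_seed(seed, 3L),
                                rnorm(length(ct), 0, noise_sd))
  dropout <- withr::with_seed(derive_seed(seed, 4L),
    runif(length(ct)) < dropout_rate)
  melt_fail <- withr::with_seed(derive_seed(seed, 5L),
    runif(length(ct)) < melt_fail_rate)
  ct[dropout] <- NA_real_
  out <- data.frame(plate_id = "plate1", sample_id = wells$sample_id,
                    gene = wells$gene, ct = ct, melt_ok = !melt_fail)
  class(out) <- c("qpcr_plate", "data.frame")
  attr(out, "truth") <- truth
  out
}
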