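#' Pearson correlation on pairwise-complete observations
#'
#' Standard product-moment correlation computed on entries where both
#' vectors are observed. Undefined cases are returned as `NA` with a
#' `reason` attribute rather than an error: fewer than 3 complete pairs, or
#' either vector constant on the complete set.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, with attributes `n_used` and (when
#'   `NA`) `reason`.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(structure(NA_real_, n_used = n, reason = "fewer than 3 complete pairs"))
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0)
    return(structure(NA_real_, n_used = n, reason = "constant vector"))
  structure(cor(xs, ys), n_used = n)
}

cor_matrix <- function(pcc, n_used, subset_label = "") {
  structure(list(pcc = pcc, n_used = n_used, subset_label = subset_label),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("cor_matrix: %d x %d%s\n", nrow(x$pcc), ncol(x$pcc),
              if (nzchar(x$subset_label)) paste0(" [", x$subset_label, "]") else ""))
  print(round(x$pcc, 2))
  invisible(x)
}

pairwise_pcc <- function(rows_x, rows_y) {
  p <- matrix(NA_real_, nrow(rows_x), nrow(rows_y),
              dimnames = list(rownames(rows_x), rownames(rows_y)))
  n <- p
  for (i in seq_len(nrow(rows_x)))
    for (j in seq_len(nrow(rows_y))) {
      r <- pcc(rows_x[i, ], rows_y[j, ])
      p[i, j] <- as.numeric(r)
      n[i, j] <- attr(r, "n_used")
    }
  list(pcc = p, n_used = n)
}

#' Correlation between enzyme expression and module enrichment profiles
#'
#' Correlates, across samples, each enzyme's expression row with each
#' module's z-score row, and the module z-rows among themselves — the
#' signature that links a chromatin modifier's level to the coordinated
#' expression of its target module. Samples are aligned by id, not by
#' position. By default modules are summarized by their z-score rows; with
#' `use_median_expression = TRUE` the per-sample median normalized
#' expression of the module genes is used instead.
#'
#' @param profile an `enrichment_profile` from [enrichment_matrix()].
#' @param em the [expr_matrix()] the profile was computed from (or any
#'   matrix sharing its samples) holding the enzyme rows.
#' @param enzymes character vector of enzyme gene ids present in `em`.
#' @param use_median_expression summarize modules by median normalized
#'   expression instead of z-scores (default FALSE).
#' @param modules required when `use_median_expression = TRUE`: the list of
#'   [gene_module()] objects the profile was built from.
#' @return A `cor_matrix` over entities `c(enzymes, modules)`.
#' @export
module_enzyme_correlation <- function(profile, em, enzymes,
                                      use_median_expression = FALSE,
                                      modules = NULL) {
  stopifnot(inherits(profile, "enrichment_profile"), inherits(em, "expr_matrix"))
  miss <- setdiff(enzymes, rownames(em$values))
  if (length(miss)) stop("enzymes absent from matrix: ", paste(miss, collapse = ", "))
  prof_samples <- colnames(profile$z)
  em_samples <- colnames(em$values)
  if (!setequal(prof_samples, em_samples))
    stop("sample-set mismatch between profile and matrix; offenders: ",
         paste(union(setdiff(prof_samples, em_samples),
                     setdiff(em_samples, prof_samples)), collapse = ", "))
  mod_rows <- if (use_median_expression) {
    if (is.null(modules)) stop("modules required for median-expression summaries")
    t(vapply(modules, function(m) {
      genes <- intersect(m$genes, rownames(em$values))
      apply(em$values[genes, prof_samples, drop = FALSE], 2L, median, na.rm = TRUE)
    }, numeric(length(prof_samples))))
  } else {
    profile$z
  }
  rownames(mod_rows) <- rownames(profile$z)
  enzyme_rows <- em$values[enzymes, prof_samples, drop = FALSE]
  block <- rbind(enzyme_rows, mod_rows)
  r <- pairwise_pcc(block, block)
  cor_matrix(r$pcc, r$n_used, subset_label = "all samples")
}

#' Pairwise gene-gene correlation within a sample subset
#'
#' Symmetric Pearson-correlation matrix of gene expression rows restricted
#' to a subset of samples (a group label from the matrix annotations, or an
#' explicit vector of sample ids) — used to search for co-regulated enzyme
#' pairs within one tissue or cancer type.
#'
#' @param em an [expr_matrix()].
#' @param genes character vector of gene ids present in `em`.
#' @param sample_subset a group label (matched against `em$groups`) or a
#'   character vector of sample ids; at least 3 samples required.
#' @return A `cor_matrix` with `n_used` counts and the subset label.
#' @export
pairwise_gene_correlation <- function(em, genes, sample_subset) {
  stopifnot(inherits(em, "expr_matrix"))
  miss <- setdiff(genes, rownames(em$values))
  if (length(miss)) stop("genes absent from matrix: ", paste(miss, collapse = ", "))
  if (length(sample_subset) == 1L && !(sample_subset %in% colnames(em$values))) {
    if (is.null(em$groups) || !(sample_subset %in% em$groups))
      stop("unknown group label '", sample_subset, "'; available: ",
           paste(unique(em$groups %||% "none"), collapse = ", "))
    ids <- names(em$groups)[em$groups == sample_subset]
    label <- sample_subset
  } else {
    miss_s <- setdiff(sample_subset, colnames(em$values))
    if (length(miss_s)) stop("unknown sample ids: ", paste(miss_s, collapse = ", "))
    ids <- sample_subset
    label <- sprintf("%d listed samples", length(ids))
  }
  if (length(ids) < 3L)
    warning("subset '", label, "' has ", length(ids),
            " samples; correlations undefined (need >= 3)")
  rows <- em$values[genes, ids, drop = FALSE]
  r <- pairwise_pcc(rows, rows)
  diag(r$pcc) <- 1
  cor_matrix(r$pcc, r$n_used, subset_label = label)
}

#' Export a correlation matrix as TSV
#'
#' Writes the PCC matrix and its pairwise-complete sample counts.
#'
#' @param cm a `cor_matrix`.
#' @param pcc_path,n_path output paths.
#' @export
write_cor_matrix <- function(cm, pcc_path, n_path = NULL) {
  write_named_matrix(cm$pcc, pcc_path)
  if (!is.null(n_path)) write_named_matrix(cm$n_used, n_path)
  invisible(pcc_path)
}
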