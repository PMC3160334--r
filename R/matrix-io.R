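#' Expression-matrix and gene-module containers
#'
#' `expr_matrix()` wraps a gene x sample matrix of log2 expression values
#' together with a scale flag and optional per-sample group annotations.
#' `probe_matrix()` holds the pre-collapse probe-level stage, with a
#' probe-to-gene map. `gene_module()` is a named set of gene symbols.
#'
#' The `scale` flag records whether values are absolute log2 intensities
#' (`"log2_absolute"`, or `"linear"` for raw intensities awaiting log2) or
#' per-gene standardized scores (`"gene_normalized"`: each row centred to
#' mean 0 and scaled to unit sample s.d.).
#'
#' @param values numeric matrix with gene (or probe) rownames and unique
#'   sample colnames.
#' @param scale character scale flag, see Details.
#' @param groups optional named character vector mapping sample id to a
#'   group label (tissue / cancer type).
#' @param constant_genes character vector of rows flagged as zero-variance
#'   during normalization.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("log2_absolute", "gene_normalized", "linear"),
                        groups = NULL, constant_genes = character()) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!is.null(groups)) groups <- groups[colnames(values)]
  structure(list(values = values, scale = scale, groups = groups,
                 constant_genes = constant_genes),
            class = "expr_matrix")
}

#' @param probe_to_gene named character vector mapping probe id to gene symbol;
#'   every probe maps to exactly one gene.
#' @rdname expr_matrix
#' @export
probe_matrix <- function(values, probe_to_gene,
                         scale = c("log2", "linear"), groups = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in probe matrix")
  if (!all(rownames(values) %in% names(probe_to_gene)))
    stop("every probe must map to a gene")
  if (!is.null(groups)) groups <- groups[colnames(values)]
  structure(list(values = values,
                 probe_to_gene = probe_to_gene[rownames(values)],
                 scale = scale, groups = groups),
            class = "probe_matrix")
}

#' @param name module name.
#' @param genes character vector of gene symbols, de-duplicated with a
#'   warning if duplicates were present (symbols are taken verbatim; the GMT
#'   reader upper-cases them as its normalization convention).
#' @param note free-text provenance note (e.g. source cell line).
#' @rdname expr_matrix
#' @export
gene_module <- function(name, genes, note = "") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty gene module '", name, "' rejected")
  if (anyDuplicated(genes)) {
    warning("module '", name, "': duplicate genes de-duplicated")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, note = note), class = "gene_module")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (length(x$constant_genes)) sprintf(", %d constant rows flagged",
                                                    length(x$constant_genes)) else ""))
  invisible(x)
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes / %d genes x %d samples [%s]\n",
              nrow(x$values), length(unique(x$probe_to_gene)), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module '%s': %d genes%s\n", x$name, length(x$genes),
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

# ---- TSV readers / writers -------------------------------------------------

split_tsv_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("parse error: '", path, "' is empty")
  # sentinel keeps trailing empty fields (strsplit would drop them)
  fields <- strsplit(paste0(lines, "\x1e"), "\t", fixed = TRUE)
  lapply(fields, function(f) {
    f[length(f)] <- sub("\x1e$", "", f[length(f)])
    f
  })
}

parse_cells <- function(x) {
  x[x %in% c("", "NA", "na", "NaN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read and write expression / probe matrices as TSV
#'
#' The matrix format is UTF-8 tab-separated text: a header row whose first
#' field is `id` (probe-level files carry a second field `gene`) followed by
#' unique sample ids; an optional second line whose first field is `group:`
#' carrying one group label per sample; then one row per gene or probe.
#' Missing cells (empty or `NA`) are read as missing, never as zero.
#'
#' @param path file path.
#' @param scale scale flag to attach to the parsed matrix (`read_matrix`
#'   cannot infer whether values are linear or log2).
#' @return `read_matrix()` returns an [expr_matrix()] or, when the file has a
#'   `gene` column, a [probe_matrix()].
#' @export
read_matrix <- function(path, scale = "log2_absolute") {
  fields <- split_tsv_lines(path)
  header <- fields[[1L]]
  if (header[1L] != "id")
    stop("format error: first header field must be 'id', got '", header[1L], "'")
  has_gene <- length(header) >= 2L && header[2L] == "gene"
  meta_cols <- if (has_gene) 2L else 1L
  samples <- header[-seq_len(meta_cols)]
  if (anyDuplicated(samples))
    stop("format error: duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- fields[-1L]
  groups <- NULL
  if (length(body) && body[[1L]][1L] == "group:") {
    g <- body[[1L]][-seq_len(meta_cols)]
    if (length(g) != length(samples))
      stop("parse error at line 2: group line has ", length(g),
           " labels for ", length(samples), " samples")
    groups <- setNames(g, samples)
    body <- body[-1L]
  }
  if (length(body) == 0L) stop("parse error: '", path, "' has no data rows")
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("parse error at line ", bad[1L] + 1L + as.integer(!is.null(groups)),
         ": expected ", length(header), " fields, found ", nf[bad[1L]])
  ids <- vapply(body, `[[`, "", 1L)
  vals <- t(vapply(body, function(f) parse_cells(f[-seq_len(meta_cols)]),
                   numeric(length(samples))))
  dimnames(vals) <- list(ids, samples)
  if (has_gene) {
    p2g <- setNames(vapply(body, `[[`, "", 2L), ids)
    probe_matrix(vals, p2g, scale = if (scale == "linear") "linear" else "log2",
                 groups = groups)
  } else {
    expr_matrix(vals, scale = scale, groups = groups)
  }
}

#' @param x an `expr_matrix` or `probe_matrix`.
#' @rdname read_matrix
#' @export
write_matrix <- function(x, path) {
  vals <- x$values
  is_probe <- inherits(x, "probe_matrix")
  header <- c("id", if (is_probe) "gene", colnames(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (!is.null(x$groups))
    writeLines(paste(c("group:", if (is_probe) "", unname(x$groups)),
                     collapse = "\t"), con)
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, digits = 15, trim = TRUE,
                                                   scientific = FALSE))
  for (i in seq_len(nrow(vals))) {
    row <- c(rownames(vals)[i], if (is_probe) unname(x$probe_to_gene[i]),
             fmt(vals[i, ]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write gene modules in GMT format
#'
#' Standard tab-separated gene-set format: one module per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are upper-cased;
#' duplicate genes within a module are dropped with a warning; empty modules
#' are rejected.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of [gene_module()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("GMT file '", path, "' has no modules")
    return(list())
  }
  mods <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("GMT parse error: line with fewer than 3 fields")
    gene_module(f[1L], toupper(f[-(1:2)]), note = f[2L])
  })
  setNames(mods, vapply(mods, `[[`, "", "name"))
}

#' @param modules list of [gene_module()] objects.
#' @rdname read_gmt
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m)
    paste(c(m$name, if (nzchar(m$note)) m$note else ".", m$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- probe filtering, collapsing, normalization ----------------------------

#' Filter unreliable probes
#'
#' Removes (i) probes with no detectable expression in any sample —
#' operationalized as every intensity at or below a detection floor, which
#' defaults to the matrix minimum — and (ii) probes that do not track their
#' sibling probes of the same gene: while a gene has three or more probes
#' and the lowest mean sibling Pearson correlation falls below
#' `min_interprobe_pcc`, the worst-correlated probe is removed and the means
#' are recomputed. Genes with one or two probes are untouched by the
#' correlation filter (two discordant probes carry no evidence about which
#' one is faulty).
#'
#' @param pm a [probe_matrix()] on the log2 scale.
#' @param min_interprobe_pcc correlation threshold in `[-1, 1]`; default 0.5.
#' @param drop_unexpressed apply the detection-floor filter (default TRUE).
#' @param floor detection floor on the stored scale; default `min(pm$values)`.
#' @return A filtered [probe_matrix()].
#' @export
filter_probes <- function(pm, min_interprobe_pcc = 0.5, drop_unexpressed = TRUE,
                          floor = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (min_interprobe_pcc < -1 || min_interprobe_pcc > 1)
    stop("min_interprobe_pcc must lie in [-1, 1]")
  if (pm$scale != "log2") stop("filter_probes expects log2-scale probes")
  vals <- pm$values
  keep <- rep(TRUE, nrow(vals))
  if (drop_unexpressed) {
    fl <- floor %||% min(vals, na.rm = TRUE)
    # "expressed nowhere": every observed value at or below the floor
    keep <- apply(vals, 1L, function(v) {
      obs <- v[!is.na(v)]
      length(obs) > 0L && max(obs) > fl
    })
  }
  g <- pm$probe_to_gene
  for (gene in unique(g[keep])) {
    repeat {
      idx <- which(keep & g == gene)
      if (length(idx) < 3L) break
      cc <- suppressWarnings(cor(t(vals[idx, , drop = FALSE]),
                                 use = "pairwise.complete.obs"))
      diag(cc) <- NA
      mean_pcc <- rowMeans(cc, na.rm = TRUE)
      if (all(mean_pcc >= min_interprobe_pcc, na.rm = TRUE)) break
      worst <- idx[which.min(mean_pcc)]  # ties: lowest row index dropped
      keep[worst] <- FALSE
    }
  }
  dropped <- sum(!keep)
  if (dropped) msg("filter_probes: dropped %d of %d probes", dropped, nrow(vals))
  probe_matrix(vals[keep, , drop = FALSE], g[keep], scale = pm$scale,
               groups = pm$groups)
}

#' Collapse probes to genes
#'
#' Linear intensities are first transformed to log2 (non-positive intensities
#' become missing with a warning); each gene's row is then the arithmetic
#' mean of its probe rows, per sample, with missing values excluded pairwise.
#' Genes with zero surviving probes are omitted with a warning.
#'
#' @param pm a [probe_matrix()].
#' @return An [expr_matrix()] with `scale = "log2_absolute"`.
#' @export
collapse_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  vals <- pm$values
  if (pm$scale == "linear") {
    if (any(vals <= 0, na.rm = TRUE)) {
      warning("non-positive intensities set to missing before log2")
      vals[vals <= 0] <- NA
    }
    vals <- log2(vals)
  }
  genes <- unique(unname(pm$probe_to_gene))
  out <- matrix(NA_real_, length(genes), ncol(vals),
                dimnames = list(genes, colnames(vals)))
  for (gene in genes) {
    rows <- vals[pm$probe_to_gene == gene, , drop = FALSE]
    out[gene, ] <- colMeans(rows, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  expr_matrix(out, scale = "log2_absolute", groups = pm$groups)
}

#' Gene-normalize an expression matrix
#'
#' Standardizes each gene row across samples: subtract the row mean, divide
#' by the row sample standard deviation (denominator n - 1). Constant rows
#' are centred to zero and flagged rather than divided by zero; rows with
#' fewer than two observed values become missing and are flagged likewise.
#' Applying the transform to an already-normalized matrix is a no-op (up to
#' numerical tolerance).
#'
#' @param em an [expr_matrix()].
#' @return An [expr_matrix()] with `scale = "gene_normalized"` and
#'   zero-variance rows listed in `$constant_genes`.
#' @export
gene_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  vals <- em$values
  if (ncol(vals) < 2L)
    stop("gene_normalize: need at least 2 samples (s.d. undefined)")
  n_obs <- rowSums(!is.na(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1L, sd, na.rm = TRUE)
  centred <- vals - mu
  constant <- rownames(vals)[n_obs >= 2L & (is.na(s) | s == 0)]
  too_few <- rownames(vals)[n_obs < 2L]
  scl <- ifelse(is.na(s) | s == 0, 1, s)
  out <- centred / scl
  out[rownames(vals) %in% constant, ] <- 0
  out[rownames(vals) %in% too_few, ] <- NA
  if (length(too_few))
    warning(length(too_few), " rows with <2 observed values set to missing")
  expr_matrix(out, scale = "gene_normalized", groups = em$groups,
              constant_genes = union(constant, too_few))
}
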