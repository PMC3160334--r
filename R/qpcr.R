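#' Read and write qPCR plate tables
#'
#' Plate input is a TSV with columns `plate_id`, `sample_id`, `gene`, `ct`
#' (numeric cycles, or `NP` for wells that produced no product) and
#' `melt_ok` (0/1: whether the melt peak was regular).
#'
#' @param path file path.
#' @return `read_qpcr_plate()` returns a `qpcr_plate` data frame.
#' @export
read_qpcr_plate <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("plate_id", "sample_id", "gene", "ct", "melt_ok")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate file missing columns: ", paste(miss, collapse = ", "))
  ct <- suppressWarnings(as.numeric(ifelse(df$ct == "NP", NA, df$ct)))
  bad <- !is.na(ct) & ct <= 0
  if (any(bad)) stop("non-positive Ct values at rows: ",
                     paste(which(bad), collapse = ", "))
  out <- data.frame(plate_id = df$plate_id, sample_id = df$sample_id,
                    gene = df$gene, ct = ct,
                    melt_ok = df$melt_ok %in% c("1", "TRUE", "true"))
  class(out) <- c("qpcr_plate", "data.frame")
  out
}

#' @param plate a `qpcr_plate` data frame.
#' @rdname read_qpcr_plate
#' @export
write_qpcr_plate <- function(plate, path) {
  df <- data.frame(plate_id = plate$plate_id, sample_id = plate$sample_id,
                   gene = plate$gene,
                   ct = ifelse(is.na(plate$ct), "NP",
                               format(plate$ct, digits = 15, trim = TRUE,
                                      scientific = FALSE)),
                   melt_ok = as.integer(plate$melt_ok))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Well-level qPCR quality control
#'
#' Applies the plate QC rules: wells with irregular melt peaks are removed
#' (non-specific amplification); wells that produced no product, or whose Ct
#' exceeds `ct_cap` (strictly greater), are assigned `assigned_value`
#' cycles. Every transformation is recorded per well in `qc_status`.
#'
#' @param wells a `qpcr_plate` data frame.
#' @param ct_cap cycles above which a Ct is treated as no signal
#'   (default 35).
#' @param assigned_value Ct assigned to no-product / above-cap wells
#'   (default 40).
#' @return The wells with added columns `ct_used` and `qc_status` in
#'   `{"ok", "assigned_40", "removed_melt"}`. Rows with `removed_melt` carry
#'   no usable Ct and are excluded downstream.
#' @export
apply_well_qc <- function(wells, ct_cap = 35, assigned_value = 40) {
  stopifnot(is.data.frame(wells))
  status <- rep("ok", nrow(wells))
  ct_used <- wells$ct
  assign_idx <- is.na(wells$ct) | wells$ct > ct_cap
  ct_used[assign_idx] <- assigned_value
  status[assign_idx] <- "assigned_40"
  status[!wells$melt_ok] <- "removed_melt"
  ct_used[!wells$melt_ok] <- NA_real_
  wells$ct_used <- ct_used
  wells$qc_status <- status
  wells
}

#' Relative quantification by the 2^-ddCt method
#'
#' For each QC-passed well: `dCt(s, g) = Ct(s, g) - Ct(s, ref)` within the
#' same sample; `ddCt(s, g) = dCt(s, g) - mean_s' dCt(s', g)`, i.e. each
#' gene is centred on its mean dCt across all samples on the array; fold
#' change `= 2^-ddCt`. Expression is therefore relative to the array-wide
#' mean for that gene (fold 1 = average), and the per-gene fold changes have
#' geometric mean 1 whenever no wells were filtered. Technical replicates
#' (repeated sample x gene wells) are averaged on the Ct scale. Samples in
#' which the reference gene was removed, never measured, or itself assigned
#' the cap value (a failed reference cannot normalize anything) get status
#' `missing_reference`. Wells assigned the cap value are included in the
#' per-gene mean by default (`exclude_assigned = FALSE`).
#'
#' @param wells a `qpcr_plate`, QC'd via [apply_well_qc()] (applied with
#'   defaults if the QC columns are absent).
#' @param reference_gene name of the reference gene (e.g. `"B2M"`).
#' @param exclude_assigned exclude assigned-cap wells from the per-gene
#'   mean dCt (sensitivity analysis; default FALSE).
#' @return A `qpcr_result` data frame with one row per (sample, gene):
#'   `ct_used`, `delta_ct`, `delta_delta_ct`, `fold_change`, `qc_status`.
#'   The reference gene itself is not reported.
#' @export
relative_quantification <- function(wells, reference_gene,
                                    exclude_assigned = FALSE) {
  if (!("ct_used" %in% names(wells))) wells <- apply_well_qc(wells)
  if (!(reference_gene %in% wells$gene))
    stop("reference gene '", reference_gene, "' absent from the plate")
  usable <- wells[wells$qc_status != "removed_melt", , drop = FALSE]
  if (nrow(usable) == 0L) {
    res <- data.frame(sample_id = character(), gene = character(),
                      ct_used = numeric(), delta_ct = numeric(),
                      delta_delta_ct = numeric(), fold_change = numeric(),
                      qc_status = character())
    class(res) <- c("qpcr_result", "data.frame")
    return(res)
  }
  # technical replicates: average on the Ct scale
  key <- interaction(usable$sample_id, usable$gene, drop = TRUE)
  agg <- data.frame(
    sample_id = tapply(usable$sample_id, key, `[`, 1L),
    gene = tapply(usable$gene, key, `[`, 1L),
    ct_used = as.numeric(tapply(usable$ct_used, key, mean)),
    assigned = as.logical(tapply(usable$qc_status == "assigned_40", key, any)),
    row.names = NULL)
  # a no-product / above-cap reference is not a measured reference:
  # normalizing against the assigned value would be meaningless, so such
  # samples are reported as missing_reference instead
  ref <- agg[agg$gene == reference_gene & !agg$assigned, ]
  ref_ct <- setNames(ref$ct_used, ref$sample_id)
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  tgt$delta_ct <- tgt$ct_used - unname(ref_ct[tgt$sample_id])
  has_ref <- tgt$sample_id %in% names(ref_ct)
  mean_dct <- vapply(split(tgt, tgt$gene), function(d) {
    use <- !is.na(d$delta_ct) & (!exclude_assigned | !d$assigned)
    if (!any(use)) NA_real_ else mean(d$delta_ct[use])
  }, numeric(1))
  tgt$delta_delta_ct <- tgt$delta_ct - unname(mean_dct[tgt$gene])
  tgt$fold_change <- 2^(-tgt$delta_delta_ct)
  tgt$qc_status <- ifelse(!has_ref, "missing_reference",
                          ifelse(tgt$assigned, "assigned_40", "ok"))
  res <- tgt[order(tgt$gene, tgt$sample_id),
             c("sample_id", "gene", "ct_used", "delta_ct", "delta_delta_ct",
               "fold_change", "qc_status")]
  rownames(res) <- NULL
  class(res) <- c("qpcr_result", "data.frame")
  res
}

#' Clip fold changes to the heatmap display scale
#'
#' Fold changes are clipped to `[lo, hi]` (defaults 0 and 10) with 1 as the
#' neutral midpoint; raw folds should be exported alongside for rendering by
#' external heatmap tools.
#'
#' @param fold_changes positive fold changes.
#' @param lo,hi clip range (defaults 0, 10).
#' @return clipped values.
#' @export
heatmap_scale <- function(fold_changes, lo = 0, hi = 10) {
  stopifnot(all(fold_changes > 0, na.rm = TRUE), lo < hi)
  pmin(pmax(fold_changes, lo), hi)
}
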