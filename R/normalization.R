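NORM_SCHEMES <- c("per_cell_ct", "mcr_ct", "tpm", "log2_tpm")

#' Normalized miRNA abundance matrix
#'
#' Thin container tagging a miRNA x sample matrix with its normalization
#' scheme: `per_cell_ct` (Ct shifted by log2 of relative cell input),
#' `mcr_ct` (global-mean / mean-centering-restricted delta-Ct), `tpm`
#' (tags per million) or `log2_tpm` (log2(TPM + 1)).
#'
#' @param values numeric matrix with row and column names; `NA` = ND for
#'   Ct-scale schemes.
#' @param scheme one of `per_cell_ct`, `mcr_ct`, `tpm`, `log2_tpm`.
#' @param reference scheme-specific metadata (reference cell count, global
#'   means per sample, pseudocount).
#' @return object of class `normalized_matrix`
#' @export
normalized_matrix <- function(values, scheme, reference = list()) {
  scheme <- match.arg(scheme, NORM_SCHEMES)
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, scheme = scheme, reference = reference),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix [%s]: %d miRNAs x %d samples\n",
              x$scheme, nrow(x$values), ncol(x$values)))
  invisible(x)
}

is_ct_scheme <- function(norm) norm$scheme %in% c("per_cell_ct", "mcr_ct")

#' Per-cell normalization of vesicular Ct values
#'
#' Corrects for unequal viable-cell input of the secretion cultures (SIPS
#' preparations start from ~10-fold fewer cells). In linear abundance this
#' divides by the cell number; in Ct space (base 2) that is
#' `Ct' = Ct + log2(cells_sample / ref_cells)`, so samples from fewer cells
#' get *lower* (more abundant-looking) corrected Ct. ND values stay ND.
#'
#' @param ct a [ct_matrix()]; spike-in rows are excluded from the output.
#' @param sheet a [sample_sheet()] with positive `cells_for_secretion`.
#' @param ref_cells reference cell number; default the largest cell count
#'   among the annotated qPCR samples.
#' @return [normalized_matrix()] with scheme `per_cell_ct`
#' @export
per_cell_normalize <- function(ct, sheet, ref_cells = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  vals <- mirna_values(ct)
  ann <- sheet_for(colnames(vals), sheet, "qpcr")
  cells <- ann$cells_for_secretion
  if (any(!is.finite(cells)) || any(cells <= 0))
    stop("cells_for_secretion must be positive for all samples")
  if (is.null(ref_cells)) ref_cells <- max(cells)
  if (ref_cells <= 0) stop("ref_cells must be positive")
  shifted <- sweep(vals, 2, log2(cells / ref_cells), "+")
  normalized_matrix(shifted, "per_cell_ct",
                    reference = list(ref_cells = ref_cells,
                                     cells = setNames(cells, ann$sample_id)))
}

#' Global-mean (MCR) normalization of vesicular Ct values
#'
#' Mean-centering-restricted normalization: from each Ct the mean Ct over
#' all *detected* miRNAs (Ct <= `limit`, ND excluded) of the same sample is
#' subtracted. This removes per-sample scale (e.g. input or plate offsets)
#' and leaves per-vesicle composition differences. ND values stay ND; values
#' above `limit` are shifted but do not contribute to the mean.
#'
#' @param ct a [ct_matrix()]; spike-ins excluded.
#' @param limit detection limit in cycles (default 38).
#' @return [normalized_matrix()] with scheme `mcr_ct`; the per-sample global
#'   means are stored in `reference$global_means`.
#' @export
global_mean_normalize <- function(ct, limit = 38) {
  stopifnot(inherits(ct, "ct_matrix"))
  vals <- mirna_values(ct)
  det <- !is.na(vals) & vals <= limit
  n_det <- colSums(det)
  if (any(n_det < 2))
    stop("fewer than 2 detected miRNAs in sample(s): ",
         paste(colnames(vals)[n_det < 2], collapse = ", "))
  gm <- vapply(seq_len(ncol(vals)),
               function(j) mean(vals[det[, j], j]), numeric(1))
  centred <- sweep(vals, 2, gm, "-")
  normalized_matrix(centred, "mcr_ct",
                    reference = list(global_means = setNames(gm, colnames(vals)),
                                     limit = limit))
}

#' TPM matrix as a normalized_matrix
#' @param counts a [count_matrix()]
#' @return [normalized_matrix()] with scheme `tpm`
#' @export
tpm_matrix <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  normalized_matrix(counts$tpm, "tpm")
}

#' TPM normalization with abundance filtering
#'
#' Computes tags per million and keeps miRNAs that reach at least `min_tpm`
#' in at least one donor. The study's phrasing is ambiguous, so the donor
#' rule is explicit: `"all_samples_of_donor"` (default, stricter) requires
#' the threshold in *every* sample of some donor; `"any_sample"` requires it
#' in any single sample.
#'
#' @param counts a [count_matrix()]
#' @param sheet a [sample_sheet()] annotating the count columns (platform ngs)
#' @param min_tpm abundance threshold (default 5 TPM)
#' @param tpm_rule donor rule, see Description
#' @param pseudocount added before log2 (default 1)
#' @return list with `norm` ([normalized_matrix()], scheme `log2_tpm`,
#'   filtered rows), `tpm` (unfiltered TPM matrix), and `kept` (character
#'   vector of retained miRNA ids)
#' @export
tpm_and_filter <- function(counts, sheet, min_tpm = 5,
                           tpm_rule = c("all_samples_of_donor", "any_sample"),
                           pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  tpm_rule <- match.arg(tpm_rule)
  ann <- sheet_for(colnames(counts$tpm), sheet, "ngs")
  tpm <- counts$tpm
  donors <- unique(ann$donor)
  keep <- switch(tpm_rule,
    all_samples_of_donor = {
      per_donor <- vapply(donors, function(d) {
        cols <- ann$donor == d
        apply(tpm[, cols, drop = FALSE] >= min_tpm, 1, all)
      }, logical(nrow(tpm)))
      if (!is.matrix(per_donor))
        per_donor <- matrix(per_donor, nrow = nrow(tpm))
      rowSums(per_donor) > 0
    },
    any_sample = apply(tpm >= min_tpm, 1, any))
  kept <- rownames(tpm)[keep]
  l2 <- log2(tpm[keep, , drop = FALSE] + pseudocount)
  list(norm = normalized_matrix(l2, "log2_tpm",
                                reference = list(pseudocount = pseudocount,
                                                 min_tpm = min_tpm,
                                                 tpm_rule = tpm_rule)),
       tpm = normalized_matrix(tpm, "tpm"),
       kept = kept)
}

# Donor-paired group means for one miRNA row; returns per-donor
# (SIPS, Q) means restricted to `rows` of the sheet.
#' Donor-paired log2 fold change (SIPS vs Q)
#'
#' For each miRNA the SIPS-vs-Q log2 fold change is computed per donor and
#' then averaged over donors. On Ct-scale schemes lower Ct means more
#' abundant, so `log2FC = mean(Ct_Q) - mean(Ct_SIPS)`; on `log2_tpm` it is
#' `mean(log2TPM_SIPS) - mean(log2TPM_Q)`. Positive values always mean more
#' abundant in SIPS. A donor contributes only if all of its required cells
#' are observed (complete-case rule); a miRNA with no complete donor gets
#' `NA`.
#'
#' @param norm a [normalized_matrix()] (schemes per_cell_ct, mcr_ct or
#'   log2_tpm)
#' @param sheet a [sample_sheet()]
#' @param day `"both"` (default) pools D7 and D21 per donor; `"D7"`/`"D21"`
#'   restrict to one time point.
#' @return named numeric vector of per-miRNA log2 fold changes
#' @export
log2fc <- function(norm, sheet, day = c("both", "D7", "D21")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  day <- match.arg(day)
  if (norm$scheme == "tpm")
    stop("use scheme log2_tpm (log-scale) for fold changes, not raw tpm")
  platform <- if (is_ct_scheme(norm)) "qpcr" else "ngs"
  ann <- sheet_for(colnames(norm$values), sheet, platform)
  if (day != "both") {
    keep <- ann$day == day
    ann <- ann[keep, , drop = FALSE]
  } else keep <- rep(TRUE, ncol(norm$values))
  vals <- norm$values[, keep, drop = FALSE]
  if (!all(c("Q", "SIPS") %in% ann$condition))
    stop("both conditions (Q, SIPS) required for a fold change")
  donors <- unique(ann$donor)
  per_donor <- vapply(donors, function(d) {
    q <- vals[, ann$donor == d & ann$condition == "Q", drop = FALSE]
    s <- vals[, ann$donor == d & ann$condition == "SIPS", drop = FALSE]
    if (!ncol(q) || !ncol(s))
      stop("donor ", d, " lacks one condition: pairing incomplete")
    mq <- rowMeans(q); ms <- rowMeans(s)  # NA if any cell missing
    if (is_ct_scheme(norm)) mq - ms else ms - mq
  }, numeric(nrow(vals)))
  if (!is.matrix(per_donor))           # single-miRNA edge case
    per_donor <- matrix(per_donor, nrow = nrow(vals))
  fc <- rowMeans(per_donor)  # NA unless complete across all donors
  setNames(fc, rownames(vals))
}
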