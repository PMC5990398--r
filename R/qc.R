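DETECTION_BINS <- c("<31", "31-35", "35-38", ">38/ND")

#' Spike-in robustness check
#'
#' For each spike-in control the Ct range across samples
#' (dCt_r = max - min) is computed; a range below `threshold` cycles marks
#' the control as robust. Interplate-calibrator (IPC) rows, recognised by
#' `ipc_pattern`, are reported against `ipc_threshold` but flagged so that
#' their spread can be treated as an observation rather than a gate.
#' A spike-in missing (ND) in any sample yields a failure record with an
#' `NA` range, not an error.
#'
#' @param ct a [ct_matrix()] whose `spikein_ids` name the control rows
#' @param threshold robustness threshold in cycles (default 1.0)
#' @param ipc_threshold threshold applied to IPC rows (default 1.0)
#' @param ipc_pattern regular expression identifying IPC controls
#' @return data.frame with columns `spikein`, `dct_r`, `is_ipc`, `pass`
#' @export
spikein_qc <- function(ct, threshold = 1.0, ipc_threshold = 1.0,
                       ipc_pattern = "UniSp3|IPC") {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!length(ct$spikein_ids)) stop("ct matrix has no spike-in rows")
  sp <- ct$values[ct$spikein_ids, , drop = FALSE]
  rng <- apply(sp, 1, function(x) {
    if (anyNA(x)) NA_real_ else max(x) - min(x)
  })
  is_ipc <- grepl(ipc_pattern, ct$spikein_ids, ignore.case = TRUE)
  thr <- ifelse(is_ipc, ipc_threshold, threshold)
  data.frame(spikein = ct$spikein_ids,
             dct_r = unname(rng),
             is_ipc = is_ipc,
             pass = !is.na(rng) & rng < thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Bin an average Ct: boundary values go to the lower-abundance (higher-Ct)
# side except 38, which still counts as detected: [., 31), [31, 35),
# [35, 38], (38, ...] / all-ND.
bin_avg_ct <- function(avg) {
  out <- rep(DETECTION_BINS[4], length(avg))
  out[!is.na(avg) & avg <= 38] <- DETECTION_BINS[3]
  out[!is.na(avg) & avg < 35] <- DETECTION_BINS[2]
  out[!is.na(avg) & avg < 31] <- DETECTION_BINS[1]
  factor(out, DETECTION_BINS)
}

#' Detection-category and donor-overlap summary
#'
#' Per miRNA: the average Ct over all samples (ND excluded, never imputed)
#' binned into the four panel reporting categories (<31, 31-35, 35-38,
#' >38/ND), and the number of donors in which the miRNA is detected
#' (Ct <= `limit`) in *every* sample of that donor (both conditions, both
#' days). Spike-in rows are excluded.
#'
#' @param ct a [ct_matrix()]
#' @param sheet a [sample_sheet()] annotating every Ct column (platform qpcr)
#' @param limit detection limit in cycles (default 38; detected = Ct <= limit)
#' @return list with `per_mirna` (data.frame: `mirna`, `avg_ct`, `category`,
#'   `donors_detected`) and `category_counts` (named integer vector over the
#'   four bins, summing to the number of miRNAs)
#' @export
detection_summary <- function(ct, sheet, limit = 38) {
  stopifnot(inherits(ct, "ct_matrix"))
  vals <- mirna_values(ct)
  ann <- sheet_for(colnames(vals), sheet, "qpcr")
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  cat <- bin_avg_ct(avg)
  det <- !is.na(vals) & vals <= limit
  donors <- unique(ann$donor)
  per_donor <- vapply(donors, function(d) {
    cols <- ann$donor == d
    apply(det[, cols, drop = FALSE], 1, all)
  }, logical(nrow(vals)))
  if (!is.matrix(per_donor))           # single-miRNA edge case
    per_donor <- matrix(per_donor, nrow = nrow(vals))
  n_donors <- rowSums(per_donor)
  per_mirna <- data.frame(mirna = rownames(vals),
                          avg_ct = unname(avg),
                          category = as.character(cat),
                          donors_detected = as.integer(n_donors),
                          row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(cat)
  list(per_mirna = per_mirna,
       category_counts = setNames(as.integer(counts), names(counts)))
}
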