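#' Ct to arbitrary units
#'
#' Linear abundance from a qPCR Ct value under the base-2 (100% efficiency)
#' model, anchored so that Ct 40 maps to 10 AU (roughly 10 molecules):
#' `AU = 10 * 2^(40 - Ct)`.
#'
#' @param ct finite Ct value(s), cycles
#' @return arbitrary units, same length as `ct`
#' @export
au_transform <- function(ct) {
  if (any(!is.finite(ct)))
    stop("au_transform requires finite Ct values (ND must be filtered first)")
  10 * 2^(40 - ct)
}

ct_values_of <- function(ct) {
  if (inherits(ct, "ct_matrix")) mirna_values(ct)
  else if (inherits(ct, "normalized_matrix") && is_ct_scheme(ct)) ct$values
  else stop("`ct` must be a ct_matrix or a Ct-scale normalized_matrix")
}

tpm_values_of <- function(tpm) {
  if (inherits(tpm, "count_matrix")) tpm$tpm
  else if (inherits(tpm, "normalized_matrix") && tpm$scheme == "tpm")
    tpm$values
  else stop("`tpm` must be a count_matrix or a tpm normalized_matrix")
}

#' Co-measurement filter for the rank/ratio correlation
#'
#' Restricts the miRNA universe to those reliably measured on both platforms,
#' in the documented order: (1) intersect the panel ids with the
#' NGS-measured ids; (2) drop miRNAs in the bottom abundance quartile
#' (quartile of cross-sample mean abundance: lowest mean TPM, highest mean
#' Ct) on both platforms (`quartile_rule = "and"`, default) or on either
#' (`"or"`); (3) drop miRNAs with TPM = 0 in any NGS sample; (4) drop
#' miRNAs with any ND across the Ct samples. miRNAs never detected in the
#' panel count as bottom-quartile on the Ct side.
#'
#' @param panel_mirnas character vector of panel miRNA ids
#' @param tpm a [count_matrix()] or unfiltered `tpm` [normalized_matrix()]
#' @param ct a [ct_matrix()] or Ct-scale [normalized_matrix()]
#' @param quartile_rule `"and"` or `"or"`, see Description
#' @param lower_pct quartile cut in percent (default 25)
#' @return list with `ids` (retained miRNAs, panel order) and `steps`
#'   (named counts after each step)
#' @export
correlation_filter <- function(panel_mirnas, tpm, ct,
                               quartile_rule = c("and", "or"),
                               lower_pct = 25) {
  quartile_rule <- match.arg(quartile_rule)
  tpm_m <- tpm_values_of(tpm)
  ct_m <- ct_values_of(ct)

  ids <- intersect(panel_mirnas, rownames(tpm_m))
  ids <- intersect(ids, rownames(ct_m))
  steps <- c(after_intersect = length(ids))
  if (!length(ids)) stop("no miRNAs shared between panel and NGS")

  mean_tpm <- rowMeans(tpm_m[ids, , drop = FALSE])
  mean_ct <- rowMeans(ct_m[ids, , drop = FALSE], na.rm = TRUE)
  all_nd <- is.nan(mean_ct)
  p <- lower_pct / 100
  low_tpm <- mean_tpm <= quantile(mean_tpm, p)
  low_ct <- all_nd |
    mean_ct >= quantile(mean_ct[!all_nd], 1 - p)
  low <- if (quartile_rule == "and") low_tpm & low_ct else low_tpm | low_ct
  ids <- ids[!low]
  steps <- c(steps, after_quartile = length(ids))
  if (!length(ids)) stop("no miRNAs left after quartile exclusion")

  ids <- ids[apply(tpm_m[ids, , drop = FALSE] > 0, 1, all)]
  steps <- c(steps, after_zero_tpm = length(ids))
  if (!length(ids)) stop("no miRNAs left after zero-TPM exclusion")

  ids <- ids[!apply(is.na(ct_m[ids, , drop = FALSE]), 1, any)]
  steps <- c(steps, after_nd = length(ids))
  if (!length(ids)) stop("no miRNAs left after ND exclusion")

  list(ids = ids, steps = steps)
}

#' Per-condition average abundances for the rank/ratio scores
#'
#' Pools donors and (by default) both days: per condition the intracellular
#' abundance is the mean TPM over the NGS samples, the vesicular abundance
#' the mean per-cell-normalized Ct over the qPCR samples, additionally
#' expressed in arbitrary units via [au_transform()].
#'
#' @param ids filtered miRNA ids ([correlation_filter()])
#' @param tpm a [count_matrix()] or `tpm` [normalized_matrix()]
#' @param ct_norm a Ct-scale [normalized_matrix()] (typically
#'   [per_cell_normalize()] output)
#' @param sheet a [sample_sheet()]
#' @param day `"both"` (default), `"D7"` or `"D21"`
#' @return data.frame of class `correlation_input` with per-condition
#'   columns `intra_Q`, `intra_SIPS`, `extra_ct_Q`, `extra_ct_SIPS`,
#'   `extra_au_Q`, `extra_au_SIPS`
#' @export
build_correlation_input <- function(ids, tpm, ct_norm, sheet,
                                    day = c("both", "D7", "D21")) {
  day <- match.arg(day)
  tpm_m <- tpm_values_of(tpm)[ids, , drop = FALSE]
  ct_m <- ct_values_of(ct_norm)[ids, , drop = FALSE]
  if (anyNA(ct_m))
    stop("ND values remain in the Ct matrix; apply correlation_filter first")
  ann_n <- sheet_for(colnames(tpm_m), sheet, "ngs")
  ann_q <- sheet_for(colnames(ct_m), sheet, "qpcr")
  pick <- function(ann, cond) {
    ann$condition == cond & (day == "both" | ann$day == day)
  }
  out <- data.frame(mirna = ids, stringsAsFactors = FALSE)
  for (cond in c("Q", "SIPS")) {
    nc <- pick(ann_n, cond); qc <- pick(ann_q, cond)
    if (!any(nc) || !any(qc))
      stop("no samples for condition ", cond, " at day ", day)
    out[[paste0("intra_", cond)]] <- rowMeans(tpm_m[, nc, drop = FALSE])
    ect <- rowMeans(ct_m[, qc, drop = FALSE])
    out[[paste0("extra_ct_", cond)]] <- ect
    out[[paste0("extra_au_", cond)]] <- au_transform(ect)
  }
  class(out) <- c("correlation_input", "data.frame")
  out
}

# rank 1 = most abundant; average ranks on ties
abundance_rank <- function(x, descending = TRUE) {
  rank(if (descending) -x else x, ties.method = "average")
}

#' Rank-difference secretion scores
#'
#' Per condition, miRNAs are ranked by intracellular abundance (descending
#' TPM, rank 1 = most abundant) and by vesicular abundance (ascending Ct).
#' `drank = rank_intra - rank_extra`: positive means relatively enriched in
#' vesicles (secreted), negative relatively retained.
#' `ddrank = drank_SIPS - drank_Q` measures the senescence-dependent shift:
#' high values indicate selective secretion upon senescence.
#'
#' @param input a [build_correlation_input()] table (n >= 3)
#' @return data.frame: `mirna`, per-condition intra/extra ranks, `drank_Q`,
#'   `drank_SIPS`, `ddrank`
#' @export
rank_scores <- function(input) {
  stopifnot(inherits(input, "correlation_input"))
  if (nrow(input) < 3) stop("rank scores need at least 3 miRNAs")
  out <- data.frame(mirna = input$mirna, stringsAsFactors = FALSE)
  for (cond in c("Q", "SIPS")) {
    ri <- abundance_rank(input[[paste0("intra_", cond)]], descending = TRUE)
    re <- abundance_rank(input[[paste0("extra_ct_", cond)]],
                         descending = FALSE)
    out[[paste0("rank_intra_", cond)]] <- ri
    out[[paste0("rank_extra_", cond)]] <- re
    out[[paste0("drank_", cond)]] <- ri - re
  }
  out$ddrank <- out$drank_SIPS - out$drank_Q
  out
}

#' Abundance-ratio secretion scores
#'
#' Per condition the vesicular/intracellular abundance ratio
#' `dratio = extra_AU / intra_TPM` is formed (high = relatively more of the
#' miRNA outside the cell). `ddratio_raw = dratio_SIPS / dratio_Q`, and
#' `ddratio` is `ddratio_raw` divided by its arithmetic mean over all valid
#' miRNAs, so the returned scores average exactly 1. High `ddratio` means
#' selective secretion upon senescence, mirroring the sign convention of
#' [rank_scores()]. Note the per-condition `dratio` mixes AU and TPM units;
#' only the doubly-relative `ddratio` is unit-free.
#'
#' miRNAs with a non-positive intracellular abundance or `dratio_Q` are
#' flagged (`valid = FALSE`), excluded from the global mean and given `NA`
#' scores.
#'
#' @param input a [build_correlation_input()] table
#' @return data.frame: `mirna`, `dratio_Q`, `dratio_SIPS`, `ddratio_raw`,
#'   `ddratio`, `valid`
#' @export
ratio_scores <- function(input) {
  stopifnot(inherits(input, "correlation_input"))
  dq <- input$extra_au_Q / input$intra_Q
  ds <- input$extra_au_SIPS / input$intra_SIPS
  valid <- is.finite(dq) & is.finite(ds) & dq > 0 & ds > 0
  raw <- ifelse(valid, ds / dq, NA_real_)
  if (!any(valid)) stop("no valid ratios (all denominators zero?)")
  norm <- raw / mean(raw[valid])
  data.frame(mirna = input$mirna,
             dratio_Q = dq, dratio_SIPS = ds,
             ddratio_raw = raw, ddratio = norm,
             valid = valid,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combined secretion score table
#'
#' Joins [rank_scores()] and [ratio_scores()], adds the abundance quartile
#' (1 = least, 4 = most abundant, from the AU-transformed average vesicular
#' Ct over both conditions) and the selective-secretion class from
#' [classify_selective()].
#'
#' @inheritParams rank_scores
#' @param lower_pct,upper_pct percentile cut-offs for classification
#' @return data.frame of class `secretion_scores` with all score columns
#'   plus `abundance_quartile` and `class`
#' @export
secretion_scores <- function(input, lower_pct = 25, upper_pct = 75) {
  rk <- rank_scores(input)
  rt <- ratio_scores(input)
  stopifnot(identical(rk$mirna, rt$mirna))
  out <- cbind(rk, rt[setdiff(names(rt), "mirna")])
  avg_au <- (input$extra_au_Q + input$extra_au_SIPS) / 2
  qs <- quantile(avg_au, c(0.25, 0.5, 0.75))
  out$abundance_quartile <- 1L + (avg_au > qs[1]) + (avg_au > qs[2]) +
    (avg_au > qs[3])
  class(out) <- c("secretion_scores", "data.frame")
  out$class <- classify_selective(out, lower_pct, upper_pct)
  out
}

#' Dual-percentile classification of selective secretion
#'
#' A miRNA is called `secreted` if it lies above the `upper_pct` percentile
#' of *both* `ddrank` and `ddratio`, `retained` if below both `lower_pct`
#' percentiles, otherwise `neutral` (concordance of the two independent
#' scoring methods is required). Percentiles use linear interpolation
#' between order statistics (type 7). With degenerate (all-equal) scores
#' everything is neutral. `NA` scores are neutral.
#'
#' @param scores data.frame with columns `ddrank` and `ddratio` (n >= 4)
#' @param lower_pct,upper_pct percentile cut-offs (defaults 25 and 75)
#' @return character vector: `secreted`, `retained` or `neutral`
#' @export
classify_selective <- function(scores, lower_pct = 25, upper_pct = 75) {
  stopifnot(all(c("ddrank", "ddratio") %in% names(scores)))
  if (nrow(scores) < 4) stop("classification needs at least 4 miRNAs")
  lo <- lower_pct / 100; hi <- upper_pct / 100
  q_rank <- quantile(scores$ddrank, c(lo, hi), na.rm = TRUE, type = 7)
  q_ratio <- quantile(scores$ddratio, c(lo, hi), na.rm = TRUE, type = 7)
  cls <- rep("neutral", nrow(scores))
  up <- scores$ddrank > q_rank[2] & scores$ddratio > q_ratio[2]
  dn <- scores$ddrank < q_rank[1] & scores$ddratio < q_ratio[1]
  cls[!is.na(up) & up] <- "secreted"
  cls[!is.na(dn) & dn] <- "retained"
  cls
}

#' Concordance between the rank and ratio methods
#'
#' Spearman correlation (two-tailed) between `ddrank` and `ddratio`, and the
#' overlap of the top-`k` miRNAs called secreted (highest scores) and
#' retained (lowest scores) by each method.
#'
#' @param scores a [secretion_scores()] table (n >= 5)
#' @param k top-list size (default 20)
#' @return list: `rho`, `p_value`, `top_secreted_overlap`,
#'   `top_retained_overlap`, `k`. `rho` is `NA` when either score vector is
#'   constant (undefined correlation).
#' @export
method_concordance <- function(scores, k = 20) {
  stopifnot(all(c("ddrank", "ddratio") %in% names(scores)))
  ok <- !is.na(scores$ddrank) & !is.na(scores$ddratio)
  if (sum(ok) < 5) stop("concordance needs at least 5 scored miRNAs")
  x <- scores$ddrank[ok]; y <- scores$ddratio[ok]; ids <- scores$mirna[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rho <- NA_real_; pval <- NA_real_
  } else {
    test <- suppressWarnings(
      cor.test(x, y, method = "spearman", alternative = "two.sided",
               exact = FALSE))
    rho <- unname(test$estimate); pval <- test$p.value
  }
  k <- min(k, length(ids))
  top <- function(v, decreasing) ids[order(v, decreasing = decreasing)][1:k]
  list(rho = rho, p_value = pval,
       top_secreted_overlap =
         length(intersect(top(x, TRUE), top(y, TRUE))),
       top_retained_overlap =
         length(intersect(top(x, FALSE), top(y, FALSE))),
       k = k)
}

#' End-to-end selective-secretion scoring
#'
#' Convenience chain used by the report and the recovery tests: per-cell Ct
#' normalization, TPM computation, the co-measurement filter, per-condition
#' averaging, dual scoring and classification.
#'
#' @param ct a [ct_matrix()]
#' @param counts a [count_matrix()]
#' @param sheet a [sample_sheet()]
#' @param quartile_rule passed to [correlation_filter()]
#' @param lower_pct,upper_pct passed to [classify_selective()]
#' @param k passed to [method_concordance()]
#' @return list: `scores` ([secretion_scores()] table), `filter` (ids +
#'   step counts), `concordance` ([method_concordance()] list)
#' @export
secretion_pipeline <- function(ct, counts, sheet, quartile_rule = "and",
                               lower_pct = 25, upper_pct = 75, k = 20) {
  percell <- per_cell_normalize(ct, sheet)
  tpm <- tpm_matrix(counts)
  flt <- correlation_filter(mirna_ids(ct), tpm, ct,
                            quartile_rule = quartile_rule,
                            lower_pct = lower_pct)
  input <- build_correlation_input(flt$ids, tpm, percell, sheet)
  scores <- secretion_scores(input, lower_pct, upper_pct)
  list(scores = scores, filter = flt,
       concordance = method_concordance(scores, k = k))
}
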