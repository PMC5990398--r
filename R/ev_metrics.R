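#' Particle size distribution summary
#'
#' Per-sample histogram of tracked particle sizes (percent of tracked
#' particles per size bin) and the median diameter (X50). The instrument's
#' proprietary peak-analysis X50 is substituted by the empirical median of
#' the tracked sizes.
#'
#' @param particles a [particle_table()]
#' @param bin_edges size bin edges in nm (default 20-nm bins to 220 nm);
#'   sizes outside the edges fall into an open overflow bin.
#' @return list with `histogram` (long data.frame: `sample_id`, `bin`,
#'   `percent`; percentages sum to 100 per sample) and `x50` (named vector
#'   of per-sample median sizes, nm)
#' @export
size_summary <- function(particles, bin_edges = seq(0, 220, by = 20)) {
  stopifnot(inherits(particles, "particle_table"))
  tr <- particles$tracks
  if (!nrow(tr)) stop("no tracked particles")
  edges <- c(bin_edges, Inf)
  labs <- c(sprintf("%g-%g", utils::head(bin_edges, -1),
                    bin_edges[-1]),
            sprintf(">%g", bin_edges[length(bin_edges)]))
  samples <- unique(tr$sample_id)
  hist_list <- lapply(samples, function(s) {
    sz <- tr$size_nm[tr$sample_id == s]
    cnt <- table(cut(sz, edges, labels = labs, right = TRUE,
                     include.lowest = TRUE))
    data.frame(sample_id = s, bin = names(cnt),
               percent = 100 * as.numeric(cnt) / length(sz),
               stringsAsFactors = FALSE)
  })
  x50 <- vapply(samples,
                function(s) median(tr$size_nm[tr$sample_id == s]),
                numeric(1))
  list(histogram = do.call(rbind, hist_list), x50 = setNames(x50, samples))
}

#' Particles secreted per cell, as fold change vs a reference group
#'
#' Each concentration record is divided by its cell count; technical
#' replicates are averaged per sample, samples are averaged per
#' (condition, day) group, and group means are divided by the reference
#' group mean (default quiescent cells at day 7). Fold changes are
#' invariant to the units of the particle totals.
#'
#' @param particles a [particle_table()]
#' @param sheet a [sample_sheet()] annotating the concentration samples
#' @param reference `c(condition, day)` of the reference group
#' @return data.frame: `condition`, `day`, `particles_per_cell`, `fold`
#' @export
particles_per_cell_fold <- function(particles, sheet,
                                    reference = c("Q", "D7")) {
  stopifnot(inherits(particles, "particle_table"))
  conc <- particles$concentration
  ann <- sheet_for(unique(conc$sample_id), sheet, "qpcr")
  ppc_rec <- conc$particles / conc$cells_for_secretion
  per_sample <- tapply(ppc_rec, conc$sample_id, mean)
  grp <- ann[match(names(per_sample), ann$sample_id),
             c("condition", "day")]
  agg <- stats::aggregate(list(particles_per_cell = as.numeric(per_sample)),
                          by = grp, FUN = mean)
  ref <- agg$particles_per_cell[agg$condition == reference[1] &
                                  agg$day == reference[2]]
  if (!length(ref))
    stop("reference group ", reference[1], "/", reference[2], " absent")
  agg$fold <- agg$particles_per_cell / ref
  agg[order(agg$condition, agg$day), ]
}

#' Total apoptotic fraction from Annexin-V / PI gating
#'
#' Total apoptotic cells = Annexin-V single-positive + double-positive +
#' PI single-positive, in percent of gated events.
#'
#' @param annexin_pct,double_pct,pi_pct gate percentages in `[0, 100]`,
#'   jointly summing to at most 100
#' @return total apoptotic percentage
#' @export
apoptosis_total <- function(annexin_pct, double_pct, pi_pct) {
  vals <- c(annexin_pct, double_pct, pi_pct)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("gate percentages must lie in [0, 100]")
  total <- annexin_pct + double_pct + pi_pct
  if (any(total > 100))
    stop("gate percentages sum to more than 100")
  total
}
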