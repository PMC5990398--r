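# Small fixtures shared across the suite; everything is built in code.

# minimal annotated design: n donors x {Q,SIPS} x days, one platform
toy_sheet <- function(donors = c("HDF1", "HDF2", "HDF3"),
                      days = c("D7", "D21"), platform = "qpcr",
                      cells_q = 1e7, cells_sips = 1e6) {
  g <- expand.grid(donor = donors, condition = c("Q", "SIPS"), day = days,
                   stringsAsFactors = FALSE)
  sample_sheet(data.frame(
    sample_id = paste(g$donor, g$condition, g$day, platform, sep = "_"),
    donor = g$donor, condition = g$condition, day = g$day,
    cells_for_secretion = ifelse(g$condition == "SIPS", cells_sips, cells_q),
    platform = platform, stringsAsFactors = FALSE))
}

both_sheet <- function(...) {
  q <- as.data.frame(toy_sheet(..., platform = "qpcr"))
  n <- as.data.frame(toy_sheet(..., platform = "ngs"))
  sample_sheet(rbind(q, n))
}

toy_ct <- function(values, sheet = NULL, spikein_ids = character(), ...) {
  ct_matrix(values, spikein_ids = spikein_ids, ...)
}

# correlation_input built directly from per-condition abundance vectors
toy_input <- function(intra_Q, intra_SIPS, extra_ct_Q, extra_ct_SIPS,
                      ids = NULL) {
  n <- length(intra_Q)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(n))
  out <- data.frame(mirna = ids,
                    intra_Q = intra_Q, intra_SIPS = intra_SIPS,
                    extra_ct_Q = extra_ct_Q, extra_ct_SIPS = extra_ct_SIPS,
                    extra_au_Q = au_transform(extra_ct_Q),
                    extra_au_SIPS = au_transform(extra_ct_SIPS),
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_input", "data.frame")
  out
}

# a matrix with sample names matching toy_sheet(qpcr), one day
named_matrix <- function(data, mirnas, samples) {
  matrix(data, nrow = length(mirnas), ncol = length(samples),
         dimnames = list(mirnas, samples))
}
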