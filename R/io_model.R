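# Default spike-in assay name patterns (extraction, RT and interplate controls
# of miRNA qPCR panels).
SPIKEIN_PATTERN <- "^(UniSp[0-9]+|cel-miR-39)"

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Vesicular qPCR Ct matrix
#'
#' Container for a miRNA x sample matrix of qPCR cycle-of-quantification (Ct)
#' values from a vesicle (sEV) miRNA panel. Not-detected (ND) wells are stored
#' as `NA`, which is deliberately distinct from a numeric Ct of 40: downstream
#' operations document whether they drop or bound ND values.
#'
#' @param values numeric matrix, rows = assays (miRNAs and spike-in controls),
#'   columns = samples; `NA` encodes not-detected. All finite values must be
#'   positive cycles.
#' @param detection_limit Ct threshold above which an assay is considered
#'   undetected for QC purposes (default 38 cycles).
#' @param spikein_ids character vector of row names that are spike-in /
#'   interplate-calibrator controls rather than miRNAs.
#'
#' @return An object of class `ct_matrix` with elements `values`,
#'   `detection_limit`, `spikein_ids`.
#' @export
ct_matrix <- function(values, detection_limit = 38, spikein_ids = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have miRNA row names and sample column names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate assay ids: ", paste(dup, collapse = ", "))
  fin <- values[is.finite(values)]
  if (any(fin <= 0))
    stop("all finite Ct values must be > 0")
  if (!all(spikein_ids %in% rownames(values)))
    stop("spikein_ids absent from matrix: ",
         paste(setdiff(spikein_ids, rownames(values)), collapse = ", "))
  structure(
    list(values = values,
         detection_limit = detection_limit,
         spikein_ids = as.character(spikein_ids)),
    class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays (%d spike-ins) x %d samples, limit %g\n",
              nrow(x$values), length(x$spikein_ids), ncol(x$values),
              x$detection_limit))
  invisible(x)
}

#' miRNA rows of a Ct matrix (spike-ins excluded)
#' @param ct a [ct_matrix()]
#' @return character vector of miRNA ids
#' @export
mirna_ids <- function(ct) setdiff(rownames(ct$values), ct$spikein_ids)

#' Ct values of the miRNA rows only
#' @param ct a [ct_matrix()]
#' @return numeric matrix
#' @export
mirna_values <- function(ct) ct$values[mirna_ids(ct), , drop = FALSE]

#' Read a Ct matrix from delimited text
#'
#' First column = assay id, header = sample ids. Cells that are empty, `NA`
#' or `ND` (case-insensitive) are mapped to the not-detected marker (`NA`).
#' Spike-in rows are recognised by `spikein_pattern` unless `spikein_ids`
#' is given explicitly.
#'
#' @param path file path (`.csv` is comma-, anything else tab-separated).
#' @param detection_limit see [ct_matrix()].
#' @param spikein_ids explicit control row names, or `NULL` to autodetect.
#' @param spikein_pattern regular expression for control assay names.
#' @return a [ct_matrix()]
#' @export
read_ct_matrix <- function(path, detection_limit = 38, spikein_ids = NULL,
                           spikein_pattern = SPIKEIN_PATTERN) {
  df <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2)
    stop("Ct table needs an id column and at least one sample column: ", path)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate miRNA rows in ", path, ": ", paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  nd <- raw == "" | toupper(trimws(raw)) %in% c("ND", "NA")
  num <- suppressWarnings(as.numeric(raw))
  bad <- !nd & is.na(num)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric Ct in row '%s', sample '%s'",
                 ids[i[1]], colnames(raw)[i[2]]))
  }
  num[nd] <- NA_real_
  vals <- matrix(num, nrow = length(ids),
                 dimnames = list(ids, colnames(raw)))
  if (is.null(spikein_ids))
    spikein_ids <- ids[grepl(spikein_pattern, ids, ignore.case = TRUE)]
  ct_matrix(vals, detection_limit = detection_limit, spikein_ids = spikein_ids)
}

#' Intracellular small-RNA-seq count matrix
#'
#' Raw miRNA counts plus derived tags-per-million (TPM). TPM columns each sum
#' to 1e6 over all annotated miRNAs.
#'
#' @param counts non-negative integer matrix, rows = miRNAs, columns = samples.
#' @return object of class `count_matrix` with elements `counts` and `tpm`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have miRNA row names and sample column names")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate miRNA rows: ", paste(dup, collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  tpm <- sweep(counts, 2, tot, "/") * 1e6
  structure(list(counts = counts, tpm = tpm), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples, median library %.3g\n",
              nrow(x$counts), ncol(x$counts),
              stats::median(colSums(x$counts))))
  invisible(x)
}

#' Read a count matrix from delimited text
#' @inheritParams read_ct_matrix
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  count_matrix(m)
}

SHEET_COLUMNS <- c("sample_id", "donor", "condition", "day",
                   "cells_for_secretion", "platform")

#' Sample sheet
#'
#' Annotation keying both platforms: one row per sample with donor, condition
#' (Q = quiescent control, SIPS = stress-induced premature senescence), day
#' post stress (D7/D21), viable cell count used for secretion, and platform
#' (`qpcr` for the vesicular panel, `ngs` for intracellular sequencing).
#' `(donor, condition, day, platform)` must uniquely identify a sample.
#'
#' @param df data.frame with columns `sample_id`, `donor`, `condition`,
#'   `day`, `cells_for_secretion`, `platform`.
#' @return validated data.frame of class `sample_sheet`
#' @export
sample_sheet <- function(df) {
  missing <- setdiff(SHEET_COLUMNS, names(df))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[SHEET_COLUMNS]
  for (col in c("sample_id", "donor", "condition", "day", "platform"))
    df[[col]] <- as.character(df[[col]])
  bad <- setdiff(unique(df$condition), c("Q", "SIPS"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (must be Q or SIPS)")
  bad <- setdiff(unique(df$day), c("D7", "D21"))
  if (length(bad))
    stop("unknown day label(s): ", paste(bad, collapse = ", "),
         " (must be D7 or D21)")
  bad <- setdiff(unique(df$platform), c("qpcr", "ngs"))
  if (length(bad))
    stop("unknown platform label(s): ", paste(bad, collapse = ", "))
  df$cells_for_secretion <- as.numeric(df$cells_for_secretion)
  if (any(!is.finite(df$cells_for_secretion)) ||
      any(df$cells_for_secretion <= 0))
    stop("cells_for_secretion must be positive")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  key <- paste(df$donor, df$condition, df$day, df$platform)
  if (anyDuplicated(key))
    stop("(donor, condition, day, platform) does not uniquely identify samples")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from delimited text
#' @inheritParams read_ct_matrix
#' @return a [sample_sheet()]
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.table(path, sep = guess_sep(path), header = TRUE,
                                 check.names = FALSE, quote = "\"",
                                 comment.char = ""))
}

# Assert every column of a data matrix is annotated on the right platform;
# returns the matching sheet rows in column order.
sheet_for <- function(cols, sheet, platform) {
  sub <- sheet[sheet$platform == platform, , drop = FALSE]
  missing <- setdiff(cols, sub$sample_id)
  if (length(missing))
    stop("sample column(s) not annotated in sample sheet (platform ",
         platform, "): ", paste(missing, collapse = ", "))
  sub[match(cols, sub$sample_id), , drop = FALSE]
}

#' Nanoparticle tracking (NTA) particle table
#'
#' @param tracks data.frame with columns `sample_id`, `size_nm`: one row per
#'   tracked particle.
#' @param concentration data.frame with columns `sample_id`, `replicate`,
#'   `particles` (total tracked-particle count for the preparation) and
#'   `cells_for_secretion`.
#' @return object of class `particle_table`
#' @export
particle_table <- function(tracks, concentration) {
  stopifnot(all(c("sample_id", "size_nm") %in% names(tracks)),
            all(c("sample_id", "replicate", "particles",
                  "cells_for_secretion") %in% names(concentration)))
  if (any(tracks$size_nm <= 0)) stop("particle sizes must be > 0")
  if (any(concentration$particles < 0)) stop("particle totals must be >= 0")
  if (any(concentration$cells_for_secretion <= 0))
    stop("cell counts must be > 0")
  structure(list(tracks = as.data.frame(tracks),
                 concentration = as.data.frame(concentration)),
            class = "particle_table")
}

#' Write a result table as delimited text
#'
#' Matrices are written with their row names in a leading `id` column;
#' data.frames are written as-is with a stable column order. Values keep full
#' double precision so that a write/read round trip is lossless to < 1e-9.
#'
#' @param table matrix or data.frame
#' @param path output path (`.csv` comma-, else tab-separated)
#' @return `path`, invisibly
#' @export
write_results <- function(table, path) {
  sep <- guess_sep(path)
  if (is.matrix(table)) {
    df <- data.frame(id = rownames(table), table, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(table)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- "NA"
    out
  })
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_results()]
#' @inheritParams read_ct_matrix
#' @return numeric matrix with `id` column as row names
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
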