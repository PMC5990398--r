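#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults match
#' the values used throughout the modules: detection limit 38 cycles,
#' spike-in robustness threshold 1 cycle, 5-TPM abundance filter with the
#' strict all-samples-of-a-donor rule, |log2FC| > 1 and raw p < 0.05 volcano
#' gates, 25/75 percentile classification, top-20 concordance lists.
#'
#' @param outdir output directory
#' @param seed top-level seed; all stage randomness derives from it
#' @param detection_limit,spikein_threshold,ipc_threshold QC parameters
#' @param min_tpm,tpm_rule TPM filter parameters
#' @param fc_threshold,p_threshold,criterion volcano parameters
#' @param lower_pct,upper_pct,k,quartile_rule secretion-scoring parameters
#' @param ref_cells per-cell normalization reference (`NULL` = largest)
#' @return object of class `run_config`
#' @export
run_config <- function(outdir = ".", seed = 1L,
                       detection_limit = 38, spikein_threshold = 1,
                       ipc_threshold = 1,
                       min_tpm = 5, tpm_rule = "all_samples_of_donor",
                       fc_threshold = 1, p_threshold = 0.05,
                       criterion = "raw_p",
                       lower_pct = 25, upper_pct = 75, k = 20,
                       quartile_rule = "and", ref_cells = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write a simulated dataset as plain delimited text
#'
#' Emits `ct.tsv` (ND cells written as `ND`), `counts.tsv`, `sheet.tsv`,
#' `nta_tracks.tsv`, `nta_concentration.tsv` and `truth.tsv`.
#'
#' @param sim output of [simulate_experiment()]
#' @param outdir directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ct_chr <- matrix(formatC(sim$ct$values, digits = 15, format = "g"),
                   nrow = nrow(sim$ct$values),
                   dimnames = dimnames(sim$ct$values))
  ct_chr[is.na(sim$ct$values)] <- "ND"
  utils::write.table(
    data.frame(mirna = rownames(ct_chr), ct_chr, check.names = FALSE),
    file.path(outdir, "ct.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_results(sim$counts$counts, file.path(outdir, "counts.tsv"))
  write_results(as.data.frame(sim$sheet), file.path(outdir, "sheet.tsv"))
  write_results(sim$particles$tracks, file.path(outdir, "nta_tracks.tsv"))
  write_results(sim$particles$concentration,
                file.path(outdir, "nta_concentration.tsv"))
  write_results(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory
#' @return list with `ct`, `counts`, `sheet`, `particles` and (if present)
#'   `truth`
#' @export
read_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("[io] missing input file: ", p)
    p
  }
  out <- list(
    ct = read_ct_matrix(need("ct.tsv")),
    counts = read_count_matrix(need("counts.tsv")),
    sheet = read_sample_sheet(need("sheet.tsv")))
  tr <- file.path(dir, "nta_tracks.tsv")
  co <- file.path(dir, "nta_concentration.tsv")
  if (file.exists(tr) && file.exists(co))
    out$particles <- particle_table(
      utils::read.table(tr, sep = "\t", header = TRUE),
      utils::read.table(co, sep = "\t", header = TRUE))
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp))
    out$truth <- utils::read.table(tp, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis chain and write a result bundle
#'
#' QC, the three normalizations, per-day donor-blocked differential
#' analysis on per-cell Ct, MCR Ct and log2 TPM, the dual rank/ratio
#' secretion scoring, NTA summaries, and a machine-readable JSON summary.
#' When the dataset carries planted ground truth, a confusion summary
#' against the predicted secretion classes is included. Deterministic given
#' the inputs and the configuration.
#'
#' @param data dataset list as from [read_dataset()] /
#'   [simulate_experiment()], or a directory path
#' @param config a [run_config()]
#' @return the summary list, invisibly; tables and `summary.json` are
#'   written to `config$outdir`
#' @export
run_report <- function(data, config = run_config()) {
  if (is.character(data)) data <- stage("io", read_dataset(data))
  for (nm in c("ct", "counts", "sheet"))
    if (is.null(data[[nm]])) stop("[io] dataset lacks component: ", nm)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  summary <- list(seed = config$seed)

  msg <- function(...) message("[sevcargo] ", sprintf(...))

  msg("qc")
  spq <- stage("qc", spikein_qc(data$ct, config$spikein_threshold,
                                config$ipc_threshold))
  det <- stage("qc", detection_summary(data$ct, data$sheet,
                                       config$detection_limit))
  write_results(spq, out("qc_spikein.tsv"))
  write_results(det$per_mirna, out("qc_detection.tsv"))
  summary$spikein_pass <- all(spq$pass[!spq$is_ipc])
  summary$detection_bins <- as.list(det$category_counts)
  summary$detected_all_donors <- sum(det$per_mirna$donors_detected ==
                                       length(unique(
                                         data$sheet$donor[data$sheet$platform == "qpcr"])))

  msg("normalize")
  percell <- stage("normalization",
                   per_cell_normalize(data$ct, data$sheet, config$ref_cells))
  mcr <- stage("normalization",
               global_mean_normalize(data$ct, config$detection_limit))
  tf <- stage("normalization",
              tpm_and_filter(data$counts, data$sheet, config$min_tpm,
                             config$tpm_rule))
  write_results(percell$values, out("norm_per_cell_ct.tsv"))
  write_results(mcr$values, out("norm_mcr_ct.tsv"))
  write_results(tf$norm$values, out("norm_log2_tpm.tsv"))
  summary$tpm_kept <- length(tf$kept)

  msg("differential")
  de_counts <- list()
  for (d in c("D7", "D21")) {
    for (sch in c("per_cell", "mcr", "tpm")) {
      nm <- switch(sch, per_cell = percell, mcr = mcr, tpm = tf$norm)
      res <- stage("differential",
                   run_differential(nm, data$sheet, day = d,
                                    fc_threshold = config$fc_threshold,
                                    p_threshold = config$p_threshold,
                                    criterion = config$criterion))
      write_results(res, out(sprintf("diff_%s_%s.tsv", sch, d)))
      de_counts[[sprintf("%s_%s", sch, d)]] <-
        list(up = sum(res$class == "up"),
             down = sum(res$class == "down"),
             tested = nrow(res))
    }
  }
  summary$de_counts <- de_counts

  msg("correlate")
  sec <- stage("secretion",
               secretion_pipeline(data$ct, data$counts, data$sheet,
                                  quartile_rule = config$quartile_rule,
                                  lower_pct = config$lower_pct,
                                  upper_pct = config$upper_pct,
                                  k = config$k))
  write_results(sec$scores, out("secretion_scores.tsv"))
  summary$filter_steps <- as.list(sec$filter$steps)
  summary$secretion_classes <- as.list(table(sec$scores$class))
  summary$concordance <- sec$concordance

  if (!is.null(data$particles)) {
    msg("evmetrics")
    ss <- stage("ev_metrics", size_summary(data$particles))
    fold <- stage("ev_metrics",
                  particles_per_cell_fold(data$particles, data$sheet))
    write_results(ss$histogram, out("nta_histogram.tsv"))
    write_results(fold, out("nta_fold.tsv"))
    summary$x50_median <- median(ss$x50)
    summary$sips_fold <-
      mean(fold$fold[fold$condition == "SIPS"])
  }

  if (!is.null(data$truth)) {
    conf <- stage("truth",
                  truth_report(data$truth,
                               data.frame(mirna = sec$scores$mirna,
                                          class = sec$scores$class)))
    write_results(conf, out("truth_confusion.tsv"))
    summary$truth <- list(
      sensitivity = setNames(as.list(conf$sensitivity), conf$class),
      specificity = setNames(as.list(conf$specificity), conf$class),
      misdirection_rate = attr(conf, "misdirection_rate"))
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      out[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  out
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
chr_or <- function(x, default) if (is.null(x)) default else as.character(x)

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `qc`, `normalize`,
#' `diff`, `correlate`, `evmetrics` (stage outputs for an existing dataset
#' directory) and `report` (the full chain). Invoke via the installed
#' `exec/sevcargo` script or directly:
#' `sev_cli(c("simulate", "--outdir", "d", "--seed", "7"))`.
#'
#' @param args character vector of command-line arguments
#' @return exit status, invisibly (0 on success)
#' @export
sev_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: sevcargo <simulate|qc|normalize|diff|correlate|",
            "evmetrics|report> [--options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  known <- c("simulate", "qc", "normalize", "diff", "correlate",
             "evmetrics", "report")
  if (!cmd %in% known) stop("unknown subcommand: ", cmd)
  opt <- parse_cli_args(args[-1])
  outdir <- chr_or(opt$outdir, ".")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (cmd == "simulate") {
    cfg <- generator_config(
      n_mirna = as.integer(num_or(opt$n_mirna, 375)),
      secretion_multiplier = num_or(opt$secretion_multiplier, 4),
      seed = as.integer(num_or(opt$seed, 1)))
    write_dataset(simulate_experiment(cfg), outdir)
    message("[sevcargo] simulated dataset written to ", outdir,
            " (seed ", cfg$seed, ")")
    return(invisible(0L))
  }

  dataset_dir <- chr_or(opt$dir, ".")
  rc <- run_config(outdir = outdir,
                   seed = as.integer(num_or(opt$seed, 1)),
                   detection_limit = num_or(opt$limit, 38),
                   min_tpm = num_or(opt$min_tpm, 5),
                   tpm_rule = chr_or(opt$tpm_rule, "all_samples_of_donor"),
                   fc_threshold = num_or(opt$fc_threshold, 1),
                   p_threshold = num_or(opt$p_threshold, 0.05),
                   criterion = chr_or(opt$criterion, "raw_p"),
                   lower_pct = num_or(opt$lower_pct, 25),
                   upper_pct = num_or(opt$upper_pct, 75),
                   k = num_or(opt$k, 20),
                   quartile_rule = chr_or(opt$quartile_rule, "and"))

  if (cmd == "report") {
    run_report(dataset_dir, rc)
    return(invisible(0L))
  }

  data <- read_dataset(dataset_dir)
  switch(cmd,
    qc = {
      write_results(spikein_qc(data$ct), file.path(outdir, "qc_spikein.tsv"))
      write_results(detection_summary(data$ct, data$sheet,
                                      rc$detection_limit)$per_mirna,
                    file.path(outdir, "qc_detection.tsv"))
    },
    normalize = {
      scheme <- chr_or(opt$scheme, "per_cell")
      nm <- switch(scheme,
        per_cell = per_cell_normalize(data$ct, data$sheet),
        mcr = global_mean_normalize(data$ct, rc$detection_limit),
        tpm = tpm_and_filter(data$counts, data$sheet, rc$min_tpm,
                             rc$tpm_rule)$norm,
        stop("unknown scheme: ", scheme))
      write_results(nm$values,
                    file.path(outdir, paste0("norm_", scheme, ".tsv")))
    },
    diff = {
      scheme <- chr_or(opt$scheme, "per_cell")
      day <- chr_or(opt$day, "both")
      nm <- switch(scheme,
        per_cell = per_cell_normalize(data$ct, data$sheet),
        mcr = global_mean_normalize(data$ct, rc$detection_limit),
        tpm = tpm_and_filter(data$counts, data$sheet, rc$min_tpm,
                             rc$tpm_rule)$norm,
        stop("unknown scheme: ", scheme))
      res <- run_differential(nm, data$sheet, day = day,
                              fc_threshold = rc$fc_threshold,
                              p_threshold = rc$p_threshold,
                              criterion = rc$criterion)
      write_results(res, file.path(outdir,
                                   sprintf("diff_%s_%s.tsv", scheme, day)))
    },
    correlate = {
      sec <- secretion_pipeline(data$ct, data$counts, data$sheet,
                                quartile_rule = rc$quartile_rule,
                                lower_pct = rc$lower_pct,
                                upper_pct = rc$upper_pct, k = rc$k)
      write_results(sec$scores, file.path(outdir, "secretion_scores.tsv"))
      jsonlite::write_json(list(steps = as.list(sec$filter$steps),
                                concordance = sec$concordance),
                           file.path(outdir, "correlate_log.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    evmetrics = {
      if (is.null(data$particles)) stop("[io] dataset has no NTA tables")
      ss <- size_summary(data$particles)
      write_results(ss$histogram, file.path(outdir, "nta_histogram.tsv"))
      write_results(particles_per_cell_fold(data$particles, data$sheet),
                    file.path(outdir, "nta_fold.tsv"))
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
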