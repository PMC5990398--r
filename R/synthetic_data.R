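# Run `code` with a deterministic RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic secretion experiment
#'
#' The defaults encode the design and effect sizes of the senescence
#' secretion study the generator emulates: 3 fibroblast donors, quiescent (Q)
#' vs stress-induced premature senescent (SIPS) cells sampled at day 7 and
#' day 21; a 4-fold increase of vesicles secreted per SIPS cell; roughly
#' 10-fold fewer cells available for SIPS vesicle preparations (1.65e6 vs
#' 1.50e7); small planted sets with altered per-vesicle composition (2 up,
#' 5 down) and intracellular differential expression (46 up, 36 down); and
#' ~12% of miRNAs each with senescence-dependent packaging bias towards
#' secretion or retention, so that ~24% of the analysable set is non-neutral.
#'
#' @param n_mirna number of panel miRNAs.
#' @param n_donors number of donors (blocking factor).
#' @param secretion_multiplier SIPS vesicles-per-cell divided by Q
#'   vesicles-per-cell.
#' @param frac_cargo_increased design target for the fraction of miRNAs with
#'   higher per-cell secretion in SIPS. This is *emergent* from the other
#'   parameters (everything not packaging-retained increases when the
#'   multiplier is 4); the field documents the stated world and is used only
#'   to sanity-check the configuration.
#' @param n_composition_up,n_composition_down miRNAs whose per-vesicle
#'   loading changes in SIPS independent of the global multiplier.
#' @param n_packaging_secreted,n_packaging_retained miRNAs with
#'   condition-dependent packaging bias (selective secretion / retention);
#'   the default is 12% each of the expected *analysable* set (the
#'   co-measurement filter keeps roughly 75% of the panel), so ~24% of
#'   analysed miRNAs are non-neutral. All planted subsets are drawn from
#'   the detectable abundance stratum (above the 30th percentile of latent
#'   abundance), since effects planted on miRNAs the filters discard are
#'   unrecoverable by construction.
#' @param intra_de_up,intra_de_down intracellular differential-expression
#'   set sizes.
#' @param intra_de_lfc,composition_lfc,packaging_lfc planted log2 effect
#'   sizes for the three signal types. The study does not quantify
#'   per-vesicle composition effects; these are order-of-magnitude defaults.
#' @param cells_q,cells_sips mean viable cells used for secretion;
#'   `cells_cv` their lognormal coefficients of variation (Q, SIPS).
#' @param ct_noise_sd qPCR measurement noise, cycles.
#' @param nb_dispersion negative-binomial dispersion of sequencing counts.
#' @param library_size_mean mean miRNA-mapped reads per NGS sample;
#'   `library_size_cv` its lognormal CV.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of the
#'   latent per-miRNA cellular abundance.
#' @param donor_sd per-donor, per-miRNA random effect (log2 scale), shared
#'   between platforms so that donor blocking is genuinely exercised.
#' @param vesicles_per_cell_q baseline vesicles secreted per Q cell.
#' @param ct_center Ct that a median-abundance miRNA reaches in a nominal Q
#'   sample; anchors the arbitrary-unit scale of the Ct model (base-2,
#'   100% PCR efficiency, AU = 10 at Ct 40, censored to ND above Ct 40).
#' @param nta_median_nm,nta_sdlog lognormal size distribution of tracked
#'   particles (median ~70 nm); `nta_tracks_per_sample` tracks per sample;
#'   `nta_replicates` technical replicates of the concentration readout;
#'   `particles_per_cell_q` baseline particles per Q cell;
#'   `particle_noise_sd` lognormal noise of particle totals.
#' @param spikein_cts named constant Ct levels of the spike-in controls;
#'   `spikein_noise_sd` their noise (cycles).
#' @param seed integer seed; the same config and seed give bit-identical
#'   output.
#' @return object of class `generator_config` (a validated list)
#' @export
generator_config <- function(n_mirna = 375,
                             n_donors = 3,
                             secretion_multiplier = 4,
                             frac_cargo_increased = 0.85,
                             n_composition_up = 2,
                             n_composition_down = 5,
                             n_packaging_secreted = round(0.12 * 0.75 * n_mirna),
                             n_packaging_retained = round(0.12 * 0.75 * n_mirna),
                             intra_de_up = 46,
                             intra_de_down = 36,
                             intra_de_lfc = 1.5,
                             composition_lfc = 1.5,
                             packaging_lfc = 2,
                             cells_q = 1.5e7,
                             cells_sips = 1.65e6,
                             cells_cv = c(Q = 0.33, SIPS = 0.30),
                             ct_noise_sd = 0.5,
                             nb_dispersion = 0.1,
                             library_size_mean = 5e6,
                             library_size_cv = 0.3,
                             abundance_meanlog = log(100),
                             abundance_sdlog = 1.8,
                             donor_sd = 0.25,
                             vesicles_per_cell_q = 150,
                             ct_center = 29,
                             nta_median_nm = 70,
                             nta_sdlog = 0.35,
                             nta_tracks_per_sample = 500,
                             nta_replicates = 3,
                             particles_per_cell_q = 2000,
                             particle_noise_sd = 0.1,
                             spikein_cts = c(UniSp2 = 19, UniSp4 = 24,
                                             UniSp5 = 29, UniSp6 = 21,
                                             "cel-miR-39" = 22,
                                             UniSp3_IPC = 20),
                             spikein_noise_sd = 0.1,
                             seed = 1L) {
  cfg <- as.list(environment())
  n_planted <- n_composition_up + n_composition_down +
    n_packaging_secreted + n_packaging_retained + intra_de_up + intra_de_down
  if (n_planted > floor(0.7 * n_mirna))
    stop("planted subsets (", n_planted, ") exceed the detectable stratum (",
         floor(0.7 * n_mirna), " of n_mirna = ", n_mirna, ")")
  if (frac_cargo_increased < 0 || frac_cargo_increased > 1)
    stop("frac_cargo_increased must be in [0, 1]")
  if (secretion_multiplier <= 0) stop("secretion_multiplier must be > 0")
  if (any(c(cells_q, cells_sips) <= 0)) stop("cell inputs must be > 0")
  if (n_donors < 1) stop("need at least one donor")
  class(cfg) <- "generator_config"
  cfg
}

au_from_ct <- function(ct) 10 * 2^(40 - ct)

#' Simulate a paired vesicular / intracellular miRNA experiment
#'
#' Generative model: (1) latent per-miRNA cellular abundance is lognormal,
#' with a per-donor multiplicative effect shared across platforms and
#' condition multipliers for the planted intracellular DE sets; (2)
#' per-vesicle loading is proportional to cellular abundance times the
#' planted packaging bias and composition factors (SIPS only); (3) the
#' vesicular molecule count of a sample is loading x vesicles-per-cell
#' (4-fold higher in SIPS by default) x viable cells; (4) the qPCR readout is
#' Ct = 40 - log2(AU/10) + noise with AU proportional to molecules, censored
#' to not-detected above Ct 40; (5) intracellular counts are
#' negative-binomial around abundance x library size; (6) spike-ins are
#' constant plus small noise; (7) NTA sizes are lognormal (median ~70 nm)
#' and particle totals scale with cells and the secretion multiplier.
#'
#' @param config a [generator_config()]
#' @return list with elements `ct` ([ct_matrix()]), `counts`
#'   ([count_matrix()]), `sheet` ([sample_sheet()]), `particles`
#'   ([particle_table()]) and `truth` (ground-truth data.frame, see
#'   [truth_report()]).
#' @export
simulate_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  mirnas <- sprintf("mir-%03d", seq_len(cfg$n_mirna))
  donors <- sprintf("HDF%d", seq_len(cfg$n_donors))
  design <- expand.grid(donor = donors, condition = c("Q", "SIPS"),
                        day = c("D7", "D21"), stringsAsFactors = FALSE)

  a <- rlnorm(cfg$n_mirna, cfg$abundance_meanlog, cfg$abundance_sdlog)

  # planted subsets: disjoint, drawn from the detectable abundance stratum
  # (bottom-quartile miRNAs are removed by the co-measurement filter, so
  # effects planted there would be unrecoverable by construction)
  eligible <- which(a >= quantile(a, 0.30))
  idx <- sample(eligible)
  take <- function(n) {
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  set_de_up <- take(cfg$intra_de_up)
  set_de_down <- take(cfg$intra_de_down)
  set_comp_up <- take(cfg$n_composition_up)
  set_comp_down <- take(cfg$n_composition_down)
  set_sec <- take(cfg$n_packaging_secreted)
  set_ret <- take(cfg$n_packaging_retained)

  de_sign <- integer(cfg$n_mirna)
  de_sign[set_de_up] <- 1L; de_sign[set_de_down] <- -1L
  comp_sign <- integer(cfg$n_mirna)
  comp_sign[set_comp_up] <- 1L; comp_sign[set_comp_down] <- -1L
  pack_sign <- integer(cfg$n_mirna)
  pack_sign[set_sec] <- 1L; pack_sign[set_ret] <- -1L

  truth <- data.frame(
    mirna = mirnas,
    intracellular_de = de_sign,
    composition_change = comp_sign,
    packaging_class = c("retained", "neutral", "secreted")[pack_sign + 2L],
    stringsAsFactors = FALSE)
  attr(truth, "secretion_multiplier") <- cfg$secretion_multiplier

  # donor effect (log2 sd donor_sd), shared by both platforms
  donor_fac <- matrix(2^rnorm(cfg$n_mirna * cfg$n_donors, 0, cfg$donor_sd),
                      cfg$n_mirna, cfg$n_donors, dimnames = list(mirnas, donors))

  cv2sdlog <- function(cv) sqrt(log(1 + cv^2))
  n_s <- nrow(design)
  is_sips <- design$condition == "SIPS"
  cells_mean <- ifelse(is_sips, cfg$cells_sips, cfg$cells_q)
  cells_sdlog <- cv2sdlog(unname(cfg$cells_cv[ifelse(is_sips, "SIPS", "Q")]))
  cells <- rlnorm(n_s, log(cells_mean) - cells_sdlog^2 / 2, cells_sdlog)

  vpc <- cfg$vesicles_per_cell_q *
    ifelse(is_sips, cfg$secretion_multiplier, 1)
  # AU scale anchored so a median-abundance miRNA in a nominal Q sample
  # reads ct_center
  au_coef <- au_from_ct(cfg$ct_center) /
    (exp(cfg$abundance_meanlog) * cfg$vesicles_per_cell_q * cfg$cells_q)

  sample_ids <- with(design, paste(donor, condition, day, sep = "_"))
  ct_vals <- matrix(NA_real_, cfg$n_mirna, n_s,
                    dimnames = list(mirnas, sample_ids))
  cnt_vals <- matrix(0, cfg$n_mirna, n_s,
                     dimnames = list(mirnas, sample_ids))
  lib_sdlog <- cv2sdlog(cfg$library_size_cv)
  lib_sizes <- rlnorm(n_s, log(cfg$library_size_mean) - lib_sdlog^2 / 2,
                      lib_sdlog)

  for (s in seq_len(n_s)) {
    d <- match(design$donor[s], donors)
    cond_mult <- if (is_sips[s]) 2^(de_sign * cfg$intra_de_lfc) else 1
    a_s <- a * donor_fac[, d] * cond_mult
    load_mult <- if (is_sips[s])
      2^(pack_sign * cfg$packaging_lfc + comp_sign * cfg$composition_lfc)
    else 1
    loading <- a_s * load_mult
    au <- loading * vpc[s] * cells[s] * au_coef
    ct <- 40 - log2(au / 10) + rnorm(cfg$n_mirna, 0, cfg$ct_noise_sd)
    ct[ct > 40] <- NA_real_  # below qPCR detection: not detected
    ct_vals[, s] <- ct
    mu <- a_s / sum(a_s) * lib_sizes[s]
    cnt_vals[, s] <- rnbinom(cfg$n_mirna, mu = mu,
                             size = 1 / cfg$nb_dispersion)
  }

  # spike-ins: constant across samples up to technical noise
  sp <- cfg$spikein_cts
  sp_vals <- matrix(rep(sp, n_s) + rnorm(length(sp) * n_s, 0,
                                         cfg$spikein_noise_sd),
                    length(sp), n_s, dimnames = list(names(sp), sample_ids))
  ct_full <- rbind(ct_vals, sp_vals)
  ct <- ct_matrix(ct_full, detection_limit = 38, spikein_ids = names(sp))

  # guard against the (extremely unlikely at defaults) all-zero NGS column
  zero <- colSums(cnt_vals) == 0
  if (any(zero)) cnt_vals[1, zero] <- 1
  counts <- count_matrix(cnt_vals)

  sheet <- sample_sheet(rbind(
    data.frame(sample_id = sample_ids, donor = design$donor,
               condition = design$condition, day = design$day,
               cells_for_secretion = cells, platform = "qpcr",
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(sample_ids, "_ngs"), donor = design$donor,
               condition = design$condition, day = design$day,
               cells_for_secretion = cells, platform = "ngs",
               stringsAsFactors = FALSE)))
  colnames(counts$counts) <- colnames(counts$tpm) <-
    paste0(sample_ids, "_ngs")

  tracks <- data.frame(
    sample_id = rep(sample_ids, each = cfg$nta_tracks_per_sample),
    size_nm = rlnorm(n_s * cfg$nta_tracks_per_sample,
                     log(cfg$nta_median_nm), cfg$nta_sdlog),
    stringsAsFactors = FALSE)
  conc <- expand.grid(replicate = seq_len(cfg$nta_replicates),
                      s = seq_len(n_s))
  conc <- data.frame(
    sample_id = sample_ids[conc$s],
    replicate = conc$replicate,
    particles = cells[conc$s] * cfg$particles_per_cell_q *
      ifelse(is_sips[conc$s], cfg$secretion_multiplier, 1) *
      rlnorm(nrow(conc), 0, cfg$particle_noise_sd),
    cells_for_secretion = cells[conc$s],
    stringsAsFactors = FALSE)
  particles <- particle_table(tracks, conc)

  list(ct = ct, counts = counts, sheet = sheet, particles = particles,
       truth = truth)
}

#' Confusion summary of predicted vs planted secretion classes
#'
#' @param truth ground-truth data.frame from [simulate_experiment()]
#'   (columns `mirna`, `packaging_class`).
#' @param predictions data.frame with columns `mirna` and `class`
#'   (levels secreted / retained / neutral), e.g. a secretion score table.
#'   miRNAs absent from `predictions` (dropped by upstream filters) count as
#'   neutral calls.
#' @return data.frame with one row per class: `n_true`, `tp`, `sensitivity`,
#'   `specificity`; the full 3x3 confusion matrix is attached as attribute
#'   `"confusion"`, and the direction-confusion rate (planted secreted
#'   called retained or vice versa) as attribute `"misdirection_rate"`.
#' @export
truth_report <- function(truth, predictions) {
  stopifnot(all(c("mirna", "packaging_class") %in% names(truth)),
            all(c("mirna", "class") %in% names(predictions)))
  unknown <- setdiff(predictions$mirna, truth$mirna)
  if (length(unknown))
    stop("predictions contain miRNAs absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  classes <- c("secreted", "retained", "neutral")
  pred <- predictions$class[match(truth$mirna, predictions$mirna)]
  pred[is.na(pred)] <- "neutral"
  tr <- factor(truth$packaging_class, classes)
  pr <- factor(pred, classes)
  conf <- table(truth = tr, predicted = pr)
  out <- data.frame(
    class = classes,
    n_true = as.integer(rowSums(conf)),
    tp = as.integer(diag(conf)),
    sensitivity = diag(conf) / rowSums(conf),
    specificity = vapply(classes, function(k) {
      neg <- tr != k
      sum(pr[neg] != k) / sum(neg)
    }, numeric(1)),
    row.names = NULL)
  planted <- tr %in% c("secreted", "retained")
  misdir <- sum(planted & pr != "neutral" & as.character(pr) != as.character(tr))
  attr(out, "confusion") <- conf
  attr(out, "misdirection_rate") <-
    if (any(planted)) misdir / sum(planted) else NA_real_
  out
}
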