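# design helper: values laid out over toy_sheet(qpcr) columns
blocked_data <- function(sheet, donor_off, cond_eff, day_eff = 0,
                         noise = 0, n_mirna = 1) {
  vals <- named_matrix(0, sprintf("m%02d", seq_len(n_mirna)),
                       sheet$sample_id)
  for (j in seq_len(ncol(vals))) {
    vals[, j] <- donor_off[sheet$donor[j]] +
      cond_eff * (sheet$condition[j] == "SIPS") +
      day_eff * (sheet$day[j] == "D21")
  }
  vals + matrix(rnorm(length(vals), 0, noise), nrow(vals))
}

test_that("zero-noise planted effects are recovered exactly", {
  sheet <- toy_sheet(platform = "ngs")
  off <- c(HDF1 = 1, HDF2 = 5, HDF3 = -2)
  vals <- blocked_data(sheet, off, cond_eff = 1.75, day_eff = 0.5)
  fit <- fit_blocked_model(normalized_matrix(vals, "log2_tpm"), sheet)
  expect_equal(fit$effect, 1.75, tolerance = 1e-9)
  expect_lt(fit$s2, 1e-18)
  # Ct-scale sign flip: a condition effect that *lowers* Ct is positive
  qsheet <- toy_sheet(platform = "qpcr")
  ct_vals <- -vals
  colnames(ct_vals) <- qsheet$sample_id   # same design order as ngs sheet
  fit_ct <- fit_blocked_model(normalized_matrix(ct_vals, "per_cell_ct"),
                              qsheet)
  expect_equal(fit_ct$effect, 1.75, tolerance = 1e-9)
})

test_that("donor offsets alone give a near-zero, non-significant effect", {
  set.seed(7)
  sheet <- toy_sheet(platform = "ngs")
  vals <- blocked_data(sheet, c(HDF1 = 3, HDF2 = 8, HDF3 = -1),
                       cond_eff = 0, noise = 0.3, n_mirna = 40)
  res <- moderate_and_test(fit_blocked_model(
    normalized_matrix(vals, "log2_tpm"), sheet))
  expect_lt(abs(mean(res$effect)), 0.15)
  expect_gt(mean(abs(res$t) < 3), 0.9)
})

test_that("blocked fit matches an independent lm() solve per miRNA", {
  set.seed(11)
  sheet <- toy_sheet(platform = "ngs", days = "D7")
  vals <- named_matrix(rnorm(5 * 6, 10, 2), sprintf("m%d", 1:5),
                       sheet$sample_id)
  fit <- fit_blocked_model(normalized_matrix(vals, "log2_tpm"), sheet,
                           day = "D7")
  for (i in 1:5) {
    df <- data.frame(y = vals[i, ], donor = factor(sheet$donor),
                     condition = factor(sheet$condition, c("Q", "SIPS")))
    lmf <- lm(y ~ donor + condition, df)
    expect_equal(fit$effect[i], unname(coef(lmf)["conditionSIPS"]),
                 tolerance = 1e-9)
    expect_equal(fit$s2[i], sum(resid(lmf)^2) / lmf$df.residual,
                 tolerance = 1e-9)
    expect_equal(fit$df, rep(lmf$df.residual, 5))
    se <- summary(lmf)$coefficients["conditionSIPS", "Std. Error"]
    expect_equal(sqrt(fit$s2[i]) * fit$se_factor[i], se, tolerance = 1e-9)
  }
})

test_that("incomplete miRNAs are dropped; rank deficiency is an error", {
  sheet <- toy_sheet(platform = "ngs", days = "D7")
  vals <- named_matrix(rnorm(12), c("ok", "holey"), sheet$sample_id)
  vals["holey", 3] <- NA
  fit <- fit_blocked_model(normalized_matrix(vals, "log2_tpm"), sheet,
                           day = "D7")
  expect_equal(fit$mirna, "ok")
  expect_equal(attr(fit, "dropped"), "holey")
  q_only <- sheet[sheet$condition == "Q", ]   # SIPS level empty -> aliased
  class(q_only) <- class(sheet)
  sub <- vals[, q_only$sample_id, drop = FALSE]
  expect_error(fit_blocked_model(normalized_matrix(sub, "log2_tpm"),
                                 q_only, day = "D7"), "rank-deficient")
})

test_that("prior_df = 0 reproduces the ordinary t-test; equal s2 collapse", {
  set.seed(3)
  sheet <- toy_sheet(platform = "ngs")
  vals <- blocked_data(sheet, c(HDF1 = 0, HDF2 = 1, HDF3 = 2), 0.5,
                       noise = 0.4, n_mirna = 30)
  fit <- fit_blocked_model(normalized_matrix(vals, "log2_tpm"), sheet)
  res0 <- moderate_and_test(fit, prior_df = 0)
  t_ord <- fit$effect / (sqrt(fit$s2) * fit$se_factor)
  expect_equal(res0$t, t_ord, tolerance = 1e-12)
  expect_equal(res0$p, 2 * pt(-abs(t_ord), fit$df), tolerance = 1e-12)

  fit_eq <- fit
  fit_eq$s2 <- rep(0.25, nrow(fit))
  res_eq <- moderate_and_test(fit_eq)
  expect_equal(res_eq$s2_post, rep(0.25, nrow(fit)))
  expect_equal(res_eq$s02[1], 0.25)
  expect_true(is.infinite(res_eq$d0[1]))
})

test_that("moment estimation recovers a known (d0, s02) prior", {
  # oracle: sample true variances from the scaled inverse-chi-square prior
  # (d0 = 4, s02 = 1), then observed s2 ~ sigma2 * chisq_d / d
  set.seed(19)
  d0 <- 4; s02 <- 1; d <- 8; n <- 50
  est <- replicate(100, {
    sigma2 <- d0 * s02 / rchisq(n, d0)
    s2 <- sigma2 * rchisq(n, d) / d
    fits <- data.frame(effect = 0, s2 = s2, df = d, se_factor = 1)
    res <- moderate_and_test(fits)
    c(d0 = res$d0[1], s02 = res$s02[1])
  })
  expect_lt(abs(median(est["d0", ]) - d0) / d0, 0.3)
  expect_lt(abs(median(est["s02", ]) - s02) / s02, 0.3)
})

test_that("moderated statistics agree with the limma oracle", {
  set.seed(23)
  sheet <- toy_sheet(platform = "ngs")
  n <- 60
  sigma <- sqrt(4 * 0.5 / rchisq(n, 4))      # heteroskedastic truth
  vals <- blocked_data(sheet, c(HDF1 = 0, HDF2 = 0.5, HDF3 = 1), 0.8,
                       noise = 0, n_mirna = n) +
    matrix(rnorm(n * 12, 0, sigma), n)
  nm <- normalized_matrix(vals, "log2_tpm")
  mine <- moderate_and_test(fit_blocked_model(nm, sheet))
  design <- model.matrix(~ factor(sheet$donor) + factor(sheet$day) +
                           factor(sheet$condition, c("Q", "SIPS")))
  eb <- limma::eBayes(limma::lmFit(vals, design))
  k <- ncol(design)
  expect_equal(mine$d0[1], eb$df.prior, tolerance = 1e-6)
  expect_equal(mine$s02[1], eb$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(eb$t[, k]), tolerance = 1e-8)
  expect_equal(mine$p, unname(eb$p.value[, k]), tolerance = 1e-8)
})

test_that("bh_adjust implements the step-up rule (hand + oracle checks)", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:5) {
    p <- runif(200)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))  # exact up to float rounding
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))   # nondecreasing in p-rank
  }
})

test_that("volcano classification gates on both fold change and p", {
  res <- data.frame(effect = c(1.5, 1.5, -0.5, -1.2),
                    p = c(0.01, 0.2, 0.001, 0.04),
                    q = c(0.2, 0.6, 0.01, 0.3))
  expect_equal(volcano_classify(res), c("up", "ns", "ns", "down"))
  expect_equal(volcano_classify(res, criterion = "q"),
               c("ns", "ns", "ns", "ns"))
})

test_that("null simulation is calibrated and moderation does not lose power", {
  set.seed(31)
  sheet <- toy_sheet(platform = "ngs")
  null_vals <- blocked_data(sheet, c(HDF1 = 0, HDF2 = 2, HDF3 = 4), 0,
                            noise = 0.5, n_mirna = 600)
  res <- run_differential(normalized_matrix(null_vals, "log2_tpm"), sheet)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.025)
  expect_lte(mean(res$q < 0.05), 0.05)

  eff_vals <- blocked_data(sheet, c(HDF1 = 0, HDF2 = 2, HDF3 = 4), 1,
                           noise = 0.5, n_mirna = 200)
  fit <- fit_blocked_model(normalized_matrix(eff_vals, "log2_tpm"), sheet)
  mod <- moderate_and_test(fit)
  ord <- moderate_and_test(fit, prior_df = 0)
  expect_gte(mean(mod$p < 0.05), mean(ord$p < 0.05))
})
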