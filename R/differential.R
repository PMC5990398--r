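#' Donor-blocked linear fit per miRNA
#'
#' Fits `value ~ donor + day + condition` (or `value ~ donor + condition`
#' when restricted to one day) by least squares to every miRNA with a
#' complete design (no missing cell; miRNAs with any ND/NA in the used
#' samples are dropped, matching the complete-dataset rule). The reported
#' effect is the SIPS-vs-Q contrast on the log2-abundance scale: for
#' Ct-scale schemes the regression coefficient's sign is flipped, since a
#' lower Ct means a more abundant miRNA.
#'
#' @param norm a [normalized_matrix()]
#' @param sheet a [sample_sheet()]
#' @param day `"both"` (pooled two-factor fit) or `"D7"`/`"D21"` (per-day
#'   contrast by subsetting)
#' @return data.frame with columns `mirna`, `effect` (log2FC SIPS vs Q),
#'   `s2` (residual variance), `df` (residual degrees of freedom),
#'   `se_factor` (unscaled standard error of the contrast, i.e.
#'   `sqrt([(X'X)^-1]_cc)`). Dropped miRNA ids are attached as attribute
#'   `"dropped"`.
#' @export
fit_blocked_model <- function(norm, sheet, day = c("both", "D7", "D21")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  day <- match.arg(day)
  platform <- if (is_ct_scheme(norm)) "qpcr" else "ngs"
  ann <- sheet_for(colnames(norm$values), sheet, platform)
  keep <- if (day == "both") rep(TRUE, nrow(ann)) else ann$day == day
  ann <- ann[keep, , drop = FALSE]
  Y <- norm$values[, keep, drop = FALSE]

  fac <- data.frame(donor = factor(ann$donor),
                    day = factor(ann$day),
                    condition = factor(ann$condition, c("Q", "SIPS")))
  form <- if (day == "both" && nlevels(fac$day) > 1)
    ~ donor + day + condition else ~ donor + condition
  X <- stats::model.matrix(form, fac)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")")
  cond_col <- "conditionSIPS"

  complete <- rowSums(is.na(Y)) == 0
  Yc <- Y[complete, , drop = FALSE]
  XtXinv <- solve(crossprod(X))
  coefs <- Yc %*% X %*% XtXinv            # n_mirna x p
  resid <- Yc - coefs %*% t(X)
  s2 <- rowSums(resid^2) / (n - p)
  eff <- coefs[, cond_col]
  if (is_ct_scheme(norm)) eff <- -eff
  out <- data.frame(mirna = rownames(Yc),
                    effect = unname(eff),
                    s2 = unname(s2),
                    df = n - p,
                    se_factor = sqrt(XtXinv[cond_col, cond_col]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped") <- rownames(Y)[!complete]
  attr(out, "scheme") <- norm$scheme
  out
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t-tests
#'
#' Shrinks per-miRNA residual variances towards a common prior and tests the
#' blocked-model contrast. The prior `(d0, s0^2)` is estimated by method of
#' moments on `log(s^2)`: under the scaled-F sampling model,
#' `E[log s^2]` and `Var[log s^2]` involve digamma/trigamma terms of both
#' the residual and the prior degrees of freedom; matching the observed mean
#' and variance of `log s^2` (after removing the known residual-df
#' contribution) yields `d0` via the inverse trigamma and then `s0^2`.
#' Posterior variances are `s~2 = (d0 s0^2 + d s^2) / (d0 + d)`, the
#' statistic is `t = effect / (s~ * se_factor)` on `d + d0` degrees of
#' freedom. When the observed spread of `log s^2` is no larger than the
#' sampling contribution, `d0 = Inf` and every variance collapses to the
#' common `s0^2`; if all `s^2` are identical that common value is used
#' directly. `prior_df = 0` disables moderation and reproduces the ordinary
#' t-test.
#'
#' @param fits data.frame from [fit_blocked_model()]
#' @param prior_df,prior_var optional fixed prior instead of the moment
#'   estimates (`prior_df = 0` means no moderation; `prior_var` is then
#'   ignored)
#' @return `fits` with added columns `s2_post`, `d0`, `s02`, `t`, `p`
#' @export
moderate_and_test <- function(fits, prior_df = NULL, prior_var = NULL) {
  stopifnot(all(c("effect", "s2", "df", "se_factor") %in% names(fits)))
  s2 <- fits$s2
  d <- fits$df
  if (is.null(prior_df)) {
    ok <- s2 > 0
    if (sum(ok) < 10)
      stop("need >= 10 positive residual variances to estimate the prior")
    e <- log(s2[ok]) - digamma(d[ok] / 2) + log(d[ok] / 2)
    emean <- mean(e)
    if (stats::sd(log(s2[ok])) < 1e-12) {
      # degenerate: no spread at all; the common variance is the prior
      d0 <- Inf
      s02 <- s2[ok][1]
    } else {
      evar <- sum((e - emean)^2) / (sum(ok) - 1) - mean(trigamma(d[ok] / 2))
      if (evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(emean)
      }
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 == 0) 0 else prior_var
    if (d0 > 0 && (is.null(prior_var) || prior_var <= 0))
      stop("prior_var must be positive when prior_df > 0")
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  tt <- fits$effect / (sqrt(s2_post) * fits$se_factor)
  df_tot <- d + d0
  p <- 2 * stats::pt(-abs(tt), df = df_tot)
  fits$s2_post <- s2_post
  fits$d0 <- d0
  fits$s02 <- s02
  fits$t <- tt
  fits$p <- p
  fits
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; ties are handled
#' stably (equal p get equal q).
#'
#' @param p vector of raw p-values in `[0, 1]` (NA allowed, passed through)
#' @return vector of BH-adjusted q-values, same order as `p`
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  }
  q
}

#' Volcano classification of differential results
#'
#' @param result data.frame with columns `effect` (log2FC) and the chosen
#'   criterion column (`p` or `q`)
#' @param fc_threshold absolute log2FC gate (default 1)
#' @param p_threshold significance gate (default 0.05)
#' @param criterion `"raw_p"` (column `p`) or `"q"` (column `q`)
#' @return character vector of labels `up`, `down`, `ns`
#' @export
volcano_classify <- function(result, fc_threshold = 1, p_threshold = 0.05,
                             criterion = c("raw_p", "q")) {
  criterion <- match.arg(criterion)
  crit <- result[[if (criterion == "raw_p") "p" else "q"]]
  fc <- result$effect
  cls <- rep("ns", nrow(result))
  cls[!is.na(crit) & crit < p_threshold & fc > fc_threshold] <- "up"
  cls[!is.na(crit) & crit < p_threshold & fc < -fc_threshold] <- "down"
  cls
}

#' Full differential pipeline for one matrix
#'
#' Convenience chain: [fit_blocked_model()] then [moderate_and_test()],
#' [bh_adjust()] and [volcano_classify()].
#'
#' @inheritParams fit_blocked_model
#' @inheritParams volcano_classify
#' @param prior_df,prior_var passed to [moderate_and_test()]
#' @return data.frame with all per-miRNA statistics plus `q` and `class`
#' @export
run_differential <- function(norm, sheet, day = c("both", "D7", "D21"),
                             fc_threshold = 1, p_threshold = 0.05,
                             criterion = c("raw_p", "q"),
                             prior_df = NULL, prior_var = NULL) {
  res <- moderate_and_test(fit_blocked_model(norm, sheet, day),
                           prior_df = prior_df, prior_var = prior_var)
  res$q <- bh_adjust(res$p)
  res$class <- volcano_classify(res, fc_threshold, p_threshold, criterion)
  res
}
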