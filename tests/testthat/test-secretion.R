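test_that("AU transform matches the Ct-40 anchor and base-2 model", {
  expect_identical(au_transform(40), 10)
  expect_identical(au_transform(39), 20)
  expect_identical(au_transform(30), 10240)
  expect_equal(au_transform(c(40, 39)), c(10, 20))
  expect_error(au_transform(NA_real_), "finite")
})

# hand-constructed 8-miRNA filter fixture: quartile step removes A,B
# (bottom-quartile mean abundance on BOTH platforms), zero-TPM step removes
# C, ND step removes D
filter_fixture <- function() {
  ids <- LETTERS[1:8]
  # column-major fill; row means: A1 B2 C30 D10 E12 F14 G16 H18
  tpm <- named_matrix(c(1, 2, 0, 10, 12, 14, 16, 18,
                        1, 2, 60, 10, 12, 14, 16, 18),
                      ids, c("n1", "n2"))
  ct <- named_matrix(39, ids, c("q1", "q2"))
  ct["A", ] <- 39; ct["B", ] <- 38.5; ct["C", ] <- 29
  ct["D", ] <- c(30, NA); ct["E", ] <- 25; ct["F", ] <- 26
  ct["G", ] <- 27; ct["H", ] <- 28
  list(ids = ids, tpm = normalized_matrix(tpm, "tpm"),
       ct = ct_matrix(ct))
}

test_that("correlation filter applies the four steps in order with counts", {
  fx <- filter_fixture()
  flt <- correlation_filter(fx$ids, fx$tpm, fx$ct)
  expect_equal(unname(flt$steps), c(8, 6, 5, 4))
  expect_setequal(flt$ids, c("E", "F", "G", "H"))
})

test_that("filter is the identity when nothing is low, zero or ND", {
  ids <- sprintf("m%d", 1:8)
  tpm <- named_matrix(seq(10, 80, 10), ids, "n1")
  ct <- named_matrix(seq(25, 32, 1), ids, "q1")
  # bottom quartile on tpm is m1/m2, on ct m7/m8: AND rule removes nothing
  flt <- correlation_filter(ids, normalized_matrix(tpm, "tpm"),
                            ct_matrix(ct))
  expect_equal(flt$ids, ids)
  # OR rule removes the union
  flt_or <- correlation_filter(ids, normalized_matrix(tpm, "tpm"),
                               ct_matrix(ct), quartile_rule = "or")
  expect_setequal(flt_or$ids, sprintf("m%d", 3:6))
})

test_that("rank scores follow the hand-ranked 3-miRNA toy", {
  # intra ranks equal in both conditions; extra order reverses in SIPS
  input <- toy_input(intra_Q = c(300, 200, 100),
                     intra_SIPS = c(300, 200, 100),
                     extra_ct_Q = c(25, 26, 27),
                     extra_ct_SIPS = c(27, 26, 25),
                     ids = c("A", "B", "C"))
  rs <- rank_scores(input)
  expect_equal(rs$rank_intra_Q, c(1, 2, 3))
  expect_equal(rs$rank_extra_Q, c(1, 2, 3))
  expect_equal(rs$rank_extra_SIPS, c(3, 2, 1))
  expect_equal(rs$drank_Q, c(0, 0, 0))
  expect_equal(rs$ddrank, c(-2, 0, 2))
})

test_that("tied extracellular Cts get average ranks", {
  input <- toy_input(intra_Q = c(3, 2, 1), intra_SIPS = c(3, 2, 1),
                     extra_ct_Q = c(25, 25, 30),
                     extra_ct_SIPS = c(25, 25, 30))
  rs <- rank_scores(input)
  expect_equal(rs$rank_extra_Q[1:2], c(1.5, 1.5))
})

test_that("ratio scores follow the vesicular/intracellular direction", {
  # intra constant; vesicular AU doubles in SIPS for X, halves for Y:
  # ddratio_raw = {X: 2, Y: 0.5}, mean 1.25 -> normalized {1.6, 0.4}
  input <- toy_input(intra_Q = c(100, 100), intra_SIPS = c(100, 100),
                     extra_ct_Q = c(30, 30),
                     extra_ct_SIPS = c(29, 31),    # -1 Ct = x2 AU
                     ids = c("X", "Y"))
  rt <- ratio_scores(input)
  expect_equal(rt$ddratio_raw, c(2, 0.5), tolerance = 1e-12)
  expect_equal(rt$ddratio, c(1.6, 0.4), tolerance = 1e-12)
  # no condition difference anywhere -> all 1; mean-1 identity
  flat <- toy_input(intra_Q = c(10, 20, 30), intra_SIPS = c(10, 20, 30),
                    extra_ct_Q = c(28, 29, 30), extra_ct_SIPS = c(28, 29, 30))
  rtf <- ratio_scores(flat)
  expect_equal(rtf$ddratio, rep(1, 3))
  set.seed(2)
  rnd <- toy_input(intra_Q = runif(40, 1, 100), intra_SIPS = runif(40, 1, 100),
                   extra_ct_Q = runif(40, 25, 35),
                   extra_ct_SIPS = runif(40, 25, 35))
  expect_equal(mean(ratio_scores(rnd)$ddratio), 1, tolerance = 1e-9)
})

test_that("zero intracellular abundance is flagged and excluded from the mean", {
  input <- toy_input(intra_Q = c(0, 100, 100), intra_SIPS = c(50, 100, 100),
                     extra_ct_Q = c(30, 30, 30),
                     extra_ct_SIPS = c(30, 29, 31))
  rt <- ratio_scores(input)
  expect_false(rt$valid[1])
  expect_true(is.na(rt$ddratio[1]))
  expect_equal(mean(rt$ddratio[rt$valid]), 1, tolerance = 1e-12)
})

test_that("dual-percentile classification needs concordance of both scores", {
  base <- c(-10, 0, 0, 0, 0, 0, 0, 10)
  sc <- data.frame(ddrank = base, ddratio = base)
  expect_equal(classify_selective(sc),
               c("retained", rep("neutral", 6), "secreted"))
  # extreme on ddrank only (ddratio flat) -> concordance fails, all neutral
  sc2 <- data.frame(ddrank = base, ddratio = rep(1, 8))
  expect_equal(classify_selective(sc2), rep("neutral", 8))
  # degenerate all-equal scores -> all neutral
  sc3 <- data.frame(ddrank = rep(1, 8), ddratio = rep(2, 8))
  expect_equal(classify_selective(sc3), rep("neutral", 8))
  expect_error(classify_selective(sc[1:3, ]), "at least 4")
})

test_that("method concordance reports rho, p and top-k overlaps", {
  set.seed(4)
  x <- rnorm(30)
  sc <- data.frame(mirna = sprintf("m%d", 1:30), ddrank = x,
                   ddratio = exp(x))           # strictly increasing map
  mc <- method_concordance(sc, k = 5)
  expect_equal(mc$rho, 1)
  expect_equal(mc$top_secreted_overlap, 5)
  expect_equal(mc$top_retained_overlap, 5)
  sc$ddratio <- -x
  expect_equal(method_concordance(sc)$rho, -1)
  sc$ddratio <- rep(1, 30)
  expect_true(is.na(method_concordance(sc)$rho))
})

test_that("condition-label swap negates ddrank and reciprocates ddratio_raw", {
  set.seed(9)
  n <- 25
  input <- toy_input(intra_Q = runif(n, 5, 500), intra_SIPS = runif(n, 5, 500),
                     extra_ct_Q = runif(n, 24, 34),
                     extra_ct_SIPS = runif(n, 24, 34))
  swapped <- input
  swapped[c("intra_Q", "intra_SIPS")] <- input[c("intra_SIPS", "intra_Q")]
  swapped[c("extra_ct_Q", "extra_ct_SIPS")] <-
    input[c("extra_ct_SIPS", "extra_ct_Q")]
  swapped[c("extra_au_Q", "extra_au_SIPS")] <-
    input[c("extra_au_SIPS", "extra_au_Q")]
  expect_equal(rank_scores(swapped)$ddrank, -rank_scores(input)$ddrank)
  expect_equal(ratio_scores(swapped)$ddratio_raw,
               1 / ratio_scores(input)$ddratio_raw, tolerance = 1e-12)
})

test_that("rank scores are invariant to monotone abundance transforms", {
  set.seed(10)
  n <- 20
  input <- toy_input(intra_Q = runif(n, 5, 500), intra_SIPS = runif(n, 5, 500),
                     extra_ct_Q = runif(n, 24, 34),
                     extra_ct_SIPS = runif(n, 24, 34))
  warped <- input
  warped$intra_Q <- log1p(input$intra_Q)          # increasing
  warped$intra_SIPS <- input$intra_SIPS^3
  warped$extra_ct_Q <- qnorm(input$extra_ct_Q / 50)  # increasing in Ct
  warped$extra_ct_SIPS <- exp(input$extra_ct_SIPS / 5)
  expect_equal(rank_scores(warped)$ddrank, rank_scores(input)$ddrank)
})

test_that("secretion_scores assembles ranks, ratios, quartiles and classes", {
  set.seed(12)
  n <- 40
  input <- toy_input(intra_Q = runif(n, 5, 500), intra_SIPS = runif(n, 5, 500),
                     extra_ct_Q = runif(n, 24, 34),
                     extra_ct_SIPS = runif(n, 24, 34))
  sc <- secretion_scores(input)
  expect_s3_class(sc, "secretion_scores")
  expect_equal(sc$ddrank, sc$drank_SIPS - sc$drank_Q)
  expect_true(all(sc$abundance_quartile %in% 1:4))
  expect_equal(unname(table(sc$abundance_quartile)), rep(10L, 4),
               ignore_attr = TRUE)
  expect_true(all(sc$class %in% c("secreted", "retained", "neutral")))
})
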