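# Window statistics: d_XY, Weir-Cockerham F_ST, ABBA-BABA D / f_D,
# RND_min, topology weights, Spearman track correlation.

one_window <- function(panel) make_windows(panel, span = panel$chrom_length,
                                           min_snps = 0)

test_that("dxy is zero for identical haplotypes and counts differences", {
  mat <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))
  panel <- toy_panel(mat, c("A", "A", "B", "B"), chrom_length = 50000)
  expect_equal(dxy(panel, "A", "B", one_window(panel)), 0)
  # 5 fixed differences over a 50-kb window -> 1e-4
  mat2 <- cbind(matrix(rep(c(1, 1, 0, 0), 5), 4), c(1, 1, 1, 1))
  p2 <- toy_panel(mat2, c("A", "A", "B", "B"), chrom_length = 50000)
  expect_equal(dxy(p2, "A", "B", one_window(p2)), 5 / 50000)
})

test_that("multi-haplotype dxy equals the brute-force pair average", {
  set.seed(11)
  mat <- matrix(rbinom(10 * 40, 1, 0.35), nrow = 10)
  panel <- toy_panel(mat, rep(c("A", "B"), each = 5), chrom_length = 4000,
                     positions = seq_len(40) * 100 - 1)
  got <- dxy(panel, "A", "B", one_window(panel))
  pairs <- expand.grid(i = 1:5, j = 6:10)
  brute <- mean(apply(pairs, 1, function(x)
    sum(mat[x[1], ] != mat[x[2], ]))) / 4000
  expect_equal(got, brute)
})

test_that("Weir-Cockerham F_ST hits 1 at fixed differences and ~0 at parity", {
  mat <- rbind(c(1, 1), c(1, 1), c(1, 1), c(0, 1),
               c(0, 1), c(0, 1), c(0, 1), c(1, 1))
  # site 1: fixed difference (A all 1, B all 0 after reorder below)
  matA <- rbind(matrix(1, 4, 1), matrix(0, 4, 1))
  panel <- toy_panel(cbind(matA, matA[8:1, , drop = FALSE]),
                     rep(c("A", "B"), each = 4))
  res <- weir_cockerham_fst(panel, "A", "B")
  expect_equal(res$per_snp$fst[1], 1)
  # identical frequencies: estimator noise is non-positive in expectation
  matE <- rbind(c(1), c(0), c(0), c(0), c(1), c(0), c(0), c(0))
  pe <- toy_panel(matE, rep(c("A", "B"), each = 4))
  expect_lte(weir_cockerham_fst(pe, "A", "B")$per_snp$fst[1], 0)
})

test_that("Weir-Cockerham components match hand-evaluated ANOVA sums", {
  # n = 4 + 4 haploid observations at one site
  xA <- c(1, 1, 1, 0); xB <- c(1, 0, 0, 0)
  panel <- toy_panel(cbind(c(xA, xB)), rep(c("A", "B"), each = 4))
  res <- weir_cockerham_fst(panel, "A", "B")
  # independent route: explicit sums of squares from raw observations
  pA <- mean(xA); pB <- mean(xB); pbar <- mean(c(xA, xB))
  ssb <- 4 * (pA - pbar)^2 + 4 * (pB - pbar)^2
  ssw <- sum((xA - pA)^2) + sum((xB - pB)^2)
  msb <- ssb / 1; msw <- ssw / 6
  nc <- (8 - (16 + 16) / 8) / 1
  a <- (msb - msw) / nc; b <- msw
  expect_equal(res$per_snp$a, a)
  expect_equal(res$per_snp$b, b)
  expect_equal(res$per_snp$fst, a / (a + b))
})

test_that("window F_ST is the ratio of summed components", {
  set.seed(3)
  mat <- matrix(rbinom(8 * 30, 1, 0.4), nrow = 8)
  panel <- toy_panel(mat, rep(c("A", "B"), each = 4), chrom_length = 3000,
                     positions = seq_len(30) * 100 - 1)
  w <- one_window(panel)
  res <- weir_cockerham_fst(panel, "A", "B", windows = w,
                            clamp_window = FALSE)
  expect_equal(res$per_window,
               sum(res$per_snp$a) / sum(res$per_snp$a + res$per_snp$b))
})

test_that("ABBA-BABA matches direct arithmetic", {
  # perfect ABBA site: p = (0, 1, 1, 0)
  panel <- freq_panel(cbind(P1 = 0, P2 = 1, P3 = 1, O = 0))
  fr <- site_frequencies(panel, "P1", "P2", "P3", "O")
  ab <- abba_baba(fr, one_window(panel))
  expect_equal(ab$abba_sum, 1)
  expect_equal(ab$baba_sum, 0)
  expect_equal(ab$D, 1)
  expect_equal(ab$f_D, 1)
  # p1 = p2 at all sites -> D = 0, f_D = 0
  p_eq <- freq_panel(cbind(P1 = c(0.4, 0.8), P2 = c(0.4, 0.8),
                           P3 = c(1, 1), O = c(0, 0)))
  fr2 <- site_frequencies(p_eq, "P1", "P2", "P3", "O")
  ab2 <- abba_baba(fr2, one_window(p_eq))
  expect_equal(ab2$D, 0)
  expect_equal(ab2$f_D, 0)
  # frequency oracle: p = (0.2, 0.8, 1.0, 0)
  p3 <- freq_panel(cbind(P1 = 0.2, P2 = 0.8, P3 = 1, O = 0))
  fr3 <- site_frequencies(p3, "P1", "P2", "P3", "O")
  ab3 <- abba_baba(fr3, one_window(p3))
  expect_equal(ab3$D, (0.64 - 0.04) / 0.68)
  expect_equal(ab3$f_D, 0.60 / 0.80)
  # no informative sites -> D undefined
  p0 <- freq_panel(cbind(P1 = 0.5, P2 = 0.5, P3 = 0, O = 0))
  fr0 <- site_frequencies(p0, "P1", "P2", "P3", "O")
  expect_true(is.na(abba_baba(fr0, one_window(p0))$D))
})

test_that("D is bounded and flips sign under P1/P2 swap", {
  set.seed(9)
  for (i in 1:5) {
    f <- cbind(P1 = runif(20), P2 = runif(20), P3 = runif(20), O = 0)
    panel <- freq_panel(f, n = c(P1 = 10, P2 = 10, P3 = 10, O = 2))
    fr12 <- site_frequencies(panel, "P1", "P2", "P3", "O")
    fr21 <- site_frequencies(panel, "P2", "P1", "P3", "O")
    w <- one_window(panel)
    d12 <- abba_baba(fr12, w)$D
    d21 <- abba_baba(fr21, w)$D
    expect_lte(abs(d12), 1)
    expect_equal(d12, -d21)
  }
})

test_that("rnd_min finds the minimum donor-recipient pair", {
  # one donor haplotype identical to a recipient -> rnd_min = 0
  mat <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0),  # donor
               c(1, 1, 0, 0), c(0, 0, 0, 1),  # recipient
               c(1, 0, 1, 1), c(1, 0, 1, 1))  # outgroup
  panel <- toy_panel(mat, c("D", "D", "R", "R", "O", "O"))
  res <- rnd_min(panel, "D", "R", "O", one_window(panel))
  expect_equal(res$rnd_min, 0)
  # all cross distances equal d, d_out = D0 -> ratio d / D0
  m2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 1, 1))
  p2 <- toy_panel(m2, c("D", "R", "O"))
  r2 <- rnd_min(p2, "D", "R", "O", one_window(p2))
  expect_equal(r2$d_min, 2 / 4)
  expect_equal(r2$d_out, mean(c(3 / 4, 3 / 4)))
  expect_equal(r2$rnd_min, (2 / 4) / (3 / 4))
})

test_that("rnd_min equals exhaustive pair enumeration on a 3x3 toy", {
  set.seed(21)
  mat <- matrix(rbinom(8 * 30, 1, 0.4), nrow = 8)
  panel <- toy_panel(mat, c(rep("D", 3), rep("R", 3), "O", "O"),
                     chrom_length = 3000, positions = seq_len(30) * 100 - 1)
  res <- rnd_min(panel, "D", "R", "O", one_window(panel))
  dists <- outer(1:3, 4:6, Vectorize(function(i, j)
    mean(mat[i, ] != mat[j, ])))
  expect_equal(res$d_min, min(dists))
  # and never exceeds the mean cross distance scaled by d_out
  expect_lte(res$rnd_min, mean(dists) / res$d_out)
})

test_that("topology weights recover a forced donor-recipient grouping", {
  # all P2 haplotypes carry a donor tract: P2 identical to P3, P1 apart
  mat <- rbind(matrix(0L, 2, 10),                       # O
               matrix(rep(c(1L, 0L), each = 5), 2, 10, byrow = TRUE), # P3
               matrix(rep(c(1L, 0L), each = 5), 2, 10, byrow = TRUE), # P2
               matrix(rep(c(0L, 1L), each = 5), 2, 10, byrow = TRUE)) # P1
  panel <- toy_panel(mat, rep(c("O", "P3", "P2", "P1"), each = 2))
  w <- make_windows(panel, span = panel$chrom_length, min_snps = 0)
  tw <- topology_weights(panel, w, list(O = "O", P3 = "P3", P2 = "P2",
                                        P1 = "P1"))
  expect_equal(tw$w_P3P2, 1)
  expect_equal(tw$w_species + tw$w_P3P2 + tw$w_P3P1, 1)
})

test_that("sampled topology weights converge to enumeration on a toy", {
  set.seed(14)
  mat <- matrix(rbinom(12 * 60, 1, 0.35), nrow = 12)
  panel <- toy_panel(mat, rep(c("O", "P3", "P2", "P1"), each = 3),
                     chrom_length = 6000,
                     positions = seq_len(60) * 100 - 1)
  w <- make_windows(panel, span = panel$chrom_length, min_snps = 0)
  taxa <- list(O = "O", P3 = "P3", P2 = "P2", P1 = "P1")
  full <- topology_weights(panel, w, taxa, enum_cap = 100)   # 81 combos
  sampled <- topology_weights(panel, w, taxa, enum_cap = 1,
                              n_quartets = 500, seed = 99)
  expect_true(all(abs(as.matrix(full[, 1:3]) -
                        as.matrix(sampled[, 1:3])) <= 0.05))
  expect_equal(rowSums(as.matrix(sampled[, 1:3])), 1)
})

test_that("Spearman track correlation matches hand-ranked computation", {
  expect_equal(correlate_tracks(1:6, (1:6)^2)$rho, 1)
  expect_equal(correlate_tracks(1:6, rev(1:6))$rho, -1)
  # 6-point hand example: sum of squared rank differences = 6
  a <- c(1, 2, 3, 4, 5, 6); b <- c(2, 1, 4, 3, 6, 5)
  expect_equal(correlate_tracks(a, b)$rho, 1 - 6 * 6 / (6 * 35))
  expect_error(correlate_tracks(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
})
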