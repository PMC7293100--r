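# The tract-level simulator: determinism, the closed-form tract-length law,
# marginal ancestry fractions, truth export.

test_that("no-admixture scenario yields no tracts and symmetric site patterns", {
  p <- scenario_params(chrom_length = 1e6, seed = 2, a = 0, m = 0,
                       n_hap = c(O = 2, P3 = 2, P1e = 8, P1w = 8, P2 = 8))
  sim <- simulate_panel(p)
  expect_equal(nrow(sim$truth$archaic), 0L)
  expect_equal(nrow(sim$truth$atlantic), 0L)
  # windowed D close to zero in the null
  w <- make_windows(sim$panel, span = 50000, min_snps = 1)
  fr <- site_frequencies(sim$panel, "P1e", "P2", "P3", "O")
  ab <- abba_baba(fr, w)
  expect_lt(abs(mean(ab$D, na.rm = TRUE)), 0.1)
})

test_that("the same seed reproduces the simulation exactly", {
  p <- scenario_params(chrom_length = 5e5, seed = 42)
  s1 <- simulate_panel(p)
  s2 <- simulate_panel(p)
  expect_identical(s1$panel$alleles, s2$panel$alleles)
  expect_identical(s1$panel$positions, s2$panel$positions)
  expect_identical(s1$truth$archaic, s2$truth$archaic)
})

test_that("mean archaic tract length follows the closed form", {
  expect_equal(expected_tract_length(0.1, 1e-8, 5000),
               1 / ((1 - 0.1) * 1e-8 * 4999))
  p <- scenario_params(chrom_length = 1e7, seed = 13, a = 0.1, r = 1e-8,
                       t_adm = 5000, m = 0,
                       n_hap = c(O = 2, P3 = 2, P1e = 2, P1w = 0, P2 = 16),
                       lambda_shared = 0, lambda_p1 = 0, lambda_p2 = 0,
                       lambda_p3 = 1e-4, lambda_out = 0)
  sim <- simulate_panel(p)
  tr <- sim$truth$archaic
  expect_gt(nrow(tr), 400)
  lens <- tr$end - tr$start
  # Monte-Carlo tolerance: 4 standard errors of the mean
  expect_lt(abs(mean(lens) - 22226.67), 4 * sd(lens) / sqrt(length(lens)))
})

test_that("marginal archaic fraction matches a outside RI and q_ri inside", {
  ri <- data.frame(start = 2e5, end = 4e5)
  p <- scenario_params(chrom_length = 1e6, seed = 8, a = 0.1, q_ri = 0.9,
                       m = 0, t_adm = 2000, r = 3e-8, ri_intervals = ri,
                       n_hap = c(O = 2, P3 = 2, P1e = 2, P1w = 0, P2 = 40))
  sim <- simulate_panel(p)
  tr <- sim$truth$archaic
  nh <- 40
  inside <- introscan:::interval_intersect(tr[, c("start", "end")], ri)
  outside <- introscan:::interval_setdiff(tr[, c("start", "end")], ri)
  frac_in <- introscan:::interval_bases(inside) / (nh * 2e5)
  frac_out <- introscan:::interval_bases(outside) / (nh * 8e5)
  expect_lt(abs(frac_in - 0.9), 3 * sqrt(0.9 * 0.1 / nh))
  expect_lt(abs(frac_out - 0.1), 0.05)
})

test_that("donor-diagnostic alleles in recipients lie on truth tracts when leak is off", {
  p <- scenario_params(chrom_length = 1e6, seed = 3, a = 0.2, m = 0.3,
                       p_leak = 0,
                       n_hap = c(O = 2, P3 = 2, P1e = 4, P1w = 4, P2 = 8))
  sim <- simulate_panel(p)
  panel <- sim$panel
  # diagnostic sites: derived in all P3, ancestral in outgroup
  diag_sites <- which(pop_freq(panel, "P3") == 1 & pop_freq(panel, "O") == 0 &
                        pop_freq(panel, c("P1e", "P1w", "P2")) > 0)
  tr_by_hap <- split(sim$truth$archaic, sim$truth$archaic$hap)
  for (h in rownames(panel$alleles)[panel$pop %in% c("P2", "P1w")]) {
    carried <- panel$positions[intersect(diag_sites,
                                         which(panel$alleles[h, ] == 1))]
    tt <- tr_by_hap[[h]]
    if (!length(carried)) next
    if (is.null(tt)) fail(paste("diagnostic allele off tract for", h))
    expect_true(all(introscan:::covered_at(
      carried, tt[order(tt$start), ])), label = h)
  }
})

test_that("tract length decreases with admixture age over a grid", {
  means <- vapply(c(500, 2000, 8000), function(t) {
    p <- scenario_params(chrom_length = 2e6, seed = 5, a = 0.15, m = 0,
                         t_adm = t, r = 3e-8,
                         n_hap = c(O = 2, P3 = 2, P1e = 2, P1w = 0, P2 = 10),
                         lambda_shared = 0, lambda_p1 = 0, lambda_p2 = 0,
                         lambda_p3 = 1e-4, lambda_out = 0)
    tr <- simulate_panel(p)$truth$archaic
    mean(tr$end - tr$start)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("degenerate tract scales are rejected with advice", {
  expect_error(simulate_panel(scenario_params(t_adm = 1e9, r = 1e-4,
                                              a = 0.5)),
               "rescale")
})

test_that("truth export writes BEDs that round-trip", {
  p <- scenario_params(chrom_length = 5e5, seed = 6,
                       n_hap = c(O = 2, P3 = 2, P1e = 4, P1w = 4, P2 = 4))
  sim <- simulate_panel(p)
  prefix <- tempfile()
  paths <- export_truth(sim$truth, prefix)
  bed <- read_bed(paths["archaic"])
  expect_equal(nrow(bed), nrow(sim$truth$archaic))
  expect_equal(bed$start, sim$truth$archaic$start)
  expect_equal(bed$name, sim$truth$archaic$hap)
  # empty class -> header-only file that reads back empty
  expect_equal(nrow(read_bed(paths["ri"])), 0L)
})
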