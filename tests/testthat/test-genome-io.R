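# Panel construction, VCF round trips, polarization and window tiling.

write_toy_vcf <- function(path, gts, pos = NULL, chrom = "chr1") {
  # gts: sites x samples character matrix of GT strings
  samples <- colnames(gts)
  if (is.null(pos)) pos <- seq_len(nrow(gts)) * 100
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=100000>", chrom),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(nrow(gts)))
    lines <- c(lines, paste(c(chrom, pos[i], ".", "A", "T", ".", "PASS",
                              ".", "GT", gts[i, ]), collapse = "\t"))
  writeLines(lines, path)
  path
}

write_toy_popmap <- function(path, samples, pops) {
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}

test_that("load_panel builds a complete matrix and drops half-called sites", {
  gts <- matrix(c("0|1", "1|1", "0|0",
                  "0|0", "0|1", "1|0",
                  "1|1", "0|0", "0|1",
                  "0|1", "./.", "0|0"), nrow = 4, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), gts)
  pm <- write_toy_popmap(tempfile(), c("a", "b", "c"), c("X", "X", "Y"))
  expect_message(panel <- load_panel(vcf, pm), "dropped 1 site")
  expect_equal(dim(panel$alleles), c(6L, 3L))  # site 4 dropped
  expect_equal(attr(panel, "n_dropped"), 1L)
  expect_equal(panel$positions, c(99, 199, 299))  # 0-based
  expect_equal(unname(panel$alleles[, 1]), c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(panel$pop, rep(c("X", "X", "Y"), each = 2))
})

test_that("load_panel errors on unknown samples and unphased genotypes", {
  gts <- matrix(c("0|1", "1|1"), nrow = 1,
                dimnames = list(NULL, c("a", "b")))
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), gts)
  pm_bad <- write_toy_popmap(tempfile(), c("a", "X"), c("X", "Y"))
  expect_error(load_panel(vcf, pm_bad), "absent from VCF.*X")

  gts2 <- matrix(c("0|1", "1/1"), nrow = 1,
                 dimnames = list(NULL, c("a", "b")))
  vcf2 <- write_toy_vcf(tempfile(fileext = ".vcf"), gts2)
  pm <- write_toy_popmap(tempfile(), c("a", "b"), c("X", "Y"))
  expect_error(load_panel(vcf2, pm), "unphased genotype for sample b")
})

test_that("write_panel / load_panel round-trips the allele matrix exactly", {
  set.seed(4)
  mat <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8)
  panel <- toy_panel(mat, rep(c("X", "Y"), each = 4),
                     positions = sort(sample(0:9999, 20)),
                     chrom_length = 10000)
  panel$sample <- rep(paste0("ind", 1:4), each = 2)
  vcf <- tempfile(fileext = ".vcf")
  write_panel(panel, vcf)
  pm <- write_toy_popmap(tempfile(), paste0("ind", 1:4),
                         rep(c("X", "Y"), each = 2))
  back <- load_panel(vcf, pm)
  expect_equal(unname(back$alleles), unname(panel$alleles))
  expect_equal(back$positions, panel$positions)
  expect_equal(back$chrom_length, 10000)
})

test_that("polarize flips by outgroup consensus and handles ties", {
  # site 1: outgroup fixed derived -> flipped; site 2: fixed ancestral ->
  # unchanged; site 3: outgroup 50/50 -> dropped under default rule
  mat <- rbind(c(1, 0, 1), c(1, 0, 0),   # outgroup
               c(0, 1, 1), c(1, 1, 0))   # ingroup
  panel <- toy_panel(mat, c("O", "O", "P", "P"), polarized = FALSE)
  pol <- polarize(panel, "O")
  expect_equal(n_sites(pol), 2L)
  expect_equal(attr(pol, "retained"), c(1L, 2L))
  expect_equal(unname(pol$alleles[, 1]), c(0L, 0L, 1L, 0L))  # flipped
  expect_equal(unname(pol$alleles[, 2]), c(0L, 0L, 1L, 1L))  # unchanged
  # "major" rule keeps the tie-free polymorphic outgroup sites
  mat2 <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))
  p2 <- toy_panel(mat2, c("O", "O", "O", "P"), polarized = FALSE)
  pol2 <- polarize(p2, "O", tie = "major")
  expect_equal(n_sites(pol2), 2L)
  expect_equal(unname(pol2$alleles[3, ]), c(0L, 1L))
})

test_that("polarization is an involution where the outgroup is fixed", {
  set.seed(7)
  mat <- rbind(matrix(rep(rbinom(30, 1, 0.5), each = 2), nrow = 2),
               matrix(rbinom(4 * 30, 1, 0.3), nrow = 4))
  panel <- toy_panel(mat, c("O", "O", rep("P", 4)), polarized = FALSE)
  once <- polarize(panel, "O")
  twice <- polarize(once, "O")
  expect_equal(twice$alleles, once$alleles)
  expect_true(all(pop_freq(once, "O") == 0))
})

test_that("make_windows tiles the chromosome and flags sparse windows", {
  panel <- toy_panel(matrix(1L, 2, 3), c("A", "A"),
                     positions = c(10, 60010, 60020), chrom_length = 120000)
  w <- make_windows(panel, span = 50000, min_snps = 2)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0, 50000, 100000))
  expect_equal(w$end, c(50000, 100000, 120000))  # terminal window shorter
  expect_equal(w$n_snps, c(1L, 2L, 0L))
  expect_equal(w$excluded, c(TRUE, FALSE, TRUE))
  # tiling covers [0, chrom_length) without gaps or overlaps
  expect_equal(w$start[-1], w$end[-nrow(w)])
  # empty panel: all zero counts, all excluded
  empty <- toy_panel(matrix(0L, 2, 0), c("A", "A"), positions = numeric(0),
                     chrom_length = 100000)
  w0 <- make_windows(empty, span = 50000, min_snps = 1)
  expect_true(all(w0$n_snps == 0) && all(w0$excluded))
})

test_that("BED and popmap round-trips preserve content", {
  bed <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(100, 9000),
                    name = c("h1", "h2"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_bed(bed, path)
  expect_equal(read_bed(path), bed)
  # empty BED keeps a header comment and reads back empty
  write_bed(bed[0, ], path)
  expect_equal(nrow(read_bed(path)), 0L)
  expect_match(readLines(path)[1], "^#")

  rm_path <- tempfile()
  writeLines(c("chrom\tr_M_per_bp", "chr1\t3.7e-8"), rm_path)
  rm <- read_recomb_map(rm_path)
  expect_equal(unname(rm["chr1"]), 3.7e-8)
  writeLines(c("chrom\tr", "chr1\t-1"), rm_path)
  expect_error(read_recomb_map(rm_path), "positive")
})
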