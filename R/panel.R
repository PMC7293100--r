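#' Construct a haplotype panel
#'
#' A `hap_panel` is the in-memory substrate of every statistic in the package:
#' a haplotype-by-site 0/1 allele matrix on one chromosome, with strictly
#' increasing site positions (0-based) and a population label per haplotype.
#' Allele code 1 means the derived (or ALT, if unpolarized) allele.
#'
#' @param alleles integer matrix, haplotypes in rows, sites in columns,
#'   entries 0/1, no missing values. Row names are haplotype ids.
#' @param positions integer vector of 0-based site coordinates, strictly
#'   increasing, one per column of `alleles`.
#' @param sample character vector: individual id of each haplotype.
#' @param pop character vector: population of each haplotype.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp; defaults to the last position
#'   plus one.
#' @param polarized logical, whether code 1 means outgroup-defined derived.
#' @return an object of class `hap_panel`.
#' @export
hap_panel <- function(alleles, positions, sample, pop, chrom = "chr1",
                      chrom_length = NULL, polarized = FALSE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(alleles) != length(positions))
    stop("number of sites in `alleles` and `positions` differ")
  if (nrow(alleles) != length(sample) || nrow(alleles) != length(pop))
    stop("`sample`/`pop` must have one entry per haplotype")
  if (anyNA(alleles))
    stop("hap_panel does not allow missing allele calls")
  if (length(positions) && !all(alleles %in% c(0L, 1L)))
    stop("allele codes must be 0/1 (biallelic sites only)")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (is.null(chrom_length))
    chrom_length <- if (length(positions)) max(positions) + 1 else 0
  if (length(positions) && max(positions) >= chrom_length)
    stop("positions must lie in [0, chrom_length)")
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0(sample, "_", stats::ave(seq_along(sample),
                                                        sample, FUN = seq_along))
  structure(list(
    chrom = chrom, chrom_length = as.numeric(chrom_length),
    positions = positions, alleles = alleles,
    sample = as.character(sample), pop = as.character(pop),
    polarized = isTRUE(polarized)
  ), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %s: %d haplotypes x %d sites (%s)\n",
              x$chrom, nrow(x$alleles), length(x$positions),
              if (x$polarized) "polarized" else "REF/ALT coding"))
  tab <- table(x$pop)
  cat("  populations:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a [hap_panel()].
#' @return integer count.
#' @export
n_haps <- function(panel) nrow(panel$alleles)

#' @rdname n_haps
#' @export
n_sites <- function(panel) length(panel$positions)

#' Row indices of the haplotypes belonging to a population
#' @param panel a [hap_panel()].
#' @param pop population label (or vector of labels).
#' @return integer vector of haplotype row indices.
#' @export
pop_haps <- function(panel, pop) {
  idx <- which(panel$pop %in% pop)
  if (!length(idx)) stop("no haplotypes found for population(s): ",
                         paste(pop, collapse = ", "))
  idx
}

#' Derived-allele frequency per site for one population
#' @inheritParams pop_haps
#' @return numeric vector of per-site frequencies in `[0, 1]`.
#' @export
pop_freq <- function(panel, pop) {
  idx <- pop_haps(panel, pop)
  colMeans(panel$alleles[idx, , drop = FALSE])
}

#' Subset a panel to a set of sites
#' @param panel a [hap_panel()].
#' @param keep logical mask or integer index over sites.
#' @return a [hap_panel()] restricted to the kept sites.
#' @export
subset_sites <- function(panel, keep) {
  panel$alleles <- panel$alleles[, keep, drop = FALSE]
  panel$positions <- panel$positions[keep]
  panel
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample`, `population`), with or without a header line.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample` and `population`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  if (identical(tolower(df$sample[1]), "sample")) df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a per-chromosome recombination map
#'
#' Two-column TSV (`chrom`, `r_M_per_bp`); rates are in Morgans per bp and
#' must be positive.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of rates, names are chromosomes.
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  r <- as.numeric(df[[2]])
  if (any(!is.finite(r)) || any(r <= 0))
    stop("recombination rates must be positive Morgans/bp")
  stats::setNames(r, df[[1]])
}

#' Load a phased haplotype panel from a VCF
#'
#' Reads phased diploid genotypes for the samples listed in a popmap, keeps
#' biallelic SNPs only, and drops every site with a missing genotype (the
#' panel is complete by construction). The number of dropped sites is
#' reported via `message()` and attached as attribute `"n_dropped"`. An
#' unphased genotype is an error naming the offending sample and site, as is
#' a popmap sample absent from the VCF.
#'
#' @param vcf_path path to a VCF (plain or bgzipped) with phased GT.
#' @param popmap_path path to the sample/population TSV (see [read_popmap()]).
#' @param region optional `list(chrom =, start =, end =)` restriction,
#'   0-based half-open.
#' @param chrom_length optional chromosome length (bp); defaults to the
#'   `##contig` header length when present.
#' @return a [hap_panel()] with two haplotypes per sample.
#' @export
load_panel <- function(vcf_path, popmap_path, region = NULL,
                       chrom_length = NULL) {
  popmap <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  as_fix_matrix <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    else x
  }
  fix <- as_fix_matrix(vcfR::getFIX(v))
  if (nrow(v@gt) == 0) stop("VCF contains no variant records")
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(popmap$sample, vcf_samples)
  if (length(missing))
    stop("samples in popmap absent from VCF: ", paste(missing, collapse = ", "))

  chroms <- unique(fix[, "CHROM"])
  if (!is.null(region)) {
    keep <- fix[, "CHROM"] == region$chrom &
      as.numeric(fix[, "POS"]) - 1 >= region$start &
      as.numeric(fix[, "POS"]) - 1 < region$end
    v <- v[keep, ]
    fix <- as_fix_matrix(vcfR::getFIX(v))
    chrom <- region$chrom
  } else if (length(chroms) > 1) {
    stop("VCF spans several chromosomes (", paste(chroms, collapse = ", "),
         "); supply `region` to pick one")
  } else chrom <- chroms

  biallelic <- vcfR::is.biallelic(v) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  v <- v[which(biallelic), ]
  fix <- as_fix_matrix(vcfR::getFIX(v))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, popmap$sample, drop = FALSE]
  unphased <- !is.na(gt) & grepl("^[01]/[01]$", gt)
  if (any(unphased)) {
    hit <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype for sample %s at %s:%s",
                 colnames(gt)[hit[2]], fix[hit[1], "CHROM"],
                 fix[hit[1], "POS"]))
  }
  phased_ok <- !is.na(gt) & grepl("^[01]\\|[01]$", gt)
  site_ok <- rowSums(phased_ok) == ncol(gt)
  n_dropped <- sum(!site_ok)
  if (n_dropped)
    message(sprintf("load_panel: dropped %d site(s) with missing or unphased genotypes",
                    n_dropped))
  gt <- gt[site_ok, , drop = FALSE]
  pos <- as.numeric(fix[site_ok, "POS"]) - 1

  nsam <- nrow(popmap)
  alleles <- matrix(0L, nrow = 2L * nsam, ncol = length(pos))
  hap_names <- character(2L * nsam)
  for (i in seq_len(nsam)) {
    g <- gt[, popmap$sample[i]]
    alleles[2L * i - 1L, ] <- as.integer(substr(g, 1L, 1L))
    alleles[2L * i, ] <- as.integer(substr(g, 3L, 3L))
    hap_names[c(2L * i - 1L, 2L * i)] <- paste0(popmap$sample[i], c("_1", "_2"))
  }
  rownames(alleles) <- hap_names

  if (is.null(chrom_length)) {
    m <- regmatches(v@meta, regexec(
      sprintf("##contig=<ID=%s,.*length=([0-9]+)", chrom), v@meta))
    len <- suppressWarnings(as.numeric(unlist(lapply(m, `[`, 2))))
    len <- len[is.finite(len)]
    chrom_length <- if (length(len)) len[1] else if (length(pos)) max(pos) + 1 else 0
  }
  out <- hap_panel(alleles, pos,
                   sample = rep(popmap$sample, each = 2),
                   pop = rep(popmap$population, each = 2),
                   chrom = chrom, chrom_length = chrom_length)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a panel as an uncompressed phased VCF
#'
#' The inverse of [load_panel()]: positions go out 1-based per the VCF
#' convention, genotypes as phased `a|b` pairs in haplotype row order.
#' REF/ALT are written as A/T placeholders when the panel has no nucleotide
#' information (allele codes are what the statistics consume).
#'
#' @param panel a [hap_panel()].
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  samples <- unique(panel$sample)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom,
            as.integer(panel$chrom_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (n_sites(panel)) {
    gt_cols <- vapply(samples, function(s) {
      rows <- which(panel$sample == s)
      paste0(panel$alleles[rows[1], ], "|", panel$alleles[rows[2], ])
    }, character(n_sites(panel)))
    if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = 1)
    lines <- paste(panel$chrom, format(panel$positions + 1, scientific = FALSE,
                                       trim = TRUE),
                   ".", "A", "T", ".", "PASS", ".", "GT",
                   apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Polarize a panel by outgroup consensus
#'
#' Flips allele codes so that the outgroup-consensus allele is 0 (ancestral)
#' at every retained site. Sites where the outgroup is polymorphic are
#' dropped under the default rule (`tie = "drop"`); with `tie = "major"` the
#' outgroup-major allele is taken as ancestral and only exact 50/50 ties are
#' dropped. Polarization is an involution on sites where the outgroup is
#' fixed.
#'
#' @param panel a [hap_panel()].
#' @param outgroup outgroup population label.
#' @param tie `"drop"` (default) or `"major"`.
#' @return a polarized [hap_panel()]; attribute `"retained"` holds the
#'   indices of the kept sites in the input panel.
#' @export
polarize <- function(panel, outgroup, tie = c("drop", "major")) {
  tie <- match.arg(tie)
  f_out <- pop_freq(panel, outgroup)
  keep <- if (tie == "drop") f_out %in% c(0, 1) else f_out != 0.5
  flip <- f_out > 0.5
  dropped <- sum(!keep)
  if (dropped)
    message(sprintf("polarize: dropped %d outgroup-ambiguous site(s)", dropped))
  out <- panel
  if (any(flip))
    out$alleles[, flip] <- 1L - out$alleles[, flip, drop = FALSE]
  out <- subset_sites(out, keep)
  out$polarized <- TRUE
  attr(out, "retained") <- which(keep)
  out
}

#' Tile a chromosome into nonoverlapping windows
#'
#' Windows start at position 0 and have the configured span; the terminal
#' window may be shorter. Windows with fewer than `min_snps` sites are
#' flagged `excluded` but retained in the table.
#'
#' @param panel a [hap_panel()] (supplies chromosome length and SNP counts).
#' @param span window span in bp (default 50,000).
#' @param min_snps minimum SNP count for a window to enter scans
#'   (default 500).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `excluded`.
#' @export
make_windows <- function(panel, span = 50000, min_snps = 500) {
  stopifnot(span > 0)
  len <- panel$chrom_length
  starts <- seq(0, max(len - 1, 0), by = span)
  ends <- pmin(starts + span, len)
  idx <- if (n_sites(panel))
    findInterval(panel$positions, starts) else integer(0)
  counts <- tabulate(idx, nbins = length(starts))
  data.frame(chrom = panel$chrom, start = starts, end = ends,
             n_snps = counts, excluded = counts < min_snps,
             stringsAsFactors = FALSE)
}

#' Map site positions to window indices
#' @param positions 0-based positions.
#' @param windows window table from [make_windows()].
#' @return integer window index per position.
#' @export
window_index <- function(positions, windows) {
  findInterval(positions, windows$start)
}

#' Read / write BED interval files
#'
#' Minimal plain-text BED3+ handling (0-based half-open, tab-separated,
#' optional `name` column, `#`/`track` lines ignored).
#'
#' @param path file path.
#' @return for `read_bed`, a data.frame with columns `chrom`, `start`,
#'   `end` and (when present) `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t")
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   start = as.numeric(vapply(parts, `[`, "", 2)),
                   end = as.numeric(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 4)) df$name <- vapply(parts, `[`, "", 4)
  df
}

#' @rdname read_bed
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED 0-based half-open", con)
  if (nrow(intervals)) {
    cols <- c("chrom", "start", "end", intersect("name", names(intervals)))
    mat <- intervals[, cols, drop = FALSE]
    mat$start <- format(mat$start, scientific = FALSE, trim = TRUE)
    mat$end <- format(mat$end, scientific = FALSE, trim = TRUE)
    writeLines(do.call(paste, c(unname(as.list(mat)), sep = "\t")), con)
  }
  invisible(path)
}
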