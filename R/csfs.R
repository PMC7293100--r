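## Site-frequency spectra of the recipient lineages conditioned on the
## donor species carrying the derived allele and the outgroup the ancestral
## one (the ABBA-BABA-informative site class), split by RI-island
## membership.

#' Conditioning mask for donor-derived sites
#'
#' Sites where the outgroup is fixed ancestral and the donor carries the
#' derived allele at frequency above `donor_min_freq` (default: present at
#' all, suited to a single sequenced donor genome).
#'
#' @param panel a polarized [hap_panel()].
#' @param outgroup,donor population labels.
#' @param donor_min_freq minimum donor derived-allele frequency (the site
#'   is kept when frequency is strictly greater, so 0 means "present").
#' @return logical mask over the panel's sites.
#' @export
conditioning_mask <- function(panel, outgroup, donor, donor_min_freq = 0) {
  if (!panel$polarized)
    warning("panel is not polarized; the mask assumes ALT = derived")
  pop_freq(panel, outgroup) == 0 & pop_freq(panel, donor) > donor_min_freq
}

#' Conditioned site frequency spectra split by RI membership
#'
#' Tallies derived-allele haplotype counts in the two recipient lineages at
#' masked sites into per-lineage spectra (CSFS) and their joint spectrum
#' (CJSFS), separately for sites inside and outside RI islands. CJSFS row
#' and column sums equal the corresponding CSFS vectors, and the total mass
#' per class equals the masked-site count of that class.
#'
#' @param panel a polarized [hap_panel()].
#' @param mask logical site mask from [conditioning_mask()].
#' @param ri_intervals data.frame of RI intervals (`start`, `end`), e.g.
#'   the `islands` element of an `ri_island_set` (may be empty).
#' @param p1,p2 recipient population labels (rows of the CJSFS index the
#'   P1 derived count, columns the P2 count).
#' @return list of class `conditioned_sfs` with elements `RI` and `nonRI`,
#'   each `list(csfs_p1, csfs_p2, cjsfs, n_sites)`; counts run 0..n
#'   haplotypes.
#' @export
build_csfs_cjsfs <- function(panel, mask, ri_intervals, p1, p2) {
  if (!any(mask)) message("build_csfs_cjsfs: empty conditioning mask")
  i1 <- pop_haps(panel, p1); i2 <- pop_haps(panel, p2)
  n1 <- length(i1); n2 <- length(i2)
  c1 <- colSums(panel$alleles[i1, , drop = FALSE])
  c2 <- colSums(panel$alleles[i2, , drop = FALSE])
  ri_intervals <- if (is.null(ri_intervals) || !nrow(ri_intervals))
    data.frame(start = numeric(), end = numeric())
  else merge_intervals(ri_intervals[, c("start", "end"), drop = FALSE])
  in_ri <- covered_at(panel$positions, ri_intervals)
  tally <- function(keep) {
    keep <- keep & mask
    jt <- matrix(0, n1 + 1, n2 + 1,
                 dimnames = list(0:n1, 0:n2))
    if (any(keep)) {
      tt <- table(factor(c1[keep], levels = 0:n1),
                  factor(c2[keep], levels = 0:n2))
      jt <- jt + unclass(tt)
    }
    list(csfs_p1 = rowSums(jt), csfs_p2 = colSums(jt), cjsfs = jt,
         n_sites = sum(keep))
  }
  structure(list(RI = tally(in_ri), nonRI = tally(!in_ri),
                 n1 = n1, n2 = n2), class = "conditioned_sfs")
}

#' Asymmetry of the high-frequency corners of a CJSFS
#'
#' Ratio of the mass where P2 is (nearly) fixed derived while P1 is rare,
#' over the mirrored corner (P1 nearly fixed, P2 rare), with a 0.5
#' continuity correction in numerator and denominator. Values above 1
#' indicate an excess of donor-derived alleles at high frequency in P2 but
#' low frequency in P1 — the signature of donor ancestry locally driven up
#' in one lineage and resisted by the other.
#'
#' @param sfs_class one class element (`RI` or `nonRI`) of
#'   [build_csfs_cjsfs()] output.
#' @param hi_frac,lo_frac corner definitions as fractions of the haplotype
#'   count (default: >= 80% derived vs <= 20%).
#' @return list with `asymmetry`, `mass_p2_high`, `mass_p1_high`.
#' @export
csfs_asymmetry <- function(sfs_class, hi_frac = 0.8, lo_frac = 0.2) {
  jt <- sfs_class$cjsfs
  n1 <- nrow(jt) - 1; n2 <- ncol(jt) - 1
  p1c <- as.integer(rownames(jt)); p2c <- as.integer(colnames(jt))
  m_p2hi <- sum(jt[p1c <= lo_frac * n1, p2c >= hi_frac * n2])
  m_p1hi <- sum(jt[p1c >= hi_frac * n1, p2c <= lo_frac * n2])
  list(asymmetry = (m_p2hi + 0.5) / (m_p1hi + 0.5),
       mass_p2_high = m_p2hi, mass_p1_high = m_p1hi)
}
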