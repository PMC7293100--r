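## Per-window divergence and introgression statistics on a haplotype panel.

# sum a per-site quantity into windows (NA-safe)
window_sum <- function(x, widx, n_windows) {
  out <- numeric(n_windows)
  agg <- tapply(x, widx, sum, na.rm = TRUE)
  out[as.integer(names(agg))] <- agg
  out
}

#' Absolute sequence divergence d_XY per window
#'
#' Mean pairwise difference per site between two populations, denominated by
#' the window span in bp (default; filtered sites are invisible so values
#' are a slight underestimate) or by the number of SNPs in the window.
#' The multi-haplotype value equals the average over all cross-population
#' haplotype pairs.
#'
#' @param panel a [hap_panel()].
#' @param popA,popB population labels.
#' @param windows window table from [make_windows()].
#' @param denom `"span"` (default) or `"sites"`.
#' @return numeric vector of per-window d_XY; windows with no usable
#'   denominator are `NA`.
#' @export
dxy <- function(panel, popA, popB, windows, denom = c("span", "sites")) {
  denom <- match.arg(denom)
  pA <- pop_freq(panel, popA)
  pB <- pop_freq(panel, popB)
  per_site <- pA * (1 - pB) + pB * (1 - pA)
  widx <- window_index(panel$positions, windows)
  tot <- window_sum(per_site, widx, nrow(windows))
  div <- if (denom == "span") windows$end - windows$start else windows$n_snps
  out <- tot / div
  out[div <= 0] <- NA_real_
  out
}

#' Weir & Cockerham (1984) F_ST for haploid samples
#'
#' Two-level ANOVA estimator treating each haplotype as one observation.
#' Per-SNP variance components: `a` (among populations) and `b` (within),
#' with theta = a / (a + b); the window value is the ratio of summed
#' components (ratio of averages). Negative per-SNP estimates are retained;
#' the window ratio may be clamped at 0 (`clamp_window = TRUE`, default).
#'
#' @param panel a [hap_panel()].
#' @param popA,popB population labels, each with >= 2 haplotypes.
#' @param windows optional window table; when supplied, per-window values
#'   are returned as well.
#' @param clamp_window clamp window-level ratios at 0.
#' @return list with `per_snp` (data.frame `pos`, `fst`, `a`, `b`) and,
#'   when `windows` is given, `per_window` (monomorphic windows are `NA`).
#' @export
weir_cockerham_fst <- function(panel, popA, popB, windows = NULL,
                               clamp_window = TRUE) {
  iA <- pop_haps(panel, popA); iB <- pop_haps(panel, popB)
  if (length(iA) < 2 || length(iB) < 2)
    stop("both populations need >= 2 haplotypes")
  n1 <- length(iA); n2 <- length(iB); nt <- n1 + n2; r <- 2
  p1 <- colMeans(panel$alleles[iA, , drop = FALSE])
  p2 <- colMeans(panel$alleles[iB, , drop = FALSE])
  pbar <- (n1 * p1 + n2 * p2) / nt
  msb <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - r)
  nc <- (nt - (n1^2 + n2^2) / nt) / (r - 1)
  a <- (msb - msw) / nc
  b <- msw
  fst <- ifelse(a + b == 0, NA_real_, a / (a + b))
  per_snp <- data.frame(pos = panel$positions, fst = fst, a = a, b = b)
  out <- list(per_snp = per_snp)
  if (!is.null(windows)) {
    widx <- window_index(panel$positions, windows)
    num <- window_sum(a, widx, nrow(windows))
    den <- window_sum(a + b, widx, nrow(windows))
    pw <- num / den
    pw[den == 0] <- NA_real_
    if (clamp_window) pw <- pmax(pw, 0)
    out$per_window <- pw
  }
  out
}

#' Site frequencies for the four-taxon tests
#'
#' Derived-allele frequencies in P1, P2, P3 and the outgroup at every site
#' of a polarized panel.
#'
#' @param panel a polarized [hap_panel()].
#' @param p1,p2,p3,outgroup population labels.
#' @return data.frame `pos`, `p1`, `p2`, `p3`, `p4`.
#' @export
site_frequencies <- function(panel, p1, p2, p3, outgroup) {
  if (!panel$polarized)
    warning("panel is not polarized; frequencies assume ALT = derived")
  data.frame(pos = panel$positions,
             p1 = pop_freq(panel, p1), p2 = pop_freq(panel, p2),
             p3 = pop_freq(panel, p3), p4 = pop_freq(panel, outgroup))
}

#' ABBA-BABA test: windowed Patterson's D and f_D
#'
#' Frequency-weighted site patterns on (((P1,P2),P3),O):
#' `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3 (1-p4)`, summed per
#' window. `D = (S_ABBA - S_BABA) / (S_ABBA + S_BABA)` measures the
#' imbalance; the admixture proportion estimator is
#' `f_D = S(P1,P2,P3,O) / S(P1,PD,PD,O)` with `S = S_ABBA - S_BABA` and the
#' dynamic donor `PD` chosen site-wise as whichever of P2/P3 has the higher
#' derived frequency. `f_D` is reported only where the window's `D` is
#' positive (the tested direction, P3 -> P2); elsewhere it is `NA`.
#'
#' @param freqs site frequencies from [site_frequencies()].
#' @param windows window table from [make_windows()].
#' @return data.frame per window: `abba_sum`, `baba_sum`, `D`, `f_D`
#'   (`D` is `NA` where `S_ABBA + S_BABA = 0`).
#' @export
abba_baba <- function(freqs, windows) {
  abba <- (1 - freqs$p1) * freqs$p2 * freqs$p3 * (1 - freqs$p4)
  baba <- freqs$p1 * (1 - freqs$p2) * freqs$p3 * (1 - freqs$p4)
  pd <- pmax(freqs$p2, freqs$p3)
  abba_d <- (1 - freqs$p1) * pd * pd * (1 - freqs$p4)
  baba_d <- freqs$p1 * (1 - pd) * pd * (1 - freqs$p4)
  widx <- window_index(freqs$pos, windows)
  nw <- nrow(windows)
  s_abba <- window_sum(abba, widx, nw)
  s_baba <- window_sum(baba, widx, nw)
  s_d <- window_sum(abba_d - baba_d, widx, nw)
  D <- ifelse(s_abba + s_baba > 0, (s_abba - s_baba) / (s_abba + s_baba),
              NA_real_)
  f_D <- ifelse(!is.na(D) & D >= 0 & s_d != 0, (s_abba - s_baba) / s_d,
                NA_real_)
  data.frame(abba_sum = s_abba, baba_sum = s_baba, D = D, f_D = f_D)
}

# per-window mismatch-proportion distance between two haplotype sets;
# returns a list of |A| x |B| matrices (denominator = SNPs in window)
pairwise_window_dist <- function(panel, idxA, idxB, windows) {
  widx <- window_index(panel$positions, windows)
  lapply(seq_len(nrow(windows)), function(w) {
    s <- which(widx == w)
    if (!length(s))
      return(matrix(NA_real_, length(idxA), length(idxB)))
    GA <- panel$alleles[idxA, s, drop = FALSE]
    GB <- panel$alleles[idxB, s, drop = FALSE]
    # mismatches between 0/1 rows: |A|x|B| via cross products
    d <- GA %*% (1 - t(GB)) + (1 - GA) %*% t(GB)
    d / length(s)
  })
}

#' RND_min: minimum donor-recipient distance scaled by outgroup divergence
#'
#' `d_min` is the minimum over donor x recipient haplotype pairs of the
#' per-site mismatch proportion in the window; `d_out` averages the mean
#' outgroup-donor and outgroup-recipient divergences; `rnd_min = d_min /
#' d_out`. Low values flag introgressed haplotypes while being robust to
#' mutation-rate variation. Distances are raw mismatch proportions (no
#' multiple-hit correction; divergences here are far from saturation).
#'
#' @param panel a [hap_panel()].
#' @param donor_pop,recipient_pop,outgroup_pop population labels.
#' @param windows window table from [make_windows()].
#' @return data.frame per window: `d_min`, `d_out`, `rnd_min` (`NA` where
#'   undefined, e.g. `d_out = 0` or empty window).
#' @export
rnd_min <- function(panel, donor_pop, recipient_pop, outgroup_pop, windows) {
  iD <- pop_haps(panel, donor_pop)
  iR <- pop_haps(panel, recipient_pop)
  iO <- pop_haps(panel, outgroup_pop)
  d_dr <- pairwise_window_dist(panel, iD, iR, windows)
  d_od <- pairwise_window_dist(panel, iO, iD, windows)
  d_or <- pairwise_window_dist(panel, iO, iR, windows)
  d_min <- vapply(d_dr, function(m) if (all(is.na(m))) NA_real_ else min(m),
                  numeric(1))
  d_out <- mapply(function(a, b) mean(c(mean(a), mean(b))), d_od, d_or)
  rnd <- ifelse(!is.na(d_out) & d_out > 0, d_min / d_out, NA_real_)
  data.frame(d_min = d_min, d_out = d_out, rnd_min = rnd)
}

# induced rooted-triplet topology of a quartet (o, x3, x2, x1) under the
# four-point condition on a tree metric D: the pairing with the smallest
# sum is the split. Returns weights over (species, P3P2, P3P1).
quartet_weights <- function(D, o, h3, h2, h1) {
  s_sp <- D[o, h3] + D[h2, h1]  # O with P3  -> (P1,P2) cherry: species tree
  s_32 <- D[o, h1] + D[h3, h2]  # O with P1  -> (P3,P2) cherry
  s_31 <- D[o, h2] + D[h3, h1]  # O with P2  -> (P3,P1) cherry
  s <- c(s_sp, s_32, s_31)
  best <- s == min(s)
  best / sum(best)
}

#' Topology weighting on per-window neighbor-joining trees
#'
#' For each (non-excluded) window, builds a neighbor-joining tree from raw
#' mismatch-proportion distances over all haplotypes of the four taxa, then
#' reads the induced quartet topology (rooted on the outgroup) for sampled
#' combinations of one haplotype per taxon. Weights are topology
#' proportions: `w_species` (P1 with P2), `w_P3P2` (donor grouped with P2),
#' `w_P3P1`. All combinations are enumerated when their number is at most
#' `enum_cap`, otherwise `n_quartets` are sampled uniformly (seeded). Ties
#' (zero-length internal branches) split their weight equally; windows
#' without informative sites get uniform weights and `degenerate = TRUE`.
#'
#' @param panel a [hap_panel()].
#' @param windows window table from [make_windows()].
#' @param taxa named list/vector with population labels `O`, `P3`, `P2`,
#'   `P1`.
#' @param n_quartets quartets to sample when not enumerating.
#' @param enum_cap full-enumeration threshold on the number of combinations.
#' @param seed RNG seed for quartet sampling.
#' @return data.frame per window: `w_species`, `w_P3P2`, `w_P3P1`,
#'   `degenerate` (excluded windows are `NA`).
#' @export
topology_weights <- function(panel, windows, taxa, n_quartets = 500,
                             enum_cap = 2000, seed = 1L) {
  io <- pop_haps(panel, taxa[["O"]]); i3 <- pop_haps(panel, taxa[["P3"]])
  i2 <- pop_haps(panel, taxa[["P2"]]); i1 <- pop_haps(panel, taxa[["P1"]])
  all_idx <- c(io, i3, i2, i1)
  widx <- window_index(panel$positions, windows)
  set.seed(seed)
  nw <- nrow(windows)
  out <- matrix(NA_real_, nw, 3,
                dimnames = list(NULL, c("w_species", "w_P3P2", "w_P3P1")))
  degen <- rep(NA, nw)
  n_comb <- length(io) * length(i3) * length(i2) * length(i1)
  for (w in seq_len(nw)) {
    if (windows$excluded[w]) next
    s <- which(widx == w)
    if (!length(s)) { out[w, ] <- 1 / 3; degen[w] <- TRUE; next }
    G <- panel$alleles[all_idx, s, drop = FALSE]
    dm <- (G %*% (1 - t(G)) + (1 - G) %*% t(G)) / length(s)
    rownames(dm) <- colnames(dm) <- as.character(all_idx)
    if (all(dm == 0)) { out[w, ] <- 1 / 3; degen[w] <- TRUE; next }
    tr <- ape::nj(stats::as.dist(dm))
    D <- ape::cophenetic.phylo(tr)
    if (n_comb <= enum_cap) {
      combs <- expand.grid(o = as.character(io), h3 = as.character(i3),
                           h2 = as.character(i2), h1 = as.character(i1),
                           stringsAsFactors = FALSE)
    } else {
      combs <- data.frame(o = as.character(sample(io, n_quartets, TRUE)),
                          h3 = as.character(sample(i3, n_quartets, TRUE)),
                          h2 = as.character(sample(i2, n_quartets, TRUE)),
                          h1 = as.character(sample(i1, n_quartets, TRUE)),
                          stringsAsFactors = FALSE)
    }
    acc <- c(0, 0, 0)
    for (q in seq_len(nrow(combs)))
      acc <- acc + quartet_weights(D, combs$o[q], combs$h3[q],
                                   combs$h2[q], combs$h1[q])
    out[w, ] <- acc / nrow(combs)
    degen[w] <- FALSE
  }
  data.frame(out, degenerate = degen)
}

#' Spearman correlation between two genome-wide window tracks
#'
#' Rank correlation on pairwise-complete windows; errors when fewer than 3
#' complete pairs remain.
#'
#' @param trackA,trackB numeric vectors aligned on the same windows.
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_tracks <- function(trackA, trackB) {
  if (length(trackA) != length(trackB))
    stop("tracks must be aligned on the same windows")
  ok <- stats::complete.cases(trackA, trackB)
  if (sum(ok) < 3) stop("fewer than 3 pairwise-complete windows")
  ct <- suppressWarnings(cor.test(trackA[ok], trackB[ok],
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
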