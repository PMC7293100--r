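## Two-panel haplotype-copying local-ancestry painting: a Li & Stephens
## type HMM whose hidden state is the reference haplotype currently being
## copied, with a uniform within-panel prior. The probability of ancestry A
## at a site is the total posterior mass on panel-A members.

#' Build a two-panel copying model
#'
#' @param panelA,panelB 0/1 allele matrices (haplotypes x sites) of the two
#'   reference panels (pure lineages), on identical site sets.
#' @param positions 0-based site positions shared by both panels.
#' @param switch_rate per-bp rate of switching copying template; the
#'   probability of a switch between adjacent sites at distance `d` bp is
#'   `1 - exp(-switch_rate * d)`. A practical choice is `r * t`, the
#'   recombination rate times the expected age (generations) of the tracts
#'   being painted.
#' @param mismatch per-site probability of disagreeing with the copied
#'   template. This absorbs both genotyping/copying error and divergence
#'   from the closest panel member, so it is interpreted on polymorphic
#'   sites (not bp); with finite, moderately diverged panels values around
#'   0.05-0.15 are realistic (default 0.1).
#' @return list of class `copying_model`.
#' @export
copying_model <- function(panelA, panelB, positions, switch_rate = 1e-5,
                          mismatch = 0.1) {
  panelA <- as.matrix(panelA); panelB <- as.matrix(panelB)
  stopifnot(ncol(panelA) == length(positions),
            ncol(panelB) == length(positions),
            switch_rate > 0, switch_rate < 1,
            mismatch > 0, mismatch < 1)
  structure(list(panelA = panelA, panelB = panelB,
                 positions = as.numeric(positions),
                 switch_rate = switch_rate, mismatch = mismatch),
            class = "copying_model")
}

#' Paint a focal haplotype against two reference panels
#'
#' Forward-backward over the joint copying state (which panel member is
#' being copied); deterministic. The prior gives each ancestry equal mass
#' (1/2), uniform within its panel, so unequal panel sizes do not bias the
#' call. The focal haplotype must not be a member of either panel.
#'
#' @param focal 0/1 allele vector on the model's site set.
#' @param model a [copying_model()].
#' @return data.frame with `pos` and `pA` (posterior probability of
#'   ancestry A per site).
#' @export
paint <- function(focal, model) {
  stopifnot(inherits(model, "copying_model"))
  KA <- nrow(model$panelA); KB <- nrow(model$panelB)
  if (!KA || !KB) stop("both reference panels must be non-empty")
  n <- length(model$positions)
  stopifnot(length(focal) == n)
  ref <- rbind(model$panelA, model$panelB)  # K x n
  match_mat <- t(ref) == rep(focal, times = 1)  # n x K
  emis <- ifelse(match_mat, 1 - model$mismatch, model$mismatch)
  d <- diff(model$positions)
  rho <- 1 - exp(-model$switch_rate * d)
  prior <- c(rep(0.5 / KA, KA), rep(0.5 / KB, KB))
  fb <- .fb_copying(emis, rho, prior)
  pA <- rowSums(fb$gamma[, seq_len(KA), drop = FALSE])
  data.frame(pos = model$positions, pA = pA)
}

#' Extract ancestry tracts from a posterior profile
#'
#' Sites where the posterior probability of the target (minor) ancestry
#' exceeds the threshold are grouped into tracts. Tract boundaries fall at
#' the midpoint between flanking sites of opposite call; terminal runs
#' extend to the chromosome ends. Gaps shorter than `merge_bp` are merged,
#' then tracts supported by fewer than `min_sites` sites are dropped.
#'
#' @param posterior data.frame from [paint()] (`pos`, `pA`).
#' @param chrom_length chromosome length in bp.
#' @param target `"A"` or `"B"`: which ancestry to extract tracts of.
#' @param threshold posterior call threshold (default 0.5).
#' @param merge_bp merge gaps shorter than this (default 1000).
#' @param min_sites minimum supporting sites per tract (default 5).
#' @return data.frame of tracts `start`, `end`, `n_sites`,
#'   `mean_posterior`; the rule parameters are attached as attributes.
#' @export
extract_tracts <- function(posterior, chrom_length, target = c("A", "B"),
                           threshold = 0.5, merge_bp = 1000, min_sites = 5) {
  target <- match.arg(target)
  if (nrow(posterior) < 2)
    stop("need posteriors at >= 2 sites to extract tracts")
  p <- if (target == "A") posterior$pA else 1 - posterior$pA
  pos <- posterior$pos
  call <- p > threshold
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_sites = integer(), mean_posterior = numeric())
  if (!any(call)) return(empty)
  r <- rle(call)
  iend <- cumsum(r$lengths)
  istart <- iend - r$lengths + 1
  on <- which(r$values)
  prev <- pmax(istart[on] - 1L, 1L)
  nxt <- pmin(iend[on] + 1L, length(pos))
  start <- ifelse(istart[on] == 1, 0, (pos[prev] + pos[istart[on]]) / 2)
  end <- ifelse(iend[on] == length(pos), chrom_length,
                (pos[iend[on]] + pos[nxt]) / 2)
  tr <- data.frame(start = start, end = end,
                   istart = istart[on], iend = iend[on])
  # merge short gaps
  if (nrow(tr) > 1 && merge_bp > 0) {
    keep <- list(tr[1, ])
    for (k in 2:nrow(tr)) {
      last <- keep[[length(keep)]]
      if (tr$start[k] - last$end < merge_bp) {
        last$end <- tr$end[k]; last$iend <- tr$iend[k]
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1]] <- tr[k, ]
    }
    tr <- do.call(rbind, keep)
  }
  tr$n_sites <- mapply(function(i, j) sum(call[i:j]), tr$istart, tr$iend)
  tr$mean_posterior <- mapply(function(i, j) mean(p[i:j][call[i:j]]),
                              tr$istart, tr$iend)
  tr <- tr[tr$n_sites >= min_sites, c("start", "end", "n_sites",
                                      "mean_posterior"), drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "rule") <- list(threshold = threshold, merge_bp = merge_bp,
                           min_sites = min_sites)
  tr
}

#' F_intro: fraction of haplotypes on an introgressed tract
#'
#' Per-position (bin-resolution) fraction of haplotypes covered by an
#' introgressed tract, averaged in nonoverlapping 50-kb windows.
#'
#' @param tract_sets named list (per haplotype) of tract data.frames.
#' @param chrom_length chromosome length in bp.
#' @param bin_bp per-position resolution (default 1000).
#' @param window_bp aggregation window (default 50,000).
#' @return list with `per_bin` and `per_window` (see
#'   [coverage_fraction()]).
#' @export
f_intro <- function(tract_sets, chrom_length, bin_bp = 1000,
                    window_bp = 50000) {
  if (!length(tract_sets)) stop("need tracts from >= 1 haplotype")
  coverage_fraction(tract_sets, chrom_length, bin_bp, window_bp)
}

#' Paint a whole population and compute F_intro
#'
#' Paints every haplotype of the focal population against the two panels,
#' extracts tracts of the introgressing ancestry (panel A), and aggregates
#' coverage to F_intro.
#'
#' @param panel a [hap_panel()].
#' @param focal_pop population to paint.
#' @param panelA_pop,panelB_pop reference populations (A = introgressing
#'   lineage, B = the focal population's own background lineage).
#' @param switch_rate,mismatch see [copying_model()].
#' @param ... tract-rule knobs passed to [extract_tracts()].
#' @return list with `tracts` (per haplotype), `f_intro`, `posteriors`.
#' @export
paint_population <- function(panel, focal_pop, panelA_pop, panelB_pop,
                             switch_rate = 1e-5, mismatch = 0.1, ...) {
  iF <- pop_haps(panel, focal_pop)
  model <- copying_model(panel$alleles[pop_haps(panel, panelA_pop), ,
                                       drop = FALSE],
                         panel$alleles[pop_haps(panel, panelB_pop), ,
                                       drop = FALSE],
                         panel$positions, switch_rate, mismatch)
  haps <- rownames(panel$alleles)[iF]
  tracts <- vector("list", length(haps)); names(tracts) <- haps
  posts <- vector("list", length(haps)); names(posts) <- haps
  for (k in seq_along(iF)) {
    po <- paint(panel$alleles[iF[k], ], model)
    posts[[k]] <- po
    tracts[[k]] <- extract_tracts(po, panel$chrom_length, target = "A", ...)
  }
  list(tracts = tracts,
       f_intro = f_intro(tracts, panel$chrom_length),
       posteriors = posts)
}
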