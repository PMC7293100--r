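## Reference-free detection of archaic introgressed tracts per haplotype
## from local excesses of private variants: a two-state (native/archaic)
## hidden Markov model with Poisson emissions on per-bin private-variant
## counts, fitted per haplotype by Baum-Welch.

#' Per-haplotype private-variant counts in bins
#'
#' A variant is private to the focal population when its derived allele is
#' absent from every haplotype of the comparison (non-admixed) population.
#' For each focal haplotype, counts the private variants it carries in
#' nonoverlapping bins tiling the chromosome.
#'
#' @param panel a polarized [hap_panel()].
#' @param focal_pop candidate recipient population label.
#' @param reference_pop non-admixed comparison population label.
#' @param bin_bp bin size in bp (default 1000).
#' @return list with `counts` (bins x focal haplotypes matrix),
#'   `bin_start` (0-based bin starts) and `bin_bp`.
#' @export
private_counts <- function(panel, focal_pop, reference_pop, bin_bp = 1000) {
  i_f <- pop_haps(panel, focal_pop)
  i_r <- pop_haps(panel, reference_pop)
  ref_freq <- colMeans(panel$alleles[i_r, , drop = FALSE])
  private <- ref_freq == 0
  bin_start <- seq(0, max(panel$chrom_length - 1, 0), by = bin_bp)
  nb <- length(bin_start)
  pos_bin <- findInterval(panel$positions, bin_start)
  counts <- vapply(i_f, function(i) {
    carried <- private & panel$alleles[i, ] == 1L
    tabulate(pos_bin[carried], nbins = nb)
  }, integer(nb))
  colnames(counts) <- rownames(panel$alleles)[i_f]
  list(counts = counts, bin_start = bin_start, bin_bp = bin_bp)
}

#' Two-state Poisson HMM parameters
#'
#' States are `native` (low private-variant rate `lambda_nat`) and
#' `archaic` (high rate `lambda_arc`). `trans[1, 2]` is the
#' native-to-archaic transition probability per bin, the quantity the
#' transition-parameter dating method consumes.
#'
#' @param lambda_nat,lambda_arc Poisson rates per bin.
#' @param p_na,p_an native->archaic and archaic->native transition
#'   probabilities per bin.
#' @return list of class `archaic_hmm_model`.
#' @export
archaic_hmm_model <- function(lambda_nat, lambda_arc, p_na = 1e-3,
                              p_an = 1e-2) {
  stopifnot(lambda_nat >= 0, lambda_arc >= 0,
            p_na > 0, p_na < 1, p_an > 0, p_an < 1)
  trans <- rbind(c(1 - p_na, p_na), c(p_an, 1 - p_an))
  init <- c(p_an, p_na) / (p_na + p_an)  # stationary distribution
  structure(list(lambda = c(nat = lambda_nat, arc = lambda_arc),
                 trans = trans, init = init),
            class = "archaic_hmm_model")
}

# default initialization: lambda_nat from the 25th percentile of nonzero
# bin counts, lambda_arc 10x larger, p = 1e-3 (robust label assignment)
init_archaic_model <- function(counts) {
  nz <- counts[counts > 0]
  base <- if (length(nz)) stats::quantile(nz, 0.25, names = FALSE) else 0.5
  base <- max(base * 0.75, 0.05)
  archaic_hmm_model(lambda_nat = base, lambda_arc = 10 * base)
}

#' Fit the archaic HMM to one haplotype and decode posteriors
#'
#' Baum-Welch until the log-likelihood increase falls below `tol`
#' (default 1e-6) or `max_iter` iterations, then forward-backward
#' posteriors. Label switching is resolved by ordering the Poisson rates;
#' a degenerate fit (`lambda_arc <= lambda_nat`) flags the haplotype as
#' no-call.
#'
#' @param counts integer vector of per-bin private-variant counts
#'   (>= 100 bins).
#' @param init an [archaic_hmm_model()]; defaults to a quantile-based
#'   initialization.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum Baum-Welch iterations.
#' @return list with `model` (fitted), `posterior` (per-bin P(archaic)),
#'   `loglik` (trace, non-decreasing), `converged`, `no_call`.
#' @export
fit_and_decode <- function(counts, init = NULL, tol = 1e-6, max_iter = 500) {
  counts <- as.numeric(counts)
  if (length(counts) < 100)
    stop("need >= 100 bins to fit the archaic HMM")
  model <- if (is.null(init)) init_archaic_model(counts) else init
  lam <- pmax(model$lambda, 1e-8)
  trans <- model$trans
  init_p <- model$init
  llh <- -Inf; trace <- numeric(0); converged <- FALSE
  for (iter in seq_len(max_iter)) {
    emis <- cbind(dpois(counts, lam[1]), dpois(counts, lam[2]))
    fb <- .fb_hmm(emis, trans, init_p)
    trace <- c(trace, fb$loglik)
    if (is.finite(llh) && fb$loglik - llh < tol) { converged <- TRUE; break }
    llh <- fb$loglik
    g <- fb$gamma
    lam <- pmax(colSums(g * counts) / colSums(g), 1e-8)
    xi <- fb$xi
    trans <- xi / pmax(rowSums(xi), 1e-300)
    trans <- pmin(pmax(trans, 1e-8), 1 - 1e-8)
    trans <- trans / rowSums(trans)
    init_p <- pmax(g[1, ], 1e-8); init_p <- init_p / sum(init_p)
  }
  # resolve label switching: state 2 is the high-rate (archaic) state
  if (lam[1] > lam[2]) {
    lam <- rev(lam)
    trans <- trans[2:1, 2:1]
    init_p <- rev(init_p)
  }
  emis <- cbind(dpois(counts, lam[1]), dpois(counts, lam[2]))
  fb <- .fb_hmm(emis, trans, init_p)
  no_call <- lam[2] <= lam[1] * (1 + 1e-6)
  fitted <- structure(list(lambda = c(nat = lam[1], arc = lam[2]),
                           trans = trans, init = init_p),
                      class = "archaic_hmm_model")
  list(model = fitted, posterior = fb$gamma[, 2], loglik = trace,
       converged = converged, no_call = no_call)
}

#' Call archaic tracts from per-bin posteriors
#'
#' Maximal runs of bins with posterior strictly above the threshold become
#' tracts (bin-resolution coordinates).
#'
#' @param posterior per-bin P(archaic).
#' @param bin_start 0-based bin starts.
#' @param bin_bp bin size in bp.
#' @param chrom_length chromosome length (last bin may be shorter).
#' @param threshold posterior threshold (default 0.8).
#' @return data.frame of tracts: `start`, `end` (0-based half-open).
#' @export
call_tracts <- function(posterior, bin_start, bin_bp,
                        chrom_length = NULL, threshold = 0.8) {
  hit <- posterior > threshold
  if (!any(hit)) return(data.frame(start = numeric(), end = numeric()))
  r <- rle(hit)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  on <- which(r$values)
  start <- bin_start[starts_idx[on]]
  end <- bin_start[ends_idx[on]] + bin_bp
  if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  data.frame(start = start, end = end)
}

#' Fraction of haplotypes covered by tracts
#'
#' Per-bin fraction of haplotypes whose tract covers the bin midpoint, and
#' its average in nonoverlapping aggregation windows (default 50 kb).
#'
#' @param tract_sets named list (per haplotype) of tract data.frames
#'   (`start`, `end`).
#' @param chrom_length chromosome length in bp.
#' @param bin_bp resolution of the per-position fraction (default 1000).
#' @param window_bp aggregation window span (default 50,000).
#' @return list with `per_bin` (data.frame `start`, `fraction`) and
#'   `per_window` (data.frame `start`, `end`, `fraction`).
#' @export
coverage_fraction <- function(tract_sets, chrom_length, bin_bp = 1000,
                              window_bp = 50000) {
  nh <- length(tract_sets)
  bin_start <- seq(0, max(chrom_length - 1, 0), by = bin_bp)
  mid <- pmin(bin_start + bin_bp / 2, chrom_length)
  cov <- numeric(length(bin_start))
  for (tr in tract_sets) {
    if (is.null(tr) || !nrow(tr)) next
    tr <- tr[order(tr$start), , drop = FALSE]
    cov <- cov + covered_at(mid, tr)
  }
  frac <- cov / max(nh, 1)
  wstart <- seq(0, max(chrom_length - 1, 0), by = window_bp)
  wi <- findInterval(bin_start, wstart)
  pw <- tapply(frac, wi, mean)
  per_window <- data.frame(start = wstart,
                           end = pmin(wstart + window_bp, chrom_length),
                           fraction = 0)
  per_window$fraction[as.integer(names(pw))] <- pw
  list(per_bin = data.frame(start = bin_start, fraction = frac),
       per_window = per_window)
}

#' Archaic-introgression scan for one population
#'
#' Runs the whole reference-free pipeline: private-variant binning,
#' per-haplotype Baum-Welch fits, posterior tract calls at the threshold,
#' and aggregation to F_archaic (fraction of haplotypes on an archaic tract,
#' averaged in 50-kb windows). The chromosome-level transition probability
#' is the mean of the per-haplotype fitted native->archaic transitions.
#'
#' @inheritParams private_counts
#' @param threshold posterior threshold for tract calls (default 0.8).
#' @param window_bp F_archaic aggregation window (default 50,000).
#' @param ... passed to [fit_and_decode()].
#' @return list with `tracts` (named list per haplotype), `f_archaic`
#'   (see [coverage_fraction()]), `fits` (per-haplotype models), `p_mean`
#'   (mean native->archaic transition over called haplotypes), `no_call`
#'   (logical per haplotype).
#' @export
detect_archaic <- function(panel, focal_pop, reference_pop, bin_bp = 1000,
                           threshold = 0.8, window_bp = 50000, ...) {
  pc <- private_counts(panel, focal_pop, reference_pop, bin_bp)
  haps <- colnames(pc$counts)
  fits <- vector("list", length(haps)); names(fits) <- haps
  tracts <- vector("list", length(haps)); names(tracts) <- haps
  no_call <- setNames(logical(length(haps)), haps)
  for (h in haps) {
    fit <- fit_and_decode(pc$counts[, h], ...)
    fits[[h]] <- fit
    no_call[h] <- fit$no_call
    tracts[[h]] <- if (fit$no_call)
      data.frame(start = numeric(), end = numeric())
    else call_tracts(fit$posterior, pc$bin_start, pc$bin_bp,
                     panel$chrom_length, threshold)
  }
  ok <- !no_call
  p_hat <- vapply(fits, function(f) f$model$trans[1, 2], numeric(1))
  list(tracts = tracts,
       f_archaic = coverage_fraction(tracts, panel$chrom_length, bin_bp,
                                     window_bp),
       fits = fits,
       p_mean = if (any(ok)) mean(p_hat[ok]) else NA_real_,
       no_call = no_call)
}
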