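## Dating the admixture pulse from (i) the mean length of introgressed
## tracts and (ii) the archaic HMM's transition parameter.

#' Date admixture from mean introgressed-tract length
#'
#' Under neutral assumptions the mean introgressed-tract length after `t`
#' generations is `L = [(1 - f) r (t - 1)]^-1`; inverting gives
#' `t = 1 / ((1 - f) r L) + 1`.
#'
#' @param L_bar mean tract length in bp.
#' @param f admixture proportion (`0 <= f < 1`).
#' @param r recombination rate in Morgans/bp.
#' @return time since admixture in generations.
#' @export
tract_length_date <- function(L_bar, f, r) {
  if (f >= 1) stop("admixture proportion f must be < 1")
  stopifnot(f >= 0, r > 0, L_bar > 0)
  1 / ((1 - f) * r * L_bar) + 1
}

#' Calibrate a generation-scale date against a reference event
#'
#' Converts a focal date to years by scaling with a reference event whose
#' age is known both in the same (relative) generation scale and in years:
#' `years = (t_focal / t_reference) * reference_years`. No rounding is
#' applied.
#'
#' @param t_focal focal estimate (generations, same estimator as the
#'   reference).
#' @param t_reference reference estimate (generations).
#' @param reference_years calibrated age of the reference event in years.
#' @return calibrated focal age in years.
#' @export
calibrate_years <- function(t_focal, t_reference, reference_years) {
  stopifnot(t_reference > 0)
  (t_focal / t_reference) * reference_years
}

#' Date admixture from the archaic HMM transition parameter
#'
#' Inverts `p ~ T * k * r * L * a`, where `p` is the fitted
#' native-to-archaic transition probability per bin, `r` the recombination
#' rate (Morgans/bp), `L` the bin size (bp) and `a` the archaic admixture
#' fraction (e.g. mean F_archaic). The constant `k` depends on the mosaic
#' the HMM was fitted to: `k = 2` (default) for a diploid-genome mosaic,
#' whose ancestry-junction density is twice the haploid one; `k = 1` for
#' per-haplotype fits as produced by [detect_archaic()].
#'
#' @param p native->archaic transition probability per bin.
#' @param r recombination rate (Morgans/bp).
#' @param L bin size in bp.
#' @param a admixture fraction (> 0).
#' @param generation_time years per generation (default 5).
#' @param k mosaic ploidy constant (see Details).
#' @return list with `generations` and `years`.
#' @export
transition_date <- function(p, r, L, a, generation_time = 5, k = 2) {
  if (any(a <= 0)) stop("admixture fraction a must be > 0 (no archaic ancestry to date)")
  stopifnot(all(p > 0), r > 0, L > 0, generation_time > 0, k > 0)
  gen <- p / (k * r * L * a)
  list(generations = gen, years = gen * generation_time)
}

#' Mode and bootstrap CI of a per-chromosome date distribution
#'
#' The point estimate is the maximizer of a Gaussian kernel density
#' estimate (Silverman's rule-of-thumb bandwidth) over the per-chromosome
#' values; the confidence interval is the percentile interval of the modes
#' of bootstrap resamples.
#'
#' @param values per-chromosome estimates (>= 5, unless all identical).
#' @param n_boot bootstrap replicates (default 10,000).
#' @param ci interval level (default 0.90).
#' @param seed RNG seed.
#' @return list with `mode`, `ci` (length-2 vector), `level`, `n_boot`.
#' @export
distribution_mode_ci <- function(values, n_boot = 10000, ci = 0.90,
                                 seed = 1L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  if (length(unique(values)) == 1)
    return(list(mode = values[1], ci = c(values[1], values[1]),
                level = ci, n_boot = 0L))
  if (length(values) < 5) stop("need >= 5 values")
  kde_mode <- function(v) {
    if (length(unique(v)) == 1) return(v[1])
    d <- density(v, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  set.seed(seed)
  m <- kde_mode(values)
  boots <- vapply(seq_len(n_boot), function(i)
    kde_mode(sample(values, replace = TRUE)), numeric(1))
  alpha <- (1 - ci) / 2
  list(mode = m,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       level = ci, n_boot = n_boot)
}

#' Mean length of tracts, optionally restricted to an interval set
#'
#' Restriction keeps the parts of each tract overlapping the supplied
#' intervals (e.g. RI islands) and averages the lengths of the clipped
#' pieces, mirroring a scan in which tracts are only interpretable inside
#' those regions.
#'
#' @param tracts data.frame with `start`, `end` (or a per-haplotype list of
#'   such data.frames).
#' @param restrict optional data.frame of intervals (`start`, `end`).
#' @return mean tract length in bp (`NA` if no tracts remain).
#' @export
mean_tract_length <- function(tracts, restrict = NULL) {
  if (is.list(tracts) && !is.data.frame(tracts))
    tracts <- do.call(rbind, lapply(tracts, function(x)
      x[, c("start", "end"), drop = FALSE]))
  if (is.null(tracts) || !nrow(tracts)) return(NA_real_)
  if (!is.null(restrict) && nrow(restrict)) {
    restrict <- merge_intervals(restrict[, c("start", "end"), drop = FALSE])
    tracts <- interval_intersect(tracts[, c("start", "end"), drop = FALSE],
                                 restrict)
    if (!nrow(tracts)) return(NA_real_)
  }
  mean(tracts$end - tracts$start)
}
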