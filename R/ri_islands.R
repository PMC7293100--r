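## Delineation of reproductive-isolation (RI) islands between the two
## recipient lineages: a three-state HMM (low / intermediate / high) with
## Gaussian emissions on the log of the F_ST / F_intro ratio, run
## chromosome-by-chromosome at SNP and window scale, with BH-FDR control.

#' Build the regularized F_ST / F_intro ratio track
#'
#' Negative per-SNP F_ST estimates are floored at 0 before division and
#' F_intro is floored at a pseudocount `eps` (default `1/(2 n_haplotypes)`,
#' half a haplotype count) so the ratio stays finite where introgression is
#' absent. The regularization applied is recorded in the result.
#'
#' @param fst numeric vector of F_ST values (per SNP or per window).
#' @param fintro aligned F_intro values.
#' @param n_haplotypes used for the default pseudocount.
#' @param eps explicit pseudocount overriding the default.
#' @return list of class `ratio_track`: `ratio`, `fst`, `fintro`,
#'   `regularization`.
#' @export
build_ratio <- function(fst, fintro, n_haplotypes = NULL, eps = NULL) {
  if (length(fst) != length(fintro)) stop("tracks must be aligned")
  if (all(is.na(fst)) || all(is.na(fintro)))
    stop("all-undefined input track")
  if (is.null(eps)) {
    if (is.null(n_haplotypes))
      stop("supply either `n_haplotypes` or `eps`")
    eps <- 1 / (2 * n_haplotypes)
  }
  ratio <- pmax(fst, 0) / pmax(fintro, eps)
  structure(list(ratio = ratio, fst = fst, fintro = fintro,
                 regularization = list(eps = eps, fst_floor = 0)),
            class = "ratio_track")
}

# most-likely state path (Viterbi) for a homogeneous HMM
viterbi_path <- function(emis, trans, init) {
  n <- nrow(emis); K <- ncol(emis)
  lE <- log(pmax(emis, 1e-300)); lT <- log(pmax(trans, 1e-300))
  delta <- log(pmax(init, 1e-300)) + lE[1, ]
  back <- matrix(1L, n, K)
  for (i in seq_len(n)[-1]) {
    cand <- delta + lT  # cand[j, k]: best-so-far via from-state j
    w <- max.col(t(cand), ties.method = "first")
    back[i, ] <- w
    delta <- cand[cbind(w, seq_len(K))] + lE[i, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (i in rev(seq_len(n)[-1])) path[i - 1] <- back[i, path[i]]
  path
}

#' Fit the three-state RI HMM and decode posteriors
#'
#' Baum-Welch with Gaussian emissions on `log(ratio)` (zero ratios are
#' floored at the regularization pseudocount before the log). States are
#' initialized at the 20/60/95th percentiles of the log-ratio and kept
#' ordered low < intermediate < high. The per-unit p-value for "not in the
#' high state" is `1 - posterior(high)`.
#'
#' The most-likely state of each unit is the Viterbi path; the per-unit
#' p-value for "not in the high state" is `1 - posterior(high)` from
#' forward-backward.
#'
#' A fit whose extreme state means are separated by less than
#' `min_separation` pooled emission standard deviations is declared
#' single-regime: the track contains no distinguishable high-ratio regime,
#' every unit is assigned the background state and no island can be called.
#'
#' @param track a `ratio_track` from [build_ratio()] (>= 100 units).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum Baum-Welch iterations.
#' @param min_separation minimum (mean high - mean low) / pooled sd for the
#'   regimes to count as distinct (default 1).
#' @return list with `model` (means, sds, trans, init), `posterior`
#'   (units x 3 matrix), `state` (most likely state 1..3, Viterbi),
#'   `p_value` (1 - posterior high), `loglik`, `converged`,
#'   `single_regime`.
#' @export
fit_ri_hmm <- function(track, tol = 1e-6, max_iter = 200,
                       min_separation = 1) {
  stopifnot(inherits(track, "ratio_track"))
  ratio <- track$ratio
  ok <- !is.na(ratio)
  if (sum(ok) < 100) stop("need >= 100 units per chromosome")
  x <- log(pmax(ratio[ok], track$regularization$eps))
  K <- 3
  mu <- stats::quantile(x, c(0.20, 0.60, 0.95), names = FALSE)
  if (any(diff(mu) <= 0)) mu <- mu + c(-1e-3, 0, 1e-3) * max(1, abs(mu))
  sg <- rep(max(sd(x), 1e-3), K)
  trans <- matrix(0.01, K, K); diag(trans) <- 0.98
  init_p <- rep(1 / K, K)
  llh <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    emis <- vapply(1:K, function(k) dnorm(x, mu[k], sg[k]), numeric(length(x)))
    emis <- pmax(emis, 1e-300)
    fb <- .fb_hmm(emis, trans, init_p)
    if (is.finite(llh) && fb$loglik - llh < tol) { converged <- TRUE; break }
    llh <- fb$loglik
    g <- fb$gamma
    w <- colSums(g)
    mu <- colSums(g * x) / w
    sg <- sqrt(colSums(g * (outer(x, mu, "-")^2)) / w)
    sg <- pmax(sg, 1e-4)
    # ordered-mean constraint
    o <- order(mu)
    mu <- mu[o]; sg <- sg[o]
    trans <- fb$xi[o, o]
    trans <- trans / pmax(rowSums(trans), 1e-300)
    trans <- pmin(pmax(trans, 1e-8), 1 - 1e-8)
    trans <- trans / rowSums(trans)
    init_p <- pmax(g[1, o], 1e-8); init_p <- init_p / sum(init_p)
  }
  emis <- vapply(1:K, function(k) dnorm(x, mu[k], sg[k]), numeric(length(x)))
  emis <- pmax(emis, 1e-300)
  fb <- .fb_hmm(emis, trans, init_p)
  posterior <- matrix(NA_real_, length(ratio), K)
  posterior[ok, ] <- fb$gamma
  state <- rep(NA_integer_, length(ratio))
  single_regime <- (mu[K] - mu[1]) < min_separation * mean(sg)
  if (single_regime) {
    state[ok] <- 1L
    warning("fit_ri_hmm: state means are not separated; ",
            "declaring a single-regime track (no high state)")
  } else {
    state[ok] <- viterbi_path(emis, trans, init_p)
  }
  list(model = list(mean = mu, sd = sg, trans = trans, init = init_p),
       posterior = posterior, state = state,
       p_value = 1 - posterior[, 3], loglik = fb$loglik,
       converged = converged, single_regime = single_regime)
}

#' Call RI islands with FDR control
#'
#' Benjamini-Hochberg adjustment of the per-unit p-values across all units;
#' units in the high state with adjusted p below `alpha` are retained and
#' contiguous retained units are merged into maximal islands.
#'
#' @param fit result of [fit_ri_hmm()].
#' @param units data.frame with `start`, `end` (0-based half-open
#'   coordinates of each unit; for SNP scale use `pos`, `pos + 1`).
#' @param alpha FDR threshold (default 0.001).
#' @param method p-adjust method (default `"BH"`).
#' @return list of class `ri_island_set`: `islands` (data.frame `start`,
#'   `end`, `n_units`), `per_unit` (state, posterior high, adjusted p,
#'   retained), `alpha`.
#' @export
call_islands <- function(fit, units, alpha = 0.001, method = "BH") {
  stopifnot(nrow(units) == length(fit$state))
  padj <- p.adjust(fit$p_value, method = method)
  retained <- !is.na(fit$state) & fit$state == 3 & padj < alpha
  per_unit <- data.frame(start = units$start, end = units$end,
                         state = fit$state,
                         posterior_high = fit$posterior[, 3],
                         p_adj = padj, retained = retained)
  islands <- data.frame(start = numeric(), end = numeric(),
                        n_units = integer())
  if (any(retained)) {
    r <- rle(retained)
    iend <- cumsum(r$lengths); istart <- iend - r$lengths + 1
    on <- which(r$values)
    islands <- data.frame(start = units$start[istart[on]],
                          end = units$end[iend[on]],
                          n_units = r$lengths[on])
  }
  structure(list(islands = islands, per_unit = per_unit, alpha = alpha),
            class = "ri_island_set")
}

#' @export
print.ri_island_set <- function(x, ...) {
  cat(sprintf("<ri_island_set> %d island(s) covering %.0f bp (%d/%d units retained, FDR < %g)\n",
              nrow(x$islands), interval_bases(x$islands),
              sum(x$per_unit$retained), nrow(x$per_unit), x$alpha))
  invisible(x)
}

#' Concordance between SNP-scale and window-scale island calls
#'
#' Fraction of SNP-scale island bases lying inside window-scale islands and
#' vice versa.
#'
#' @param snp_set,window_set `ri_island_set` objects.
#' @return list with `snp_in_window`, `window_in_snp` (fractions).
#' @export
island_concordance <- function(snp_set, window_set) {
  a <- merge_intervals(snp_set$islands)
  b <- merge_intervals(window_set$islands)
  both <- interval_bases(interval_intersect(a, b))
  list(snp_in_window = if (interval_bases(a)) both / interval_bases(a) else NA,
       window_in_snp = if (interval_bases(b)) both / interval_bases(b) else NA)
}
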