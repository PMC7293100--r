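# Independent brute-force oracles and tiny panel builders used across the
# test files. The oracles enumerate state paths / haplotype pairs directly
# and never call the package's own recursions.

# exact HMM posteriors by enumeration over all K^n state paths
enum_hmm_posterior <- function(emis, trans, init) {
  n <- nrow(emis); K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  probs <- apply(paths, 1, function(s) {
    p <- init[s[1]] * emis[1, s[1]]
    for (i in seq_len(n - 1))
      p <- p * trans[s[i], s[i + 1]] * emis[i + 1, s[i + 1]]
    p
  })
  post <- matrix(0, n, K)
  for (i in seq_len(n)) for (k in seq_len(K))
    post[i, k] <- sum(probs[paths[, i] == k])
  list(posterior = post / sum(probs), loglik = log(sum(probs)))
}

# same, for the copying HMM: prior pi over templates (also the jump
# distribution), per-step switch probability rho
enum_copying_posterior <- function(emis, rho, pi = rep(1 / ncol(emis),
                                                       ncol(emis))) {
  K <- ncol(emis)
  trans_at <- function(j) {
    (1 - rho[j]) * diag(K) + rho[j] * matrix(pi, K, K, byrow = TRUE)
  }
  n <- nrow(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  probs <- apply(paths, 1, function(s) {
    p <- emis[1, s[1]] * pi[s[1]]
    for (i in seq_len(n - 1))
      p <- p * trans_at(i)[s[i], s[i + 1]] * emis[i + 1, s[i + 1]]
    p
  })
  post <- matrix(0, n, K)
  for (i in seq_len(n)) for (k in seq_len(K))
    post[i, k] <- sum(probs[paths[, i] == k])
  post / sum(probs)
}

# panel from an explicit haplotype x site matrix
toy_panel <- function(mat, pops, positions = NULL, chrom_length = NULL,
                      polarized = TRUE) {
  mat <- as.matrix(mat)
  if (is.null(positions)) positions <- seq_len(ncol(mat)) * 10
  hap_panel(mat, positions,
            sample = paste0("s", seq_len(nrow(mat))),
            pop = pops, chrom = "chrT", chrom_length = chrom_length,
            polarized = polarized)
}

# panel whose per-population derived-allele frequencies hit given targets
# exactly (one site per row of `freqs`; pops sized to make that possible)
freq_panel <- function(freqs, n = c(P1 = 5, P2 = 5, P3 = 2, O = 2),
                       span = 50000) {
  nsite <- nrow(freqs)
  pops <- rep(names(n), times = n)
  mat <- matrix(0L, sum(n), nsite)
  off <- c(0, cumsum(n))
  for (j in seq_len(nsite))
    for (k in seq_along(n)) {
      nd <- round(freqs[j, k] * n[k])
      if (nd > 0) mat[off[k] + seq_len(nd), j] <- 1L
    }
  toy_panel(mat, pops, positions = seq_len(nsite) * 100 - 1,
            chrom_length = span)
}

# base-level accuracy of called vs truth tracts at bin midpoints
tract_accuracy <- function(called, truth, chrom_length, bin_bp = 1000) {
  mid <- seq(0, chrom_length - 1, by = bin_bp) + bin_bp / 2
  cov <- function(tr) {
    if (is.null(tr) || !nrow(tr)) return(rep(FALSE, length(mid)))
    tr <- tr[order(tr$start), , drop = FALSE]
    idx <- findInterval(mid, tr$start)
    idx > 0 & mid < tr$end[pmax(idx, 1)]
  }
  mean(cov(called) == cov(truth))
}
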