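## Tract-level haplotype simulator for a four-taxon system
## (((P1, P2), P3), O) with an ancient donor pulse P3 -> P2 and a recent
## secondary contact P2 -> P1. The generator is the exact inverse of the
## tract-length dating model: introgressed segment lengths are exponential
## with mean [(1 - f) r (t - 1)]^-1, which makes parameter recovery a sharp
## test for every downstream stage.

#' Simulation scenario parameters
#'
#' Defines the study conditions for [simulate_panel()]. Population roles are
#' fixed: `O` outgroup, `P3` donor species, `P2` admixed recipient lineage
#' (Atlantic role), `P1w` recipient lineage receiving recent gene flow from
#' `P2` (western Mediterranean role) and `P1e` its non-admixed counterpart
#' (eastern Mediterranean role, the reference for private-variant scans).
#'
#' Site classes are Poisson processes (rates per bp): `lambda_shared`
#' (derived fixed in the recipient species, absent on donor-ancestry
#' tracts), `lambda_p1`/`lambda_p2` (lineage-private variants of the two
#' recipient lineages, carried by each haplotype of the lineage with
#' probability `carrier_freq` — so the per-haplotype private-variant
#' density is `carrier_freq * lambda`), `lambda_p3` (donor-diagnostic
#' variants, carried by a recipient haplotype only where it is covered by a
#' donor-ancestry tract, plus an incomplete-lineage-sorting stand-in: each
#' recipient haplotype carries an off-tract diagnostic allele with
#' probability `p_leak`), and `lambda_out` (outgroup-specific derived
#' variants).
#'
#' @param n_hap named integer vector of haplotype counts for
#'   `O, P3, P1e, P1w, P2`.
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param r recombination rate in Morgans/bp.
#' @param t_adm generations since the donor pulse P3 -> P2 (must be > 1).
#' @param a donor pulse admixture fraction in `[0, 1]`.
#' @param t_sc generations since the P2 -> P1 secondary contact.
#' @param m secondary-contact admixture fraction in `[0, 1]`.
#' @param q_ri marginal donor-ancestry frequency forced inside
#'   `ri_intervals` in P2 (secondary-contact introgression into P1w is
#'   suppressed there).
#' @param ri_intervals data.frame with columns `start`, `end` (0-based
#'   half-open) of reproductive-isolation islands; may be empty.
#' @param lambda_shared,lambda_p1,lambda_p2,lambda_p3,lambda_out site rates
#'   per bp (see Details).
#' @param p_leak per-haplotype probability of carrying an off-tract
#'   donor-diagnostic allele (default 0.05, i.e. 5% of `lambda_p3`).
#' @param carrier_freq per-haplotype carrier probability at
#'   lineage-private sites (default 0.5).
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return a validated list of class `scenario_params`.
#' @export
scenario_params <- function(n_hap = c(O = 2, P3 = 2, P1e = 16, P1w = 16, P2 = 16),
                            chrom_length = 5e6, chrom = "chr1",
                            r = 3.7e-8, t_adm = 5000, a = 0.1,
                            t_sc = 2300, m = 0.3, q_ri = 0.9,
                            ri_intervals = data.frame(start = numeric(),
                                                      end = numeric()),
                            lambda_shared = 5e-4, lambda_p1 = 5e-4,
                            lambda_p2 = 5e-4, lambda_p3 = 5e-3,
                            lambda_out = 2e-4, p_leak = 0.05,
                            carrier_freq = 0.5, seed = 1L) {
  roles <- c("O", "P3", "P1e", "P1w", "P2")
  if (!all(roles %in% names(n_hap)))
    stop("n_hap must name all of: ", paste(roles, collapse = ", "))
  rates <- c(lambda_shared, lambda_p1, lambda_p2, lambda_p3, lambda_out)
  stopifnot(a >= 0, a <= 1, m >= 0, m <= 1, q_ri >= 0, q_ri <= 1,
            all(rates >= 0), p_leak >= 0, p_leak <= 1,
            carrier_freq > 0, carrier_freq <= 1,
            chrom_length > 0, r > 0, t_adm > 1, t_sc > 1)
  ri_intervals <- as.data.frame(ri_intervals)
  if (nrow(ri_intervals)) {
    stopifnot(all(ri_intervals$start >= 0),
              all(ri_intervals$end <= chrom_length),
              all(ri_intervals$end > ri_intervals$start))
    ri_intervals <- ri_intervals[order(ri_intervals$start), , drop = FALSE]
  }
  structure(list(
    n_hap = n_hap[roles], chrom_length = chrom_length, chrom = chrom,
    r = r, t_adm = t_adm, a = a, t_sc = t_sc, m = m, q_ri = q_ri,
    ri_intervals = ri_intervals, lambda_shared = lambda_shared,
    lambda_p1 = lambda_p1, lambda_p2 = lambda_p2, lambda_p3 = lambda_p3,
    lambda_out = lambda_out, p_leak = p_leak,
    carrier_freq = carrier_freq, seed = as.integer(seed)
  ), class = "scenario_params")
}

#' Expected mean introgressed-tract length
#'
#' Closed form `1 / ((1 - f) * r * (t - 1))`, the law the simulator draws
#' tract lengths from and [tract_length_date()] inverts.
#'
#' @param f admixture fraction.
#' @param r recombination rate (Morgans/bp).
#' @param t generations since admixture.
#' @return expected mean tract length in bp.
#' @export
expected_tract_length <- function(f, r, t) {
  stopifnot(f >= 0, f < 1, r > 0, t > 1)
  1 / ((1 - f) * r * (t - 1))
}

## ---- interval helpers (0-based half-open, single chromosome) ----

merge_intervals <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order(df$start), , drop = FALSE]
  s <- df$start; e <- df$end
  keep_s <- s[1]; keep_e <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= keep_e) keep_e <- max(keep_e, e[i])
    else { out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
           keep_s <- s[i]; keep_e <- e[i] }
  }
  data.frame(start = c(out_s, keep_s), end = c(out_e, keep_e))
}

interval_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(start = numeric(), end = numeric()))
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
    ok <- e > s
    out[[i]] <- data.frame(start = s[ok], end = e[ok])
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

interval_setdiff <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[, c("start", "end"), drop = FALSE])
  b <- merge_intervals(b)
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    segs <- data.frame(start = a$start[i], end = a$end[i])
    for (j in seq_len(nrow(b))) {
      nxt <- vector("list", nrow(segs))
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        bs <- b$start[j]; be <- b$end[j]
        if (be <= s || bs >= e) nxt[[k]] <- data.frame(start = s, end = e)
        else {
          left <- if (bs > s) data.frame(start = s, end = bs) else NULL
          right <- if (be < e) data.frame(start = be, end = e) else NULL
          nxt[[k]] <- rbind(left, right)
        }
      }
      segs <- do.call(rbind, nxt)
      if (is.null(segs) || !nrow(segs)) break
    }
    out[[i]] <- segs
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(start = numeric(), end = numeric())
  else res[order(res$start), , drop = FALSE]
}

# total length of an interval set
interval_bases <- function(df) if (nrow(df)) sum(df$end - df$start) else 0

# TRUE where pos falls inside one of the (sorted, disjoint) intervals
covered_at <- function(pos, intervals) {
  if (!nrow(intervals) || !length(pos)) return(logical(length(pos)))
  idx <- findInterval(pos, intervals$start)
  idx > 0 & pos < intervals$end[pmax(idx, 1)]
}

## Alternating exponential renewal process: "on" segments with marginal
## probability q and mean on-length mean_on, stationary at the left edge.
sim_mosaic <- function(L, q, mean_on) {
  if (q <= 0) return(data.frame(start = numeric(), end = numeric()))
  if (q >= 1) return(data.frame(start = 0, end = L))
  mean_off <- mean_on * (1 - q) / q
  pos <- 0
  state_on <- runif(1) < q
  starts <- numeric(0); ends <- numeric(0)
  while (pos < L) {
    len <- rexp(1, rate = 1 / if (state_on) mean_on else mean_off)
    if (state_on) { starts <- c(starts, pos); ends <- c(ends, min(pos + len, L)) }
    pos <- pos + len
    state_on <- !state_on
  }
  data.frame(start = starts, end = ends)
}

## Poisson site positions (integer bp) on [0, L)
sim_positions <- function(rate, L) {
  n <- rpois(1, rate * L)
  if (n == 0) return(integer(0))
  sort.int(floor(runif(n, 0, L)))
}

#' Simulate a phased haplotype panel with ground-truth ancestry tracts
#'
#' Generates a polarized [hap_panel()] under the scenario in `params`
#' together with a truth set: per-haplotype donor-ancestry ("archaic")
#' tracts in P2 (and those inherited by P1w through secondary contact) and
#' per-haplotype Atlantic tracts in P1w. Donor-ancestry segment lengths are
#' exponential with mean `expected_tract_length(a, r, t_adm)`; inside
#' `ri_intervals` each P2 haplotype is wholly donor-derived with probability
#' `q_ri`, and secondary-contact tracts in P1w are suppressed.
#'
#' @param params a [scenario_params()] object.
#' @return list with elements `panel` (a polarized [hap_panel()]) and
#'   `truth` (class `truth_set`: data.frames `archaic` and `atlantic` with
#'   columns `hap`, `start`, `end`, the echoed `ri_intervals` and `params`).
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)
  L <- params$chrom_length
  mean_arc <- expected_tract_length(params$a, params$r, params$t_adm)
  if (params$a > 0 && mean_arc < 1)
    stop("mean archaic tract length < 1 bp for chosen (a, r, t_adm); ",
         "rescale t_adm or r")
  mean_sc <- expected_tract_length(params$m, params$r, params$t_sc)
  if (params$m > 0 && mean_sc < 1)
    stop("mean secondary-contact tract length < 1 bp; rescale t_sc or r")

  nh <- params$n_hap
  pop <- rep(names(nh), times = nh)
  hap_ids <- paste0(pop, "_", unlist(lapply(nh, seq_len)))
  nhap <- length(pop)
  rows <- split(seq_len(nhap), pop)
  ri <- params$ri_intervals

  ## donor-ancestry mosaics in P2 (background a, forced q_ri inside RI)
  arch <- setNames(vector("list", nhap), hap_ids)
  for (i in seq_len(nhap)) arch[[i]] <- data.frame(start = numeric(),
                                                   end = numeric())
  for (i in rows$P2) {
    mos <- sim_mosaic(L, params$a, mean_arc)
    if (nrow(ri)) {
      mos <- interval_setdiff(mos, ri)
      forced <- ri[runif(nrow(ri)) < params$q_ri, , drop = FALSE]
      mos <- merge_intervals(rbind(mos, forced[, c("start", "end")]))
    }
    arch[[i]] <- mos
  }

  ## secondary-contact (Atlantic) mosaics in P1w, suppressed inside RI;
  ## each tract copies one donor P2 haplotype, inheriting its archaic cover
  atl <- setNames(vector("list", length(rows$P1w)), hap_ids[rows$P1w])
  for (i in rows$P1w) {
    mos <- sim_mosaic(L, params$m, mean_sc)
    if (nrow(ri)) mos <- interval_setdiff(mos, ri)
    if (nrow(mos)) {
      mos$donor <- sample(rows$P2, nrow(mos), replace = TRUE)
      inherited <- vector("list", nrow(mos))
      for (k in seq_len(nrow(mos)))
        inherited[[k]] <- interval_intersect(mos[k, , drop = FALSE],
                                             arch[[mos$donor[k]]])
      arch[[i]] <- merge_intervals(do.call(rbind, c(
        list(data.frame(start = numeric(), end = numeric())), inherited)))
    } else mos$donor <- integer(0)
    atl[[hap_ids[i]]] <- mos
  }

  ## ---- site placement ----
  site_pos <- list(); site_car <- list()
  add_sites <- function(pos, carriers_list) {
    if (!length(pos)) return()
    site_pos[[length(site_pos) + 1L]] <<- pos
    site_car[[length(site_car) + 1L]] <<- carriers_list
  }
  recip <- c(rows$P1e, rows$P1w, rows$P2)

  # outgroup-derived
  p_out <- sim_positions(params$lambda_out, L)
  add_sites(p_out, lapply(seq_along(p_out), function(j) rows$O))

  # recipient-species shared derived: all recip haplotypes except where
  # their ancestry is donor-derived
  p_sh <- sim_positions(params$lambda_shared, L)
  if (length(p_sh)) {
    carry <- !vapply(recip, function(i) covered_at(p_sh, arch[[i]]),
                     logical(length(p_sh)))
    if (is.null(dim(carry))) carry <- matrix(carry, nrow = length(p_sh))
    add_sites(p_sh, lapply(seq_along(p_sh),
                           function(j) recip[carry[j, ]]))
  }

  # donor-diagnostic pool: fixed derived in P3; recipient haplotypes carry
  # on archaic tracts, plus the ILS leak off-tract
  p_d <- sim_positions(params$lambda_p3, L)
  if (length(p_d)) {
    onto <- vapply(recip, function(i) covered_at(p_d, arch[[i]]),
                   logical(length(p_d)))
    if (is.null(dim(onto))) onto <- matrix(onto, nrow = length(p_d))
    leak <- matrix(runif(length(p_d) * length(recip)) < params$p_leak,
                   nrow = length(p_d))
    carry <- onto | (!onto & leak)
    add_sites(p_d, lapply(seq_along(p_d),
                          function(j) c(rows$P3, recip[carry[j, ]])))
  }

  # P2-lineage variants: pooled sites, each carried by a P2 haplotype with
  # probability carrier_freq except where its own ancestry is archaic;
  # P1w haplotypes inherit the donor's carrier status inside Atlantic tracts
  p2_pos <- sim_positions(params$lambda_p2, L)
  if (length(p2_pos)) {
    C2 <- matrix(FALSE, length(p2_pos), nhap)
    for (i in rows$P2)
      C2[, i] <- (runif(length(p2_pos)) < params$carrier_freq) &
        !covered_at(p2_pos, arch[[i]])
    for (i in rows$P1w) {
      mos <- atl[[hap_ids[i]]]
      for (k in seq_len(nrow(mos))) {
        hit <- p2_pos >= mos$start[k] & p2_pos < mos$end[k]
        C2[hit, i] <- C2[hit, mos$donor[k]]
      }
    }
    add_sites(p2_pos, lapply(seq_along(p2_pos), function(j) which(C2[j, ])))
  }

  # P1-lineage variants: pooled sites carried by each P1 haplotype with
  # probability carrier_freq; absent from P1w Atlantic tracts
  p1_pos <- sim_positions(params$lambda_p1, L)
  if (length(p1_pos)) {
    C1 <- matrix(FALSE, length(p1_pos), nhap)
    for (i in c(rows$P1e, rows$P1w)) {
      carry <- runif(length(p1_pos)) < params$carrier_freq
      if (i %in% rows$P1w) {
        mos <- atl[[hap_ids[i]]]
        carry <- carry & !covered_at(p1_pos,
                                     mos[order(mos$start), , drop = FALSE])
      }
      C1[, i] <- carry
    }
    add_sites(p1_pos, lapply(seq_along(p1_pos), function(j) which(C1[j, ])))
  }

  ## merge, deduplicate (1-bp jitter), sort
  pos <- unlist(site_pos, use.names = FALSE)
  carriers <- do.call(c, site_car)
  if (is.null(pos)) pos <- integer(0)
  if (length(pos)) {
    # monomorphic-ancestral draws (no carrier) never reach the VCF
    seg <- lengths(carriers) > 0
    pos <- pos[seg]; carriers <- carriers[seg]
  }
  if (length(pos)) {
    for (iter in 1:50) {
      dup <- duplicated(pos)
      if (!any(dup)) break
      pos[dup] <- (pos[dup] + 1) %% L
    }
    keep <- !duplicated(pos)
    pos <- pos[keep]; carriers <- carriers[keep]
    o <- order(pos)
    pos <- pos[o]; carriers <- carriers[o]
  }

  alleles <- matrix(0L, nrow = nhap, ncol = length(pos))
  if (length(pos)) {
    j_idx <- rep.int(seq_along(carriers), lengths(carriers))
    alleles[cbind(unlist(carriers), j_idx)] <- 1L
  }
  rownames(alleles) <- hap_ids
  panel <- hap_panel(alleles, pos, sample = sub("_[0-9]+$", "", hap_ids),
                     pop = pop, chrom = params$chrom, chrom_length = L,
                     polarized = TRUE)
  # two haplotypes per pseudo-individual for VCF round trips
  panel$sample <- paste0(pop, "_ind", ceiling(unlist(lapply(nh, seq_len)) / 2))

  tract_df <- function(lst, ids) {
    out <- do.call(rbind, lapply(ids, function(id) {
      tr <- lst[[id]]
      if (is.null(tr) || !nrow(tr)) return(NULL)
      data.frame(hap = id, start = tr$start, end = tr$end,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(out)) data.frame(hap = character(), start = numeric(),
                                 end = numeric(), stringsAsFactors = FALSE)
    else out
  }
  names(arch) <- hap_ids
  truth <- structure(list(
    archaic = tract_df(arch, hap_ids[c(rows$P2, rows$P1w)]),
    atlantic = tract_df(atl, hap_ids[rows$P1w]),
    ri_intervals = ri, params = params
  ), class = "truth_set")
  list(panel = panel, truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d archaic tract(s), %d Atlantic tract(s), %d RI interval(s)\n",
              nrow(x$archaic), nrow(x$atlantic), nrow(x$ri_intervals)))
  invisible(x)
}

#' Export ground-truth tracts as BED files
#'
#' Writes one BED file per ancestry class (`<prefix>_archaic.bed`,
#' `<prefix>_atlantic.bed`, `<prefix>_ri.bed`), haplotype id in the name
#' column. Empty classes produce a header-only BED.
#'
#' @param truth a `truth_set` from [simulate_panel()].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
export_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "truth_set"))
  chrom <- truth$params$chrom
  as_bed <- function(df, name) {
    if (!nrow(df)) return(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), name = character()))
    data.frame(chrom = chrom, start = df$start, end = df$end, name = name,
               stringsAsFactors = FALSE)
  }
  paths <- c(archaic = paste0(prefix, "_archaic.bed"),
             atlantic = paste0(prefix, "_atlantic.bed"),
             ri = paste0(prefix, "_ri.bed"))
  write_bed(as_bed(truth$archaic, truth$archaic$hap), paths["archaic"])
  write_bed(as_bed(truth$atlantic, truth$atlantic$hap), paths["atlantic"])
  ri <- truth$ri_intervals
  write_bed(as_bed(ri, if (nrow(ri)) "RI" else character(0)), paths["ri"])
  invisible(paths)
}
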