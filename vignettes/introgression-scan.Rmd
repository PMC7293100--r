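---
title: "Scanning phased genomes for ancient introgression and reproductive-isolation islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning phased genomes for ancient introgression and reproductive-isolation islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

Speciation genomics repeatedly finds that the genomic regions responsible
for reproductive isolation (RI) between young lineages carry haplotypes far
older than the lineage split itself. One candidate source of such old
alleles is an ancient admixture pulse from a related donor species into one
of the two lineages. Testing this hypothesis requires a chain of analyses
on phased whole-genome haplotypes from four taxon groups — an outgroup
`O`, a donor species `P3`, and two partially isolated recipient lineages
`P1` (the lineage resisting gene flow; in the motivating system the
Mediterranean role, with a non-admixed eastern reference population `P1e`
and a western population `P1w` that receives recent gene flow) and `P2`
(the lineage that received the ancient pulse; the Atlantic role):

1. detect donor ancestry (window statistics, a reference-free archaic HMM);
2. localize the recent-introgression landscape between the two recipient
   lineages (haplotype-copying local-ancestry painting);
3. delineate RI islands (a 3-state HMM on the F~ST~/F~intro~ ratio);
4. date the ancient pulse (tract lengths and the HMM transition parameter);
5. characterize how donor-derived alleles segregate in the two lineages
   (conditioned site frequency spectra).

`introscan` implements this chain as composable functions on a single
container, the `hap_panel` (haplotype-by-site 0/1 matrix, 0-based
positions, population labels), plus a tract-level simulator that generates
panels with known ground truth so that every stage is testable without
external data.

## Window statistics

All scans run in nonoverlapping windows (default 50 kb, windows with fewer
than 500 SNPs flagged and excluded, following standard practice for this
data type).

* **d~XY~** — mean pairwise difference per site between two populations.
  The default denominator is the window span in bp; because filtered sites
  are invisible this slightly underestimates divergence, which is the
  convention the scan results are interpreted under. A per-SNP denominator
  is available (`denom = "sites"`).
* **F~ST~** — the Weir & Cockerham (1984) ANOVA estimator with each
  haplotype as one (haploid) observation. Per-SNP variance components `a`
  (among populations) and `b` (within) give `theta = a/(a+b)`; window
  values are ratios of summed components. Negative per-SNP estimates are
  kept (they carry information about the estimator's noise); window ratios
  are clamped at 0 by default.
* **Patterson's D and f~D~** — frequency-weighted ABBA/BABA sums on
  (((P1,P2),P3),O). `D` measures the imbalance of discordant genealogy
  classes; it is unsuitable as a window-level admixture *proportion*, so
  the admixture fraction is estimated by `f_D`, which normalizes the
  observed excess by the excess expected under complete donor ancestry,
  with the dynamic donor `PD` chosen site-wise as whichever of P2/P3 has
  the higher derived frequency. `f_D` is only meaningful in the direction
  being tested; windows with negative `D` report `NA` rather than a
  negative admixture proportion.
* **RND~min~** — the minimum donor-recipient haplotype distance divided by
  the mean divergence of both to the outgroup. Low values flag rare
  introgressed haplotypes; the outgroup scaling removes mutation-rate
  variation. Distances are raw mismatch proportions: at the divergences
  this statistic is used for (well below 5%) multiple-hit correction would
  change nothing but add a model assumption.
* **Topology weighting** — per window, a neighbor-joining tree over all
  haplotypes of the four taxa (raw mismatch distances), then the induced
  quartet topology for combinations of one haplotype per taxon, rooted on
  the outgroup. The induced topology is read with the four-point condition
  on the tree's cophenetic distances, which is exact for a tree metric and
  equivalent to pruning; ties from zero-length branches split their weight
  equally. Full enumeration is used when the number of combinations is
  small (`enum_cap`), otherwise seeded uniform sampling.

## The archaic HMM

Donor ancestry is detected without a donor reference, from local excesses
of private variants: derived alleles carried by a focal haplotype and
absent from a non-admixed comparison population. Counts are binned (1 kb)
and modelled per haplotype by a two-state HMM — `native` and `archaic` —
with Poisson emissions, the natural distribution for binned point counts
under a constant mutation and call rate. Parameters are fitted by
Baum-Welch (tolerance 1e-6 on the log-likelihood, at most 500 iterations),
initialized at `lambda_nat` = three quarters of the 25th percentile of
nonzero bin counts and `lambda_arc` = 10x that, with native-to-archaic
transition 1e-3; label switching is resolved by ordering the rates, and a
fit where the rates do not separate flags the haplotype as no-call rather
than reporting meaningless tracts. Tracts are maximal runs of bins with
posterior probability above 0.8. `F_archaic` is the fraction of haplotypes
covered at a position, averaged in 50-kb windows; the chromosome-level
transition probability is the mean of the per-haplotype fits.

## Local-ancestry painting

Recent introgression between the recipient lineages is painted with a
Li & Stephens haplotype-copying HMM: the hidden state is which member of
two reference panels (one per lineage) the focal haplotype is currently
copying. The probability of switching template between adjacent sites at
distance `d` is `1 - exp(-switch_rate * d)`; a practical `switch_rate` is
`r * t` with `r` the recombination rate and `t` the expected age in
generations of the tracts being painted. The prior (and the jump target
distribution) gives each *ancestry* mass 1/2, uniform within its panel, so
unequal panel sizes do not bias the call. The `mismatch` parameter is the
per-site probability of disagreeing with the copied template; it absorbs
copying error *and* divergence from the closest available panel member, so
with finite panels realistic values are 0.05–0.15 (default 0.1) — far
larger than a pure genotyping-error rate.

Tracts of the introgressing ancestry are sites with posterior above 0.5,
with boundaries at the midpoint between flanking sites of opposite call
(terminal runs extend to the chromosome ends), gaps shorter than
`merge_bp` (default 1000) merged, and tracts with fewer than `min_sites`
(default 5) supporting sites dropped; all three knobs are recorded on the
result. `F_intro` is the haplotype coverage fraction, averaged in 50-kb
windows. Haplotype fractions are used throughout (for `F_archaic` and
`F_intro` alike); individual fractions would differ only by within-individual
correlation of tracts.

## RI islands

RI islands combine elevated differentiation with resistance to gene flow:
high F~ST~ between the lineages *and* low F~intro~ into the focal lineage,
hence a high F~ST~/F~intro~ ratio. Before division, negative per-SNP F~ST~
is floored at 0 and F~intro~ at a pseudocount (default `1/(2 n_hap)`, half
a haplotype); the regularization is recorded. The log ratio is modelled
chromosome-by-chromosome with a 3-state HMM (low / intermediate / high,
i.e. neutral / linked-selection / RI) with Gaussian emissions, initialized
at the 20/60/95th percentiles of the log-ratio and kept mean-ordered
through Baum-Welch. The most-likely state sequence is the Viterbi path;
the evidence that a unit is *not* in the high state is
`1 - posterior(high)` from forward-backward, and Benjamini-Hochberg
adjustment across all units at FDR 0.001 decides which high-state units
are retained. Contiguous retained units merge into islands; the scan runs
at SNP scale and 50-kb window scale, and `island_concordance()`
cross-tabulates the two.

One degenerate case is declared explicitly: if the fitted extreme state
means are separated by less than one pooled emission standard deviation
(`min_separation`), the track is declared single-regime — a 3-state
mixture fitted to one regime otherwise splits the density arbitrarily —
and no island can be called.

## Dating the pulse

Recombination breaks introgressed tracts at an (approximately) constant
rate, so tract length measures time. Under neutrality the mean length
after `t` generations is

L = [ (1 - f) * r * (t - 1) ]^-1,

with `f` the admixture fraction and `r` the local recombination rate in
Morgans/bp; `tract_length_date()` inverts this. Because tract detection is
only reliable where the two recipient lineages actually differ in archaic
content, the mean is typically computed over tracts restricted to RI
windows (`mean_tract_length(tracts, restrict =)`). Absolute ages inherit
the biases of tract calling, so the focal date is best *calibrated*
against an event of known age estimated with the same machinery
(`calibrate_years()`): the ratio of the two generation-scale estimates
times the reference age in years.

The second estimator inverts the archaic HMM transition parameter:
`p ~ T * k * r * L * a`, with `L` the bin size and `a` the archaic
fraction. The constant `k` encodes which mosaic the HMM walked along: a
diploid genome accumulates ancestry junctions at twice the haploid rate,
so `k = 2` for fits on unphased diploid genomes (the classical form of the
formula, and the default), while the per-haplotype fits produced by
`detect_archaic()` require `k = 1` — using `k = 2` on haplotype fits
halves the age. Per-chromosome estimates are summarized by the mode of a
Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth,
the standard default when no estimator is otherwise specified) with a
percentile bootstrap confidence interval (default level 0.90, 10,000
resamples, seeded).

## Conditioned spectra

To ask how donor-derived alleles segregate in the two recipient lineages,
sites are conditioned on the outgroup being fixed ancestral and the donor
carrying the derived allele (threshold configurable; the default `present`
suits a single sequenced donor genome). Derived *haplotype* counts in P1
and P2 are tallied into per-lineage spectra (CSFS) and their joint
spectrum (CJSFS), separately for sites inside and outside RI islands. The
diagnostic signature of ancient admixture concentrated in one lineage is
an excess of sites nearly fixed in P2 but rare in P1 relative to the
mirrored configuration; `csfs_asymmetry()` reports the ratio of the two
corner masses (corners at 80%/20% of the haplotype counts, 0.5 continuity
correction so the ratio is finite when a corner is empty).

## The simulator

`simulate_panel()` is deliberately a *tract-level* generative model, not a
coalescent: ancestry mosaics are laid down first and sites are placed on
them, so the tract-length dating formula is the exact inverse of the
generator and parameter recovery is a sharp test. Per P2 haplotype, archaic
segments alternate with native ones (stationary marginal `a`, archaic
lengths exponential with the mean above); inside declared RI intervals each
haplotype is instead wholly archaic with probability `q_ri`. P1w receives
P2 segments the same way (`m`, `t_sc`), suppressed inside RI intervals,
each segment copying one concrete P2 haplotype — including its archaic
sub-segments and its lineage variants.

Site classes and their default rates (per bp) are study conditions chosen
once to mirror the motivating system:

| class | rate | carried by |
|---|---|---|
| donor-diagnostic | `lambda_p3 = 5e-3` (the ~0.55% donor-recipient divergence) | all P3; recipients where archaic-covered; off-tract with probability `p_leak` (ILS stand-in, default 5%) |
| recipient-shared | `lambda_shared = 5e-4` | all P1/P2 haplotypes except where archaic-covered |
| lineage-private | `lambda_p1 = lambda_p2 = 5e-4` | each haplotype of the lineage with probability `carrier_freq = 0.5` (per-haplotype private density `0.5 * lambda`) |
| outgroup-derived | `lambda_out = 2e-4` | outgroup |

Admixture defaults `a = 0.1`, `t_adm = 5000`, `m = 0.3`, `t_sc = 2300`,
`q_ri = 0.9` reflect the scale of the motivating system (a ~10% ancient
pulse several thousand generations before a postglacial secondary contact
of ~2300 generations with ~30% admixture, donor ancestry near fixation
inside RI islands). Sites from all processes are merged; position
collisions are resolved by 1-bp jitter; everything is deterministic under
the seed.

What the simulator does **not** emulate — and hence what passing tests do
not certify about real data: genealogical noise beyond the constant
ILS leak (no ancestral recombination graph), glacial bottlenecks or any
population-size change, selection against introgressed tracts, variable
recombination or mutation rates along the chromosome, genotyping and
phasing error, and site-frequency spectra with realistic shapes
(lineage-private variants use one constant carrier frequency). The test
scenarios are also scaled down: a 10-Mb chromosome with 16+16 recipient
haplotypes for dating recovery, 5 Mb with three 0.3–0.5-Mb RI islands for
island delineation, 2.5 Mb (50 windows) for the null checks — sizes the
package's own test suite uses, chosen to make each property measurable
with comfortable Monte-Carlo margins.

## Numerical choices

* Coordinates are 0-based half-open internally; VCF positions are written
  1-based and BED intervals 0-based, each format's own convention.
* Outgroup-polymorphic sites are dropped at polarization by default (ties
  are undefined when the outgroup is a single genome); `tie = "major"` is
  available for multi-genome outgroups.
* Haplotype order within an individual follows the VCF phase columns and
  is stable across a run.
* Forward-backward uses per-step scaling (exact in floating point, no
  underflow); Baum-Welch transition estimates are clamped away from 0/1 by
  1e-8 to keep the chain ergodic; Poisson rates are floored at 1e-8.
* NJ distance ties are broken deterministically by haplotype index order;
  quartet sampling is seeded.
* The archaic HMM refuses fits where the two Poisson rates do not separate
  (no-call), and `fit_ri_hmm()` refuses chromosomes with fewer than 100
  units.

## Known limitations

* The painter assumes panels of *pure* lineage representatives; in real
  data the reference panels must be chosen (or reconstructed) carefully,
  and panel contamination biases F~intro~ upward.
* Tract-length dating assumes neutral tract decay; positive selection on
  introgressed haplotypes lengthens tracts and biases dates toward the
  recent, which is precisely why the calibrated ratio and the
  transition-parameter estimator are both reported.
* The conversion of HMM state assignments to FDR-controlled calls uses
  `1 - posterior(high)` as the per-unit evidence; other conventions exist
  and the choice is recorded here rather than hidden.
* Window statistics with the span denominator underestimate absolute
  levels when many sites are filtered; comparisons across windows of the
  same dataset are unaffected.
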