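# introscan

Genome scans for **ancient admixture** between a donor species and one
lineage of a recipient species, and for the **reproductive-isolation (RI)
islands** that such admixture can seed between the recipient's lineages —
all from phased whole-genome haplotypes.

The package is written for population and speciation genomicists working
with a four-taxon design `(((P1,P2),P3),O)`: an outgroup `O`, a candidate
donor species `P3`, and two partially isolated recipient lineages `P1`
(the lineage resisting gene flow) and `P2` (the candidate admixed
lineage). It provides, as composable R functions on one haplotype-panel
container:

* **Window statistics** — d<sub>XY</sub>, Weir & Cockerham
  F<sub>ST</sub> (haploid ANOVA estimator), Patterson's
  D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA) and the window-level admixture
  proportion f<sub>D</sub> = S(P1,P2,P3,O)/S(P1,P<sub>D</sub>,P<sub>D</sub>,O),
  RND<sub>min</sub> = d<sub>min</sub>/d<sub>out</sub>, topology weights
  from per-window neighbor-joining trees, Spearman correlations between
  genome-wide tracks.
* **Archaic-tract detection** without a donor reference: a two-state HMM
  with Poisson emissions on 1-kb private-variant counts per haplotype,
  fitted by Baum-Welch; tracts at posterior > 0.8; F<sub>archaic</sub>
  per position and 50-kb window.
* **Local-ancestry painting** — a Li & Stephens haplotype-copying HMM
  against two reference panels; tract extraction; F<sub>intro</sub>.
* **RI-island delineation** — a 3-state (neutral / linked-selection / RI)
  HMM with Gaussian emissions on log(F<sub>ST</sub>/F<sub>intro</sub>),
  SNP and 50-kb scale, Benjamini–Hochberg FDR < 0.001.
* **Dating** — from mean introgressed-tract length,
  t = 1/((1−f)·r·L̄) + 1, with calibration against a reference event; and
  from the archaic HMM transition parameter, T = p/(k·r·L·a), with a
  KDE-mode + bootstrap-CI summary across chromosomes.
* **Conditioned spectra** — CSFS/CJSFS of donor-derived alleles in the two
  recipient lineages, split by RI membership, with a corner-asymmetry
  statistic.
* **A tract-level simulator** with exported ground truth, whose
  introgressed-tract lengths are exponential with mean
  [(1−f)·r·(t−1)]<sup>−1</sup> — the exact inverse of the dating model —
  so every stage of the pipeline is testable end-to-end.

Standard formats are used throughout: phased VCF in (via `vcfR`),
uncompressed VCF out, TSV popmaps and recombination maps, BED tracts and
islands.

## Worked example

Dating an ancient pulse from published summary inputs — mean archaic tract
length 5,513 bp at admixture fraction 0.096 and r = 3.693×10⁻⁸ M/bp,
against secondary-contact tracts of 52,026 bp (f = 0.341,
r = 3.23×10⁻⁸), calibrated on a secondary contact of known age
(2,300 generations ≈ 11,500 years):

```r
library(introscan)
t_donor <- tract_length_date(L_bar = 5513,  f = 0.096, r = 3.693e-8)
t_sc    <- tract_length_date(L_bar = 52026, f = 0.341, r = 3.23e-8)
t_donor                              # 5434 generations
t_sc                                 # 904 generations
t_donor / t_sc                       # 6.01 -- pulse ~6x older than contact
calibrate_years(t_donor, t_sc, 11500)  # 69131 years
```

The same estimators recover a simulated truth. A 5-Mb chromosome with a
10% donor pulse 5,000 generations ago (r = 10⁻⁸ M/bp), scanned with the
reference-free archaic HMM:

```r
p <- scenario_params(chrom_length = 5e6, seed = 42, a = 0.1, t_adm = 5000,
                     r = 1e-8, m = 0,
                     n_hap = c(O = 2, P3 = 2, P1e = 8, P1w = 0, P2 = 8))
sim <- simulate_panel(p)
sim$panel
#> <hap_panel> chr1: 20 haplotypes x 33365 sites (polarized)
#>   populations: O=2, P1e=8, P2=8, P3=2

det <- detect_archaic(sim$panel, focal_pop = "P2", reference_pop = "P1e")
mean(det$f_archaic$per_window$fraction)
#> 0.095        # fraction of haplotypes on archaic tracts; simulated a = 0.1

L_hat <- mean_tract_length(det$tracts)
tract_length_date(L_hat, f = 0.1, r = 1e-8)
#> 4165         # generations; simulated 5000 (called tracts are merged a
#>              # little long on this short chromosome -- the 10-Mb
#>              # acceptance scenario recovers within ~10-15%)
transition_date(det$p_mean, r = 1e-8, L = 1000, a = 0.1, k = 1)$generations
#> 4273         # the independent transition-parameter estimator
```

`mean F_archaic` is the per-window fraction of haplotypes covered by
called archaic tracts — with no planted RI islands it estimates the pulse
fraction `a`. The two dating routes use completely different information
(tract lengths vs. HMM switch rates) and should agree within tens of
percent; a large disagreement flags either selection on tracts or a
mis-specified recombination rate.

The full pipeline — F<sub>ST</sub>, painting, the ratio HMM, islands, and
conditioned spectra — is exercised end-to-end in
`tests/testthat/test-acceptance.R`, and the methods and their assumptions
are documented in `vignettes/introgression-scan.Rmd`.

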