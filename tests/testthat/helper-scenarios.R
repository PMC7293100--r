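# Reference simulation scenarios shared by the acceptance tests. Each is
# computed once per test run and cached; the scenario settings are the study
# conditions (see the methods vignette) and are fixed independently of any
# test outcome.

.scenario_cache <- new.env(parent = emptyenv())

scenario_fixture <- function(name, builder) {
  if (!exists(name, envir = .scenario_cache))
    assign(name, builder(), envir = .scenario_cache)
  get(name, envir = .scenario_cache)
}

# 10-Mb chromosome, a = 0.1, t_adm = 5000 generations, r = 1e-8 M/bp:
# the parameter-recovery scenario for both dating estimators
dating_scenario <- function() scenario_fixture("dating", function() {
  p <- scenario_params(chrom_length = 1e7, seed = 11, r = 1e-8,
                       a = 0.1, t_adm = 5000, m = 0,
                       n_hap = c(O = 2, P3 = 2, P1e = 16, P1w = 0, P2 = 16))
  sim <- simulate_panel(p)
  det <- detect_archaic(sim$panel, "P2", "P1e")
  list(params = p, sim = sim, det = det)
})

# 5-Mb chromosome with three RI islands (1.2 Mb total), donor pulse at
# a = 0.05 forced to q_ri = 0.9 inside islands, secondary contact m = 0.3
# suppressed inside; leak at 1% so that diagnostic sites dominate the
# ILS stand-in (the f_D tracking condition)
ri_scenario <- function() scenario_fixture("ri", function() {
  ri <- data.frame(start = c(1.0e6, 2.6e6, 4.2e6),
                   end = c(1.4e6, 3.1e6, 4.5e6))
  p <- scenario_params(chrom_length = 5e6, seed = 9, r = 3e-8,
                       a = 0.05, t_adm = 5000, t_sc = 2300, m = 0.3,
                       q_ri = 0.9, ri_intervals = ri, p_leak = 0.01,
                       n_hap = c(O = 2, P3 = 2, P1e = 12, P1w = 12, P2 = 24))
  sim <- simulate_panel(p)
  w <- make_windows(sim$panel, span = 50000, min_snps = 500)
  fst <- weir_cockerham_fst(sim$panel, "P2", "P1w", windows = w)
  painted <- paint_population(sim$panel, "P1w", "P2", "P1e",
                              switch_rate = 3e-8 * 2300)
  track <- build_ratio(fst$per_window, painted$f_intro$per_window$fraction,
                       n_haplotypes = 24)
  fit <- fit_ri_hmm(track)
  islands <- call_islands(fit, w, alpha = 0.001)
  list(params = p, sim = sim, ri = ri, windows = w, fst = fst,
       painted = painted, fit = fit, islands = islands)
})

# null scenario: no admixture in either direction, 50 windows of 50 kb
null_scenario <- function() scenario_fixture("null", function() {
  p <- scenario_params(chrom_length = 2.5e6, seed = 21, a = 0, m = 0,
                       n_hap = c(O = 2, P3 = 2, P1e = 12, P1w = 12, P2 = 12))
  sim <- simulate_panel(p)
  w <- make_windows(sim$panel, span = 50000, min_snps = 500)
  list(params = p, sim = sim, windows = w)
})
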