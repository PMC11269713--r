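# Shared simulation fixtures, built once per test run and cached in the
# session. Three worlds are used:
#  - the reference world: sim_config() defaults (N = 500, L = 2 Mb,
#    s = 0.05), used for the end-to-end recovery criterion;
#  - a scaled world (N = 200) for cheap structural tests, with s and rates
#    scaled to keep N*s and theta fixed;
#  - a small null world (N = 100, theta matched via mu) for the 50,000-SNP
#    neutral calibration criterion, where per-replicate cost matters most.

scaled_config <- function(s = 0, sweep_start_gen = 0, L = 2e6,
                          n_sample = c(TBP = 50, DUROC = 25, YKX = 16)) {
  sim_config(N = 200, L = L, mu = 2.5e-7, rho = 2.5e-8, burn_in = 400,
             split_target = 150, split_refs = 100, s = s,
             sweep_pos = L / 2, sweep_start_gen = sweep_start_gen,
             n_sample = n_sample)
}

null_config <- function(s = 0, sweep_start_gen = 0) {
  sim_config(N = 100, L = 2e6, mu = 1e-6, rho = 1.25e-7, burn_in = 200,
             split_target = 60, split_refs = 30, s = s,
             sweep_start_gen = sweep_start_gen,
             n_sample = c(TBP = 30, DUROC = 15, YKX = 8))
}

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .sim_cache)) assign(key, fn(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# panels of one replicate, pooled-MAF filtered, as a calibration pair
calib_pair <- function(cfg, seed) {
  s <- simulate_populations(cfg, seed = seed)
  p <- pooled_maf_filter(s$panels)
  list(target = p$TBP, ref = p$DUROC, sweep_pos = s$truth$sweep_pos)
}

# reference-world calibration: 6 neutral + 8 sweep replicates; also keeps
# the neutral composite scores as the null threshold reference
get_calibration <- function() {
  cached("calib_ref", function() {
    cfg_n <- sim_config(s = 0, sweep_start_gen = 0)
    neutral <- lapply(1:6, function(i) calib_pair(cfg_n, seed = 1000 + i))
    sweep <- lapply(1:8, function(i) calib_pair(sim_config(), seed = 2000 + i))
    calib <- calibrate_cms(neutral, sweep, flank = 2.5e4, min_values = 50)
    null_cms <- unlist(lapply(neutral, function(pp)
      cms_score(compute_site_scores(pp$target, pp$ref), calib)$cms))
    list(dists = calib, null_cms = null_cms)
  })
}

# null-world calibration (same simulator, smaller N; moderate sweep so all
# five statistics stay defined around the swept site)
get_null_calibration <- function() {
  cached("calib_null", function() {
    neutral <- lapply(1:4, function(i)
      calib_pair(null_config(), seed = 4000 + i))
    sweep <- lapply(1:5, function(i)
      calib_pair(null_config(s = 0.15, sweep_start_gen = 30),
                 seed = 5000 + i))
    calibrate_cms(neutral, sweep, flank = 1e5, min_values = 50)
  })
}

# a small scaled study reused by structural tests
get_small_study <- function() {
  cached("small_study", function() {
    simulate_study(scaled_config(s = 0.125, sweep_start_gen = 70), seed = 42)
  })
}
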