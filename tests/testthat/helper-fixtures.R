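# Shared simulated fixtures, built once per test run and cached.

fix_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_pair(sim_config(n_snps = 10000L, seed = 42L))
    }
    cache
  }
})

# The two-chromosome change-point scenario at purity 0.7 with ~500
# heterozygous SNPs per flank, plus its fit and detectability report.
fix_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- changepoint_scenario(kappa = 0.7, snps_per_region = 1250L,
                             seed = 20260301L)
      fit <- tumorboost(sim$pair)
      report <- evaluate_pair(fit, sim$specs, eval_config(seed = 99L))
      cache <<- list(sim = sim, fit = fit, report = report)
    }
    cache
  }
})

report_value <- function(report, label, signal, h, col) {
  report[report$label == label & report$signal == signal &
           report$h == h, col]
}
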