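test_that("configurations reject broken segment tilings", {
  expect_error(sim_config(segments = data.frame(
    chromosome = "1", start = c(1, 50), end = c(100, 120),
    c1 = c(1, 1), c2 = c(1, 2))), class = "bafnorm_config_error")
  expect_error(simulate_pair(sim_config(
    segments = data.frame(chromosome = "1", start = 1, end = 100,
                          c1 = 1, c2 = 1),
    positions = data.frame(chromosome = "1", position = c(50, 200)))),
    class = "bafnorm_config_error")
})

test_that("noise-free limits reproduce the exact mixture signals", {
  loh <- sim_config(n_snps = 2000, seed = 2, kappa = 1, noise_sd = 0,
                    offset = 0, affinity_sd = 0,
                    segments = data.frame(chromosome = "1", start = 1,
                                          end = 1e8, c1 = 0, c2 = 2))
  sim <- simulate_pair(loh)
  het <- sim$truth$genotype == 0.5
  expect_true(all(sim$pair$beta_t[het] %in% c(0, 1)))
  expect_equal(tumor_tcn(sim$pair), rep(2, nrow(sim$pair)))

  gain <- sim_config(n_snps = 1000, seed = 3, kappa = 0.6, noise_sd = 0,
                     offset = 0, affinity_sd = 0,
                     segments = data.frame(chromosome = "1", start = 1,
                                           end = 1e8, c1 = 1, c2 = 2))
  sim2 <- simulate_pair(gain)
  expect_equal(tumor_tcn(sim2$pair),
               rep(0.6 * 3 + 0.4 * 2, nrow(sim2$pair)), tolerance = 1e-12)
})

test_that("at zero purity the tumor mirrors the normal per genotype", {
  sim <- simulate_pair(sim_config(n_snps = 5000, seed = 4, kappa = 0))
  for (g in c(0, 0.5, 1)) {
    sel <- sim$truth$genotype == g
    expect_equal(mean(sim$pair$beta_t[sel]), mean(sim$pair$beta_n[sel]),
                 tolerance = 0.01)
  }
})

test_that("shared affinities create the genotype-specific diagonal structure", {
  sim <- fix_sim()  # sigma_phi = 0.3, offset 0.2, diploid, J = 1e4
  het <- sim$truth$genotype == 0.5
  expect_gt(cor(sim$pair$beta_n[het], sim$pair$beta_t[het]), 0.5)
})

test_that("het tumor fractions concentrate at the contamination-model bands", {
  sim <- simulate_pair(sim_config(
    n_snps = 8000, seed = 6, kappa = 0.7, offset = 0,
    segments = data.frame(chromosome = "1", start = 1, end = 1e8,
                          c1 = 0, c2 = 2)))
  het <- sim$truth$genotype == 0.5
  for (major in c(TRUE, FALSE)) {
    sel <- het & sim$truth$b_on_major == major
    b_copies <- if (major) 2 else 0
    expected <- true_het_beta(pcn_state(0, 2), 0.7, b_copies)
    se <- sd(sim$pair$beta_t[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(sim$pair$beta_t[sel]) - expected), 3 * se + 0.01)
  }
})

test_that("simulated genotype frequencies satisfy Hardy-Weinberg", {
  sim <- fix_sim()
  ep <- 0.35
  ep2 <- 0.35^2 + 0.3^2 / 12
  expected <- c(1 - 2 * ep + ep2, 2 * (ep - ep2), ep2)
  obs <- as.numeric(table(factor(sim$truth$genotype,
                                 levels = c(0, 0.5, 1)))) /
    nrow(sim$truth)
  se <- sqrt(expected * (1 - expected) / nrow(sim$truth))
  expect_true(all(abs(obs - expected) < 3 * se))
})

test_that("an additive offset compresses allele fractions toward one half", {
  s0 <- simulate_pair(sim_config(n_snps = 5000, seed = 9, offset = 0))
  s1 <- simulate_pair(sim_config(n_snps = 5000, seed = 9, offset = 0.5))
  expect_lt(mean(mirrored_baf(s1$pair$beta_n)),
            mean(mirrored_baf(s0$pair$beta_n)))
})

test_that("the change-point scenario emits the five canonical specs", {
  scen <- fix_scenario()
  specs <- scen$sim$specs
  expect_named(specs, c("N/G", "G/L", "N/D", "D/L", "N/N"))
  expect_equal(unclass(specs[["N/N"]]$state1), unclass(specs[["N/N"]]$state2))
  expect_equal(unname(unclass(specs[["G/L"]]$state1)), c(1, 2))
  expect_equal(unname(unclass(specs[["G/L"]]$state2)), c(0, 2))
  # every flank holds enough heterozygous SNPs for J' = 250 sampling
  calls <- scen$fit
  for (sp in specs) {
    fl <- extract_flanking_signals(
      data.frame(chromosome = scen$sim$pair$chromosome,
                 position = scen$sim$pair$position,
                 value = scen$sim$pair$beta_t),
      structure(list(mu_hat = scen$fit$mu_hat,
                     chromosome = scen$sim$pair$chromosome,
                     position = scen$sim$pair$position),
                class = "genotype_calls"),
      sp)
    expect_gte(length(fl$region1$values), 250)
    expect_gte(length(fl$region2$values), 250)
  }
  # reproducible under a fixed seed
  again <- changepoint_scenario(kappa = 0.7, snps_per_region = 1250L,
                           seed = 20260301L)
  expect_identical(again$pair, scen$sim$pair)
  expect_identical(again$truth, scen$sim$truth)
})
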