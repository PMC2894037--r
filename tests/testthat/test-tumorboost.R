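test_that("SNP effect and eta match their defining arithmetic", {
  expect_equal(snp_effect(c(0.05, 0.55, 1.0), c(0, 0.5, 1)),
               c(0.05, 0.05, 0))
  expect_true(is.na(snp_effect(0.4, NA)))
  expect_equal(eta(0.3, 0.6), 0.5)
  expect_equal(eta(0.7, 0.4), 0.5)
  x <- seq(0.05, 0.95, by = 0.05)
  expect_equal(eta(x, x), rep(1, length(x)))
  expect_error(eta(0.3, 0), class = "bafnorm_degenerate_denominator")
  expect_error(eta(0.3, 1), class = "bafnorm_degenerate_denominator")
})

test_that("per-SNP normalization matches the eta formula on both branches", {
  expect_equal(normalize_beta(0.3, 0.6, 0.5)$beta, 0.25)
  expect_equal(normalize_beta(0.7, 0.4, 0.5)$beta, 0.75)
  expect_identical(normalize_beta(0.55, 0.55, 0.5)$beta, 0.5)
  expect_equal(normalize_beta(0.08, 0.05, 0)$beta, 0.03)
  # brute-force evaluation of beta_t - eta * (beta_n - 1/2)
  set.seed(31)
  bt <- runif(400)
  bn <- runif(400, 0.01, 0.99)
  res <- normalize_beta(bt, bn, rep(0.5, 400))
  brute <- bt - eta(bt, bn) * (bn - 0.5)
  expect_equal(res$beta, brute, tolerance = 1e-12)
  expect_true(all(res$beta >= 0 & res$beta <= 1))
  expect_equal(res$eta, eta(bt, bn), tolerance = 1e-15)
})

test_that("heterozygous path is monotone in beta_t and stays in [0, 1]", {
  for (bn in c(0.2, 0.45, 0.55, 0.8)) {
    bt <- seq(0, 1, by = 0.001)
    out <- normalize_beta(bt, rep(bn, length(bt)), rep(0.5, length(bt)))$beta
    expect_true(all(diff(out) >= 0))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("missing or degenerate SNPs are passed through and flagged", {
  res <- normalize_beta(c(0.4, 0.4, NA, 0.4), c(0.5, 0, 0.5, NA),
                        c(NA, 0.5, 0.5, 0.5))
  expect_equal(res$beta, c(0.4, 0.4, NA, 0.4))
  expect_false(any(res$normalized))
  expect_true(all(is.na(res$eta)))
  # homozygous output is not truncated by default, clamp on request
  expect_equal(normalize_beta(0.02, 0.09, 0)$beta, -0.07)
  expect_equal(normalize_beta(0.02, 0.09, 0, clamp_hom = TRUE)$beta, 0)
})

test_that("normalizing the normal against itself returns the genotype exactly", {
  sim <- fix_sim()
  pair <- sim$pair
  pair$beta_t <- pair$beta_n
  pair$theta_t <- pair$theta_n
  fit <- tumorboost(pair)
  ok <- fit$normalized
  expect_gt(sum(ok), 9000)
  expect_identical(fit$beta_t_norm[ok], fit$mu_hat[ok])
})

test_that("total signals and TCN are untouched by normalization", {
  sim <- fix_sim()
  fit <- tumorboost(sim$pair)
  expect_identical(fit$data$theta_t, sim$pair$theta_t)
  expect_identical(fit$data$theta_n, sim$pair$theta_n)
  expect_identical(dh_track(fit)$tcn, tumor_tcn(sim$pair))
})

test_that("normalization is per-SNP local and chunk-independent", {
  set.seed(17)
  bt <- runif(300)
  bn <- runif(300, 0.01, 0.99)
  mu <- sample(c(0, 0.5, 1), 300, replace = TRUE)
  perm <- sample.int(300)
  expect_identical(normalize_beta(bt, bn, mu)$beta[perm],
                   normalize_beta(bt[perm], bn[perm], mu[perm])$beta)

  sim <- fix_sim()
  calls <- call_genotypes_naive(sim$pair$beta_n)
  f1 <- tumorboost(sim$pair, calls, chunk_size = 137)
  f2 <- tumorboost(sim$pair, calls, chunk_size = 1e6)
  expect_identical(f1$beta_t_norm, f2$beta_t_norm)
  expect_identical(f1$eta, f2$eta)
})

test_that("normalization shrinks within-genotype spread and decorrelates the pair", {
  sim <- fix_sim()  # copy-neutral (diploid) genome, sigma_phi = 0.3
  fit <- tumorboost(sim$pair)
  for (g in c(0, 0.5, 1)) {
    sel <- !is.na(fit$mu_hat) & fit$mu_hat == g & fit$normalized
    expect_lt(var(fit$beta_t_norm[sel]), var(sim$pair$beta_t[sel]))
  }
  het <- !is.na(fit$mu_hat) & fit$mu_hat == 0.5 & fit$normalized
  expect_gt(cor(sim$pair$beta_n[het], sim$pair$beta_t[het]), 0.5)
  expect_lt(abs(cor(sim$pair$beta_n[het], fit$beta_t_norm[het])), 0.1)
})

test_that("dual intensity form preserves totals and inverts to the fraction", {
  expect_equal(dual_intensity_form(2, 0.25),
               data.frame(theta_a = 1.5, theta_b = 0.5))
  set.seed(23)
  theta <- runif(500, 0.1, 8)
  beta <- runif(500)
  ab <- dual_intensity_form(theta, beta)
  expect_equal(ab$theta_a + ab$theta_b, theta, tolerance = 2^-50)
  expect_equal(theta_beta(ab$theta_a, ab$theta_b)$beta, beta,
               tolerance = 1e-12)
})

test_that("normalized ASCN clusters tighten in a copy-neutral LOH region", {
  sim <- simulate_pair(sim_config(
    n_snps = 8000L, seed = 21L,
    segments = data.frame(chromosome = "1", start = 1, end = 1e8,
                          c1 = 0, c2 = 2)))
  fit <- tumorboost(sim$pair)
  het <- !is.na(fit$mu_hat) & fit$mu_hat == 0.5 & fit$normalized &
    sim$truth$genotype == 0.5
  tcn <- tumor_tcn(sim$pair)
  raw <- ascn(tcn[het], sim$pair$beta_t[het])
  nrm <- ascn(tcn[het], fit$beta_t_norm[het])
  branch <- sim$truth$b_on_major[het]
  within_var <- function(a) {
    mean(c(tapply(a$c_a, branch, var), tapply(a$c_b, branch, var)))
  }
  expect_lt(within_var(nrm), within_var(raw))
})

test_that("normalized DH equals the corrected tumor-normal difference", {
  expect_equal(dh_normalized(c(0.25, 0.5)), c(0.5, 0))
  b_hat <- normalize_beta(0.3, 0.6, 0.5)$beta
  expect_equal(dh_normalized(b_hat), (0.6 - 0.3) / 0.6)
})

test_that("genotype calls are aligned on coordinates, extras dropped", {
  sim <- fix_sim()
  calls <- call_genotypes_naive(sim$pair$beta_n,
                                chromosome = sim$pair$chromosome,
                                position = sim$pair$position)
  sub <- bafnorm:::subset_calls(calls, 1:9000)
  fit <- tumorboost(sim$pair, sub)
  expect_false(any(fit$normalized[9001:10000]))
  expect_identical(fit$beta_t_norm[9001:10000], sim$pair$beta_t[9001:10000])
  # coordinate-free calls must match the table length
  nocoord <- bafnorm:::subset_calls(calls, 1:9000)
  nocoord$chromosome <- NULL
  nocoord$position <- NULL
  expect_error(tumorboost(sim$pair, nocoord),
               class = "bafnorm_alignment_error")
})
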