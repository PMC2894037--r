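toy_spec <- function(margin = 5) {
  changepoint_spec("toy", "1", 0, 1000, 500, margin,
                   pcn_state(1, 1), pcn_state(0, 2))
}

toy_track <- function(n = 100) {
  pos <- seq(5, 995, length.out = n)
  data.frame(chromosome = "1", position = pos,
             value = as.numeric(pos > 500), stringsAsFactors = FALSE)
}

toy_calls <- function(n = 100, mu = 0.5) {
  structure(list(mu_hat = rep(mu, n), confidence = rep(1, n),
                 thresholds = c(0.3, 0.7), source = "external",
                 chromosome = rep("1", n),
                 position = seq(5, 995, length.out = n)),
            class = "genotype_calls")
}

test_that("changepoint specs reject inverted or empty-flank geometries", {
  expect_error(changepoint_spec("x", "1", 10, 5, 7, 0,
                                pcn_state(1, 1), pcn_state(1, 2)),
               class = "bafnorm_invalid_spec")
  expect_error(changepoint_spec("x", "1", 0, 100, 50, 60,
                                pcn_state(1, 1), pcn_state(1, 2)),
               class = "bafnorm_invalid_spec")
})

test_that("flank extraction excludes the safety region and splits states", {
  trk <- toy_track(100)
  # positions spaced 10 apart; margin 45 covers positions 455..545 (10 SNPs)
  fl <- extract_flanking_signals(trk, toy_calls(100), toy_spec(margin = 45))
  expect_equal(fl$n_excluded, 10)
  expect_equal(length(fl$region1$values) + length(fl$region2$values), 90)
  expect_true(all(fl$region1$values == 0) && all(fl$region2$values == 1))
  # margin covering no SNP: nothing excluded
  fl0 <- extract_flanking_signals(trk, toy_calls(100), toy_spec(margin = 1))
  expect_equal(fl0$n_excluded, 0)
  # het-only on an all-homozygous region is an error
  expect_error(
    extract_flanking_signals(trk, toy_calls(100, mu = 0), toy_spec()),
    class = "bafnorm_insufficient_data")
})

test_that("balanced sampling is reproducible and size-checked", {
  r1 <- rnorm(300)
  r2 <- rnorm(500)
  s <- balanced_sample(r1, r2, n = 250, seed = 10)
  expect_length(s$x, 250)
  expect_length(s$y, 250)
  expect_identical(s, balanced_sample(r1, r2, n = 250, seed = 10))
  s2 <- balanced_sample(r1, r2, n = 250, seed = 11)
  expect_false(identical(s, s2))
  expect_error(balanced_sample(r1, r2, n = 400, seed = 1),
               class = "bafnorm_insufficient_data")
})

test_that("pooled t statistic behaves at the null and under a unit shift", {
  x <- rep(c(0, 1), 20)
  expect_equal(t_statistic(x, x), 0)
  set.seed(3)
  a <- rnorm(250)
  b <- rnorm(250, 1)
  tt <- t_statistic(a, b)
  expect_equal(t_statistic(b, a), -tt)
  # expected |t| is sqrt(n/2); t sd approx sqrt(1 + ncp^2 / (2 df))
  expect_lt(abs(abs(tt) - sqrt(125)), 3 * sqrt(1 + 125 / (2 * 498)))
  expect_error(t_statistic(rep(1, 5), rep(1, 5)),
               class = "bafnorm_undefined_statistic")
  expect_error(t_statistic(1, 1:3), class = "bafnorm_insufficient_data")
})

test_that("bootstrap t summary is calibrated at the null and deterministic", {
  set.seed(8)
  r1 <- rnorm(400)
  r2 <- rnorm(400)
  cfg <- eval_config(n_sampled = 250, n_boot = 100, seed = 55)
  bt <- bootstrap_t(r1, r2, cfg)
  # E|t| of a null t statistic is about 0.8; generous band
  expect_gt(bt[["mean_t"]], 0.4)
  expect_lt(bt[["mean_t"]], 1.5)
  expect_lt(bt[["sd_t"]], bt[["mean_t"]])
  expect_identical(bt, bootstrap_t(r1, r2, cfg))
  b1 <- bootstrap_t(r1, r2, eval_config(n_sampled = 250, n_boot = 1,
                                        seed = 5))
  expect_equal(b1[["sd_t"]], 0)
})

test_that("binning averages full bins and drops the remainder", {
  expect_equal(bin_signal(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(bin_signal(c(1, 2, 3, 4, 9), 2), c(1.5, 3.5))
  v <- rnorm(10)
  expect_identical(bin_signal(v, 1), v)
  r <- structure(list(values = c(1, 2, 3, 4, 5), positions = c(1, 2, 3, 4, 5),
                      state_label = 1L), class = "region_signal")
  rb <- bin_signal(r, 2)
  expect_equal(rb$values, c(1.5, 3.5))
  expect_equal(rb$positions, c(1.5, 3.5))
})

test_that("ROC analysis separates, orients, and matches the binormal form", {
  perfect <- roc_curve(neg = runif(50), pos = runif(50) + 2)
  expect_equal(perfect$auc, 1)
  set.seed(1)
  neg <- rnorm(1e4)
  pos <- rnorm(1e4, 1)
  r <- roc_curve(neg, pos)
  expect_equal(r$auc, pnorm(1 / sqrt(2)), tolerance = 0.01)
  expect_equal(r$orientation, 1)
  # orientation flip leaves the AUC unchanged, sign recorded
  rflip <- roc_curve(-neg, -pos)
  expect_equal(rflip$auc, r$auc)
  expect_equal(rflip$orientation, -1)
  # invariance under strictly monotone transforms
  rexp <- roc_curve(exp(neg), exp(pos))
  expect_identical(rexp$auc, r$auc)
  # curve runs from (0,0) to (1,1), nondecreasing
  expect_equal(c(r$fp_rate[1], r$tp_rate[1]), c(0, 0))
  expect_equal(c(max(r$fp_rate), max(r$tp_rate)), c(1, 1))
  expect_true(all(diff(r$fp_rate) >= 0) && all(diff(r$tp_rate) >= 0))
  # null: identically distributed
  set.seed(2)
  rnull <- roc_curve(rnorm(5000), rnorm(5000))
  expect_equal(rnull$auc, 0.5, tolerance = 0.03)
})

test_that("hand-rolled AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  neg <- rnorm(800)
  pos <- rnorm(800, 0.6)
  ours <- roc_curve(neg, pos)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(0:1, each = 800), predictor = c(neg, pos),
    quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the change-point report is reproducible and well-formed", {
  scen <- fix_scenario()
  cfg <- eval_config(seed = 99)
  r1 <- evaluate_pair(scen$fit, scen$sim$specs["N/G"], cfg)
  r2 <- evaluate_pair(scen$fit, scen$sim$specs["N/G"], cfg)
  expect_identical(r1, r2)
  expect_setequal(r1$signal, c("tcn", "dh_raw", "dh_norm"))
  expect_setequal(r1$h, c(1, 2, 4))
  expect_true(all(r1$n_used > 0 & r1$n_used <= 250))
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  # equal counts enforced across compared signals at each resolution
  for (h in c(1, 2, 4)) expect_length(unique(r1$n_used[r1$h == h]), 1)
})
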