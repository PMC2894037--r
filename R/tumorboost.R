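# TumorBoost normalization: per-SNP, genotype-stratified correction of tumor
# allele B fractions using the matched normal. The SNP effect is estimated in
# the normal as delta = beta_N - mu_hat; homozygous SNPs are corrected by
# subtracting it fully, heterozygous SNPs with the eta safeguard against
# overcorrection in aberrant regions.

#' Estimated SNP effect in the normal
#'
#' `delta = beta_n - mu_hat`: the reproducible deviation of the observed
#' allele B fraction from its genotype value. `NA` genotype gives a missing
#' effect.
#'
#' @param beta_n Normal allele B fractions.
#' @param mu_hat Genotypes in `{0, 0.5, 1}` (or `NA`).
#' @return Numeric vector of SNP effects (allele-B-fraction units, may be
#'   negative).
#' @export
snp_effect <- function(beta_n, mu_hat) beta_n - mu_hat

#' Heterozygous-path scale factor eta
#'
#' The shrinkage factor protecting heterozygous SNPs from overcorrection:
#' `beta_t / beta_n` when `beta_t <= beta_n`, and symmetrically
#' `(1 - beta_t) / (1 - beta_n)` otherwise. Always in `[0, 1]` (clipped only
#' against floating-point spill).
#'
#' @param beta_t,beta_n Tumor and normal allele B fractions; `beta_n` must
#'   lie strictly inside `(0, 1)` on the heterozygous path.
#' @return Numeric vector of scale factors in `[0, 1]`.
#' @export
eta <- function(beta_t, beta_n) {
  deg <- !is.na(beta_n) & (beta_n <= 0 | beta_n >= 1)
  if (any(deg)) {
    stop_bafnorm(
      sprintf("beta_n in {0, 1} for %d heterozygous SNP(s): eta undefined",
              sum(deg)), "bafnorm_degenerate_denominator")
  }
  e <- ifelse(beta_t <= beta_n, beta_t / beta_n,
              (1 - beta_t) / (1 - beta_n))
  pmin(pmax(e, 0), 1)
}

#' Normalize tumor allele B fractions against the matched normal
#'
#' The per-SNP correction. Homozygous SNPs (`mu_hat` 0 or 1):
#' `beta_t - beta_n + mu_hat`, not truncated to `[0, 1]` unless
#' `clamp_hom = TRUE`. Heterozygous SNPs (`mu_hat = 0.5`):
#' `beta_t - eta * (beta_n - 1/2)`, computed through the algebraically
#' equivalent closed forms `beta_t / (2 * beta_n)` (when
#' `beta_t <= beta_n`) and `1 - (1 - beta_t) / (2 * (1 - beta_n))`
#' (otherwise), which keep the result in `[0, 1]` and make normalizing the
#' normal against itself return the genotype exactly. SNPs with a missing
#' genotype, a missing allele fraction, or a degenerate heterozygous
#' denominator (`beta_n` exactly 0 or 1) are passed through unchanged and
#' flagged as not normalized.
#'
#' @param beta_t,beta_n Tumor and normal allele B fractions.
#' @param mu_hat Normal genotypes in `{0, 0.5, 1}`, `NA` allowed.
#' @param clamp_hom Truncate homozygous-path output to `[0, 1]`?
#' @return A data frame with columns `beta` (normalized fraction), `eta`
#'   (scale factor used; 1 on the homozygous path; `NA` where not
#'   normalized) and `normalized` (logical flag).
#' @export
normalize_beta <- function(beta_t, beta_n, mu_hat, clamp_hom = FALSE) {
  n <- length(beta_t)
  stopifnot(length(beta_n) == n, length(mu_hat) == n)
  beta <- beta_t
  e <- rep(NA_real_, n)
  done <- rep(FALSE, n)

  ok <- !is.na(beta_t) & !is.na(beta_n) & !is.na(mu_hat)

  hom <- ok & (mu_hat == 0 | mu_hat == 1)
  if (any(hom)) {
    b <- beta_t[hom] - beta_n[hom] + mu_hat[hom]
    if (clamp_hom) b <- pmin(pmax(b, 0), 1)
    beta[hom] <- b
    e[hom] <- 1
    done[hom] <- TRUE
  }

  het <- ok & mu_hat == 0.5 & beta_n > 0 & beta_n < 1
  if (any(het)) {
    bt <- beta_t[het]
    bn <- beta_n[het]
    lower <- bt <= bn
    b <- ifelse(lower, bt / (2 * bn), 1 - (1 - bt) / (2 * (1 - bn)))
    ehet <- ifelse(lower, bt / bn, (1 - bt) / (1 - bn))
    beta[het] <- b
    e[het] <- pmin(pmax(ehet, 0), 1)
    done[het] <- TRUE
  }

  data.frame(beta = beta, eta = e, normalized = done)
}

#' TumorBoost normalization of a paired tumor-normal SNP table
#'
#' The main fitting function. Estimates per-SNP effects from the normal
#' sample and removes them from the tumor allele B fractions, stratified by
#' the normal genotype, one tumor-normal pair and one SNP at a time. Total
#' signals (`theta`) and total copy numbers are never adjusted. When no
#' genotype calls are supplied, the normal is genotyped with the naive
#' kernel-density genotyper ([call_genotypes_naive()]).
#'
#' @param pair A [paired_snps()] table.
#' @param calls Optional `"genotype_calls"` for the normal (naive or
#'   external). If the calls carry coordinates, SNPs are aligned on
#'   (chromosome, position) and the intersection is used; pair SNPs without
#'   a call are passed through unnormalized.
#' @param clamp_hom Truncate homozygous-path output to `[0, 1]`?
#' @param chunk_size SNPs processed per chunk (bounded-memory contract;
#'   default 1e6). Results are independent of the chunking.
#' @return An object of class `"tumorboost"`: list with the input `data`,
#'   aligned genotype vector `mu_hat`, `confidence`, `beta_t_norm`, `eta`,
#'   `normalized` flags, the normal `snp_effect`, and bookkeeping counts.
#' @examples
#' sim <- simulate_pair(sim_config(n_snps = 2000, seed = 7))
#' fit <- tumorboost(sim$pair)
#' summary(fit)
#' @export
tumorboost <- function(pair, calls = NULL, clamp_hom = FALSE,
                       chunk_size = 1e6) {
  stopifnot(inherits(pair, "paired_snps"), chunk_size >= 1)
  if (is.null(calls)) {
    calls <- call_genotypes_naive(pair$beta_n,
                                  chromosome = pair$chromosome,
                                  position = pair$position)
  }
  stopifnot(inherits(calls, "genotype_calls"))

  n <- nrow(pair)
  if (!is.null(calls$position) && !is.null(calls$chromosome)) {
    key_pair <- paste(pair$chromosome, pair$position)
    key_call <- paste(calls$chromosome, calls$position)
    idx <- match(key_pair, key_call)
    n_unmatched_calls <- sum(!(key_call %in% key_pair))
    mu <- calls$mu_hat[idx]
    conf <- calls$confidence[idx]
    if (n_unmatched_calls > 0 || anyNA(idx)) {
      log_msg("info", sprintf(
        "genotype alignment: %d call(s) not in table dropped, %d SNP(s) without a call",
        n_unmatched_calls, sum(is.na(idx))))
    }
  } else {
    if (length(calls) != n) {
      stop_bafnorm("genotype calls carry no coordinates and differ in length from the table",
                   "bafnorm_alignment_error")
    }
    mu <- calls$mu_hat
    conf <- calls$confidence
    n_unmatched_calls <- 0L
  }

  beta_t_norm <- numeric(n)
  eta_used <- numeric(n)
  normalized <- logical(n)
  starts <- seq(1L, n, by = as.integer(min(chunk_size, n)))
  for (s in starts) {
    i <- s:min(s + chunk_size - 1, n)
    res <- normalize_beta(pair$beta_t[i], pair$beta_n[i], mu[i],
                          clamp_hom = clamp_hom)
    beta_t_norm[i] <- res$beta
    eta_used[i] <- res$eta
    normalized[i] <- res$normalized
  }

  structure(list(
    data = pair,
    mu_hat = mu,
    confidence = conf,
    thresholds = calls$thresholds,
    genotype_source = calls$source,
    beta_t_norm = beta_t_norm,
    eta = eta_used,
    normalized = normalized,
    snp_effect = snp_effect(pair$beta_n, mu),
    clamp_hom = clamp_hom,
    n_dropped_calls = n_unmatched_calls,
    call = match.call()
  ), class = "tumorboost")
}

#' @export
print.tumorboost <- function(x, ...) {
  cat("TumorBoost-normalized tumor-normal pair\n")
  cat(sprintf("  SNPs: %d (%d normalized, %d passed through)\n",
              nrow(x$data), sum(x$normalized), sum(!x$normalized)))
  cat(sprintf("  genotypes: %s (AA %d, AB %d, BB %d, missing %d)\n",
              x$genotype_source,
              sum(x$mu_hat == 0, na.rm = TRUE),
              sum(x$mu_hat == 0.5, na.rm = TRUE),
              sum(x$mu_hat == 1, na.rm = TRUE),
              sum(is.na(x$mu_hat))))
  invisible(x)
}

#' @export
summary.tumorboost <- function(object, ...) {
  het <- !is.na(object$mu_hat) & object$mu_hat == 0.5 & object$normalized
  sd_raw <- stats::sd(object$data$beta_t[het])
  sd_norm <- stats::sd(object$beta_t_norm[het])
  r_raw <- if (sum(het) > 2) {
    stats::cor(object$data$beta_n[het], object$data$beta_t[het])
  } else NA_real_
  r_norm <- if (sum(het) > 2) {
    stats::cor(object$data$beta_n[het], object$beta_t_norm[het])
  } else NA_real_
  out <- list(
    n = nrow(object$data), n_normalized = sum(object$normalized),
    n_het = sum(het), sd_het_raw = sd_raw, sd_het_norm = sd_norm,
    cor_het_raw = r_raw, cor_het_norm = r_norm,
    genotype_source = object$genotype_source
  )
  class(out) <- "summary.tumorboost"
  out
}

#' @export
print.summary.tumorboost <- function(x, ...) {
  cat("TumorBoost normalization summary\n")
  cat(sprintf("  %d SNPs, %d normalized, %d heterozygous\n",
              x$n, x$n_normalized, x$n_het))
  cat(sprintf("  het beta_T sd: %.4f raw -> %.4f normalized\n",
              x$sd_het_raw, x$sd_het_norm))
  cat(sprintf("  het cor(beta_N, beta_T): %.3f raw -> %.3f normalized\n",
              x$cor_het_raw, x$cor_het_norm))
  invisible(x)
}

#' @export
fitted.tumorboost <- function(object, ...) object$beta_t_norm

#' Per-SNP effects estimated from the normal
#'
#' @param object A `"tumorboost"` fit.
#' @param ... Unused.
#' @return The SNP effects `beta_n - mu_hat` (`NA` where the genotype is
#'   missing).
#' @export
residuals.tumorboost <- function(object, ...) object$snp_effect

#' @export
plot.tumorboost <- function(x, ...) {
  het <- !is.na(x$mu_hat)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  col <- ifelse(x$mu_hat[het] == 0.5, "black", "grey60")
  graphics::plot(x$data$beta_n[het], x$data$beta_t[het], pch = ".",
                 col = col, xlab = expression(beta[N]),
                 ylab = expression(beta[T]), main = "raw", ...)
  graphics::abline(0, 1, col = "grey80")
  graphics::plot(x$data$beta_n[het], x$beta_t_norm[het], pch = ".",
                 col = col, xlab = expression(beta[N]),
                 ylab = expression(hat(beta)[T]), main = "normalized", ...)
  graphics::abline(0, 1, col = "grey80")
  invisible(x)
}

#' Dual allelic-intensity form of the normalized tumor
#'
#' Re-expresses normalized allele B fractions as corrected allele
#' intensities: `theta_b = theta_t * beta_norm`,
#' `theta_a = theta_t - theta_b`, so the total tumor signal is preserved
#' exactly (the identifiability constraint of the paired setup) and
#' converting back through [theta_beta()] recovers the normalized fraction.
#'
#' @param theta_t Tumor total SNP signals.
#' @param beta_t_norm Normalized tumor allele B fractions (defined).
#' @return A data frame with columns `theta_a` and `theta_b`.
#' @export
dual_intensity_form <- function(theta_t, beta_t_norm) {
  if (anyNA(beta_t_norm)) {
    stop_bafnorm("normalized beta undefined for some SNPs",
                 "bafnorm_undefined_beta")
  }
  theta_b <- theta_t * beta_t_norm
  data.frame(theta_a = theta_t - theta_b, theta_b = theta_b)
}

#' Corrected allele intensities from a fit
#'
#' @param fit A `"tumorboost"` fit.
#' @return [dual_intensity_form()] of the fit's tumor total signals and
#'   normalized fractions.
#' @export
normalized_intensities <- function(fit) {
  stopifnot(inherits(fit, "tumorboost"))
  dual_intensity_form(fit$data$theta_t, fit$beta_t_norm)
}

#' Normalized decrease in heterozygosity
#'
#' `2 * |beta_t_norm - 1/2|`; on the `beta_t <= beta_n` branch this equals
#' `(beta_n - beta_t) / beta_n`, i.e. the tumor-normal difference with the
#' eta correction factor.
#'
#' @param beta_t_norm Normalized tumor allele B fractions.
#' @return Values in `[0, 1]`.
#' @export
dh_normalized <- function(beta_t_norm) 2 * abs(beta_t_norm - 0.5)

#' Raw and normalized DH tracks of a fit
#'
#' @param fit A `"tumorboost"` fit.
#' @return Data frame with `chromosome`, `position`, `het` (normal
#'   heterozygous and normalized), `tcn`, `dh_raw`, `dh_norm`.
#' @export
dh_track <- function(fit) {
  stopifnot(inherits(fit, "tumorboost"))
  data.frame(
    chromosome = fit$data$chromosome,
    position = fit$data$position,
    het = !is.na(fit$mu_hat) & fit$mu_hat == 0.5 & fit$normalized,
    tcn = tumor_tcn(fit$data),
    dh_raw = dh(fit$data$beta_t),
    dh_norm = dh_normalized(fit$beta_t_norm),
    stringsAsFactors = FALSE
  )
}
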