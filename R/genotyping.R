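# Naive single-sample genotyping of the normal from its allele B fractions:
# a Gaussian-kernel density estimate on [0,1], thresholds at the local minima
# separating the genotype modes, interval-membership calls, and a
# distance-to-threshold confidence score.

#' Gaussian kernel density estimate of allele B fractions
#'
#' Estimates the empirical density of normal allele B fractions on a fixed
#' uniform grid of 512 points on `[0, 1]`, using a Gaussian kernel. The
#' default bandwidth is Silverman's rule-of-thumb (`stats::bw.nrd0`) on the
#' defined, `[0, 1]`-clipped values.
#'
#' @param beta_n Numeric vector of normal allele B fractions (`NA` allowed,
#'   dropped).
#' @param bandwidth Kernel bandwidth, or `NULL` for Silverman's rule.
#' @param min_snps Minimum number of defined values required (default 100).
#' @return An object of class `"beta_density"`: list with `grid` (512
#'   points on `[0,1]`), `density` (nonnegative values) and `bandwidth`.
#' @export
estimate_beta_density <- function(beta_n, bandwidth = NULL, min_snps = 100L) {
  x <- beta_n[!is.na(beta_n)]
  if (length(x) < min_snps) {
    stop_bafnorm(sprintf(
      "need at least %d defined allele B fractions, got %d",
      min_snps, length(x)), "bafnorm_insufficient_data")
  }
  x <- pmin(pmax(x, 0), 1)
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(x)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 0.01
  }
  d <- stats::density(x, bw = bandwidth, kernel = "gaussian",
                      from = 0, to = 1, n = 512L)
  # renormalize: kernels near the boundaries put mass outside [0, 1]
  step <- d$x[2] - d$x[1]
  mass <- sum((d$y[-1] + d$y[-length(d$y)]) / 2) * step
  structure(list(grid = d$x, density = d$y / mass, bandwidth = d$bw),
            class = "beta_density")
}

#' @export
print.beta_density <- function(x, ...) {
  cat(sprintf("Allele B fraction density: %d grid points on [0,1], bw = %.4g\n",
              length(x$grid), x$bandwidth))
  invisible(x)
}

# Local maxima / minima indices of a gridded curve (plateaus collapse to
# their first index).
local_extrema <- function(y) {
  n <- length(y)
  dy <- diff(y)
  sgn <- sign(dy)
  # carry sign through flat stretches
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  turns <- diff(sgn)
  maxima <- which(turns < 0) + 1L
  minima <- which(turns > 0) + 1L
  # boundary modes count as maxima (e.g. hom bands piling at 0 or 1)
  if (n >= 2 && y[1] > y[2]) maxima <- c(1L, maxima)
  if (n >= 2 && y[n] > y[n - 1]) maxima <- c(maxima, n)
  list(maxima = sort(unique(maxima)), minima = sort(unique(minima)))
}

# Peak prominence: height minus the higher of the two key saddles (lowest
# point between the peak and the nearest higher peak on each side; the
# curve edge if no higher peak exists).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    higher <- peaks[y[peaks] > h]
    left <- higher[higher < p]
    right <- higher[higher > p]
    lsad <- if (length(left)) min(y[max(left):p]) else min(y[1:p])
    rsad <- if (length(right)) min(y[p:min(right)]) else min(y[p:length(y)])
    h - max(lsad, rsad)
  }, numeric(1))
}

#' Genotype thresholds from the density of allele B fractions
#'
#' Finds the `n_classes - 1` local minima of the gridded density separating
#' the `n_classes` most prominent modes (three classes AA/AB/BB for diploid
#' chromosomes, two for hemizygous ones). Minima are the grid argmin between
#' consecutive selected peaks.
#'
#' @param dens A [estimate_beta_density()] result.
#' @param n_classes Number of genotype classes: 3 (diploid, default) or 2
#'   (hemizygous).
#' @return Numeric vector of `n_classes - 1` strictly increasing thresholds
#'   in `(0, 1)`.
#' @export
find_genotype_thresholds <- function(dens, n_classes = 3L) {
  stopifnot(inherits(dens, "beta_density"), n_classes %in% c(2L, 3L))
  ex <- local_extrema(dens$density)
  peaks <- ex$maxima
  if (length(peaks) < n_classes) {
    stop_bafnorm(sprintf(
      "found %d density mode(s), need %d for %d genotype classes",
      length(peaks), n_classes, n_classes), "bafnorm_mode_error",
      n_modes = length(peaks))
  }
  if (length(peaks) > n_classes) {
    prom <- peak_prominence(dens$density, peaks)
    peaks <- sort(peaks[order(prom, decreasing = TRUE)[seq_len(n_classes)]])
  }
  tau <- vapply(seq_len(n_classes - 1L), function(k) {
    lo <- peaks[k]
    hi <- peaks[k + 1L]
    seg <- lo:hi
    dens$grid[seg[which.min(dens$density[seg])]]
  }, numeric(1))
  if (any(diff(tau) <= 0) || any(tau <= 0) || any(tau >= 1)) {
    stop_bafnorm("degenerate thresholds detected", "bafnorm_mode_error",
                 n_modes = length(peaks))
  }
  tau
}

#' Genotype calls from allele B fractions and thresholds
#'
#' Calls each SNP by interval membership: with diploid thresholds
#' `(tau1, tau2)`, `mu_hat = 0` if `beta < tau1`, `1/2` if
#' `tau1 <= beta <= tau2` (values exactly on a threshold go to the middle,
#' heterozygous class), and `1` if `beta > tau2`. With a single hemizygous
#' threshold, `mu_hat` is 0 or 1. Missing `beta` yields a missing call.
#' The confidence score of a call is its distance to the nearest threshold
#' (0 exactly on a threshold, increasing with distance).
#'
#' @param beta_n Numeric vector of normal allele B fractions.
#' @param thresholds Ordered threshold vector (length 2 diploid, 1
#'   hemizygous), e.g. from [find_genotype_thresholds()].
#' @param chromosome,position Optional per-SNP coordinates carried along for
#'   downstream alignment.
#' @param source Call provenance label: `"naive"` or `"external"`.
#' @return An object of class `"genotype_calls"`: list with `mu_hat`
#'   (`0`, `0.5`, `1` or `NA`), `confidence`, `thresholds`, `source`, and
#'   optional `chromosome`/`position`.
#' @export
call_genotypes <- function(beta_n, thresholds, chromosome = NULL,
                           position = NULL, source = "naive") {
  stopifnot(length(thresholds) %in% c(1L, 2L), !is.unsorted(thresholds))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_bafnorm("thresholds must lie inside (0, 1)", "bafnorm_mode_error")
  }
  n <- length(beta_n)
  mu <- rep(NA_real_, n)
  ok <- !is.na(beta_n)
  if (length(thresholds) == 2L) {
    mu[ok & beta_n < thresholds[1]] <- 0
    mu[ok & beta_n >= thresholds[1] & beta_n <= thresholds[2]] <- 0.5
    mu[ok & beta_n > thresholds[2]] <- 1
  } else {
    mu[ok & beta_n <= thresholds[1]] <- 0
    mu[ok & beta_n > thresholds[1]] <- 1
  }
  conf <- rep(NA_real_, n)
  conf[ok] <- do.call(pmin, lapply(thresholds,
                                   function(t) abs(beta_n[ok] - t)))
  structure(list(
    mu_hat = mu, confidence = conf, thresholds = thresholds,
    source = source, chromosome = chromosome, position = position
  ), class = "genotype_calls")
}

#' Naive genotyping of a normal sample
#'
#' One-call convenience wrapper: density estimate, threshold detection, and
#' interval-membership calls on the pooled values, so that all SNPs are
#' genotyped with the same thresholds.
#'
#' @inheritParams call_genotypes
#' @inheritParams estimate_beta_density
#' @param n_classes Passed to [find_genotype_thresholds()].
#' @return A `"genotype_calls"` object.
#' @examples
#' set.seed(1)
#' b <- c(rnorm(300, 0.03, 0.02), rnorm(300, 0.5, 0.04), rnorm(300, 0.97, 0.02))
#' calls <- call_genotypes_naive(pmin(pmax(b, 0), 1))
#' table(calls$mu_hat)
#' @export
call_genotypes_naive <- function(beta_n, bandwidth = NULL, n_classes = 3L,
                                 chromosome = NULL, position = NULL,
                                 min_snps = 100L) {
  dens <- estimate_beta_density(beta_n, bandwidth = bandwidth,
                                min_snps = min_snps)
  tau <- find_genotype_thresholds(dens, n_classes = n_classes)
  call_genotypes(beta_n, tau, chromosome = chromosome, position = position,
                 source = "naive")
}

#' @export
print.genotype_calls <- function(x, ...) {
  tab <- table(factor(x$mu_hat, levels = c(0, 0.5, 1)), useNA = "always")
  cat(sprintf(
    "Genotype calls (%s): %d SNPs | AA %d, AB %d, BB %d, missing %d\n",
    x$source, length(x$mu_hat), tab[1], tab[2], tab[3], tab[4]))
  cat("thresholds:", paste(signif(x$thresholds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.genotype_calls <- function(x) length(x$mu_hat)

# Subset a genotype_calls object by index, preserving metadata.
subset_calls <- function(calls, idx) {
  structure(list(
    mu_hat = calls$mu_hat[idx], confidence = calls$confidence[idx],
    thresholds = calls$thresholds, source = calls$source,
    chromosome = if (!is.null(calls$chromosome)) calls$chromosome[idx],
    position = if (!is.null(calls$position)) calls$position[idx]
  ), class = "genotype_calls")
}

#' Drop the least-confident genotype calls
#'
#' Retains the `ceiling((1 - drop_fraction) * n)` calls with the highest
#' confidence scores; ties are broken by original (genomic) order, earlier
#' SNPs kept first. With `drop_fraction = 0` this is the identity.
#'
#' @param calls A `"genotype_calls"` object.
#' @param drop_fraction Proportion in `[0, 1)` of calls to drop (default
#'   0.10: the 10% least confident).
#' @return A `"genotype_calls"` subset, in genomic order, with an attribute
#'   `"kept"` giving the retained indices relative to the input.
#' @export
filter_by_confidence <- function(calls, drop_fraction = 0.10) {
  stopifnot(inherits(calls, "genotype_calls"),
            drop_fraction >= 0, drop_fraction < 1)
  n <- length(calls)
  k <- ceiling((1 - drop_fraction) * n)
  ord <- order(-calls$confidence, seq_len(n), na.last = TRUE)
  keep <- sort(ord[seq_len(k)])
  out <- subset_calls(calls, keep)
  attr(out, "kept") <- keep
  out
}
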