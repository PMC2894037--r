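# Change-point detectability evaluation: flanking-region extraction around a
# known change point with a safety margin, balanced without-replacement
# sampling, bootstrap two-sample t statistics, non-overlapping binning, and
# ROC analysis of how well a per-SNP statistic separates the two states.

#' Change-point specification
#'
#' One evaluation unit: a genomic region split by a known change point, a
#' safety margin absorbing localization error, and the parental copy-number
#' states of the two flanking regions.
#'
#' @param label Name of the change point (e.g. `"N/G"`).
#' @param chromosome Chromosome label.
#' @param region_start,region_end Region bounds in bp (closed interval).
#' @param changepoint Change-point position in bp, strictly inside the
#'   region.
#' @param safety_margin Margin in bp excluded on each side of the change
#'   point.
#' @param state1,state2 [pcn_state()] objects of the left and right flank.
#' @return An object of class `"changepoint_spec"`.
#' @export
changepoint_spec <- function(label, chromosome, region_start, region_end,
                             changepoint, safety_margin, state1, state2) {
  stopifnot(inherits(state1, "pcn_state"), inherits(state2, "pcn_state"),
            safety_margin >= 0)
  if (!(region_start < changepoint && changepoint < region_end)) {
    stop_bafnorm("need region_start < changepoint < region_end",
                 "bafnorm_invalid_spec")
  }
  if (changepoint - safety_margin <= region_start ||
      changepoint + safety_margin >= region_end) {
    stop_bafnorm("safety region leaves an empty flank",
                 "bafnorm_invalid_spec")
  }
  structure(list(
    label = label, chromosome = as.character(chromosome),
    region_start = region_start, region_end = region_end,
    changepoint = changepoint, safety_margin = safety_margin,
    state1 = state1, state2 = state2
  ), class = "changepoint_spec")
}

#' @export
print.changepoint_spec <- function(x, ...) {
  cat(sprintf(
    "Change point %s: chr %s %.3g-%.3g Mb, cp %.3g Mb (+/- %.3g Mb), (%g,%g) vs (%g,%g)\n",
    x$label, x$chromosome, x$region_start / 1e6, x$region_end / 1e6,
    x$changepoint / 1e6, x$safety_margin / 1e6,
    x$state1[["c1"]], x$state1[["c2"]], x$state2[["c1"]], x$state2[["c2"]]))
  invisible(x)
}

#' Extract the two flanking signal vectors of a change point
#'
#' Restricts a per-SNP track to the spec's region on its chromosome, removes
#' SNPs inside the closed safety interval
#' `[changepoint - margin, changepoint + margin]`, optionally keeps only
#' SNPs called heterozygous in the normal, and splits the remainder into the
#' two flanks.
#'
#' @param track Data frame with columns `chromosome`, `position`, `value`
#'   (per-SNP statistic: DH, normalized DH, or TCN).
#' @param calls `"genotype_calls"` aligned row-by-row with `track` (or
#'   `NULL` when `het_only = FALSE`).
#' @param spec A [changepoint_spec()].
#' @param het_only Keep only SNPs with `mu_hat == 0.5`?
#' @return List with `region1` and `region2` (each a `"region_signal"`:
#'   `values`, `positions`, `state_label`) and `n_excluded` (SNPs dropped by
#'   the safety region).
#' @export
extract_flanking_signals <- function(track, calls, spec, het_only = TRUE) {
  stopifnot(inherits(spec, "changepoint_spec"),
            all(c("chromosome", "position", "value") %in% names(track)))
  keep <- track$chromosome == spec$chromosome &
    track$position >= spec$region_start &
    track$position <= spec$region_end
  if (het_only) {
    if (is.null(calls)) {
      stop_bafnorm("het_only = TRUE requires genotype calls",
                   "bafnorm_alignment_error")
    }
    stopifnot(length(calls$mu_hat) == nrow(track))
    keep <- keep & !is.na(calls$mu_hat) & calls$mu_hat == 0.5
  }
  keep <- keep & !is.na(track$value)
  pos <- track$position[keep]
  val <- track$value[keep]
  in_safety <- pos >= spec$changepoint - spec$safety_margin &
    pos <= spec$changepoint + spec$safety_margin
  left <- !in_safety & pos < spec$changepoint
  right <- !in_safety & pos > spec$changepoint
  if (!any(left) || !any(right)) {
    stop_bafnorm(sprintf("empty flanking region for change point %s",
                         spec$label), "bafnorm_insufficient_data")
  }
  region <- function(sel, lab) {
    o <- order(pos[sel])
    structure(list(values = val[sel][o], positions = pos[sel][o],
                   state_label = lab), class = "region_signal")
  }
  list(region1 = region(left, 1L), region2 = region(right, 2L),
       n_excluded = sum(in_safety))
}

as_values <- function(x) if (inherits(x, "region_signal")) x$values else x

#' Balanced sampling of two flanking regions
#'
#' Uniform without-replacement samples of equal size `n` from each region,
#' balancing true positives and true negatives for ROC analysis and making
#' t statistics comparable across regions of different sizes.
#'
#' @param r1,r2 `"region_signal"` objects (or plain numeric vectors).
#' @param n Sample size per region; defaults to the smaller region size.
#' @param seed Optional integer seed for reproducibility.
#' @param replace Sample with replacement instead (off by default).
#' @return List with numeric vectors `x` and `y` of length `n` each.
#' @export
balanced_sample <- function(r1, r2, n = NULL, seed = NULL, replace = FALSE) {
  v1 <- as_values(r1)
  v2 <- as_values(r2)
  if (is.null(n)) n <- min(length(v1), length(v2))
  if (!replace && (n > length(v1) || n > length(v2))) {
    stop_bafnorm(sprintf(
      "cannot draw %d SNPs without replacement from regions of size %d and %d",
      n, length(v1), length(v2)), "bafnorm_insufficient_data")
  }
  if (!is.null(seed)) set.seed(seed)
  list(x = v1[sample.int(length(v1), n, replace = replace)],
       y = v2[sample.int(length(v2), n, replace = replace)])
}

#' Two-sample Student's t statistic
#'
#' Pooled-variance Student's t by default (`stats::t.test` with
#' `var.equal = TRUE`); Welch's unequal-variance statistic with
#' `pooled = FALSE`.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @param pooled Pooled-variance (Student) or Welch?
#' @return The signed t statistic (a scalar).
#' @export
t_statistic <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop_bafnorm("each sample needs at least two values",
                 "bafnorm_insufficient_data")
  }
  if (stats::var(x) + stats::var(y) <= 0) {
    stop_bafnorm("zero pooled variance: t statistic undefined",
                 "bafnorm_undefined_statistic")
  }
  unname(stats::t.test(x, y, var.equal = pooled)$statistic)
}

#' Evaluation configuration
#'
#' @param n_sampled Heterozygous SNPs drawn per region and bootstrap
#'   repetition (J'; default 250).
#' @param n_boot Bootstrap repetitions (B; default 100).
#' @param bin_sizes Bin widths H in data points (default `c(1, 2, 4)`).
#' @param het_only Restrict to SNPs heterozygous in the normal (default).
#' @param seed Integer seed driving all sampling.
#' @param replace Bootstrap with replacement (default without).
#' @param pooled Pooled-variance t (default) or Welch.
#' @return A list of class `"eval_config"`.
#' @export
eval_config <- function(n_sampled = 250L, n_boot = 100L,
                        bin_sizes = c(1L, 2L, 4L), het_only = TRUE,
                        seed = NULL, replace = FALSE, pooled = TRUE) {
  stopifnot(n_sampled >= 2, n_boot >= 1, all(bin_sizes >= 1))
  structure(list(n_sampled = as.integer(n_sampled),
                 n_boot = as.integer(n_boot),
                 bin_sizes = as.integer(bin_sizes), het_only = het_only,
                 seed = seed, replace = replace, pooled = pooled),
            class = "eval_config")
}

#' Bootstrap summary of the t statistic between two regions
#'
#' Repeats `n_boot` times: draw a balanced sample of `n_sampled` values per
#' region, compute `|t|`; reports the mean and standard deviation (the
#' "mean +/- sd" convention). The draw size is capped at the smaller region.
#'
#' @param r1,r2 `"region_signal"` objects or numeric vectors.
#' @param config An [eval_config()]. `config$seed`, if set, is applied once
#'   at entry.
#' @return Named numeric vector `c(mean_t, sd_t, n_used)`.
#' @export
bootstrap_t <- function(r1, r2, config = eval_config()) {
  v1 <- as_values(r1)
  v2 <- as_values(r2)
  n <- min(config$n_sampled, length(v1), length(v2))
  if (!is.null(config$seed)) set.seed(config$seed)
  tt <- vapply(seq_len(config$n_boot), function(b) {
    s <- balanced_sample(v1, v2, n = n, replace = config$replace)
    abs(t_statistic(s$x, s$y, pooled = config$pooled))
  }, numeric(1))
  sd_t <- if (config$n_boot == 1L) {
    log_msg("info", "n_boot = 1: reporting sd 0 by convention")
    0
  } else stats::sd(tt)
  c(mean_t = mean(tt), sd_t = sd_t, n_used = n)
}

#' Average a signal in non-overlapping bins
#'
#' Position-ordered groups of exactly `h` consecutive values are replaced by
#' their arithmetic mean; a trailing incomplete bin is dropped. `h = 1` is
#' the identity.
#'
#' @param r A `"region_signal"` or plain numeric vector (assumed
#'   position-ordered).
#' @param h Bin size in data points.
#' @return Same type as the input, binned.
#' @export
bin_signal <- function(r, h) {
  stopifnot(h >= 1)
  h <- as.integer(h)
  bin <- function(v) {
    if (h == 1L) return(v)
    nb <- length(v) %/% h
    if (nb == 0L) return(numeric(0))
    colMeans(matrix(v[seq_len(nb * h)], nrow = h))
  }
  if (inherits(r, "region_signal")) {
    structure(list(values = bin(r$values), positions = bin(r$positions),
                   state_label = r$state_label), class = "region_signal")
  } else {
    bin(r)
  }
}

#' ROC curve for separating two flanking regions
#'
#' Sweeps a threshold over the pooled values and traces the true-positive
#' rate against the false-positive rate. The orientation is chosen from the
#' sign of the mean difference so that larger (oriented) values indicate the
#' positive state and the AUC is at least 0.5 on average; the chosen sign is
#' recorded. Tied values collapse into a single threshold step and the AUC
#' is the trapezoidal area (equivalently the tie-corrected rank statistic).
#'
#' @param neg Values from the negative state (TCN equal to two, by the
#'   convention that the positive state is the one with TCN different from
#'   two).
#' @param pos Values from the positive state.
#' @return An object of class `"roc_curve"`: `fp_rate`, `tp_rate` (from
#'   (0,0) to (1,1)), `auc`, `orientation` (+1 or -1).
#' @export
roc_curve <- function(neg, pos) {
  neg <- as_values(neg)
  pos <- as_values(pos)
  if (!length(neg) || !length(pos)) {
    stop_bafnorm("both states need at least one value",
                 "bafnorm_insufficient_data")
  }
  orientation <- if (mean(pos) >= mean(neg)) 1 else -1
  v <- orientation * c(neg, pos)
  is_pos <- rep(c(FALSE, TRUE), c(length(neg), length(pos)))
  o <- order(v, decreasing = TRUE)
  v <- v[o]
  is_pos <- is_pos[o]
  # collapse ties: one step per distinct threshold
  last_of_run <- c(v[-1] != v[-length(v)], TRUE)
  tp <- cumsum(is_pos)[last_of_run] / length(pos)
  fp <- cumsum(!is_pos)[last_of_run] / length(neg)
  fp <- c(0, fp)
  tp <- c(0, tp)
  auc <- sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
  structure(list(fp_rate = fp, tp_rate = tp, auc = auc,
                 orientation = orientation), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC %.4f (orientation %+d, %d points)\n",
              x$auc, x$orientation, length(x$fp_rate)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fp_rate, x$tp_rate, type = "l",
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Full detectability report for one change point
#'
#' For each signal (TCN, raw DH, normalized DH) and each bin size H in the
#' configuration: extract the flanking regions (heterozygous SNPs by
#' default, safety region excluded), bin, compute the bootstrap t summary
#' and the ROC curve on balanced samples. All signals are evaluated on the
#' same SNPs, and the number of data points sampled is constrained to be
#' equal across the compared signals.
#'
#' @param track_raw,track_norm,track_tcn Numeric per-SNP vectors (raw DH,
#'   normalized DH, TCN), aligned row-by-row with `calls`.
#' @param calls `"genotype_calls"` carrying `chromosome` and `position`.
#' @param spec A [changepoint_spec()].
#' @param config An [eval_config()].
#' @return Data frame with columns `label`, `signal`, `h`, `mean_t`,
#'   `sd_t`, `auc`, `n_used`; ROC curves attached as attribute
#'   `"roc_curves"` (named `"<signal>.H<h>"`). Deterministic under
#'   `config$seed`.
#' @export
evaluate_changepoint <- function(track_raw, track_norm, track_tcn, calls,
                                 spec, config = eval_config()) {
  stopifnot(inherits(calls, "genotype_calls"),
            !is.null(calls$chromosome), !is.null(calls$position))
  n <- length(calls$mu_hat)
  stopifnot(length(track_raw) == n, length(track_norm) == n,
            length(track_tcn) == n)
  signals <- list(tcn = track_tcn, dh_raw = track_raw, dh_norm = track_norm)
  flanks <- lapply(signals, function(v) {
    extract_flanking_signals(
      data.frame(chromosome = calls$chromosome, position = calls$position,
                 value = v, stringsAsFactors = FALSE),
      calls, spec, het_only = config$het_only)
  })
  rows <- list()
  rocs <- list()
  k <- 0L
  for (h in config$bin_sizes) {
    binned <- lapply(flanks, function(f) {
      list(r1 = bin_signal(f$region1, h), r2 = bin_signal(f$region2, h))
    })
    # equal counts across compared signals at this resolution
    n_avail <- min(vapply(binned, function(b) {
      min(length(b$r1$values), length(b$r2$values))
    }, numeric(1)))
    n_used <- min(config$n_sampled, n_avail)
    for (sig in names(binned)) {
      k <- k + 1L
      sub <- config
      if (!is.null(config$seed)) sub$seed <- config$seed + k
      sub$n_sampled <- n_used
      bt <- bootstrap_t(binned[[sig]]$r1, binned[[sig]]$r2, sub)
      bs <- balanced_sample(binned[[sig]]$r1, binned[[sig]]$r2, n = n_used,
                            seed = if (!is.null(sub$seed)) sub$seed,
                            replace = config$replace)
      roc <- roc_curve(bs$x, bs$y)
      rows[[k]] <- data.frame(
        label = spec$label, signal = sig, h = h,
        mean_t = bt[["mean_t"]], sd_t = bt[["sd_t"]], auc = roc$auc,
        n_used = n_used, stringsAsFactors = FALSE)
      rocs[[paste0(sig, ".H", h)]] <- roc
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "roc_curves") <- rocs
  out
}

#' Evaluate aligned tracks over several change points
#'
#' Runs [evaluate_changepoint()] on each spec, offsetting the seed per spec
#' so reports are deterministic but draws differ between change points.
#'
#' @param track_raw,track_norm,track_tcn Per-SNP vectors aligned with
#'   `calls`.
#' @param calls `"genotype_calls"` carrying coordinates.
#' @param specs List of [changepoint_spec()] objects.
#' @param config An [eval_config()].
#' @return Combined report data frame (one block of rows per spec).
#' @export
evaluate_regions <- function(track_raw, track_norm, track_tcn, calls, specs,
                             config = eval_config()) {
  reports <- lapply(seq_along(specs), function(i) {
    sub <- config
    if (!is.null(config$seed)) sub$seed <- config$seed + 1000L * i
    evaluate_changepoint(track_raw, track_norm, track_tcn, calls,
                         specs[[i]], sub)
  })
  do.call(rbind, reports)
}

#' Evaluate a fitted pair over several change points
#'
#' Convenience wrapper deriving the raw DH, normalized DH and TCN tracks
#' from a [tumorboost()] fit and running [evaluate_regions()].
#'
#' @param fit A `"tumorboost"` fit.
#' @param specs List of [changepoint_spec()] objects.
#' @param config An [eval_config()].
#' @return Combined report data frame (one block of rows per spec).
#' @export
evaluate_pair <- function(fit, specs, config = eval_config()) {
  stopifnot(inherits(fit, "tumorboost"))
  calls <- structure(list(
    mu_hat = fit$mu_hat, confidence = fit$confidence,
    thresholds = fit$thresholds, source = fit$genotype_source,
    chromosome = fit$data$chromosome, position = fit$data$position
  ), class = "genotype_calls")
  trk <- dh_track(fit)
  evaluate_regions(trk$dh_raw, trk$dh_norm, trk$tcn, calls, specs, config)
}
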