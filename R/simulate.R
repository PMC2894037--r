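# Synthetic paired tumor-normal generator. SNP effects arise mechanistically
# from per-SNP multiplicative allele affinities shared between the two
# hybridizations of a pair, plus an additive offset and noise; tumor signals
# mix the tumor-cell parental copy numbers with normal cells at purity kappa.

#' Simulation configuration
#'
#' @param n_snps Number of SNPs (ignored when `positions` is given).
#' @param segments Data frame with columns `chromosome`, `start`, `end`,
#'   `c1`, `c2`: the tumor's parental copy-number segments, tiling each
#'   chromosome without overlap. Default: one diploid chromosome of 100 Mb.
#' @param kappa Tumor purity in `[0, 1]` (default 0.7).
#' @param maf_range Minor-allele-frequency interval; per-SNP MAF is drawn
#'   uniformly from it (default `c(0.2, 0.5)`).
#' @param affinity_sd SD of the log per-SNP per-allele multiplicative
#'   affinities (sigma_phi, default 0.3): the source of the reproducible
#'   genotype-specific SNP effect.
#' @param offset Additive intensity offset (default 0.2): emulates
#'   incomplete offset correction, compressing allele B fractions toward
#'   1/2.
#' @param noise_sd SD of additive intensity noise per allele (default 0.03).
#' @param scale Global intensity scale; the diploid total signal is
#'   approximately `scale` (default 2, so totals read like copy numbers).
#' @param seed Integer seed; all randomness of [simulate_pair()] flows from
#'   it.
#' @param positions Optional data frame `chromosome`, `position` fixing the
#'   SNP coordinates.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 10000L, segments = NULL, kappa = 0.7,
                       maf_range = c(0.2, 0.5), affinity_sd = 0.3,
                       offset = 0.2, noise_sd = 0.03, scale = 2,
                       seed = NULL, positions = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(chromosome = "1", start = 1, end = 1e8,
                           c1 = 1, c2 = 1, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chromosome", "start", "end", "c1", "c2") %in%
                  names(segments)),
            kappa >= 0, kappa <= 1, affinity_sd >= 0, noise_sd >= 0,
            offset >= 0, scale > 0,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            all(segments$c1 <= segments$c2), all(segments$c1 >= 0))
  for (chr in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == chr, ]
    s <- s[order(s$start), ]
    if (any(s$start > s$end) ||
        (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))) {
      stop_bafnorm(sprintf("segments overlap or are inverted on chromosome %s",
                           chr), "bafnorm_config_error")
    }
  }
  structure(list(n_snps = as.integer(n_snps), segments = segments,
                 kappa = kappa, maf_range = maf_range,
                 affinity_sd = affinity_sd, offset = offset,
                 noise_sd = noise_sd, scale = scale, seed = seed,
                 positions = positions),
            class = "sim_config")
}

# Segment index for each SNP; NA outside all segments.
assign_segments <- function(segments, chromosome, position) {
  seg_id <- rep(NA_integer_, length(position))
  for (chr in unique(chromosome)) {
    rows <- which(segments$chromosome == chr)
    rows <- rows[order(segments$start[rows])]
    sel <- chromosome == chr
    i <- findInterval(position[sel], segments$start[rows])
    ok <- i >= 1 & position[sel] <= segments$end[rows][pmax(i, 1)]
    seg_id[sel][ok] <- rows[i[ok]]
  }
  seg_id
}

#' Simulate one paired tumor-normal hybridization
#'
#' Generates per-SNP paired allele signals with full ground truth. Genotypes
#' follow Hardy-Weinberg at a per-SNP MAF; for heterozygous SNPs the B
#' allele sits on the minor or major parental copy with probability 1/2; the
#' tumor sample mixes tumor-cell and normal-cell allelic copy numbers at
#' purity `kappa`. Intensities are
#' `theta = phi * (c/2) * scale + offset + noise`, truncated at 0, with the
#' log-normal allele affinities `(phi_A, phi_B)` shared between the tumor
#' and the normal of the pair — the mechanism that reproduces the
#' genotype-specific SNP effect and its tumor-normal correlation.
#'
#' @param config A [sim_config()].
#' @return List with `pair` (a [paired_snps()] table) and `truth` (data
#'   frame: `chromosome`, `position`, `genotype`, `b_on_major`,
#'   `segment_id`, `c1`, `c2`, `maf`, `phi_a`, `phi_b`, `kappa`).
#' @examples
#' sim <- simulate_pair(sim_config(n_snps = 1000, seed = 1))
#' head(sim$truth)
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  seg <- config$segments

  if (is.null(config$positions)) {
    widths <- seg$end - seg$start + 1
    n_per <- stats::rmultinom(1, config$n_snps, widths / sum(widths))[, 1]
    chromosome <- rep(seg$chromosome, n_per)
    position <- round(stats::runif(sum(n_per), rep(seg$start, n_per),
                                   rep(seg$end, n_per)))
  } else {
    chromosome <- as.character(config$positions$chromosome)
    position <- config$positions$position
  }
  o <- order(chromosome, position)
  chromosome <- chromosome[o]
  position <- position[o]
  dup <- duplicated(paste(chromosome, position))
  chromosome <- chromosome[!dup]
  position <- position[!dup]
  n <- length(position)

  seg_id <- assign_segments(seg, chromosome, position)
  if (anyNA(seg_id)) {
    stop_bafnorm("some SNP positions fall outside all segments",
                 "bafnorm_config_error")
  }
  c1 <- seg$c1[seg_id]
  c2 <- seg$c2[seg_id]

  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  g <- stats::runif(n)
  mu <- ifelse(g < (1 - maf)^2, 0, ifelse(g < (1 - maf)^2 +
                                            2 * maf * (1 - maf), 0.5, 1))
  het <- mu == 0.5
  b_on_major <- rep(NA, n)
  b_on_major[het] <- stats::runif(sum(het)) < 0.5

  # tumor-cell allelic copy numbers given the segment state
  c_tb <- ifelse(het, ifelse(b_on_major, c2, c1), (c1 + c2) * mu)
  c_ta <- (c1 + c2) - c_tb
  # normal-cell allelic copy numbers from the genotype
  c_nb <- 2 * mu
  c_na <- 2 - c_nb
  # cell mixture observed in the tumor sample
  kap <- config$kappa
  c_Ta <- kap * c_ta + (1 - kap) * c_na
  c_Tb <- kap * c_tb + (1 - kap) * c_nb

  phi_a <- exp(stats::rnorm(n, 0, config$affinity_sd))
  phi_b <- exp(stats::rnorm(n, 0, config$affinity_sd))
  intensity <- function(phi, cn) {
    pmax(0, phi * (cn / 2) * config$scale + config$offset +
           stats::rnorm(n, 0, config$noise_sd))
  }
  pair <- paired_snps_from_intensities(
    chromosome, position,
    theta_a_normal = intensity(phi_a, c_na),
    theta_b_normal = intensity(phi_b, c_nb),
    theta_a_tumor = intensity(phi_a, c_Ta),
    theta_b_tumor = intensity(phi_b, c_Tb)
  )
  truth <- data.frame(
    chromosome = chromosome, position = position, genotype = mu,
    b_on_major = b_on_major, segment_id = seg_id, c1 = c1, c2 = c2,
    maf = maf, phi_a = phi_a, phi_b = phi_b, kappa = kap,
    stringsAsFactors = FALSE
  )
  list(pair = pair, truth = truth)
}

#' Two-chromosome change-point scenario
#'
#' Builds a synthetic genome replicating the canonical evaluation layout:
#' chromosome 2 with a normal (1,1) region, a single-copy gain (1,2) from
#' 124 Mb and a copy-neutral LOH (0,2) from 141 Mb; chromosome 10 with a
#' hemizygous deletion (0,1) from 94 Mb and a copy-neutral LOH (0,2) from
#' 110 Mb. Five change-point specs are emitted: N/G, G/L, N/D, D/L, and an
#' N/N negative control, each with a 0.5 Mb safety margin per side. SNP
#' positions are drawn uniformly within each flank (plus 5% inside each
#' safety region) so that every flank holds about
#' `snps_per_region * E[2p(1-p)]` heterozygous SNPs.
#'
#' @param kappa Tumor purity (default 0.7).
#' @param snps_per_region SNPs drawn per flanking region (default 1250,
#'   about 550 heterozygous at the default MAF range).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [sim_config()] (noise, offset,
#'   affinity_sd, ...).
#' @return List with `pair`, `truth` (as in [simulate_pair()]) and `specs`
#'   (named list of five [changepoint_spec()] objects).
#' @export
changepoint_scenario <- function(kappa = 0.7, snps_per_region = 1250L,
                            seed = NULL, ...) {
  Mb <- 1e6
  segments <- data.frame(
    chromosome = c("2", "2", "2", "10", "10", "10"),
    start = c(1, 124 * Mb + 1, 141 * Mb + 1, 1, 94 * Mb + 1, 110 * Mb + 1),
    end = c(124 * Mb, 141 * Mb, 158 * Mb, 94 * Mb, 110 * Mb, 114 * Mb),
    c1 = c(1, 1, 0, 1, 0, 0),
    c2 = c(1, 2, 2, 1, 1, 2),
    stringsAsFactors = FALSE
  )
  margin <- 0.5 * Mb
  specs <- list(
    `N/G` = changepoint_spec("N/G", "2", 108 * Mb, 140 * Mb, 124 * Mb,
                             margin, pcn_state(1, 1), pcn_state(1, 2)),
    `G/L` = changepoint_spec("G/L", "2", 125 * Mb, 157 * Mb, 141 * Mb,
                             margin, pcn_state(1, 2), pcn_state(0, 2)),
    `N/D` = changepoint_spec("N/D", "10", 80 * Mb, 109 * Mb, 94 * Mb,
                             margin, pcn_state(1, 1), pcn_state(0, 1)),
    `D/L` = changepoint_spec("D/L", "10", 106.5 * Mb, 113.5 * Mb, 110 * Mb,
                             margin, pcn_state(0, 1), pcn_state(0, 2)),
    `N/N` = changepoint_spec("N/N", "2", 55 * Mb, 75 * Mb, 60 * Mb,
                             margin, pcn_state(1, 1), pcn_state(1, 1))
  )
  if (!is.null(seed)) set.seed(seed)
  n_safety <- ceiling(0.05 * snps_per_region)
  intervals <- list()
  for (sp in specs) {
    lo <- sp$changepoint - sp$safety_margin
    hi <- sp$changepoint + sp$safety_margin
    intervals <- c(intervals, list(
      list(sp$chromosome, sp$region_start, lo, snps_per_region),
      list(sp$chromosome, hi, sp$region_end, snps_per_region),
      list(sp$chromosome, lo, hi, n_safety)
    ))
  }
  pos <- do.call(rbind, lapply(intervals, function(iv) {
    data.frame(chromosome = iv[[1]],
               position = round(stats::runif(iv[[4]], iv[[2]], iv[[3]])),
               stringsAsFactors = FALSE)
  }))
  config <- sim_config(segments = segments, kappa = kappa, seed = NULL,
                       positions = pos, ...)
  sim <- simulate_pair(config)
  c(sim, list(specs = specs))
}
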