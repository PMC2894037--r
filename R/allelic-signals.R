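# Core allele-signal representations: (theta_A, theta_B) <-> (theta, beta),
# total and allele-specific copy numbers, mirrored BAF, and decrease in
# heterozygosity (DH).

#' Convert allele intensities to total signal and allele B fraction
#'
#' Transforms summarized allele-specific SNP intensities `(theta_a, theta_b)`
#' into the total SNP signal `theta = theta_a + theta_b` and the allele B
#' fraction `beta = theta_b / theta`. The transform is bijective except when
#' `theta = 0`, where `beta` is undefined and returned as `NA` (an explicit
#' missing flag, never silent 0/0).
#'
#' @param theta_a,theta_b Numeric vectors of nonnegative summarized
#'   allele A and allele B intensities (arbitrary units, same length).
#' @return A data frame with columns `theta` and `beta`. `beta` is `NA`
#'   where `theta == 0`.
#' @examples
#' theta_beta(3, 1)        # theta 4, beta 0.25
#' theta_beta(0, 0)$beta   # NA: undefined at theta == 0
#' @seealso [allele_intensities()] for the inverse transform.
#' @export
theta_beta <- function(theta_a, theta_b) {
  if (length(theta_a) != length(theta_b)) {
    stop_bafnorm("theta_a and theta_b must have equal length",
                 "bafnorm_invalid_signal")
  }
  bad <- (!is.na(theta_a) & (theta_a < 0 | !is.finite(theta_a))) |
         (!is.na(theta_b) & (theta_b < 0 | !is.finite(theta_b)))
  if (any(bad)) {
    stop_bafnorm(sprintf("negative or non-finite intensities at %d position(s)",
                         sum(bad)), "bafnorm_invalid_signal")
  }
  theta <- theta_a + theta_b
  beta <- ifelse(!is.na(theta) & theta > 0, theta_b / theta, NA_real_)
  data.frame(theta = theta, beta = beta)
}

#' Convert total signal and allele B fraction back to allele intensities
#'
#' Inverse of [theta_beta()]: `theta_a = theta * (1 - beta)`,
#' `theta_b = theta * beta`.
#'
#' @param theta Numeric vector of nonnegative total SNP signals.
#' @param beta Numeric vector of allele B fractions in `[0, 1]`; must be
#'   defined (non-`NA`).
#' @return A data frame with columns `theta_a` and `theta_b`.
#' @export
allele_intensities <- function(theta, beta) {
  if (anyNA(beta)) {
    stop_bafnorm("beta is undefined (NA) for some SNPs; cannot invert",
                 "bafnorm_undefined_beta")
  }
  if (any(beta < 0 | beta > 1)) {
    stop_bafnorm("beta outside [0, 1]", "bafnorm_invalid_signal")
  }
  data.frame(theta_a = theta * (1 - beta), theta_b = theta * beta)
}

#' Paired tumor-normal SNP table
#'
#' Container for per-SNP paired allele signals of one tumor-normal pair in
#' the `(theta, beta)` representation: a data frame of class `"paired_snps"`
#' with columns `chromosome`, `position`, `theta_n`, `beta_n`, `theta_t`,
#' `beta_t`. Positions must be 1-based and strictly increasing within each
#' chromosome.
#'
#' @param chromosome Chromosome label per SNP.
#' @param position 1-based base-pair coordinate per SNP.
#' @param theta_n,beta_n Total signal and allele B fraction in the normal.
#' @param theta_t,beta_t Total signal and allele B fraction in the tumor.
#' @return A `paired_snps` data frame.
#' @export
paired_snps <- function(chromosome, position, theta_n, beta_n,
                        theta_t, beta_t) {
  n <- length(position)
  if (length(chromosome) == 1L) chromosome <- rep(chromosome, n)
  lens <- c(length(chromosome), length(theta_n), length(beta_n),
            length(theta_t), length(beta_t))
  if (any(lens != n)) {
    stop_bafnorm("all per-SNP vectors must have equal length",
                 "bafnorm_alignment_error")
  }
  if (!check_sorted_positions(chromosome, position)) {
    stop_bafnorm("positions must be strictly increasing within chromosome",
                 "bafnorm_unsorted_positions")
  }
  out <- data.frame(
    chromosome = as.character(chromosome), position = as.numeric(position),
    theta_n = theta_n, beta_n = beta_n,
    theta_t = theta_t, beta_t = beta_t,
    stringsAsFactors = FALSE
  )
  class(out) <- c("paired_snps", "data.frame")
  out
}

#' Build a paired SNP table from allele intensities
#'
#' @param chromosome,position As in [paired_snps()].
#' @param theta_a_normal,theta_b_normal Allele A/B intensities in the normal.
#' @param theta_a_tumor,theta_b_tumor Allele A/B intensities in the tumor.
#' @return A `paired_snps` data frame.
#' @export
paired_snps_from_intensities <- function(chromosome, position,
                                         theta_a_normal, theta_b_normal,
                                         theta_a_tumor, theta_b_tumor) {
  tb_n <- theta_beta(theta_a_normal, theta_b_normal)
  tb_t <- theta_beta(theta_a_tumor, theta_b_tumor)
  paired_snps(chromosome, position,
              theta_n = tb_n$theta, beta_n = tb_n$beta,
              theta_t = tb_t$theta, beta_t = tb_t$beta)
}

#' @export
print.paired_snps <- function(x, ...) {
  cat(sprintf("Paired tumor-normal SNP table: %d SNPs on %d chromosome(s)\n",
              nrow(x), length(unique(x$chromosome))))
  NextMethod()
}

#' Tumor total copy number relative to the matched normal
#'
#' Observed total copy number (TCN) of the tumor relative to the matched
#' normal, taking the diploid reference as two copies:
#' `C_T = 2 * theta_t / theta_n`. SNPs with `theta_n == 0` are returned as
#' `NA` (missing, not an error).
#'
#' @param table A [paired_snps()] table.
#' @return Numeric vector of TCN ratios.
#' @export
tumor_tcn <- function(table) {
  stopifnot(inherits(table, "paired_snps"))
  ifelse(!is.na(table$theta_n) & table$theta_n > 0,
         2 * table$theta_t / table$theta_n, NA_real_)
}

#' Allele-specific copy numbers from TCN and allele B fraction
#'
#' Decomposes a total copy number into per-allele copy numbers
#' `(c_a, c_b) = (tcn * (1 - beta), tcn * beta)`, so `c_a + c_b = tcn`.
#'
#' @param tcn Numeric vector of total copy numbers.
#' @param beta Numeric vector of allele B fractions (must be defined).
#' @return A data frame with columns `c_a` and `c_b`.
#' @export
ascn <- function(tcn, beta) {
  if (anyNA(beta)) {
    stop_bafnorm("beta is undefined (NA); ASCN not computable",
                 "bafnorm_undefined_beta")
  }
  c_b <- tcn * beta
  data.frame(c_a = tcn - c_b, c_b = c_b)
}

#' Mirrored allele B fraction
#'
#' `|beta - 1/2|`, folding the symmetric BAF distribution about its center.
#'
#' @param beta Numeric vector of allele B fractions.
#' @return Values in `[0, 1/2]`.
#' @export
mirrored_baf <- function(beta) abs(beta - 0.5)

#' Decrease in heterozygosity (DH)
#'
#' `DH = 2 * |beta - 1/2|`, scaled so DH is close to one in a region of LOH
#' in a pure tumor and close to zero under allelic balance. Intended for
#' SNPs heterozygous in the normal; computed for any defined `beta`.
#'
#' @param beta Numeric vector of tumor allele B fractions.
#' @return Values in `[0, 1]` for `beta` in `[0, 1]`.
#' @export
dh <- function(beta) 2 * abs(beta - 0.5)
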