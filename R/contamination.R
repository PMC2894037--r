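# Normal-contamination model: true allele B fractions and true decrease in
# heterozygosity for heterozygous SNPs when a tumor with parental copy
# numbers (c1, c2) is mixed with a fraction (1 - kappa) of normal cells,
# assuming average tumor ploidy two and a homogeneous tumor.

#' Parental copy-number state
#'
#' @param c1,c2 Minor and major parental copy numbers (integers,
#'   `0 <= c1 <= c2`).
#' @return A named numeric vector `c(c1, c2)` of class `"pcn_state"`.
#' @examples
#' pcn_state(0, 2)  # copy-neutral LOH
#' @export
pcn_state <- function(c1, c2) {
  stopifnot(length(c1) == 1, length(c2) == 1)
  if (is.na(c1) || is.na(c2) || c1 < 0 || c2 < c1 ||
      c1 != round(c1) || c2 != round(c2)) {
    stop_bafnorm("need integer copy numbers with 0 <= c1 <= c2",
                 "bafnorm_invalid_state")
  }
  structure(c(c1 = c1, c2 = c2), class = "pcn_state")
}

#' @export
print.pcn_state <- function(x, ...) {
  cat(sprintf("PCN state (%g, %g), TCN %g\n", x[["c1"]], x[["c2"]],
              sum(x)))
  invisible(x)
}

#' True allele B fraction of a heterozygous SNP under contamination
#'
#' For a SNP heterozygous in the normal, in a tumor region with parental
#' copy numbers `(c1, c2)`, purity `kappa`, and the B allele carried by the
#' parental copy contributing `b_copies` copies:
#' `beta* = (kappa * b_copies + (1 - kappa)) /
#'          (kappa * (c1 + c2) + 2 * (1 - kappa))`.
#' The normal cells contribute one copy of each allele; average tumor ploidy
#' is assumed to be two.
#'
#' @param state A [pcn_state()].
#' @param kappa Tumor purity in `[0, 1]` (vectorized).
#' @param b_copies Copies of the B allele among the tumor's parental copies;
#'   must equal `c1` or `c2`.
#' @return True allele B fraction(s); `NA` where the denominator is zero
#'   (pure tumor with homozygous deletion).
#' @export
true_het_beta <- function(state, kappa, b_copies) {
  stopifnot(inherits(state, "pcn_state"),
            all(kappa >= 0 & kappa <= 1, na.rm = TRUE))
  if (!(b_copies %in% state)) {
    stop_bafnorm("b_copies must be one of the state's parental copy numbers",
                 "bafnorm_invalid_state")
  }
  den <- kappa * sum(state) + 2 * (1 - kappa)
  ifelse(den > 0, (kappa * b_copies + (1 - kappa)) / den, NA_real_)
}

#' True decrease in heterozygosity under contamination
#'
#' `DH* = kappa * (c2 - c1) / (kappa * (c1 + c2) + 2 * (1 - kappa))`,
#' which equals `2 * |beta* - 1/2|` for either allele assignment.
#'
#' @inheritParams true_het_beta
#' @return True DH value(s) in `[0, 1]`; `NA` where undefined.
#' @examples
#' true_dh(pcn_state(0, 2), 1)    # pure-tumor LOH: 1
#' true_dh(pcn_state(1, 1), 0.7)  # balanced: 0
#' @export
true_dh <- function(state, kappa) {
  stopifnot(inherits(state, "pcn_state"),
            all(kappa >= 0 & kappa <= 1, na.rm = TRUE))
  den <- kappa * sum(state) + 2 * (1 - kappa)
  ifelse(den > 0, kappa * (state[["c2"]] - state[["c1"]]) / den, NA_real_)
}

#' Change-point detectability: difference in true DH between flanking states
#'
#' `|DH*(state2, kappa) - DH*(state1, kappa)|`. Under the assumption that
#' the DH variance does not depend on its mean, the power to detect a change
#' point with a t statistic is a linear function of this difference.
#'
#' @param state1,state2 [pcn_state()] objects of the two flanking regions.
#' @inheritParams true_het_beta
#' @return Nonnegative difference(s).
#' @export
dh_difference <- function(state1, state2, kappa) {
  abs(true_dh(state2, kappa) - true_dh(state1, kappa))
}

#' Purity maximizing the change-point detectability
#'
#' Maximizes [dh_difference()] over `kappa` in `[0, 1]`: coarse grid scan
#' followed by golden-section refinement to tolerance `1e-6`; ties resolved
#' to the smallest `kappa`. For a deletion/copy-neutral-LOH pair the
#' maximum is interior (at `2 - sqrt(2)`); for most other pairs the
#' difference is monotone in purity and the maximizer is 1.
#'
#' @param state1,state2 Distinct [pcn_state()] objects.
#' @param grid_resolution Spacing of the initial grid (default `1e-3`).
#' @return The maximizing purity.
#' @examples
#' argmax_purity(pcn_state(0, 1), pcn_state(0, 2))  # 2 - sqrt(2)
#' @export
argmax_purity <- function(state1, state2, grid_resolution = 1e-3) {
  if (identical(unclass(state1), unclass(state2))) {
    stop_bafnorm("states are identical: DH difference is 0 for every purity",
                 "bafnorm_no_maximum")
  }
  grid <- seq(0, 1, by = grid_resolution)
  delta <- dh_difference(state1, state2, grid)
  delta[is.na(delta)] <- -Inf
  i <- which.max(delta)  # first occurrence: smallest kappa on ties
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(grid[i])
  opt <- stats::optimize(function(k) dh_difference(state1, state2, k),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  # guard: boundary maxima (monotone differences) beat the interior refine
  cand <- c(opt$maximum, grid[i])
  cand[which.max(dh_difference(state1, state2, cand))]
}

#' Detectability curves over a purity grid
#'
#' Evaluates [dh_difference()] for several change points on a common purity
#' grid, ready for plotting or TSV export.
#'
#' @param changepoints Named list; each element a list with `state1` and
#'   `state2` ([pcn_state()] objects).
#' @param kappa_grid Purity grid (default 0 to 1 by 0.01).
#' @return Data frame with columns `kappa`, `label`, `delta`.
#' @export
dh_difference_curves <- function(changepoints,
                                 kappa_grid = seq(0, 1, by = 0.01)) {
  stopifnot(is.list(changepoints), length(names(changepoints)) ==
              length(changepoints))
  do.call(rbind, lapply(names(changepoints), function(lab) {
    cp <- changepoints[[lab]]
    data.frame(kappa = kappa_grid, label = lab,
               delta = dh_difference(cp$state1, cp$state2, kappa_grid),
               stringsAsFactors = FALSE)
  }))
}
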