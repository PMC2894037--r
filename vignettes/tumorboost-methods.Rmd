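---
title: "Methods: paired BAF normalization and change-point detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired BAF normalization and change-point detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bafnorm)
```

# The model

A SNP genotyping array reports, per SNP and hybridization, summarized
allele intensities $(\theta_A, \theta_B)$, equivalently the total signal
$\theta = \theta_A + \theta_B$ and the allele B fraction
$\beta = \theta_B/\theta$ (undefined only when $\theta = 0$; the package
represents that case as an explicit missing value rather than letting
$0/0$ propagate). For a tumor--normal pair from one individual, the observed
$\beta$ deviates from its genotype value $\mu \in \{0, \tfrac12, 1\}$ by a
per-SNP effect $\delta$ that is strongly correlated between the tumor and
the normal, because it originates in probe chemistry (differential allele
affinities, crosstalk, incomplete offset correction) rather than biology.

`tumorboost()` estimates this effect in the normal, $\hat\delta = \beta_N -
\hat\mu$, and removes it from the tumor:

* **homozygous SNPs** ($\hat\mu \in \{0, 1\}$):
  $\hat\beta_T = \beta_T - \beta_N + \hat\mu$;
* **heterozygous SNPs** ($\hat\mu = \tfrac12$):
  $\hat\beta_T = \beta_T - \eta\,(\beta_N - \tfrac12)$ with
  $\eta = \beta_T/\beta_N$ if $\beta_T \le \beta_N$, else
  $\eta = (1-\beta_T)/(1-\beta_N)$.

The shrinkage $\eta \in [0,1]$ exists because in regions of copy-number
change the heterozygous clusters regress on the normal with slope below
one; subtracting the full effect would overcorrect. The correction is
applied to each pair and each SNP independently, so it needs no knowledge
of change points, runs in $O(J)$ time, and is processed in fixed-size
chunks (default $10^6$ SNPs) so memory is bounded by the chunk size.
Total signals and total copy numbers are never modified: methods operating
on TCN alone are unaffected by the normalization.

## Numerical choices

The heterozygous path is computed through the algebraically equivalent
closed forms $\hat\beta_T = \beta_T/(2\beta_N)$ (lower branch) and
$1 - (1-\beta_T)/(2(1-\beta_N))$ (upper branch) instead of the literal
$\beta_T - \eta(\beta_N - \tfrac12)$. The two are identical in exact
arithmetic, but the closed forms guarantee the $[0,1]$ range of the output
and make self-normalization of the normal *bit-exact*: applying the method
to the normal against itself returns $\hat\mu$ exactly for every called
SNP (in IEEE double arithmetic, $x - (x - \tfrac12)$ is not exactly
$\tfrac12$ for $x < \tfrac14$, whereas $x/(2x)$ is). The equivalence with
the $\eta$ form is asserted in the test suite to $10^{-12}$.

Homozygous output is deliberately *not* truncated to $[0,1]$ by default
(`clamp_hom = FALSE`): truncation would break the linearity that
downstream segmentation relies on, and no truncation rule is canonical.
Heterozygous SNPs whose $\beta_N$ is exactly 0 or 1 (a genotype/data
inconsistency) have an undefined $\eta$; they are passed through unchanged
and flagged, since forcing a value would fabricate signal. Missing
$\beta$ or missing genotype likewise means pass-through with
`normalized = FALSE`, no imputation.

In the dual allelic-intensity form the corrected intensities are computed
as $\hat\theta_{TB} = \theta_T \hat\beta_T$ and $\hat\theta_{TA} =
\theta_T - \hat\theta_{TB}$, so the total tumor signal is preserved to one
ulp — the identifiability constraint of the paired setup (signal may move
between alleles of a SNP, never in or out of it).

# Naive genotyping of the normal

When no external calls are supplied, the normal is genotyped from
$\{\beta_N\}$ alone: a Gaussian-kernel density on a fixed 512-point grid
over $[0,1]$, thresholds at the two local minima separating the three most
prominent modes, and interval-membership calls. Choices made here:

* **Pooled thresholds.** All SNPs are called with one threshold pair
  estimated from the pooled autosomal density. A per-chromosome variant is
  possible by calling `call_genotypes_naive()` per chromosome subset; the
  pooled default uses more data per threshold and is what the package's
  evaluations use.
* **Bandwidth.** Silverman's rule-of-thumb on the $[0,1]$-clipped data,
  overridable. The density is renormalized to integrate to 1 on $[0,1]$
  because kernels centered near the homozygous bands put mass outside the
  interval; renormalization does not move the valley locations.
* **Mode selection.** If the gridded density has more than the requested
  number of local maxima (wiggles), the modes with the greatest prominence
  are kept; fewer modes than classes is an error that reports the count
  found. Hemizygous chromosomes use two classes and one threshold.
* **Tie rule.** A value exactly on a threshold is assigned to the middle
  (heterozygous) class.
* **Confidence.** The score of a call is its distance to the nearest
  threshold — zero exactly on a threshold, increasing monotonically with
  distance. This is the simplest score consistent with the observation
  that genotyping errors concentrate near the density minima; no canonical
  formula exists. `filter_by_confidence()` drops the lowest-scoring
  fraction (10% in the package's evaluation defaults), breaking ties by
  genomic order.

# Normal contamination

A tumor sample is modeled as a mixture of one tumor clone (fraction
$\kappa$, the purity) with parental copy numbers $(C_1, C_2)$, $C_1 \le
C_2$, and normal cells (fraction $1-\kappa$) that are diploid at every
locus; average tumor ploidy is assumed to be two. For a SNP heterozygous
in the normal, the true allele B fraction with $b \in \{C_1, C_2\}$ copies
of B in the tumor is

$$\beta^* = \frac{\kappa b + (1-\kappa)}{\kappa (C_1+C_2) + 2(1-\kappa)},$$

and the true decrease in heterozygosity is $\mathrm{DH}^* = \kappa
(C_2-C_1) / (\kappa(C_1+C_2) + 2(1-\kappa)) = 2|\beta^* - \tfrac12|$.
This form is pinned by two analytic anchors verified in the tests: a pure
single-copy gain has heterozygous bands at $\{1/3, 2/3\}$, and the purity
maximizing the DH difference between a hemizygous deletion $(0,1)$ and a
copy-neutral LOH $(0,2)$ is $2-\sqrt2 \approx 0.59$, with maximum
difference $3 - 2\sqrt2$. `argmax_purity()` uses a $10^{-3}$ grid scan
followed by golden-section refinement to $10^{-6}$, resolving ties to the
smallest purity; monotone pairs (e.g. normal vs gain) correctly return 1.
The detectability difference $\Delta(\kappa) = |\mathrm{DH}^*_2 -
\mathrm{DH}^*_1|$ is reported without any variance-dependent
proportionality constant: the constant affects neither orderings nor
optima, which is all the package asserts. Tumor heterogeneity
(multi-clone mixtures) is outside the model.

# Change-point detectability

Given a known change-point position, a safety margin absorbs localization
error: SNPs within the closed interval [changepoint − margin, changepoint
+ margin] are excluded, and the two flanks are assumed internally
homogeneous. In the bundled scenario the safety region is 1 Mb wide
(margin 0.5 Mb per side). Evaluation uses heterozygous SNPs only, and the
TCN track is evaluated on the same heterozygous SNPs as DH so that
resolutions are comparable; the framework is *not* designed to compare TCN
vs DH power in absolute terms.

* **t statistics.** Pooled-variance Student's t between the flanks
  (Welch available via `pooled = FALSE`). Because t depends on sample
  size, each of B = 100 bootstrap repetitions draws J' = 250 heterozygous
  SNPs per flank, and the mean ± sd of $|t|$ is reported. Draws are
  *without replacement* within each flank (a with-replacement mode is
  provided); when a binned track has fewer than J' points per flank the
  draw size is capped at the available minimum, and the same count is
  enforced across all compared signals at that resolution.
* **Binning.** Non-overlapping, position-ordered bins of exactly H points
  averaged with the arithmetic mean; a trailing incomplete bin is dropped
  so per-bin variance is constant. H = 1 is the identity.
* **ROC.** The positive state is the one with TCN different from two.
  Because the direction of the DH difference flips for some pairs (a
  deletion has *lower* DH than a copy-neutral LOH), the curve is
  auto-oriented from the sign of the mean difference and the chosen sign
  is recorded. Tied values collapse to a single threshold step and the
  AUC is the trapezoidal area, identical to the tie-corrected rank
  statistic (cross-checked against an independent ROC implementation in
  the tests). Regions are balanced by equal-size sampling before the
  sweep.

All sampling flows from one seed in `eval_config()`; per-signal,
per-resolution and per-change-point draws use fixed offsets from it, so a
full report is bit-reproducible.

# The simulator

`simulate_pair()` generates what the method assumes about real arrays:

* genotypes from Hardy–Weinberg with per-SNP MAF uniform on
  $[0.2, 0.5]$ (common SNPs, as on genotyping arrays);
* per-SNP allele affinities $\varphi_A, \varphi_B \sim
  \mathrm{lognormal}(0, \sigma_\varphi^2)$ **shared between the tumor and
  normal** of the pair — the mechanistic source of the reproducible SNP
  effect, reproducing the diagonal tumor-vs-normal structure within
  genotype;
* segmental parental copy numbers for the tumor, mixed with diploid
  normal copy numbers at purity $\kappa$; for heterozygous SNPs the B
  allele sits on the minor or major copy with probability $\tfrac12$;
* intensities $\theta = \varphi\,(c/2)\,\mathrm{scale} + \mathrm{offset} +
  \varepsilon$, truncated at zero.

Defaults were fixed once as plausible array-like conditions: scale 2
(diploid totals read like copy numbers), $\sigma_\varphi = 0.3$ (wide
within-genotype clouds, heterozygous $\beta_N$ SD $\approx 0.1$), offset
0.2 (incomplete offset correction; this is what makes the heterozygous
regression slopes fall below one in aberrant regions and compresses
$|\beta - \tfrac12|$, so the $\eta$ safeguard has something to guard
against), intensity noise SD 0.03, purity $\kappa = 0.7$.
`changepoint_scenario()` lays out two chromosomes with the five canonical
change points — normal/gain (N/G), gain/copy-neutral-LOH (G/L),
normal/deletion (N/D), deletion/LOH (D/L) and a no-change N/N control —
drawing 1250 SNPs per flank so each flank holds roughly 500 heterozygous
SNPs.

The simulator does **not** emulate genomic waves, GC bias, batch effects,
probe saturation or multi-clone tumors. Tests passing on simulated data
therefore demonstrate the internal consistency of the method and its
implementation under the stated model, not performance on any particular
platform's artifacts.

# Problem sizes and runtime

The test suite runs the full scenario at 1250 SNPs per flank
(≈ 13,000 SNPs total), J' = 250, B = 100, H ∈ {1, 2, 4} — about a second —
and checks the linear-scaling contract by timing the fit at $10^4$ vs
$10^5$ SNPs. Whole-genome inputs ($10^6$ SNPs) stream through
`read_paired_signals()` in chunks.

# Known limitations

* Normalization removes systematic across-SNP effects but does not
  *calibrate* DH levels: the mean DH of a region remains a biased
  estimator of its true value (offset and platform biases persist), so
  region means should not be read as purity-corrected copy numbers.
* Genotyping errors by the naive caller become isolated DH outliers after
  normalization; they are second-order for segment-level detection and
  can be reduced by confidence filtering, but single-SNP calls should not
  be trusted.
* Estimating $\kappa$, calling parental copy-number states, ploidy
  estimation and segmentation itself are out of scope; the package
  prepares signals for such methods and quantifies detectability, nothing
  more.
* Non-polymorphic (CN-only) probes carry $\theta$ but no $\beta$; they
  pass through untouched.
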