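# bafnorm

Tumor–normal normalization of allele B fractions (the **TumorBoost** method)
and evaluation of copy-number change-point detectability from allelic
imbalance, for SNP genotyping-array data.

## The problem

Allele-specific copy-number analysis of tumors works with two per-SNP
signals: the total signal θ and the **allele B fraction** (BAF)
β = θ_B / (θ_A + θ_B). In a normal sample β should sit at 0, 1/2 or 1
according to the genotype, but every array platform shows a large,
reproducible per-SNP deviation from those values — a *SNP effect* δ that is
shared between hybridizations of the same individual. This effect blurs the
BAF bands of the tumor and hides allelic-imbalance events, most notably
copy-neutral LOH, which is invisible in total copy numbers.

When a matched normal is available, the SNP effect can be estimated from the
normal and removed from the tumor, one pair and one SNP at a time:

* estimate δ̂ = β_N − μ̂, where μ̂ ∈ {0, 1/2, 1} is the normal genotype;
* homozygous SNPs: β̂_T = β_T − β_N + μ̂;
* heterozygous SNPs: β̂_T = β_T − η (β_N − 1/2), with the shrinkage factor
  η = β_T/β_N if β_T ≤ β_N and η = (1 − β_T)/(1 − β_N) otherwise, which
  prevents overcorrection in regions of copy-number change.

Total signals and total copy numbers are never adjusted. Downstream, allelic
imbalance is summarized per heterozygous SNP by the **decrease in
heterozygosity** DH = 2 |β_T − 1/2|, which is 0 under allelic balance and
approaches 1 in pure-tumor LOH.

The package provides, behind one fitting function:

* `tumorboost()` — the normalization, returning a fitted object with
  `print`/`summary`/`fitted`/`residuals`/`plot` methods;
* `call_genotypes_naive()` — single-sample genotyping of the normal by
  thresholding β_N at the two local minima of its Gaussian-kernel density,
  with confidence scores and `filter_by_confidence()`;
* `true_dh()`, `dh_difference()`, `argmax_purity()` — the normal
  contamination model: with tumor purity κ and parental copy numbers
  (C₁, C₂), the true DH of a heterozygous SNP is
  κ (C₂ − C₁) / (κ (C₁ + C₂) + 2 (1 − κ));
* `evaluate_pair()` / `evaluate_changepoint()` — change-point detectability:
  flanking regions around a known change point (safety margin excluded),
  balanced sampling, bootstrap Student-t summaries and ROC/AUC analysis on
  full-resolution and binned DH tracks;
* `simulate_pair()` / `changepoint_scenario()` — a synthetic paired tumor-normal
  generator with full ground truth (shared log-normal allele affinities,
  Hardy–Weinberg genotypes, segmental parental copy numbers, κ-mixing);
* TSV readers/writers and a CLI (`inst/cli/bafnorm`, or `cli_main()`)
  with `simulate`, `genotype`, `normalize`, `dh`, `evaluate` and `curves`
  subcommands.

## Worked example

```r
library(bafnorm)
sim <- simulate_pair(sim_config(n_snps = 2000, seed = 7))
fit <- tumorboost(sim$pair)
summary(fit)
#> TumorBoost normalization summary
#>   2000 SNPs, 2000 normalized, 903 heterozygous
#>   het beta_T sd: 0.0863 raw -> 0.0136 normalized
#>   het cor(beta_N, beta_T): 0.989 raw -> 0.109 normalized
```

On this copy-neutral pair the heterozygous tumor BAF spread shrinks more
than sixfold, and the tumor–normal correlation within genotype — the
signature of the shared SNP effect — essentially disappears.

Detectability of a gain → copy-neutral-LOH change point at purity 0.7:

```r
scen <- changepoint_scenario(kappa = 0.7, snps_per_region = 600, seed = 11)
fit2 <- tumorboost(scen$pair)
evaluate_pair(fit2, scen$specs["G/L"], eval_config(seed = 2))
#>  label  signal h mean_t  sd_t   auc n_used
#>    G/L     tcn 1   35.2 0.406 0.988    242
#>    G/L  dh_raw 1   29.1 0.993 0.951    242
#>    G/L dh_norm 1   92.2 1.809 1.000    242
#>    ...
```

`mean_t` ± `sd_t` is the bootstrap summary of the absolute two-sample t
statistic between the two flanking regions (J' = 242 heterozygous SNPs per
draw here, B = 100 draws) and `auc` the area under the ROC curve separating
them; normalized DH (`dh_norm`) separates the states far better than raw DH.

The contamination model's best-case purity for detecting a deletion next to
a copy-neutral LOH:

```r
argmax_purity(pcn_state(0, 1), pcn_state(0, 2))
#> [1] 0.5857864   # = 2 - sqrt(2), i.e. 0.59 at two decimals
```

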