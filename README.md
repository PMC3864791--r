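# polygc — genomic control for non-additive association models

Population substructure and cryptic relatedness inflate genome-wide
association (GWAS) test statistics and manufacture false positives.
Genomic control (GC) repairs a scan post hoc by rescaling the statistics so
their null distribution matches the reference chi-square.  The classical
recipe — divide everything by the median-based inflation factor
λ = median(χ²)/0.455 — is exact only for the additive (trend) test.  For
the **recessive, dominant and over-dominant** models the inflation depends
on the coded-allele frequency *p*, so a constant correction leaves the scan
liberal in some frequency ranges and conservative in others.

`polygc` implements frequency-aware genomic control for analysts running
non-additive GWAS (and for methodologists studying stratification):

* the analytic variance inflation factor for a 1-df coding with
  heterozygote weight *x* (0 = recessive, ½ = additive, 1 = dominant;
  over-dominant codes the heterozygote alone),

  VIF(p) = 1 + [C(p) / σ²(p)] · (K/N − 1),

  where σ²(p) is the marginal coded-genotype variance under inbreeding
  *F*, C(p) the coded-genotype covariance of two members of the same
  subpopulation under Balding–Nichols drift with differentiation *F*, and
  K = Σₛ (n₁ₛS − n₂ₛR)²/(RS) summarises how unevenly cases and controls
  are drawn from the subpopulations (K/N² is 0 for a balanced design, ½
  for fully separated case/control sampling);
* **VIFGC** — estimation of effective (F, K) from the scan itself by
  matching the ordered corrected statistics to χ² quantiles (lower 95%),
  then correcting each marker by VIF(p);
* **PGC** (polynomial GC) — the correction factor modelled as a cubic
  λ(p) = β₀ + β₁p + β₂p² + β₃p³, fitted the same way; works for the 2-df
  genotypic test too;
* the **robust 2df** test T = (Z²ᵣ − 2ρZᵣZ_d + Z²_d)/(1 − ρ²) built from
  VIFGC-corrected recessive and dominant statistics;
* score tests for all five inheritance models (binary traits: identical to
  the Cochran–Armitage trend test; quantitative traits: score test of zero
  slope; hard calls, dosages or imputed probability triples);
* a stratified-population simulator (Balding–Nichols demes, liability
  threshold phenotypes, polygenic background) and a type-1-error / power
  harness stratified by the five standard allele-frequency bins.

## Worked example

Simulate a structured case-control study (20 demes, Fst = 0.05, N = 2000,
unbalanced sampling), scan it under the recessive model, and correct:

```r
library(polygc)
set.seed(1)

## the analytic curves at F = 0.05, N = 1000, K = 11000
th <- structure_params(N = 1000, F = 0.05, K = 11000)
round(vif(c(0.1, 0.3, 0.5, 0.7, 0.9), "recessive", th), 3)
#> [1] 1.273 1.495 1.660 1.787 1.888        # rises with p
round(vif(c(0.1, 0.3, 0.5, 0.7, 0.9), "additive", th), 3)
#> [1] 1.952 1.952 1.952 1.952 1.952        # flat, and an upper bound

cfg  <- sim_config(M = 20000, seed = 42)   # reference study conditions
st   <- sim_study(cfg)                     # null: qtl_var = 0
scan <- run_scan(st$G, st$y, models = c("recessive", "additive"))
rec  <- scan[scan$model == "recessive" & !scan$flag, ]

lambda_median(rec$chi2, df = 1)
#> <lambda_estimate> lambda_median = 1.3172 (df = 1, M = 19769)

fit <- fit_FK(rec$chi2, rec$caf, N = st$N, model = "recessive")
fit
#> <fk_fit> model = recessive, F = 0.0624, K = 10476.1 (K/N = 5.238), ...

corr <- vifgc_correct(rec$chi2, rec$caf, fit, "recessive")
lambda_median(corr$chi2_corr, df = 1)
#> <lambda_estimate> lambda_median = 0.9946 (df = 1, M = 19769)

## empirical type-1 error per frequency bin, before and after
round(tapply(rec$pval       <= 0.05, caf_bin(rec$caf), mean), 3)
#> [0.05,0.25)  [0.25,0.4)  [0.4,0.6)  [0.6,0.75)  [0.75,0.95]
#>       0.073       0.087      0.082       0.100        0.109
round(tapply(corr$pval_corr <= 0.05, caf_bin(rec$caf), mean), 3)
#>       0.048       0.050      0.046       0.052        0.057
```

The uncorrected recessive scan rejects 7–11% of null markers at the 5%
level, worst at high frequency where the recessive VIF peaks; after the
VIF-based correction each bin sits near the nominal 0.05 (residual wobble
here reflects a single 20000-SNP cycle; the harness pools 30–50 cycles).

The full table machinery:

```r
rep <- type1_report(sim_config(), cycles = 50, seed = 1)   # lambda + E per bin
pow <- power_report(sim_config(M = 4000, qtl_var = 0.0035), cycles = 25)
```

A thin command-line interface (`inst/scripts/polygc`) exposes
`simulate`, `assoc`, `correct` and `evaluate` over text files; see
`?gc_cli`.

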