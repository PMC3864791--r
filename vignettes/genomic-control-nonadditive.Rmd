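---
title: "Genomic control for non-additive association models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic control for non-additive association models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygc)
```

## The problem

Genome-wide association scans computed on a structured sample — discrete
subpopulations, a genetic isolate, cryptic relatedness — show inflated test
statistics even at markers with no effect on the trait.  Genomic control
(GC) repairs this post hoc: estimate the inflation from the genome-wide
distribution of the statistics and rescale them so the null matches the
reference chi-square.

For the additive (trend) test a single constant suffices, because the
inflation of the additive score statistic does not depend on allele
frequency.  For recessive, dominant and over-dominant codings it does.
Dividing a recessive scan by its median-based $\lambda$ fixes the *average*
type-1 error while leaving low-frequency markers conservative and
high-frequency markers liberal (or vice versa for the dominant model).  The
methods in this package make the correction a *function of coded-allele
frequency*.

## The analytic VIF

Write $g(G) \in \{0, x, 1\}$ for the coded genotype with heterozygote
weight $x$ ($x = 0$ recessive, $\tfrac12$ additive, $1$ dominant; the
over-dominant coding is $\{0,1,0\}$).  The 1-df score statistic for a
binary trait is the Cochran–Armitage trend test,
$\chi^2 = N r^2$ with $r$ the sample correlation between $g(G)$ and the
phenotype, whose nominal variance uses the *marginal* coded-genotype
variance $\sigma^2(p)$.

The structure model is Balding–Nichols drift: each subpopulation's allele
frequency is $\pi_s \sim \mathrm{Beta}$ with mean $p$ and variance
$F\,p(1-p)$, with Hardy–Weinberg genotypes within subpopulations, so that
the pooled sample shows inbreeding-type genotype frequencies
$P_2 = p^2 + Fp(1-p)$ etc.  Two individuals of the same subpopulation then
share the drift draw, giving a between-individual coded-genotype covariance

$$C(p) \;=\; \mathrm{Var}_\pi\!\big(E[g \mid \pi]\big),
\qquad E[g \mid \pi] = 2x\,\pi + (1-2x)\,\pi^2,$$

a polynomial in the first four Beta moments (closed-form in $p$ and $F$).
Propagating this covariance through the score statistic's numerator, and
summarising the case-control sampling design by

$$K \;=\; \sum_s \frac{(n_{1s} S - n_{2s} R)^2}{R\,S},$$

($n_{1s}, n_{2s}$ = cases/controls drawn from subpopulation $s$; $R$, $S$,
$N = R+S$ the totals) yields the inflation factor

$$\mathrm{VIF}(p) \;=\; 1 + \frac{C(p)}{\sigma^2(p)}
  \Big(\frac{K}{N} - 1\Big).$$

Properties (all verified by the test suite):

* additive model: $C/\sigma^2 = 2F/(1+F)$, independent of $p$ — the
  classical constant-$\lambda$ situation;
* the recessive curve at $p$ mirrors the dominant curve at $1-p$;
* a large heterozygote weight approaches the over-dominant curve;
* the additive VIF bounds every other model's VIF from above;
* $K/N^2 = 0$ for any design with a constant case:control ratio across
  subpopulations, and $\tfrac12$ when cases and controls are sampled from
  disjoint subpopulations;
* $F = 0$ (no differentiation) gives $\mathrm{VIF} \equiv 1$.

`N` in the formula is the **total** sample size; with that convention the
parameter set $F = 0.05$, $N = 1000$, $K = 11000$ (i.e. $K/N^2 = 0.011$)
produces an additive VIF near 1.95 and the familiar fan of non-additive
curves below it.

### Validity domain

The closed form divides the expected numerator variance by the expected
nominal variance, which is exact in the *many-subpopulation* limit: when
the drift contrasts average over many demes (or families), the confounding
component of the score is asymptotically normal and the statistic is
distributed as $\mathrm{VIF}(p)\cdot\chi^2_1$.  With only two or three
demes a single drift contrast dominates each marker: the statistic becomes
a heavy scale mixture, its median-based $\lambda$ separates from its mean,
and the realised pooled genotype variance under-represents the
between-deme (Wahlund) component by a factor $1 - \sum_s \omega_s^2$
($\omega_s$ = subpopulation weights).  The package's simulation oracle
tests therefore probe the VIF in designs with 20 demes, and the default
synthetic substrate (below) uses the same regime — which is also the
regime of the family-structured isolates that motivate the method, where
hundreds of sibships each contribute a small drift contrast.

## Estimating (F, K) and the polynomial correction

Real scans do not come with known $(F, K)$.  Both fitted corrections match
the *ordered* corrected statistics to the expected chi-square quantiles:

$$S(\theta) \;=\; \sum_{i \le 0.95 M}
  \Big[\mathrm{sort}\big(\chi^2_j / \lambda_\theta(p_j)\big)_{(i)}
  - q_i\Big]^2,
  \qquad q_i = F^{-1}_{\chi^2_{df}}\!\Big(\frac{i-0.5}{M}\Big),$$

with re-sorting at every candidate correction (a frequency-dependent
correction permutes ranks) and the upper 5% excluded so genuine
association signals cannot drag the fit.

A practical caveat discovered during development shapes the optimiser
design: at desk-scale $M$ (up to $\sim 10^6$ statistics) this pooled loss
is nearly flat in the *shape* direction.  A mild scale mixture — a wrong,
even constant, correction applied to a sloped inflation curve — shifts the
pooled quantiles by $O(\text{spread}^2)$, which is within the sampling
noise of the loss; distinguishing curves reliably through the pooled loss
alone would need tens of millions of statistics.  The frequency *profile*
is, however, strongly identified by local quantile information.  The
fitters therefore split the work:

* **shape** — `fit_FK()` profiles over $F$: for each candidate $F$ the
  best $K$ is a closed-form least-squares match of the VIF family to the
  binned median-inflation curve (20 equal-count frequency bins), and $F$
  minimises the curve misfit.  `fit_pgc()` estimates the cubic
  $\lambda(p) = \beta_0 + \beta_1 p + \beta_2 p^2 + \beta_3 p^3$ by a
  Gamma regression with identity link on mean $df\cdot\lambda(p)$ — the
  maximum-likelihood fit of a frequency-dependent scale — initialised from
  the binned-curve OLS fit and with only the extreme upper 0.5% of
  statistics (relative to the current curve) excluded;
* **scale** — the remaining magnitude (one parameter: $K$ at the selected
  $F$, or a common factor on $\beta$) is polished by minimising $S(\theta)$
  itself, which is well conditioned in that direction.

The degree is fixed at 3: low enough to be stable at the frequency
boundaries, flexible enough to track every 1-df VIF curve within a few
percent on $[0.05, 0.95]$ (a test asserts PGC–VIFGC agreement within 5%
on scans generated from the VIF family).  Positivity of $\lambda(p)$ on
$[0.05, 0.95]$ is enforced by shrinking towards the constant fit before
the scale stage and checked after it.  The fitted polynomial is tied to
the scan's frequency range; applying it outside $[0.05, 0.95]$ warns.

The fitted $(\hat F, \hat K)$ should be read as *effective* parameters of
the correction curve, not as estimates of the population's true inbreeding
and design coefficients: the two trade off along the fitted curve, and
only the curve itself is identified (the parameter-recovery test asserts
2% uniform accuracy of the curve, not of $F$ and $K$ separately).

## The 2df genotypic test

The genotypic (2-df) score test makes no assumption on the heterozygote
effect; the statistic is $N R^2$ from the two-indicator projection
(equal to the Pearson 2×3 chi-square for binary traits) and is invariant
to the choice of coding basis.  Two corrections are offered:

* **PGC** with chi-square(2) reference quantiles — the recommended route;
* **robust 2df**: combine the VIFGC-corrected signed recessive and
  dominant statistics,
  $T = (Z_r^2 - 2\rho Z_r Z_d + Z_d^2)/(1-\rho^2) \sim \chi^2_2$, with
  $\rho$ the per-SNP null correlation of the two codings computed from the
  marker's genotype frequencies, $\rho = P_0 P_2 / \sqrt{P_2(1-P_2)P_0(1-P_0)}$.
  This test is conservative in practice (the harness reproduces empirical
  type-1 error near 0.044 at a nominal 0.05), matching its known
  behaviour; PGC is preferred for 2-df scans.

## The synthetic substrate

`sim_config()` defines the reference study conditions used by the
evaluation harness and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| demes | 20 × 100 sampled | many-deme regime (families/isolate surrogate) |
| `Fst` | 0.05 | Balding–Nichols drift between demes |
| design | 62/38 vs 38/62 alternating | $K/N = 5.76$, additive $\lambda \approx 1.45$ |
| `M` | 20000 SNPs | ancestral CAF uniform on $[0.05, 0.95]$ |
| `h2_range` | $U(0.5, 0.8)$ per cycle | liability heritability |
| `n_polygenes` | 500 | equal shares of $h^2 - q$, random sign, additive |
| `qtl_var` | 0 (type 1) / 0.0035 (power) | QTL share of liability variance |
| `case_fraction` | 1/3 | cases = lower tail of liability |

Phenotypes follow a liability-threshold model: liability is the sum of the
polygenic score, the optional QTL term (acting through the simulated
inheritance model's coding) and a normal residual scaled to leave total
variance 1; an individual is a case when liability falls below the
standard-normal 1/3 quantile.  "Chromosomes" are emulated as 20 contiguous
SNP blocks so polygenes are never drawn from the QTL's block.  The design
unbalance was chosen once so that the uncorrected additive inflation sits
near 1.45 — the moderate-confounding regime in which frequency-dependent
GC matters and its asymptotics hold; it is not tuned per experiment.

What the generator does **not** emulate: linkage disequilibrium (markers
are exchangeable given the drift draws), pedigree transmission (relatedness
is represented entirely by deme structure), genotyping error or
imputation uncertainty, and ascertainment beyond the case-control design.
Passing tests therefore demonstrate control of *structure-driven*
inflation under the model's own assumptions; on real data with LD, the
effective number of independent null markers is smaller and fitted curves
correspondingly noisier.

### Harness conventions

* Corrections in the harness are estimated from the known-null markers —
  the definition of genomic control (inflation is read off null loci).  In
  real data all markers stand in for null loci; at the default causal
  density (500 polygenes in 20000 markers = 2.5%) fitting on all markers
  would bias $\lambda$ upward by about 2.5% and the corrected type-1 error
  downward by about 0.003.
* Type-1 metrics ($\lambda_{median}$, $\lambda_{regress}$, $E$ = fraction
  of p-values $\le 0.05$) are computed over null markers only, pooled
  across simulation cycles; corrections are fitted once on the pooled
  scan (noted in the report attributes).
* The scan filter keeps coded-allele frequencies in $[0.05, 0.95]$;
  markers whose coded genotype is monomorphic in the sample are flagged
  and excluded from fits and metrics; genotypic-test markers with a
  missing genotype class fall back to the additive 1-df test and are
  excluded from 2-df summaries.

## Numerical choices and degenerate inputs

* Reference medians: $\chi^2_1$ median 0.4549, $\chi^2_2$ median
  $2\ln 2 \approx 1.3863$.
* $\lambda$ is **not** clamped at 1: a deflated scan is scaled up
  (corrected scans can legitimately report $\lambda$ below 1, and the
  clamp is available as an option where a conservative convention is
  wanted).
* `lambda_regress` pairs sorted statistics with quantiles at plotting
  positions $(i - 0.5)/M$ and uses the centred covariance slope; no
  intercept is forced.
* The ordered-statistic loss is evaluated on a deterministic systematic
  subsample of at most $2\times10^5$ statistics (stride through the
  CAF-sorted order), so fits are reproducible and independent of the RNG
  state.
* Probability-triple genotypes are coded by the expectation of the coded
  value, $E[g(G)] = \sum_k w_k P_k$ — not $g(E[G])$, which is undefined
  for non-additive codings; plain dosages are accepted only for the
  additive model.
* Missing genotypes: per-SNP complete-case analysis.
* `robust_2df` suppresses markers with $|\rho| \ge 1 - 10^{-6}$
  (degenerate at extreme frequencies).

## Problem sizes

The default harness scales are chosen for a desk-class machine: 50
simulation cycles of $M = 20000$ markers and $N = 2000$ samples for the
type-1 tables (about a million pooled statistics per model), and 25 cycles
per simulated model at $M = 4000$ for the power table, with corrections
refitted each cycle.  The acceptance script (`scripts/acceptance.R`) runs
the 50-cycle type-1 harness end to end; the test suite runs a 30-cycle
version plus the simulation-oracle and curve-recovery checks at
$2.5\times10^5$ and $10^5$ statistics respectively.

## Known limitations

* The analytic VIF is a leading-order result for the many-subpopulation
  regime; with a handful of demes it understates the realised inflation
  and no member of the $(F, K)$ family matches the realised curve exactly
  (the fitted corrections still calibrate the bulk, but per-bin type-1
  error control degrades).
* $(\hat F, \hat K)$ are effective parameters (see above).
* No covariates, no mixed models, no multi-allelic or X-linked markers,
  no meta-analysis machinery.
* The quantitative-trait score test is provided and calibrated under the
  null, but the simulation harness exercises the binary liability design.
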