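#' Structure parameters of the VIF
#'
#' Container for the population parameters entering the analytic variance
#' inflation factor: total sample size `N`, Wright's inbreeding coefficient
#' `F`, and the substructure coefficient `K` summarising how unevenly cases
#' and controls are drawn from the subpopulations (see [substructure_K()]).
#' `K / N^2` ranges from 0 for a balanced design to 1/2 when cases and
#' controls come from disjoint subpopulations.
#'
#' @param N Total sample size (cases plus controls).
#' @param F Inbreeding coefficient in \[0, 1\].
#' @param K Substructure coefficient, in \[0, N^2/2\].
#'
#' @return An object of class `structure_params`.
#' @examples
#' structure_params(N = 1000, F = 0.05, K = 11000)
#' @export
structure_params <- function(N, F, K) {
  stopifnot(is.numeric(N), length(N) == 1L, N > 1,
            is.numeric(F), length(F) == 1L, F >= 0, F <= 1,
            is.numeric(K), length(K) == 1L, K >= 0)
  if (K / N^2 > 0.5 + 1e-12)
    stop("K/N^2 cannot exceed 1/2")
  structure(list(N = N, F = F, K = K), class = "structure_params")
}

#' @export
print.structure_params <- function(x, ...) {
  cat(sprintf("<structure_params> N = %g, F = %.4g, K = %.6g (K/N^2 = %.4g)\n",
              x$N, x$F, x$K, x$K / x$N^2))
  invisible(x)
}

## Raw moments E[pi^k], k = 1..4, of the subpopulation allele frequency
## pi ~ Beta(p(1-F)/F, (1-p)(1-F)/F), i.e. mean p and variance F p (1-p).
## Closed forms stay valid at F = 0 (degenerate) and F = 1 (Bernoulli(p)).
.drift_moments <- function(p, F) {
  q <- 1 - p
  m2 <- p^2 + F * p * q
  m3 <- m2 * (p * (1 - F) + 2 * F) / (1 + F)
  m4 <- m3 * (p * (1 - F) + 3 * F) / (1 + 2 * F)
  cbind(m1 = p, m2 = m2, m3 = m3, m4 = m4)
}

## Covariance of the coded genotype between two individuals of the same
## subpopulation: C = Var_pi(E[g | pi]) with E[g | pi] quadratic in pi.
## For coding (w0, w1, w2) on genotypes 0/1/2 under within-subpopulation HWE:
## E[g | pi] = w0 + a1 pi + a2 pi^2 with a1 = 2(w1 - w0), a2 = w0 - 2 w1 + w2.
.between_cov <- function(p, F, model) {
  model <- gc_model(model)
  w <- model$weights
  a1 <- 2 * (w[2] - w[1])
  a2 <- w[1] - 2 * w[2] + w[3]
  m <- .drift_moments(p, F)
  v1 <- m[, "m2"] - m[, "m1"]^2            # Var(pi)
  v2 <- m[, "m4"] - m[, "m2"]^2            # Var(pi^2)
  c12 <- m[, "m3"] - m[, "m1"] * m[, "m2"] # Cov(pi, pi^2)
  a1^2 * v1 + a2^2 * v2 + 2 * a1 * a2 * c12
}

#' Analytic variance inflation factor for 1-df association tests
#'
#' Inflation of the score (trend) test statistic under population
#' substructure, as a function of the coded-allele frequency `p`, the
#' inheritance model, and the population parameters `(N, F, K)`.  Writing
#' `sigma2(p)` for the marginal variance of the coded genotype at inbreeding
#' `F` and `C(p)` for the coded-genotype covariance between two members of
#' the same subpopulation (both induced by a Balding--Nichols drift model
#' whose allele-frequency variance is `F p (1-p)`), the VIF is
#'
#' \deqn{VIF(p) = 1 + \frac{C(p)}{\sigma^2(p)}\left(\frac{K}{N} - 1\right).}
#'
#' For the additive model `C/sigma2 = 2F/(1+F)` is frequency-independent;
#' for non-additive models the VIF depends on `p`, with the recessive curve
#' the mirror image (in `p -> 1-p`) of the dominant one, and the additive
#' VIF an upper bound for all models.  The expression is the leading-order
#' asymptotic inflation when drift averages over many subpopulations (many
#' demes or families); see the package vignette for its validity domain.
#'
#' @param p Coded-allele frequency (vectorised).
#' @param model 1-df inheritance model (`"recessive"`, `"additive"`,
#'   `"dominant"`, `"overdominant"`, or a numeric heterozygote weight `x`
#'   giving the coding `c(0, x, 1)`).
#' @param params A [structure_params()] object (or list with `N`, `F`, `K`).
#'
#' @return Numeric vector of inflation factors (1 when `F = 0`).
#'
#' @examples
#' th <- structure_params(N = 1000, F = 0.05, K = 11000)
#' vif(c(0.1, 0.5, 0.9), "additive", th)   # flat in p
#' vif(0.3, "recessive", th)
#' @export
vif <- function(p, model, params) {
  stopifnot(all(p > 0 & p < 1))
  if (is.numeric(model)) {
    x <- model
    model <- structure(list(tag = sprintf("x=%g", x), x = x,
                            weights = c(0, x, 1), df = 1L), class = "gc_model")
  } else {
    model <- gc_model(model)
  }
  if (model$df != 1L)
    stop("the analytic VIF covers 1-df models; correct the genotypic test ",
         "with PGC or the robust 2df combination")
  F <- params$F; K <- params$K; N <- params$N
  if (F == 0) return(rep(1, length(p)))
  s2 <- coded_moments(p, F, model)$var
  C <- .between_cov(p, F, model)
  unname(1 + (C / s2) * (K / N - 1))
}

#' Substructure coefficient K of a case-control design
#'
#' Summarises how unevenly cases and controls are sampled from the
#' subpopulations:
#' \deqn{K = \sum_s (n_{1s} S - n_{2s} R)^2 / (R S)}
#' where `n_{1s}`/`n_{2s}` are the case/control counts in subpopulation `s`
#' and `R`, `S` the totals.  `K/N^2` is 0 whenever every subpopulation has
#' the same case:control ratio, and reaches its maximum 1/2 when cases and
#' controls are drawn from disjoint subpopulations (two of them, equal
#' sizes).  `K` is invariant to relabelling subpopulations.
#'
#' @param cases Integer vector of case counts per subpopulation.
#' @param controls Integer vector of control counts per subpopulation
#'   (same length).
#'
#' @return The scalar `K`.
#'
#' @examples
#' substructure_K(c(250, 250), c(250, 250))    # balanced: 0
#' substructure_K(c(500, 0), c(0, 500)) / 1000^2  # separated: 1/2
#' @export
substructure_K <- function(cases, controls) {
  stopifnot(length(cases) == length(controls), length(cases) >= 1L,
            all(cases >= 0), all(controls >= 0))
  R <- sum(cases); S <- sum(controls)
  if (R == 0 || S == 0) stop("design needs at least one case and one control")
  sum((cases * S - controls * R)^2) / (R * S)
}

#' Null correlation between recessive and dominant codings
#'
#' Correlation, under the null, of the recessive (`1{G=2}`) and dominant
#' (`1{G>=1}`) codings of the same marker, from its genotype frequencies:
#' `rho = P0 P2 / sqrt(P2 (1-P2) P0 (1-P0))`.  Used to combine corrected
#' recessive and dominant statistics into the robust 2df test.
#'
#' @param P0,P2 Frequencies of the 0-copy and 2-copy genotype classes
#'   (vectorised).
#'
#' @return Numeric vector of correlations in (0, 1).
#' @examples
#' null_rho(0.25, 0.25)  # HWE at p = 0.5: 1/3
#' @export
null_rho <- function(P0, P2) {
  stopifnot(all(P0 >= 0), all(P2 >= 0), all(P0 + P2 <= 1 + 1e-9))
  P0 * P2 / sqrt(P2 * (1 - P2) * P0 * (1 - P0))
}

#' Robust 2df statistic from corrected 1df statistics
#'
#' Combines genomic-control-corrected signed recessive and dominant
#' statistics into a two-degree-of-freedom test:
#' \deqn{T = (Z_r^2 - 2\rho Z_r Z_d + Z_d^2) / (1 - \rho^2),}
#' referred to the chi-square distribution with 2 df.  `rho` is the per-SNP
#' null correlation of the two codings ([null_rho()]).  SNPs with `|rho|`
#' within `tol` of 1 (degenerate at extreme allele frequencies) are
#' suppressed (`NA`).
#'
#' @param z_rec,z_dom Corrected signed 1df statistics per SNP.
#' @param rho Per-SNP null correlation between the two codings.
#' @param tol Degeneracy guard on `1 - |rho|` (default `1e-6`).
#'
#' @return A data.frame with columns `chi2`, `df` (= 2) and `pval`.
#' @examples
#' robust_2df(1, 1, 0)   # independent: T = 2
#' @export
robust_2df <- function(z_rec, z_dom, rho, tol = 1e-6) {
  stopifnot(length(z_rec) == length(z_dom), length(rho) == length(z_rec))
  bad <- !is.finite(rho) | abs(rho) >= 1 - tol
  T <- (z_rec^2 - 2 * rho * z_rec * z_dom + z_dom^2) / (1 - rho^2)
  T[bad] <- NA_real_
  data.frame(chi2 = T, df = 2L,
             pval = stats::pchisq(T, df = 2, lower.tail = FALSE))
}
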