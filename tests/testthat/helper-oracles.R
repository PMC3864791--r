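## Independent reference implementations used as oracles.  These deliberately
## do not share code with the package: the trend statistic is the textbook
## contingency-table formula, and the null-statistic simulator works on
## genotype counts rather than individual-level matrices.

## Cochran-Armitage trend statistic from a 2x3 table (textbook form).
## r, s: genotype counts (0/1/2 copies) among cases and controls.
oracle_ca_trend <- function(r, s, w) {
  n <- r + s
  N <- sum(n); R <- sum(r); S <- sum(s)
  num <- sum(w * (S * r - R * s))^2 * N
  den <- R * S * (N * sum(w^2 * n) - sum(w * n)^2)
  num / den
}

## Expand a 2x3 table into an individual-level genotype vector + phenotype.
table_to_data <- function(r, s) {
  G <- c(rep(0:2, r), rep(0:2, s))
  y <- c(rep(1, sum(r)), rep(0, sum(s)))
  list(G = matrix(G, ncol = 1), y = y)
}

## Counts-level simulator of null case-control trend statistics under the
## Balding-Nichols drift model: per replicate, each deme's allele frequency
## is a Beta draw around p, genotype counts are trinomial under HWE within
## demes, and the trend statistic is computed from the pooled 2x3 table.
oracle_null_stats <- function(p, Fst, cases, controls, reps, w) {
  S <- length(cases)
  cc <- matrix(0, reps, 3); tt <- matrix(0, reps, 3)
  a <- p * (1 - Fst) / Fst; b <- (1 - p) * (1 - Fst) / Fst
  for (s in seq_len(S)) {
    pi_s <- rbeta(reps, a, b)
    P2 <- pi_s^2; P1 <- 2 * pi_s * (1 - pi_s)
    c2 <- rbinom(reps, cases[s], P2)
    c1 <- rbinom(reps, cases[s] - c2, pmin(P1 / (1 - P2), 1))
    cc <- cc + cbind(cases[s] - c2 - c1, c1, c2)
    d2 <- rbinom(reps, controls[s], P2)
    d1 <- rbinom(reps, controls[s] - d2, pmin(P1 / (1 - P2), 1))
    tt <- tt + cbind(controls[s] - d2 - d1, d1, d2)
  }
  R <- sum(cases); Sc <- sum(controls); N <- R + Sc
  nj <- cc + tt
  U <- (cc %*% w) - R / N * (nj %*% w)
  V <- (R * Sc / N^2) * ((nj %*% w^2) - (nj %*% w)^2 / N)
  chi2 <- as.vector(U^2 / V)
  chi2[is.finite(chi2)]
}

## The trimmed ordered-statistic loss, reimplemented for loss-property tests.
oracle_ordered_loss <- function(chi2_corr, trim = 0.95, df = 1) {
  M <- length(chi2_corr)
  m <- floor(trim * M)
  q <- qchisq((seq_len(m) - 0.5) / M, df)
  sum((sort(chi2_corr)[seq_len(m)] - q)^2)
}

## Reference design used across tests: 20 demes, mild alternating unbalance.
test_design <- function(n_deme = 100) {
  f <- n_deme / 100
  list(cases = rep(c(62, 38) * f, 10), controls = rep(c(38, 62) * f, 10))
}
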