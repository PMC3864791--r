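#include <Rcpp.h>
using namespace Rcpp;

// Draw hard genotypes for a stratified cohort in one pass.
// n_per_subpop: individuals per deme (rows are grouped by deme);
// C0, C1: M x S matrices of cumulative genotype probabilities per SNP
// (column s holds P0 and P0+P1 for deme s).
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sample_cohort_cpp(IntegerVector n_per_subpop,
                                NumericMatrix C0, NumericMatrix C1) {
  int S = n_per_subpop.size(), M = C0.nrow();
  int n_tot = 0;
  for (int s = 0; s < S; ++s) n_tot += n_per_subpop[s];
  IntegerMatrix G(n_tot, M);
  for (int j = 0; j < M; ++j) {
    int *col = &G(0, j);
    int i = 0;
    for (int s = 0; s < S; ++s) {
      double a = C0(j, s), b = C1(j, s);
      for (int k = 0; k < n_per_subpop[s]; ++k, ++i) {
        double u = unif_rand();
        col[i] = (u > a) + (u > b);
      }
    }
  }
  return G;
}

// Per-SNP genotype-class counts, overall and among cases (y = 1), in one
// pass over a hard genotype matrix with a binary phenotype.
// Returns a 4 x M matrix: rows S1 (total het), S2 (total hom),
// T1 (case het), T2 (case hom).
// [[Rcpp::export]]
NumericMatrix genotype_counts_cpp(IntegerMatrix G, IntegerVector y) {
  int n = G.nrow(), M = G.ncol();
  NumericMatrix out(4, M);
  for (int j = 0; j < M; ++j) {
    const int *col = &G(0, j);
    double s1 = 0, s2 = 0, t1 = 0, t2 = 0;
    for (int i = 0; i < n; ++i) {
      int g = col[i];
      if (g == 1) { s1++; t1 += y[i]; }
      else if (g == 2) { s2++; t2 += y[i]; }
    }
    out(0, j) = s1; out(1, j) = s2; out(2, j) = t1; out(3, j) = t2;
  }
  return out;
}
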