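// Gamete-sampling and fitness kernels for the Wright-Fisher engine.
// RNG goes through R's stream (unif_rand), so results are reproducible
// under set.seed() like any R-level sampler. Raw column pointers are used
// throughout (matrices are column-major).

#include <Rcpp.h>
using namespace Rcpp;

// Offspring copy counts under free recombination: each offspring draws,
// independently per locus, one allele from each parent (Bernoulli(copies/2);
// deterministic for homozygous parents).
// [[Rcpp::export(name = ".offspring_unlinked")]]
IntegerMatrix offspring_unlinked(const IntegerMatrix& copies,
                                 const IntegerVector& mom,
                                 const IntegerVector& dad) {
  const int n = mom.size(), L = copies.ncol(), N = copies.nrow();
  IntegerMatrix out(n, L);
  const int* C = INTEGER(copies);
  int* O = INTEGER(out);
  std::vector<int> m(n), d(n);
  for (int i = 0; i < n; ++i) { m[i] = mom[i] - 1; d[i] = dad[i] - 1; }
  for (int j = 0; j < L; ++j) {
    const int* cj = C + (size_t)j * N;
    int* oj = O + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const int cm = cj[m[i]], cd = cj[d[i]];
      int g = (cm == 2) ? 1 : (cm == 1 ? (unif_rand() < 0.5) : 0);
      g += (cd == 2) ? 1 : (cd == 1 ? (unif_rand() < 0.5) : 0);
      oj[i] = g;
    }
  }
  return out;
}

// One gamete per parent with crossovers between adjacent loci at
// probabilities rprob (length L-1); starting haplotype uniform.
static void gametes_linked(const int* H1, const int* H2, const int N,
                           const int L, const std::vector<int>& par,
                           const double* r, int* out, const int n) {
  for (int i = 0; i < n; ++i) {
    const int p = par[i];
    int cur = unif_rand() < 0.5;
    out[i] = cur ? H2[p] : H1[p];
    for (int j = 1; j < L; ++j) {
      if (unif_rand() < r[j - 1]) cur = 1 - cur;
      const size_t off = (size_t)j * N;
      out[i + (size_t)j * n] = cur ? H2[p + off] : H1[p + off];
    }
  }
}

// [[Rcpp::export(name = ".offspring_linked")]]
List offspring_linked(const IntegerMatrix& h1, const IntegerMatrix& h2,
                      const IntegerVector& mom, const IntegerVector& dad,
                      const NumericVector& rprob) {
  const int n = mom.size(), L = h1.ncol(), N = h1.nrow();
  IntegerMatrix g1(n, L), g2(n, L);
  std::vector<int> m(n), d(n);
  for (int i = 0; i < n; ++i) { m[i] = mom[i] - 1; d[i] = dad[i] - 1; }
  gametes_linked(INTEGER(h1), INTEGER(h2), N, L, m, REAL(rprob),
                 INTEGER(g1), n);
  gametes_linked(INTEGER(h1), INTEGER(h2), N, L, d, REAL(rprob),
                 INTEGER(g2), n);
  return List::create(Named("g1") = g1, Named("g2") = g2);
}

// Log-fitness of the population-genetic family in one pass:
// sum_i log(1 + h_i s_i) + alpha * (x - delta)^2 with x the normalized
// weighted dosage.
// [[Rcpp::export(name = ".logw_popgen")]]
NumericVector logw_popgen(const IntegerMatrix& copies,
                          const NumericVector& log_het,
                          const NumericVector& log_hom,
                          const NumericVector& s,
                          double alpha, double delta, double sum_s) {
  const int n = copies.nrow(), L = copies.ncol();
  NumericVector out(n);
  double* O = REAL(out);
  const int* C = INTEGER(copies);
  std::vector<double> dosage(n, 0.0);
  for (int j = 0; j < L; ++j) {
    const int* cj = C + (size_t)j * n;
    const double lh = log_het[j], lH = log_hom[j], sj = s[j];
    for (int i = 0; i < n; ++i) {
      const int c = cj[i];
      if (c == 1) { O[i] += lh; dosage[i] += sj; }
      else if (c == 2) { O[i] += lH; dosage[i] += 2.0 * sj; }
    }
  }
  if (alpha != 0.0) {
    for (int i = 0; i < n; ++i) {
      const double x = dosage[i] / (2.0 * sum_s) - delta;
      O[i] += alpha * x * x;
    }
  }
  return out;
}
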