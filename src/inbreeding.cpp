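#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursive inbreeding computation.
// sire/dam are 1-based codes into a parents-first ordering, 0 = unknown.
// For animal i with both parents known, F_i = a(s,d)/2 is obtained from the
// L'DL decomposition of A restricted to the ancestors of i.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), v(n);

  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree not sorted parents-first at position %d", i + 1);
    // Mendelian sampling variance of i (unit additive variance)
    if (s >= 0 && d >= 0)
      D[i] = 0.5 - 0.25 * (F[s] + F[d]);
    else if (s >= 0)
      D[i] = 0.75 - 0.25 * F[s];
    else if (d >= 0)
      D[i] = 0.75 - 0.25 * F[d];
    else
      D[i] = 1.0;

    if (s < 0 || d < 0) {
      F[i] = 0.0;  // unknown parent = unrelated non-inbred base animal
      continue;
    }
    // a_ii = sum_k L_ik^2 D_k over ancestors k of i (including i)
    double aii = 0.0;
    std::fill(v.begin(), v.begin() + i + 1, 0.0);
    v[i] = 1.0;
    for (int k = i; k >= 0; --k) {
      double vk = v[k];
      if (vk == 0.0) continue;
      aii += vk * vk * D[k];
      int ks = sire[k] - 1, kd = dam[k] - 1;
      if (ks >= 0) v[ks] += 0.5 * vk;
      if (kd >= 0) v[kd] += 0.5 * vk;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Gene dropping across a sorted pedigree: one Mendelian-sampled allele per
// parent per locus, loci independent.  geno is animals x loci, codes 0/1/2,
// founders prefilled, non-founder rows overwritten.  unif is a stream of
// uniforms consumed two per (non-founder, locus).
// [[Rcpp::export]]
IntegerMatrix gene_drop_cpp(IntegerMatrix geno, IntegerVector sire,
                            IntegerVector dam, NumericVector unif) {
  int n = geno.nrow(), m = geno.ncol();
  R_xlen_t u = 0;
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s < 0 && d < 0) continue;  // founder row already drawn
    for (int j = 0; j < m; ++j) {
      int a1, a2;
      if (s >= 0)
        a1 = (unif[u++] < geno(s, j) / 2.0) ? 1 : 0;
      else
        a1 = (unif[u++] < 0.5) ? 1 : 0;  // should not happen in simulated peds
      if (d >= 0)
        a2 = (unif[u++] < geno(d, j) / 2.0) ? 1 : 0;
      else
        a2 = (unif[u++] < 0.5) ? 1 : 0;
      geno(i, j) = a1 + a2;
    }
  }
  return geno;
}
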