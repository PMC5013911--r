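#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise distance kernels.  All profile matrices arrive transposed
// (features x samples) so each sample is a contiguous column.  Pairs whose
// denominator is zero (e.g. two empty samples) yield NA_REAL; the R layer
// screens zero-total samples before calling in.

// [[Rcpp::export]]
NumericMatrix cpp_pair_bray(const NumericMatrix& prop) {
  const int m = prop.nrow(), n = prop.ncol();
  NumericMatrix D(n, n);
  for (int j = 0; j < n; ++j) {
    const double* pj = &prop(0, j);
    for (int k = j + 1; k < n; ++k) {
      const double* pk = &prop(0, k);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < m; ++i) {
        num += std::fabs(pj[i] - pk[i]);
        den += pj[i] + pk[i];
      }
      const double d = den > 0.0 ? num / den : NA_REAL;
      D(j, k) = d; D(k, j) = d;
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_jaccard(const NumericMatrix& pres) {
  const int m = pres.nrow(), n = pres.ncol();
  NumericMatrix D(n, n);
  for (int j = 0; j < n; ++j) {
    const double* aj = &pres(0, j);
    for (int k = j + 1; k < n; ++k) {
      const double* ak = &pres(0, k);
      int n01 = 0, n11 = 0;
      for (int i = 0; i < m; ++i) {
        const bool pj = aj[i] > 0.0, pk = ak[i] > 0.0;
        if (pj && pk) ++n11;
        else if (pj || pk) ++n01;
      }
      const double d = (n01 + n11) > 0 ? (double)n01 / (n01 + n11) : NA_REAL;
      D(j, k) = d; D(k, j) = d;
    }
  }
  return D;
}

// weighted UniFrac: sum b|pj-pk| / sum b(pj+pk)
// [[Rcpp::export]]
NumericMatrix cpp_pair_wunifrac(const NumericMatrix& pb,
                                const NumericVector& blen) {
  const int L = pb.nrow(), n = pb.ncol();
  NumericMatrix D(n, n);
  for (int j = 0; j < n; ++j) {
    const double* pj = &pb(0, j);
    for (int k = j + 1; k < n; ++k) {
      const double* pk = &pb(0, k);
      double num = 0.0, den = 0.0;
      for (int l = 0; l < L; ++l) {
        num += blen[l] * std::fabs(pj[l] - pk[l]);
        den += blen[l] * (pj[l] + pk[l]);
      }
      const double d = den > 0.0 ? num / den : NA_REAL;
      D(j, k) = d; D(k, j) = d;
    }
  }
  return D;
}

// generalized UniFrac / presence-weighted UniFrac share one form:
// sum_l b (s)^alpha |d/s| / sum_l b (s)^alpha over branches with s > 0,
// with s = vj + vk, d = vj - vk, v = branch proportion (generalized) or
// branch richness count (presence-weighted).
// [[Rcpp::export]]
NumericMatrix cpp_pair_alpha_unifrac(const NumericMatrix& vb,
                                     const NumericVector& blen,
                                     const double alpha) {
  const int L = vb.nrow(), n = vb.ncol();
  NumericMatrix D(n, n);
  const bool a1 = alpha == 1.0, a0 = alpha == 0.0;
  for (int j = 0; j < n; ++j) {
    const double* vj = &vb(0, j);
    for (int k = j + 1; k < n; ++k) {
      const double* vk = &vb(0, k);
      double num = 0.0, den = 0.0;
      for (int l = 0; l < L; ++l) {
        const double s = vj[l] + vk[l];
        if (s <= 0.0) continue;            // unoccupied branch: no weight
        const double ratio = std::fabs(vj[l] - vk[l]) / s;
        double w;
        if (a1) w = s;
        else if (a0) w = 1.0;
        else w = std::pow(s, alpha);
        num += blen[l] * w * ratio;
        den += blen[l] * w;
      }
      const double d = den > 0.0 ? num / den : NA_REAL;
      D(j, k) = d; D(k, j) = d;
    }
  }
  return D;
}

// unweighted UniFrac: sum b|I(nj>0)-I(nk>0)| / sum b (all branches)
// [[Rcpp::export]]
NumericMatrix cpp_pair_uwunifrac(const NumericMatrix& nb,
                                 const NumericVector& blen) {
  const int L = nb.nrow(), n = nb.ncol();
  double btot = 0.0;
  for (int l = 0; l < L; ++l) btot += blen[l];
  NumericMatrix D(n, n);
  for (int j = 0; j < n; ++j) {
    const double* nj = &nb(0, j);
    for (int k = j + 1; k < n; ++k) {
      const double* nk = &nb(0, k);
      double num = 0.0;
      for (int l = 0; l < L; ++l) {
        const bool oj = nj[l] > 0.0, ok = nk[l] > 0.0;
        if (oj != ok) num += blen[l];
      }
      const double d = btot > 0.0 ? num / btot : NA_REAL;
      D(j, k) = d; D(k, j) = d;
    }
  }
  return D;
}
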