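// Accumulation of two-level-system third-order phase averages.
//
// Given per-bond cumulative phase integrals I(t) = int_0^t dw10(tau) dtau
// (trapezoid, rad), the rephasing / non-rephasing phase factors for delays
// (t1, t2, t3) starting at origin s are
//   phi_rp = exp(+i [I(s+t1)-I(s)] - i [I(s+t1+t2+t3)-I(s+t1+t2)])
//   phi_nr = exp(-i [I(s+t1)-I(s)] - i [I(s+t1+t2+t3)-I(s+t1+t2)])
// averaged over bonds and time origins.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".phase_average_cpp")]]
List phase_average_cpp(const arma::mat& Iphase,      // n_time x n_bonds
                       const arma::ivec& origins,    // 0-based frame indices
                       const arma::ivec& i1,         // t1 offsets in frames
                       int i2,                       // t2 offset in frames
                       const arma::ivec& i3) {       // t3 offsets in frames
  const int n1 = i1.n_elem, n3 = i3.n_elem;
  arma::cx_mat rp(n1, n3, arma::fill::zeros), nr(n1, n3, arma::fill::zeros);
  long count = 0;
  const arma::cx_double I(0.0, 1.0);
  for (arma::uword b = 0; b < Iphase.n_cols; ++b) {
    const double* col = Iphase.colptr(b);
    for (arma::uword k = 0; k < origins.n_elem; ++k) {
      int s = origins[k];
      double I0 = col[s];
      for (int a = 0; a < n1; ++a) {
        double phi1 = col[s + i1[a]] - I0;
        int base = s + i1[a] + i2;
        double Ib = col[base];
        arma::cx_double e_p = std::exp(I * phi1);
        arma::cx_double e_m = std::exp(-I * phi1);
        for (int c = 0; c < n3; ++c) {
          double phi3 = col[base + i3[c]] - Ib;
          arma::cx_double e3 = std::exp(-I * phi3);
          rp(a, c) += e_p * e3;
          nr(a, c) += e_m * e3;
        }
      }
      ++count;
    }
  }
  rp /= double(count);
  nr /= double(count);
  return List::create(_["phi_rp"] = rp, _["phi_nr"] = nr);
}
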