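// Hot numerical kernels of the temporal network: depthwise convolution on
// the period x frequency grid and batched multi-head softmax attention.
// Shapes follow the R side: conv tensors are (p, f, B, C) column-major,
// attention tensors are (L, B, D) with D split evenly across heads.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x) {
  return x.attr("dim");
}

// [[Rcpp::export(name = ".dwconv_fwd_cpp")]]
NumericVector dwconv_fwd_cpp(const NumericVector& x, const NumericVector& K,
                             const NumericVector& b) {
  IntegerVector d = dims_of(x);
  const int p = d[0], f = d[1], B = d[2], C = d[3];
  IntegerVector dk = dims_of(K);
  const int kl = dk[0];
  const int ctr = kl / 2;  // 0-based center
  NumericVector out(x.size());
  out.attr("dim") = d;
  const double* xp = x.begin();
  double* op = out.begin();
  const double* kp = K.begin();
  const R_xlen_t plane = (R_xlen_t)p * f;
  for (int c = 0; c < C; ++c) {
    const double bias = b[c];
    for (int bb = 0; bb < B; ++bb) {
      const R_xlen_t base = ((R_xlen_t)c * B + bb) * plane;
      const double* xs = xp + base;
      double* os = op + base;
      for (int col = 0; col < f; ++col) {
        for (int row = 0; row < p; ++row) {
          double acc = bias;
          for (int kj = 0; kj < kl; ++kj) {
            const int cc = col + kj - ctr;
            if (cc < 0 || cc >= f) continue;
            for (int ki = 0; ki < kl; ++ki) {
              const int rr = row + ki - ctr;
              if (rr < 0 || rr >= p) continue;
              acc += kp[ki + kl * (kj + kl * c)] * xs[rr + (R_xlen_t)p * cc];
            }
          }
          os[row + (R_xlen_t)p * col] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dwconv_bwd_cpp")]]
List dwconv_bwd_cpp(const NumericVector& dY, const NumericVector& x,
                    const NumericVector& K) {
  IntegerVector d = dims_of(x);
  const int p = d[0], f = d[1], B = d[2], C = d[3];
  IntegerVector dk = dims_of(K);
  const int kl = dk[0];
  const int ctr = kl / 2;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dK(K.size());
  dK.attr("dim") = dk;
  NumericVector db(C);
  const double* xp = x.begin();
  const double* gp = dY.begin();
  const double* kp = K.begin();
  double* dxp = dx.begin();
  double* dkp = dK.begin();
  const R_xlen_t plane = (R_xlen_t)p * f;
  for (int c = 0; c < C; ++c) {
    double bsum = 0.0;
    for (int bb = 0; bb < B; ++bb) {
      const R_xlen_t base = ((R_xlen_t)c * B + bb) * plane;
      const double* xs = xp + base;
      const double* gs = gp + base;
      double* dxs = dxp + base;
      for (int col = 0; col < f; ++col) {
        for (int row = 0; row < p; ++row) {
          const double g = gs[row + (R_xlen_t)p * col];
          bsum += g;
          for (int kj = 0; kj < kl; ++kj) {
            const int cc = col + kj - ctr;
            if (cc < 0 || cc >= f) continue;
            for (int ki = 0; ki < kl; ++ki) {
              const int rr = row + ki - ctr;
              if (rr < 0 || rr >= p) continue;
              const double xv = xs[rr + (R_xlen_t)p * cc];
              const R_xlen_t kidx = ki + kl * (kj + kl * c);
              dkp[kidx] += g * xv;
              dxs[rr + (R_xlen_t)p * cc] += g * kp[kidx];
            }
          }
        }
      }
    }
    db[c] = bsum;
  }
  return List::create(Named("dx") = dx, Named("dK") = dK, Named("db") = db);
}

static arma::mat softmax_rows_arma(arma::mat S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
  return S;
}

// Q is (L, B, D); K and V are (Lk, B, D) and may be pooled (Lk <= L).
// [[Rcpp::export(name = ".mha_fwd_cpp")]]
NumericVector mha_fwd_cpp(const NumericVector& Q, const NumericVector& K,
                          const NumericVector& V, const int heads) {
  IntegerVector d = dims_of(Q);
  const int L = d[0], B = d[1], D = d[2];
  const int Lk = dims_of(K)[0];
  const int dh = D / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericVector out(Q.size());
  out.attr("dim") = d;
  // column (b, c) of the L x (B*D) matrix view sits at offset (c*B + b)*L
  const arma::mat Qm(const_cast<double*>(Q.begin()), L, B * D, false, true);
  const arma::mat Km(const_cast<double*>(K.begin()), Lk, B * D, false, true);
  const arma::mat Vm(const_cast<double*>(V.begin()), Lk, B * D, false, true);
  arma::mat Om(out.begin(), L, B * D, false, true);
  arma::uvec cols(dh);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      for (int j = 0; j < dh; ++j) cols[j] = (h * dh + j) * B + b;
      arma::mat q = Qm.cols(cols), k = Km.cols(cols), v = Vm.cols(cols);
      arma::mat A = softmax_rows_arma(q * k.t() * scale);
      Om.cols(cols) = A * v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".mha_bwd_cpp")]]
List mha_bwd_cpp(const NumericVector& Q, const NumericVector& K,
                 const NumericVector& V, const NumericVector& dO,
                 const int heads) {
  IntegerVector d = dims_of(Q);
  const int L = d[0], B = d[1], D = d[2];
  const int Lk = dims_of(K)[0];
  const int dh = D / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericVector dQ(Q.size()), dK(K.size()), dV(V.size());
  dQ.attr("dim") = d;
  dK.attr("dim") = dims_of(K);
  dV.attr("dim") = dims_of(V);
  const arma::mat Qm(const_cast<double*>(Q.begin()), L, B * D, false, true);
  const arma::mat Km(const_cast<double*>(K.begin()), Lk, B * D, false, true);
  const arma::mat Vm(const_cast<double*>(V.begin()), Lk, B * D, false, true);
  const arma::mat dOm(const_cast<double*>(dO.begin()), L, B * D, false, true);
  arma::mat dQm(dQ.begin(), L, B * D, false, true);
  arma::mat dKm(dK.begin(), Lk, B * D, false, true);
  arma::mat dVm(dV.begin(), Lk, B * D, false, true);
  arma::uvec cols(dh);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      for (int j = 0; j < dh; ++j) cols[j] = (h * dh + j) * B + b;
      arma::mat q = Qm.cols(cols), k = Km.cols(cols), v = Vm.cols(cols);
      arma::mat g = dOm.cols(cols);
      arma::mat A = softmax_rows_arma(q * k.t() * scale);
      arma::mat dA = g * v.t();
      dVm.cols(cols) = A.t() * g;
      arma::mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
      dQm.cols(cols) = dS * k * scale;
      dKm.cols(cols) = dS.t() * q * scale;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}

// [[Rcpp::export(name = ".col_max_cpp")]]
NumericVector col_max_cpp(const NumericMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  for (int j = 0; j < nc; ++j) {
    const double* c = &x(0, j);
    double m = c[0];
    for (int i = 1; i < nr; ++i) if (c[i] > m) m = c[i];
    out[j] = m;
  }
  return out;
}
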