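// Low-level numeric kernels for the 1-D convolutional network and the
// polyphase resampler. Batches are arma::cube with dimensions
// (width, channels, batch); weights are (filter_width * in_channels,
// out_channels) with row index t + filter_width * channel, matching the
// fan-in used by the He initializer.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// "same" padding: output width = ceil(w_in / stride); surplus goes right.
static inline void same_pad(int w_in, int k, int stride, int &w_out,
                            int &pad_left) {
  w_out = (w_in + stride - 1) / stride;
  int pad_total = (w_out - 1) * stride + k - w_in;
  if (pad_total < 0) pad_total = 0;
  pad_left = pad_total / 2;
}

static void im2col(const cube &X, uword slice, int k, int stride,
                   int pad_left, int w_out, mat &out) {
  const int w_in = X.n_rows, c_in = X.n_cols;
  out.zeros(w_out, (uword)k * c_in);
  for (int cc = 0; cc < c_in; ++cc) {
    const double *xc = X.slice_colptr(slice, cc);
    for (int t = 0; t < k; ++t) {
      double *oc = out.colptr((uword)cc * k + t);
      for (int o = 0; o < w_out; ++o) {
        int p = o * stride + t - pad_left;
        if (p >= 0 && p < w_in) oc[o] = xc[p];
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube &X, const arma::mat &W,
                          const arma::vec &b, int k, int stride) {
  const int w_in = X.n_rows, m = X.n_slices, c_out = W.n_cols;
  int w_out, pad_left;
  same_pad(w_in, k, stride, w_out, pad_left);
  cube Y(w_out, c_out, m);
  mat cols;
  for (int i = 0; i < m; ++i) {
    im2col(X, i, k, stride, pad_left, w_out, cols);
    Y.slice(i) = cols * W;
    Y.slice(i).each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube &X, const arma::mat &W,
                          const arma::cube &dY, int k, int stride,
                          bool need_dx, bool need_dw) {
  const int w_in = X.n_rows, c_in = X.n_cols, m = X.n_slices;
  const int w_out = dY.n_rows;
  int w_out_chk, pad_left;
  same_pad(w_in, k, stride, w_out_chk, pad_left);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_cols, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(w_in, c_in, m);
  mat cols, G;
  for (int i = 0; i < m; ++i) {
    if (need_dw) {
      im2col(X, i, k, stride, pad_left, w_out, cols);
      dW += cols.t() * dY.slice(i);
      db += sum(dY.slice(i), 0).t();
    }
    if (need_dx) {
      G = dY.slice(i) * W.t();  // (w_out, k * c_in)
      for (int cc = 0; cc < c_in; ++cc) {
        double *xc = dX.slice_colptr(i, cc);
        for (int t = 0; t < k; ++t) {
          const double *gc = G.colptr((uword)cc * k + t);
          for (int o = 0; o < w_out; ++o) {
            int p = o * stride + t - pad_left;
            if (p >= 0 && p < w_in) xc[p] += gc[o];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube &X, int k, int stride) {
  const int w_in = X.n_rows, c = X.n_cols, m = X.n_slices;
  int w_out, pad_left;
  same_pad(w_in, k, stride, w_out, pad_left);
  cube Y(w_out, c, m);
  Rcpp::IntegerVector idx(Rcpp::Dimension(w_out, c, m));  // 0-based argmax
  int *ip = INTEGER(idx);
  for (int i = 0; i < m; ++i)
    for (int cc = 0; cc < c; ++cc) {
      const double *xc = X.slice_colptr(i, cc);
      for (int o = 0; o < w_out; ++o) {
        double best = -datum::inf;
        int besti = -1;
        int lo = o * stride - pad_left;
        for (int t = 0; t < k; ++t) {
          int p = lo + t;
          if (p >= 0 && p < w_in && xc[p] > best) {
            best = xc[p];
            besti = p;
          }
        }
        Y(o, cc, i) = best;
        ip[(size_t)o + (size_t)w_out * (cc + (size_t)c * i)] = besti;
      }
    }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const Rcpp::IntegerVector &idx,
                           const arma::cube &dY, int w_in) {
  const int w_out = dY.n_rows, c = dY.n_cols, m = dY.n_slices;
  cube dX(w_in, c, m, fill::zeros);
  const int *ip = INTEGER(idx);
  for (int i = 0; i < m; ++i)
    for (int cc = 0; cc < c; ++cc) {
      double *xc = dX.slice_colptr(i, cc);
      const double *gc = dY.slice_colptr(i, cc);
      for (int o = 0; o < w_out; ++o) {
        int p = ip[(size_t)o + (size_t)w_out * (cc + (size_t)c * i)];
        if (p >= 0) xc[p] += gc[o];
      }
    }
  return dX;
}

// Rational polyphase resampling by L/M with FIR taps h (designed in R,
// already scaled by L). Output n computed so that length equals
// round(n_in * L / M). D = (length(h)-1)/2 centers the filter (zero group
// delay for odd-length symmetric h).
// [[Rcpp::export]]
arma::vec cpp_resample_poly(const arma::vec &x, int L, int M,
                            const arma::vec &h) {
  const long long n_in = x.n_elem;
  const long long n_out = (long long)std::llround((double)n_in * L / M);
  const long long nt = h.n_elem, D = (nt - 1) / 2;
  vec y(n_out, fill::zeros);
  for (long long n = 0; n < n_out; ++n) {
    long long j = n * (long long)M + D;
    long long t0 = j % L;  // taps with (j - t) divisible by L
    double acc = 0.0;
    for (long long t = t0; t < nt; t += L) {
      long long q = (j - t) / L;
      if (q >= 0 && q < n_in) acc += h(t) * x(q);
    }
    y(n) = acc;
  }
  return y;
}
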