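// Low-level numeric kernels for the network: image-to-column unrolling for
// stride-1 same-padded 2D convolution, 3x3 same-padded max pooling, and the
// LSTM recurrence (forward + backpropagation through time).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Unroll a [H x W x D] feature cube into a [(H*W) x (kh*kw*D)] patch matrix
// for stride-1 convolution with zero ("same") padding. Row index runs over
// output positions in column-major (h fastest) order.
// [[Rcpp::export]]
arma::mat im2col_same(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, D = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  mat out(H * W, kh * kw * D, fill::zeros);
  for (int d = 0; d < D; ++d) {
    const double* xs = x.slice_memptr(d);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* oc = out.colptr(d * kh * kw + j * kh + i);
        // valid output rows h for this kernel offset form a contiguous run
        const int h0 = std::max(0, ph - i);
        const int h1 = std::min(H - 1, H - 1 + ph - i);
        const int run = h1 - h0 + 1;
        if (run <= 0) continue;
        const int w0 = std::max(0, pw - j);
        const int w1 = std::min(W - 1, W - 1 + pw - j);
        for (int w = w0; w <= w1; ++w) {
          const double* src = xs + (w + j - pw) * H + (h0 + i - ph);
          std::memcpy(oc + w * H + h0, src, run * sizeof(double));
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_same: scatter-add patch-matrix gradients back onto the
// input cube.
// [[Rcpp::export]]
arma::cube col2im_same(const arma::mat& cols, int H, int W, int D,
                       int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  cube out(H, W, D, fill::zeros);
  for (int d = 0; d < D; ++d) {
    double* os = out.slice_memptr(d);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* cc = cols.colptr(d * kh * kw + j * kh + i);
        const int h0 = std::max(0, ph - i);
        const int h1 = std::min(H - 1, H - 1 + ph - i);
        const int run = h1 - h0 + 1;
        if (run <= 0) continue;
        const int w0 = std::max(0, pw - j);
        const int w1 = std::min(W - 1, W - 1 + pw - j);
        for (int w = w0; w <= w1; ++w) {
          double* dst = os + (w + j - pw) * H + (h0 + i - ph);
          const double* src = cc + w * H + h0;
          for (int r = 0; r < run; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return out;
}

// Stride-1 same-padded max pooling. Returns the pooled cube and, for each
// output element, the 0-based linear index (within its slice) of the winning
// input element, for use by the backward pass.
// [[Rcpp::export]]
Rcpp::List maxpool_same_fwd(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, D = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  cube out(H, W, D);
  icube arg(H, W, D);
  for (int d = 0; d < D; ++d) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double best = -datum::inf;
        int besti = 0;
        for (int j = -pw; j <= kw - 1 - pw; ++j) {
          const int ws = w + j;
          if (ws < 0 || ws >= W) continue;
          for (int i = -ph; i <= kh - 1 - ph; ++i) {
            const int hs = h + i;
            if (hs < 0 || hs >= H) continue;
            const double v = x(hs, ws, d);
            if (v > best) { best = v; besti = ws * H + hs; }
          }
        }
        out(h, w, d) = best;
        arg(h, w, d) = besti;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool_same_bwd(const arma::cube& dout, const arma::icube& argmax) {
  const int H = dout.n_rows, W = dout.n_cols, D = dout.n_slices;
  cube dx(H, W, D, fill::zeros);
  for (int d = 0; d < D; ++d) {
    double* slice = dx.slice_memptr(d);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        slice[argmax(h, w, d)] += dout(h, w, d);
  }
  return dx;
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// One-direction LSTM forward over a sequence.
//   X  : [I x B x T] inputs (slice t = time step t)
//   Wx : [4H x I], Wh : [4H x H], b : [4H]; gate row order i, f, g, o.
// Returns hidden states H [H x B x T], cell states C, and post-activation
// gates G [4H x B x T] cached for the backward pass. Initial h, c are zero.
// [[Rcpp::export]]
Rcpp::List lstm_fwd(const arma::cube& X, const arma::mat& Wx,
                    const arma::mat& Wh, const arma::vec& b) {
  const int B = X.n_cols, T = X.n_slices;
  const int Hn = Wh.n_cols;
  cube Hs(Hn, B, T), Cs(Hn, B, T), Gs(4 * Hn, B, T);
  mat h(Hn, B, fill::zeros), c(Hn, B, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat Z = Wx * X.slice(t) + Wh * h;
    Z.each_col() += b;
    mat i = sigm(Z.rows(0, Hn - 1));
    mat f = sigm(Z.rows(Hn, 2 * Hn - 1));
    mat g = tanh(Z.rows(2 * Hn, 3 * Hn - 1));
    mat o = sigm(Z.rows(3 * Hn, 4 * Hn - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    Hs.slice(t) = h;
    Cs.slice(t) = c;
    Gs.slice(t) = join_cols(i, f, g, o);
  }
  return Rcpp::List::create(Rcpp::Named("h") = Hs, Rcpp::Named("c") = Cs,
                            Rcpp::Named("g") = Gs);
}

// Backpropagation through time for lstm_fwd. dH is the gradient of the loss
// with respect to every hidden state. Returns gradients w.r.t. inputs and
// parameters.
// [[Rcpp::export]]
Rcpp::List lstm_bwd(const arma::cube& X, const arma::cube& Hs,
                    const arma::cube& Cs, const arma::cube& Gs,
                    const arma::mat& Wx, const arma::mat& Wh,
                    const arma::cube& dH) {
  const int I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const int Hn = Hs.n_rows;
  cube dX(I, B, T, fill::zeros);
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  vec db(4 * Hn, fill::zeros);
  mat dh_next(Hn, B, fill::zeros), dc_next(Hn, B, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const mat i = Gs.slice(t).rows(0, Hn - 1);
    const mat f = Gs.slice(t).rows(Hn, 2 * Hn - 1);
    const mat g = Gs.slice(t).rows(2 * Hn, 3 * Hn - 1);
    const mat o = Gs.slice(t).rows(3 * Hn, 4 * Hn - 1);
    const mat tc = tanh(Cs.slice(t));
    const mat c_prev = (t > 0) ? mat(Cs.slice(t - 1))
                               : mat(Hn, B, fill::zeros);
    const mat h_prev = (t > 0) ? mat(Hs.slice(t - 1))
                               : mat(Hn, B, fill::zeros);
    mat dh = dH.slice(t) + dh_next;
    mat do_ = dh % tc;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat di = dc % g;
    mat df = dc % c_prev;
    mat dg = dc % i;
    dc_next = dc % f;
    mat dZ = join_cols(di % i % (1.0 - i),
                       df % f % (1.0 - f),
                       dg % (1.0 - g % g),
                       do_ % o % (1.0 - o));
    dX.slice(t) = Wx.t() * dZ;
    dh_next = Wh.t() * dZ;
    dWx += dZ * X.slice(t).t();
    dWh += dZ * h_prev.t();
    db += sum(dZ, 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}
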