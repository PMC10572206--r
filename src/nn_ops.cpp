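// Minimal convolutional-network primitives: im2col-based 2-D convolution
// (forward and backward) and 2x2 max pooling, on H x W x C arrays. R arrays
// and Armadillo cubes share column-major layout, so conversion is free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int pad, int stride,
                  int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(C * kh * kw, Hout * Wout, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = c * kh * kw + kj * kh + ki;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            cols(row, wo * Hout + ho) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
Rcpp::List conv2d_forward(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, int kh, int kw, int pad,
                          int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int Cout = Wm.n_rows;
  mat cols = im2col(x, kh, kw, pad, stride, Hout, Wout);
  mat out = Wm * cols;
  out.each_col() += b;
  cube y(Hout, Wout, Cout);
  for (int c = 0; c < Cout; ++c) {
    y.slice(c) = reshape(out.row(c), Hout, Wout);
  }
  return Rcpp::List::create(Rcpp::Named("out") = y);
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& Wm,
                           const arma::cube& dout, int kh, int kw, int pad,
                           int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = dout.n_rows, Wout = dout.n_cols, Cout = dout.n_slices;
  mat cols = im2col(x, kh, kw, pad, stride, Hout, Wout);
  mat dout_m(Cout, Hout * Wout);
  for (int c = 0; c < Cout; ++c) {
    dout_m.row(c) = reshape(dout.slice(c), 1, Hout * Wout);
  }
  mat dW = dout_m * cols.t();
  vec db = sum(dout_m, 1);
  mat dcols = Wm.t() * dout_m;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = c * kh * kw + kj * kh + ki;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            dx(hi, wi, c) += dcols(row, wo * Hout + ho);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2, ceil-mode (odd trailing rows/cols pool over the
// available cells). argmax holds 0-based linear indices into the input.
// [[Rcpp::export]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = (H + 1) / 2, Wout = (W + 1) / 2;
  cube y(Hout, Wout, C);
  arma::ucube am(Hout, Wout, C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        double best = -datum::inf;
        uword bidx = 0;
        for (int dw = 0; dw < 2; ++dw) {
          const int wi = 2 * wo + dw;
          if (wi >= W) continue;
          for (int dh = 0; dh < 2; ++dh) {
            const int hi = 2 * ho + dh;
            if (hi >= H) continue;
            const double v = x(hi, wi, c);
            if (v > best) {
              best = v;
              bidx = (uword)hi + (uword)wi * H + (uword)c * H * W;
            }
          }
        }
        y(ho, wo, c) = best;
        am(ho, wo, c) = bidx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y,
                            Rcpp::Named("argmax") = am);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& dout, const arma::ucube& argmax,
                             int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  const uword n = dout.n_elem;
  for (uword i = 0; i < n; ++i) {
    dx(argmax(i)) += dout(i);
  }
  return dx;
}

// Iterative (soft-)NMS engine. mode: 0 = hard, 1 = linear, 2 = gaussian.
// Ties in the running maximum go to the lowest input index. Returns 1-based
// picked indices in selection order with their final (decayed) scores.
// [[Rcpp::export]]
Rcpp::List nms_engine(const arma::mat& boxes, const arma::vec& scores,
                      int mode, double Nt, double sigma, double floor_) {
  const int n = boxes.n_rows;
  std::vector<bool> alive(n, true);
  vec s = scores;
  vec area(n);
  for (int i = 0; i < n; ++i) {
    area(i) = std::max(0.0, boxes(i, 2) - boxes(i, 0)) *
              std::max(0.0, boxes(i, 3) - boxes(i, 1));
  }
  std::vector<int> picked;
  std::vector<double> pscore;
  int remaining = n;
  while (remaining > 0) {
    int m = -1;
    double best = -datum::inf;
    for (int i = 0; i < n; ++i) {
      if (alive[i] && s(i) > best) { best = s(i); m = i; }
    }
    if (m < 0) break;
    alive[m] = false;
    --remaining;
    picked.push_back(m + 1);
    pscore.push_back(s(m));
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      const double ix1 = std::max(boxes(m, 0), boxes(i, 0));
      const double iy1 = std::max(boxes(m, 1), boxes(i, 1));
      const double ix2 = std::min(boxes(m, 2), boxes(i, 2));
      const double iy2 = std::min(boxes(m, 3), boxes(i, 3));
      const double inter = std::max(0.0, ix2 - ix1) * std::max(0.0, iy2 - iy1);
      const double uni = area(m) + area(i) - inter;
      const double ov = uni > 0 ? inter / uni : 0.0;
      bool kill = false;
      if (mode == 0) {
        kill = ov > Nt;
      } else {
        if (mode == 1) {
          if (ov >= Nt) s(i) *= (1.0 - ov);
        } else {
          s(i) *= std::exp(-ov * ov / sigma);
        }
        kill = s(i) < floor_;
      }
      if (kill) { alive[i] = false; --remaining; }
    }
  }
  return Rcpp::List::create(Rcpp::Named("picked") = picked,
                            Rcpp::Named("scores") = pscore);
}
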