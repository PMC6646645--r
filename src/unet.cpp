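// Minimal CNN kernels for the U-net harness: 3x3 same-padding convolution
// (forward/backward via im2col + BLAS GEMM), 2x2 max pooling, and 2x
// nearest-neighbour upsampling. Tensors are R arrays with dim (H, W, C, N),
// column-major as R stores them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; i++) d[i] = dm[i];
}

static NumericVector make_arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill the im2col matrix M (9*Cin x H*W) for sample n of x.
static void im2col3(const double* xn, int H, int W, int Cin, arma::mat& M) {
  M.zeros();
  for (int ci = 0; ci < Cin; ci++) {
    const double* xc = xn + (size_t)ci * H * W;
    for (int kj = 0; kj < 3; kj++) {
      for (int ki = 0; ki < 3; ki++) {
        int row = ci * 9 + kj * 3 + ki;
        int dh = ki - 1, dw = kj - 1;
        for (int w = 0; w < W; w++) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* src = xc + (size_t)sw * H + dh;
          double* dst = M.memptr() + (size_t)(w * H) * M.n_rows + row;
          for (int h = h0; h < h1; h++) {
            dst[(size_t)h * M.n_rows] = src[h];
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& w, int Cin, int Cout) {
  arma::mat Wm(Cout, 9 * Cin);
  const double* wp = w.begin(); // dim (3,3,Cin,Cout)
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < Cin; ci++)
      for (int kj = 0; kj < 3; kj++)
        for (int ki = 0; ki < 3; ki++)
          Wm(co, ci * 9 + kj * 3 + ki) =
            wp[ki + 3 * (kj + 3 * (ci + Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int d[4]; get_dims4(x, d);
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch between input and weights");
  arma::mat Wm = weight_matrix(w, Cin, Cout);
  arma::vec bv(b.begin(), Cout);
  NumericVector out = make_arr4(H, W, Cout, N);
  arma::mat M(9 * Cin, H * W);
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + (size_t)n * H * W * Cin;
    im2col3(xn, H, W, Cin, M);
    arma::mat Y = Wm * M; // Cout x HW
    Y.each_col() += bv;
    double* on = out.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; co++)
      for (int p = 0; p < H * W; p++)
        on[(size_t)co * H * W + p] = Y(co, p);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int d[4]; get_dims4(x, d);
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  arma::mat Wm = weight_matrix(w, Cin, Cout);
  arma::mat dWm(Cout, 9 * Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx = make_arr4(H, W, Cin, N);
  arma::mat M(9 * Cin, H * W);
  arma::mat G(Cout, H * W);
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + (size_t)n * H * W * Cin;
    im2col3(xn, H, W, Cin, M);
    const double* dyn = dy.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; co++)
      for (int p = 0; p < H * W; p++)
        G(co, p) = dyn[(size_t)co * H * W + p];
    dWm += G * M.t();
    db += arma::sum(G, 1);
    arma::mat D = Wm.t() * G; // 9Cin x HW
    double* dxn = dx.begin() + (size_t)n * H * W * Cin;
    for (int ci = 0; ci < Cin; ci++) {
      double* dxc = dxn + (size_t)ci * H * W;
      for (int kj = 0; kj < 3; kj++) {
        for (int ki = 0; ki < 3; ki++) {
          int row = ci * 9 + kj * 3 + ki;
          int dh = ki - 1, dw = kj - 1;
          for (int w2 = 0; w2 < W; w2++) {
            int sw = w2 + dw;
            if (sw < 0 || sw >= W) continue;
            int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            for (int h = h0; h < h1; h++)
              dxc[(size_t)sw * H + h + dh] += D(row, h + H * w2);
          }
        }
      }
    }
  }
  NumericVector dwv = make_arr4(3, 3, Cin, Cout);
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < Cin; ci++)
      for (int kj = 0; kj < 3; kj++)
        for (int ki = 0; ki < 3; ki++)
          dwv[ki + 3 * (kj + 3 * (ci + Cin * co))] =
            dWm(co, ci * 9 + kj * 3 + ki);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int d[4]; get_dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector out = make_arr4(Ho, Wo, C, N);
  IntegerVector idx(out.size()); // 0-based linear index into x
  size_t o = 0;
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; w++) {
        for (int h = 0; h < Ho; h++) {
          int h2 = 2 * h, w2 = 2 * w;
          size_t i00 = (size_t)w2 * H + h2;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          for (int k = 1; k < 4; k++)
            if (xc[cand[k]] > xc[best]) best = cand[k];
          out[((size_t)n * C + c) * Ho * Wo + (size_t)w * Ho + h] = xc[best];
          idx[((size_t)n * C + c) * Ho * Wo + (size_t)w * Ho + h] =
            (int)(base + best);
          o++;
        }
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx = make_arr4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); i++) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  int d[4]; get_dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out = make_arr4(2 * H, 2 * W, C, N);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* oc = out.begin() + ((size_t)n * C + c) * 4 * H * W;
      for (int w = 0; w < W; w++) {
        for (int h = 0; h < H; h++) {
          double v = xc[(size_t)w * H + h];
          size_t b = (size_t)(2 * w) * 2 * H + 2 * h;
          oc[b] = v; oc[b + 1] = v;
          oc[b + 2 * H] = v; oc[b + 2 * H + 1] = v;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  int d[4]; get_dims4(dy, d);
  int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx = make_arr4(H, W, C, N);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* gc = dy.begin() + ((size_t)n * C + c) * H2 * W2;
      double* xc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; w++) {
        for (int h = 0; h < H; h++) {
          size_t b = (size_t)(2 * w) * H2 + 2 * h;
          xc[(size_t)w * H + h] =
            gc[b] + gc[b + 1] + gc[b + H2] + gc[b + H2 + 1];
        }
      }
    }
  }
  return dx;
}
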