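// 3D convolution and max-pooling kernels (stride 1, "same" zero padding).
//
// Volumes are R arrays in column-major order with dim (H, W, D, C) or
// (H, W, D, C, N) for a minibatch. Convolutions are computed by im2col +
// BLAS gemm; the weight matrix has K = kh*kw*kd*Cin rows (kh fastest, then
// kw, kd, channel) and Cout columns. Even kernels pad only on the far edge
// (pad = floor((k-1)/2) on the near side), which keeps output spatial size
// equal to input size for stride 1.

#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dims(const NumericVector& x, int dims[5]) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 4) {
    dims[0] = d[0]; dims[1] = d[1]; dims[2] = d[2]; dims[3] = d[3]; dims[4] = 1;
  } else if (d.size() == 5) {
    for (int i = 0; i < 5; ++i) dims[i] = d[i];
  } else {
    stop("expected a 4-D (H,W,D,C) or 5-D (H,W,D,C,N) array");
  }
}

// Fill `cols` (H*W*D x kh*kw*kd*Cin) from one sample.
static void im2col(const double* x, int H, int W, int D, int C,
                   int kh, int kw, int kd, arma::mat& cols) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2, pd = (kd - 1) / 2;
  const int HW = H * W, HWD = H * W * D;
  for (int c = 0; c < C; ++c) {
    for (int dd = 0; dd < kd; ++dd) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const int q = dh + kh * (dw + kw * (dd + kd * c));
          double* col = cols.colptr(q);
          for (int d = 0; d < D; ++d) {
            const int id = d + dd - pd;
            const bool dok = id >= 0 && id < D;
            for (int w = 0; w < W; ++w) {
              const int iw = w + dw - pw;
              const bool wok = dok && iw >= 0 && iw < W;
              double* dst = col + d * HW + w * H;
              if (!wok) {
                std::fill(dst, dst + H, 0.0);
                continue;
              }
              const double* src = x + c * HWD + id * HW + iw * H;
              for (int h = 0; h < H; ++h) {
                const int ih = h + dh - ph;
                dst[h] = (ih >= 0 && ih < H) ? src[ih] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add `cols` back into a sample gradient.
static void col2im(const arma::mat& cols, int H, int W, int D, int C,
                   int kh, int kw, int kd, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2, pd = (kd - 1) / 2;
  const int HW = H * W, HWD = H * W * D;
  for (int c = 0; c < C; ++c) {
    for (int dd = 0; dd < kd; ++dd) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const int q = dh + kh * (dw + kw * (dd + kd * c));
          const double* col = cols.colptr(q);
          for (int d = 0; d < D; ++d) {
            const int id = d + dd - pd;
            if (id < 0 || id >= D) continue;
            for (int w = 0; w < W; ++w) {
              const int iw = w + dw - pw;
              if (iw < 0 || iw >= W) continue;
              const double* src = col + d * HW + w * H;
              double* dst = dx + c * HWD + id * HW + iw * H;
              for (int h = 0; h < H; ++h) {
                const int ih = h + dh - ph;
                if (ih >= 0 && ih < H) dst[ih] += src[h];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, arma::mat Wm,
                                 arma::vec b, IntegerVector kernel) {
  int dm[5];
  get_dims(x, dm);
  const int H = dm[0], W = dm[1], D = dm[2], C = dm[3], N = dm[4];
  const int kh = kernel[0], kw = kernel[1], kd = kernel[2];
  const int K = kh * kw * kd * C;
  if ((int)Wm.n_rows != K) stop("weight rows do not match kernel*channels");
  const int Cout = Wm.n_cols;
  const int V = H * W * D;

  NumericVector out((R_xlen_t)V * Cout * N);
  arma::mat cols(V, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * V * C, H, W, D, C, kh, kw, kd, cols);
    arma::mat o = cols * Wm;
    o.each_row() += b.t();
    std::copy(o.begin(), o.end(), out.begin() + (R_xlen_t)n * V * Cout);
  }
  IntegerVector xd = x.attr("dim");
  if (xd.size() == 4) {
    out.attr("dim") = IntegerVector::create(H, W, D, Cout);
  } else {
    out.attr("dim") = IntegerVector::create(H, W, D, Cout, N);
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, arma::mat Wm, NumericVector gout,
                         IntegerVector kernel) {
  int dm[5];
  get_dims(x, dm);
  const int H = dm[0], W = dm[1], D = dm[2], C = dm[3], N = dm[4];
  const int kh = kernel[0], kw = kernel[1], kd = kernel[2];
  const int K = kh * kw * kd * C;
  const int Cout = Wm.n_cols;
  const int V = H * W * D;

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(V, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * V * C, H, W, D, C, kh, kw, kd, cols);
    arma::mat g(const_cast<double*>(gout.begin()) + (R_xlen_t)n * V * Cout,
                V, Cout, false, true);
    dW += cols.t() * g;
    db += arma::sum(g, 0).t();
    arma::mat dcols = g * Wm.t();
    col2im(dcols, H, W, D, C, kh, kw, kd,
           dx.begin() + (R_xlen_t)n * V * C);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward_cpp(NumericVector x) {
  int dm[5];
  get_dims(x, dm);
  const int H = dm[0], W = dm[1], D = dm[2], C = dm[3], N = dm[4];
  const int Ho = H / 2, Wo = W / 2, Do = D / 2;
  if (Ho < 1 || Wo < 1 || Do < 1) stop("volume too small for 2x2x2 pooling");
  const R_xlen_t Vin = (R_xlen_t)H * W * D, Vout = (R_xlen_t)Ho * Wo * Do;

  NumericVector out(Vout * C * N);
  IntegerVector arg(Vout * C * N);
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (n * C + c) * Vin;
      double* os = out.begin() + ((R_xlen_t)n * C + c) * Vout;
      int* as = arg.begin() + ((R_xlen_t)n * C + c) * Vout;
      for (int d = 0; d < Do; ++d) {
        for (int w = 0; w < Wo; ++w) {
          for (int h = 0; h < Ho; ++h) {
            double best = -HUGE_VAL;
            int besti = 0;
            for (int dd = 0; dd < 2; ++dd)
              for (int dw = 0; dw < 2; ++dw)
                for (int dh = 0; dh < 2; ++dh) {
                  const int idx = (2 * h + dh) + (2 * w + dw) * H +
                                  (2 * d + dd) * HW;
                  if (xs[idx] > best) { best = xs[idx]; besti = idx; }
                }
            const int oidx = h + w * Ho + d * Ho * Wo;
            os[oidx] = best;
            as[oidx] = besti;
          }
        }
      }
    }
  }
  IntegerVector d4 = x.attr("dim");
  IntegerVector odim = (d4.size() == 4)
      ? IntegerVector::create(Ho, Wo, Do, C)
      : IntegerVector::create(Ho, Wo, Do, C, N);
  out.attr("dim") = odim;
  arg.attr("dim") = odim;
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward_cpp(NumericVector gout, IntegerVector argmax,
                                     IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  int N = xdim.size() == 5 ? xdim[4] : 1;
  const R_xlen_t Vin = (R_xlen_t)H * W * D;
  int dm[5];
  get_dims(gout, dm);
  const R_xlen_t Vout = (R_xlen_t)dm[0] * dm[1] * dm[2];

  NumericVector dx(Vin * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gs = gout.begin() + ((R_xlen_t)n * C + c) * Vout;
      const int* as = argmax.begin() + ((R_xlen_t)n * C + c) * Vout;
      double* ds = dx.begin() + ((R_xlen_t)n * C + c) * Vin;
      for (R_xlen_t i = 0; i < Vout; ++i) ds[as[i]] += gs[i];
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}
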