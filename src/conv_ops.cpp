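// Convolution and max-pooling primitives for the image model.
// Layout convention (column-major, matching R arrays):
//   activations: array dim (H, W, C, B)  -> arma::cube with C*B slices,
//                slice index c + C*b
//   kernels:     array dim (kh, kw, Cin, Cout) -> slice index ci + Cin*co
// Convolutions are zero-padded "same": pad_beg = (k - 1) / 2 (floor), so
// even kernel sizes pad asymmetrically and preserve the spatial dims.
// Implemented as im2col + GEMM so the heavy lifting runs in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Patch matrix for one sample: rows = output pixel (r + H*c), columns
// q = dy + kh*(dx + kw*ci).  Out-of-image taps stay zero.
static void im2col(const arma::cube& x, int b, int Cin,
                   int kh, int kw, arma::mat& col) {
  const int H = x.n_rows, W = x.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  col.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const arma::mat& xs = x.slice(ci + Cin * b);
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        const int q = dy + kh * (dx + kw * ci);
        // output pixel (r, c) reads input (r + dy - ph, c + dx - pw)
        const int r0 = std::max(0, ph - dy), r1 = std::min(H, H + ph - dy);
        const int c0 = std::max(0, pw - dx), c1 = std::min(W, W + pw - dx);
        for (int c = c0; c < c1; ++c) {
          const double* src = xs.colptr(c + dx - pw) + (r0 + dy - ph);
          double* dst = col.colptr(q) + (r0 + (arma::uword)H * c);
          std::copy(src, src + (r1 - r0), dst);
        }
      }
    }
  }
}

// Scatter-add transpose of im2col.
static void col2im_add(arma::mat& dxs_all, const arma::mat& dcol, int b,
                       int Cin, int H, int W, int kh, int kw,
                       arma::cube& dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    arma::mat& dxs = dx.slice(ci + Cin * b);
    for (int dxk = 0; dxk < kw; ++dxk) {
      for (int dy = 0; dy < kh; ++dy) {
        const int q = dy + kh * (dxk + kw * ci);
        const int r0 = std::max(0, ph - dy), r1 = std::min(H, H + ph - dy);
        const int c0 = std::max(0, pw - dxk), c1 = std::min(W, W + pw - dxk);
        for (int c = c0; c < c1; ++c) {
          const double* src = dcol.colptr(q) + (r0 + (arma::uword)H * c);
          double* dst = dxs.colptr(c + dxk - pw) + (r0 + dy - ph);
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  (void)dxs_all;
}

static arma::mat kernel_matrix(const arma::cube& w, int Cin, int Cout) {
  const int kh = w.n_rows, kw = w.n_cols;
  arma::mat wm(kh * kw * Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      std::copy(w.slice(ci + Cin * co).begin(), w.slice(ci + Cin * co).end(),
                wm.colptr(co) + kh * kw * ci);
  return wm;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::cube& w,
                      const arma::vec& b, int B, int Cin, int Cout) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = w.n_rows, kw = w.n_cols;
  const arma::mat wm = kernel_matrix(w, Cin, Cout);
  arma::cube y(H, W, (arma::uword)Cout * B);
  arma::mat col(H * W, kh * kw * Cin);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x, bb, Cin, kh, kw, col);
    arma::mat out = col * wm;            // (H*W) x Cout
    out.each_row() += b.t();
    for (int co = 0; co < Cout; ++co)
      y.slice(co + Cout * bb) =
        arma::reshape(out.col(co), H, W);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::cube& w,
                const arma::cube& dy, int B, int Cin, int Cout) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = w.n_rows, kw = w.n_cols;
  const arma::mat wm = kernel_matrix(w, Cin, Cout);
  arma::mat dwm(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dx(H, W, (arma::uword)Cin * B, arma::fill::zeros);
  arma::mat col(H * W, kh * kw * Cin);
  arma::mat dym(H * W, Cout);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x, bb, Cin, kh, kw, col);
    for (int co = 0; co < Cout; ++co)
      dym.col(co) = arma::vectorise(dy.slice(co + Cout * bb));
    dwm += col.t() * dym;
    db += arma::sum(dym, 0).t();
    arma::mat dcol = dym * wm.t();       // (H*W) x (kh*kw*Cin)
    col2im_add(col, dcol, bb, Cin, H, W, kh, kw, dx);
  }
  arma::cube dw(kh, kw, (arma::uword)Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      std::copy(dwm.colptr(co) + kh * kw * ci,
                dwm.colptr(co) + kh * kw * (ci + 1),
                dw.slice(ci + Cin * co).begin());
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export]]
List maxpool_fwd(const arma::cube& x, int p, int B, int C) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = H / p, Wo = W / p;
  arma::cube y(Ho, Wo, (arma::uword)C * B);
  arma::ucube idx(Ho, Wo, (arma::uword)C * B);   // linear index into slice
  for (arma::uword s = 0; s < x.n_slices; ++s) {
    const arma::mat& xs = x.slice(s);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dc = 0; dc < p; ++dc) {
          for (int dr = 0; dr < p; ++dr) {
            const int rr = r * p + dr, cc = c * p + dc;
            const double v = xs(rr, cc);
            if (v > best) { best = v; bi = rr + (arma::uword)H * cc; }
          }
        }
        y(r, c, s) = best;
        idx(r, c, s) = bi;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::cube& dy, const arma::ucube& idx,
                       int H, int W) {
  arma::cube dx(H, W, dy.n_slices, arma::fill::zeros);
  for (arma::uword s = 0; s < dy.n_slices; ++s) {
    arma::mat& dxs = dx.slice(s);
    const arma::mat& gs = dy.slice(s);
    const arma::umat& is = idx.slice(s);
    for (arma::uword j = 0; j < gs.n_elem; ++j) dxs(is(j)) += gs(j);
  }
  return dx;
}
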