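// Low-level numeric kernels for the spatial-attention U-Net.
//
// Feature maps are (H*W) x C double matrices. Pixels are stored
// column-major over the image grid: linear index p = r + c*H for
// 0-based row r and column c (origin top-left, (row, col) indexing).
//
// 3x3 convolution weights are (9*C_in) x C_out matrices whose row index
// is off*C_in + ch with off = (dr+1) + (dc+1)*3 for window offsets
// dr, dc in {-1, 0, 1} (dr fastest, matching R's column-major order of a
// 3x3 kernel matrix).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const arma::mat& X, const int H, const int W) {
  const int C = X.n_cols;
  arma::mat col(static_cast<arma::uword>(H) * W, 9 * C, arma::fill::zeros);
  int off = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++off) {
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int ch = 0; ch < C; ++ch) {
        const double* src = X.colptr(ch);
        double* dst = col.colptr(off * C + ch);
        for (int c = c0; c < c1; ++c) {
          // col[r + c*H] = X[(r+dr) + (c+dc)*H] for r in [r0, r1)
          std::memcpy(dst + r0 + c * H, src + (r0 + dr) + (c + dc) * H,
                      sizeof(double) * (r1 - r0));
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::mat cpp_conv3x3_fwd(const arma::mat& X, int H, int W,
                          const arma::mat& Wt, const arma::rowvec& b) {
  arma::mat out = im2col3(X, H, W) * Wt;
  out.each_row() += b;
  return out;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(const arma::mat& X, int H, int W,
                     const arma::mat& Wt, const arma::mat& dY) {
  arma::mat col = im2col3(X, H, W);
  arma::mat dW = col.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dcol = dY * Wt.t();
  col.reset();
  const int C = X.n_cols;
  arma::mat dX(X.n_rows, C, arma::fill::zeros);
  int off = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++off) {
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int ch = 0; ch < C; ++ch) {
        double* dst = dX.colptr(ch);
        const double* src = dcol.colptr(off * C + ch);
        for (int c = c0; c < c1; ++c) {
          const int base_dst = (r0 + dr) + (c + dc) * H;
          const int base_src = r0 + c * H;
          for (int r = 0; r < r1 - r0; ++r) dst[base_dst + r] += src[base_src + r];
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& X, int H, int W, int f) {
  const int Ho = H / f, Wo = W / f, C = X.n_cols;
  arma::mat out(static_cast<arma::uword>(Ho) * Wo, C);
  IntegerMatrix idx(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = -1;
        for (int dc = 0; dc < f; ++dc) {
          for (int dr = 0; dr < f; ++dr) {
            const int p = (ro * f + dr) + (co * f + dc) * H;
            if (x[p] > best) { best = x[p]; bi = p; }
          }
        }
        out(ro + co * Ho, ch) = best;
        idx(ro + co * Ho, ch) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dY, const IntegerMatrix& idx, int HW) {
  const int C = dY.n_cols, n = dY.n_rows;
  arma::mat dX(HW, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int i = 0; i < n; ++i)
      dX(idx(i, ch), ch) += dY(i, ch);
  return dX;
}

// Sum over non-overlapping f x f blocks; avg-pool = sumpool / f^2 and the
// adjoint of nearest-neighbour upsampling.
// [[Rcpp::export]]
arma::mat cpp_sumpool(const arma::mat& X, int H, int W, int f) {
  const int Ho = H / f, Wo = W / f, C = X.n_cols;
  arma::mat out(static_cast<arma::uword>(Ho) * Wo, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    double* o = out.colptr(ch);
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro) {
        double s = 0.0;
        for (int dc = 0; dc < f; ++dc)
          for (int dr = 0; dr < f; ++dr)
            s += x[(ro * f + dr) + (co * f + dc) * H];
        o[ro + co * Ho] = s;
      }
  }
  return out;
}

// Nearest-neighbour upsample of an H x W map by integer factor f.
// [[Rcpp::export]]
arma::mat cpp_upsample_nearest(const arma::mat& X, int H, int W, int f) {
  const int Ho = H * f, Wo = W * f, C = X.n_cols;
  arma::mat out(static_cast<arma::uword>(Ho) * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    double* o = out.colptr(ch);
    for (int c = 0; c < Wo; ++c) {
      const int cs = c / f;
      for (int r = 0; r < Ho; ++r)
        o[r + c * Ho] = x[(r / f) + cs * H];
    }
  }
  return out;
}

// Connected-component labeling of a binary H x W mask (BFS), 4- or
// 8-connectivity. Labels are contiguous 1..k in first-encounter
// (column-major raster scan) order; background stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int k = 0; k < nn; ++k) {
          const int qr = pr + dr8[k], qc = pc + dc8[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * H);
          }
        }
      }
    }
  }
  return lab;
}

// For each row of A (n x 2 coordinates), the minimum Euclidean distance to
// any row of B. Used for directed Hausdorff percentiles.
// [[Rcpp::export]]
NumericVector cpp_directed_min_dists(const NumericMatrix& A, const NumericMatrix& B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ar = A(i, 0), ac = A(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dr = ar - B(j, 0), dc = ac - B(j, 1);
      const double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
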