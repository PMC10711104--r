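// Low-level numerical kernels for the segmentation network and image ops.
// Feature maps cross the R/C++ boundary as arma::cube with dims (H, W, C),
// matching R arrays of dim c(H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col / col2im for stride-1 dilated 2-D convolution.
// Column index of the output matrix = io + jo * Ho (column-major spatial).
// Row index = ((c * k + kj) * k + ki), ki fastest.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int k, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int span = dil * (k - 1);
  const int Ho = H + 2 * pad - span;
  const int Wo = W + 2 * pad - span;
  if (Ho < 1 || Wo < 1) stop("im2col: kernel span exceeds padded input");
  arma::mat cols(C * k * k, (size_t)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = (c * k + kj) * k + ki;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jx = jo + kj * dil - pad;
          if (jx < 0 || jx >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int ix = io + ki * dil - pad;
            if (ix < 0 || ix >= H) continue;
            cols(row, (size_t)jo * Ho + io) = x(ix, jx, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C,
                      int k, int pad, int dil) {
  const int span = dil * (k - 1);
  const int Ho = H + 2 * pad - span;
  const int Wo = W + 2 * pad - span;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = (c * k + kj) * k + ki;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jx = jo + kj * dil - pad;
          if (jx < 0 || jx >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int ix = io + ki * dil - pad;
            if (ix < 0 || ix >= H) continue;
            x(ix, jx, c) += cols(row, (size_t)jo * Ho + io);
          }
        }
      }
    }
  }
  return x;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2, with argmax bookkeeping for the backward pass.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool: odd spatial size");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index into x
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        double best = -arma::datum::inf; arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ix = 2 * io + di, jx = 2 * jo + dj;
            const double v = x(ix, jx, c);
            if (v > best) {
              best = v;
              bi = (arma::uword)c * H * W + (arma::uword)jx * H + ix;
            }
          }
        y(io, jo, c) = best;
        idx(io, jo, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const arma::cube& dy, const arma::ucube& idx,
                            int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword t = 0; t < dy.n_elem; ++t) dx(idx(t)) += dy(t);
  return dx;
}

// ---------------------------------------------------------------------------
// Bilinear resize (half-pixel centres, edge clamped) and its transpose.
// ---------------------------------------------------------------------------

static inline void bilin_coef(int o, int n_in, int n_out,
                              int& i0, int& i1, double& w1) {
  double src = (o + 0.5) * ((double)n_in / n_out) - 0.5;
  if (src < 0) src = 0;
  if (src > n_in - 1) src = n_in - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = src - i0;
}

// [[Rcpp::export]]
arma::cube bilinear_fwd_cpp(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(Ho, Wo, C);
  for (int jo = 0; jo < Wo; ++jo) {
    int j0, j1; double wj;
    bilin_coef(jo, W, Wo, j0, j1, wj);
    for (int io = 0; io < Ho; ++io) {
      int i0, i1; double wi;
      bilin_coef(io, H, Ho, i0, i1, wi);
      for (int c = 0; c < C; ++c)
        y(io, jo, c) =
          (1 - wi) * (1 - wj) * x(i0, j0, c) + wi * (1 - wj) * x(i1, j0, c) +
          (1 - wi) * wj * x(i0, j1, c) + wi * wj * x(i1, j1, c);
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube bilinear_bwd_cpp(const arma::cube& dy, int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int jo = 0; jo < Wo; ++jo) {
    int j0, j1; double wj;
    bilin_coef(jo, W, Wo, j0, j1, wj);
    for (int io = 0; io < Ho; ++io) {
      int i0, i1; double wi;
      bilin_coef(io, H, Ho, i0, i1, wi);
      for (int c = 0; c < C; ++c) {
        const double g = dy(io, jo, c);
        dx(i0, j0, c) += (1 - wi) * (1 - wj) * g;
        dx(i1, j0, c) += wi * (1 - wj) * g;
        dx(i0, j1, c) += (1 - wi) * wj * g;
        dx(i1, j1, c) += wi * wj * g;
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Median filter with arbitrary window offsets and reflect padding.
// ---------------------------------------------------------------------------

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& x,
                                const IntegerMatrix& offs) {
  const int H = x.nrow(), W = x.ncol(), n = offs.nrow();
  NumericMatrix y(H, W);
  std::vector<double> buf(n);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      for (int t = 0; t < n; ++t)
        buf[t] = x(reflect_idx(i + offs(t, 0), H),
                   reflect_idx(j + offs(t, 1), W));
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        // even windows: average the two central order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        med = (med + lo) / 2.0;
      }
      y(i, j) = med;
    }
  return y;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Returns, per pixel, the squared distance to the nearest `true` pixel
// (Inf when the mask has none).
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  int q0 = 0;
  while (q0 < n && !std::isfinite(f[q0])) ++q0;
  if (q0 == n) {  // no source in this line
    std::fill(d.begin(), d.end(), arma::datum::inf);
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -arma::datum::inf;
  z[1] = arma::datum::inf;
  for (int q = q0 + 1; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;  // parabola at +inf never minimal
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = arma::datum::inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& feature) {
  const int H = feature.nrow(), W = feature.ncol();
  NumericMatrix out(H, W);
  // column pass
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i)
      f[i] = feature(i, j) ? 0.0 : arma::datum::inf;
    std::vector<double> fc(f.begin(), f.begin() + H), dc(H);
    dt1d(fc, dc);
    for (int i = 0; i < H; ++i) out(i, j) = dc[i];
  }
  // row pass
  for (int i = 0; i < H; ++i) {
    std::vector<double> fr(W), dr(W);
    for (int j = 0; j < W; ++j) fr[j] = out(i, j);
    dt1d(fr, dr);
    for (int j = 0; j < W; ++j) out(i, j) = dr[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Criss-cross attention core.  Each position (i, j) attends over the W
// positions of its row and the H positions of its column; the duplicate
// self position in the column is masked out, so the softmax runs over
// H + W - 1 distinct positions.
//  Q, K: (H, W, d)  V: (H, W, C)
//  Arow: cube (W, W, H), slice i holds A[(j), (w)] for row i
//  Acol: cube (H, H, W), slice j holds A[(i), (h)] for column j
// ---------------------------------------------------------------------------

static arma::mat row_mat(const arma::cube& X, int i) {
  // (W x d) matrix of X(i, ., .)
  arma::mat M(X.n_cols, X.n_slices);
  for (arma::uword d = 0; d < X.n_slices; ++d)
    for (arma::uword j = 0; j < X.n_cols; ++j) M(j, d) = X(i, j, d);
  return M;
}

static arma::mat col_mat(const arma::cube& X, int j) {
  // (H x d) matrix of X(., j, .)
  arma::mat M(X.n_rows, X.n_slices);
  for (arma::uword d = 0; d < X.n_slices; ++d)
    for (arma::uword i = 0; i < X.n_rows; ++i) M(i, d) = X(i, j, d);
  return M;
}

// [[Rcpp::export]]
List cca_attention_fwd_cpp(const arma::cube& Q, const arma::cube& K,
                           const arma::cube& V) {
  const int H = Q.n_rows, W = Q.n_cols, C = V.n_slices;
  // transposed energy layouts keep the per-pixel softmax gather contiguous:
  // Erow.slice(i) is (w, j); Ecol.slice(j) is (h, i)
  arma::cube Erow(W, W, H), Ecol(H, H, W);
  for (int i = 0; i < H; ++i) {
    arma::mat Qi = row_mat(Q, i), Ki = row_mat(K, i);
    Erow.slice(i) = Ki * Qi.t();           // (w, j)
  }
  for (int j = 0; j < W; ++j) {
    arma::mat Qj = col_mat(Q, j), Kj = col_mat(K, j);
    Ecol.slice(j) = Kj * Qj.t();           // (h, i)
  }
  arma::cube Arow(W, W, H), Acol(H, H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double* er = Erow.slice_colptr(i, j);      // length W
      double* ec = Ecol.slice_colptr(j, i);      // length H
      // max and sum over the H + W - 1 unmasked positions only
      double m = -arma::datum::inf;
      for (int w = 0; w < W; ++w) m = std::max(m, er[w]);
      for (int h = 0; h < H; ++h) if (h != i) m = std::max(m, ec[h]);
      double* ar = Arow.slice_colptr(i, j);
      double* ac = Acol.slice_colptr(j, i);
      double sum = 0.0;
      for (int w = 0; w < W; ++w) { ar[w] = std::exp(er[w] - m); sum += ar[w]; }
      for (int h = 0; h < H; ++h) {
        ac[h] = (h == i) ? 0.0 : std::exp(ec[h] - m);
        sum += ac[h];
      }
      const double inv = 1.0 / sum;
      for (int w = 0; w < W; ++w) ar[w] *= inv;
      for (int h = 0; h < H; ++h) ac[h] *= inv;
    }
  arma::cube agg(H, W, C);
  for (int i = 0; i < H; ++i) {
    arma::mat Vi = row_mat(V, i);                // (W x C)
    arma::mat Ri = Vi.t() * Arow.slice(i);       // (c, j)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j) agg(i, j, c) = Ri(c, j);
  }
  for (int j = 0; j < W; ++j) {
    arma::mat Vj = col_mat(V, j);                // (H x C)
    arma::mat Cj = Vj.t() * Acol.slice(j);       // (c, i)
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < H; ++i) agg(i, j, c) += Cj(c, i);
  }
  return List::create(_["agg"] = agg, _["Arow"] = Arow, _["Acol"] = Acol);
}

// [[Rcpp::export]]
List cca_attention_bwd_cpp(const arma::cube& Q, const arma::cube& K,
                           const arma::cube& V, const arma::cube& Arow,
                           const arma::cube& Acol, const arma::cube& dAgg) {
  const int H = Q.n_rows, W = Q.n_cols, d = Q.n_slices, C = V.n_slices;
  arma::cube dQ(H, W, d), dK(H, W, d, arma::fill::zeros),
      dV(H, W, C, arma::fill::zeros);
  // layouts match the forward pass: slice(i) of row cubes is (w, j),
  // slice(j) of column cubes is (h, i); dE* hold dA* on entry and are
  // overwritten in place by the softmax backward
  arma::cube dErow(W, W, H), dEcol(H, H, W);
  for (int i = 0; i < H; ++i) {
    arma::mat Vi = row_mat(V, i);                 // W x C
    arma::mat dGi = row_mat(dAgg, i);             // W x C (rows j)
    dErow.slice(i) = Vi * dGi.t();                // dArow: (w, j)
    arma::mat dVi = Arow.slice(i) * dGi;          // (w, c)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) dV(i, w, c) += dVi(w, c);
  }
  for (int j = 0; j < W; ++j) {
    arma::mat Vj = col_mat(V, j);                 // H x C
    arma::mat dGj = col_mat(dAgg, j);             // H x C (rows i)
    dEcol.slice(j) = Vj * dGj.t();                // dAcol: (h, i)
    arma::mat dVj = Acol.slice(j) * dGj;          // (h, c)
    for (int c = 0; c < C; ++c)
      for (int h = 0; h < H; ++h) dV(h, j, c) += dVj(h, c);
  }
  // softmax backward, jointly over the row and column parts
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      const double* ar = Arow.slice_colptr(i, j);
      const double* ac = Acol.slice_colptr(j, i);
      double* gr = dErow.slice_colptr(i, j);
      double* gc = dEcol.slice_colptr(j, i);
      double dot = 0.0;
      for (int w = 0; w < W; ++w) dot += ar[w] * gr[w];
      for (int h = 0; h < H; ++h) dot += ac[h] * gc[h];
      for (int w = 0; w < W; ++w) gr[w] = ar[w] * (gr[w] - dot);
      for (int h = 0; h < H; ++h) gc[h] = ac[h] * (gc[h] - dot);
    }
  for (int i = 0; i < H; ++i) {
    arma::mat Ki = row_mat(K, i), Qi = row_mat(Q, i);
    arma::mat dQi = dErow.slice(i).t() * Ki;      // (j, d)
    arma::mat dKi = dErow.slice(i) * Qi;          // (w, d)
    for (int t = 0; t < d; ++t)
      for (int w = 0; w < W; ++w) {
        dQ(i, w, t) = dQi(w, t);
        dK(i, w, t) += dKi(w, t);
      }
  }
  for (int j = 0; j < W; ++j) {
    arma::mat Kj = col_mat(K, j), Qj = col_mat(Q, j);
    arma::mat dQj = dEcol.slice(j).t() * Kj;      // (i, d)
    arma::mat dKj = dEcol.slice(j) * Qj;          // (h, d)
    for (int t = 0; t < d; ++t)
      for (int i = 0; i < H; ++i) {
        dQ(i, j, t) += dQj(i, t);
        dK(i, j, t) += dKj(i, t);
      }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
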