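// Low-level kernels: connected-component labeling for particle counting and
// im2col-based conv/pool/upsample primitives for the embedding network.
// Images are column-major matrices (R layout); feature maps are (H*W) x C
// matrices with pixel index i = (col-1)*H + row (0-based here).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass union-find labeling. connectivity is 4 or 8; labels are 1..n in
// raster order of first appearance (column-major).
// [[Rcpp::export(name = ".labelComponents")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      // previously visited neighbours in column-major raster order
      int neigh[4]; int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r + 1 < H && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(r, c) = m;
        for (int k = 0; k < nn; ++k) uf_union(parent, m, neigh[k]);
      }
    }
  }
  // flatten and relabel consecutively in order of root appearance
  std::vector<int> remap(next, 0);
  int nlab = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c)) {
        int root = uf_find(parent, lab(r, c));
        if (!remap[root]) remap[root] = ++nlab;
        lab(r, c) = remap[root];
      }
  return lab;
}

// im2col for a 3x3 window with zero padding 1. X is (H*W) x Cin; result is
// (H*W) x (9*Cin), block order: channel-major, then (dr, dc) in
// {-1,0,1} x {-1,0,1} column-major (dr fastest).
static arma::mat im2col3(const arma::mat& X, int H, int W) {
  const int N = H * W, Cin = X.n_cols;
  arma::mat cols(N, 9 * Cin, arma::fill::zeros);
  for (int ch = 0; ch < Cin; ++ch) {
    const double* src = X.colptr(ch);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        double* dst = cols.colptr(ch * 9 + k);
        for (int c = 0; c < W; ++c) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          const double* s = src + cc * H + dr;
          double* d = dst + c * H;
          for (int r = r0; r < r1; ++r) d[r] = s[r];
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col3
static arma::mat col2im3(const arma::mat& cols, int H, int W, int Cin) {
  arma::mat X(H * W, Cin, arma::fill::zeros);
  for (int ch = 0; ch < Cin; ++ch) {
    double* dst = X.colptr(ch);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        const double* src = cols.colptr(ch * 9 + k);
        for (int c = 0; c < W; ++c) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          double* d = dst + cc * H + dr;
          const double* s = src + c * H;
          for (int r = r0; r < r1; ++r) d[r] += s[r];
        }
      }
    }
  }
  return X;
}

// 3x3 same convolution: Y = im2col(X) * Wm + b. Wm is (9*Cin) x Cout.
// [[Rcpp::export(name = ".convForward")]]
arma::mat conv_forward(const arma::mat& X, const arma::mat& Wm,
                       const arma::vec& b, int H, int W) {
  arma::mat Y = im2col3(X, H, W) * Wm;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export(name = ".convBackward")]]
List conv_backward(const arma::mat& X, const arma::mat& Wm,
                   const arma::mat& dY, int H, int W) {
  arma::mat cols = im2col3(X, H, W);
  arma::mat dW = cols.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dX = col2im3(dY * Wm.t(), H, W, X.n_cols);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// batch normalisation over the pixel dimension, per channel
// [[Rcpp::export(name = ".bnForwardC")]]
List bn_forward(const arma::mat& z, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  const int N = z.n_rows, C = z.n_cols;
  arma::rowvec mu = arma::mean(z, 0);
  arma::mat xhat = z.each_row() - mu;
  arma::rowvec sd = arma::sqrt(arma::mean(arma::square(xhat), 0) + eps);
  xhat.each_row() /= sd;
  arma::mat y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  (void)N; (void)C;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sd"] = sd.t());
}

// [[Rcpp::export(name = ".bnBackwardC")]]
List bn_backward(const arma::mat& dy, const arma::mat& xhat,
                 const arma::vec& sd, const arma::vec& gamma) {
  const double N = dy.n_rows;
  arma::rowvec dgamma = arma::sum(dy % xhat, 0);
  arma::rowvec dbeta = arma::sum(dy, 0);
  arma::mat dxhat = dy;
  dxhat.each_row() %= gamma.t();
  arma::rowvec t1 = arma::sum(dxhat, 0) / N;
  arma::rowvec t2 = arma::sum(dxhat % xhat, 0) / N;
  arma::mat dz = dxhat;
  dz.each_row() -= t1;
  dz -= xhat.each_row() % t2;
  dz.each_row() /= sd.t();
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma.t(),
                      _["dbeta"] = dbeta.t());
}

// 2x2 max pooling (H, W even). Returns pooled map and 1-based argmax index
// into the input pixel dimension, both (H/2*W/2) x C.
// [[Rcpp::export(name = ".maxpoolForward")]]
List maxpool_forward(const arma::mat& X, int H, int W) {
  const int h = H / 2, w = W / 2, C = X.n_cols;
  arma::mat Y(h * w, C);
  arma::umat idx(h * w, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = X.colptr(ch);
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        int cand[4] = {(2 * c) * H + 2 * r, (2 * c) * H + 2 * r + 1,
                       (2 * c + 1) * H + 2 * r, (2 * c + 1) * H + 2 * r + 1};
        int best = cand[0];
        for (int k = 1; k < 4; ++k)
          if (src[cand[k]] > src[best]) best = cand[k];
        Y(c * h + r, ch) = src[best];
        idx(c * h + r, ch) = best + 1;
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpoolBackward")]]
arma::mat maxpool_backward(const arma::mat& dY, const arma::umat& idx,
                           int H, int W) {
  const int C = dY.n_cols;
  arma::mat dX(H * W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (arma::uword i = 0; i < dY.n_rows; ++i)
      dX(idx(i, ch) - 1, ch) += dY(i, ch);
  return dX;
}

// nearest-neighbour 2x upsampling: (h*w) x C -> (2h*2w) x C
// [[Rcpp::export(name = ".upsampleForward")]]
arma::mat upsample_forward(const arma::mat& X, int h, int w) {
  const int H = 2 * h, W = 2 * w, C = X.n_cols;
  arma::mat Y(H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = X.colptr(ch);
    double* dst = Y.colptr(ch);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        dst[c * H + r] = src[(c / 2) * h + r / 2];
  }
  return Y;
}

// [[Rcpp::export(name = ".upsampleBackward")]]
arma::mat upsample_backward(const arma::mat& dY, int h, int w) {
  const int H = 2 * h, C = dY.n_cols, W = 2 * w;
  arma::mat dX(h * w, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = dY.colptr(ch);
    double* dst = dX.colptr(ch);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        dst[(c / 2) * h + r / 2] += src[c * H + r];
  }
  return dX;
}
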