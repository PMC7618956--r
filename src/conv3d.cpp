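// Batched 3D convolution primitives for the patch VAE.
//
// Layout (column-major R matrices, sample-major rows):
//   activations: N x (C * V) where column index = c + C*v and the voxel
//     index v = i1 + n*(i2 + n*i3) (cubic spatial dims).
//   conv weight: Cout x (Cin*k^3), column index r = ci + Cin*(k1 + k*(k2 + k*k3))
//   transposed-conv weight: Cin x (Cout*k^3) (the weight of the adjoint conv).
//
// A convolution is computed as one large GEMM over an (N*Vo) x (Cin*k^3)
// gathered matrix; gathers and scatters move contiguous length-N column
// blocks, which keeps the cost memcpy-bound.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// source column (c-base excluded) for kernel slot (k1,k2,k3) at output voxel
// (o1,o2,o3); returns voxel index or -1 when in the zero padding
static inline int src_voxel(int o1, int o2, int o3, int k1, int k2, int k3,
                            int ni, int s, int p) {
  const int i1 = o1 * s - p + k1;
  if (i1 < 0 || i1 >= ni) return -1;
  const int i2 = o2 * s - p + k2;
  if (i2 < 0 || i2 >= ni) return -1;
  const int i3 = o3 * s - p + k3;
  if (i3 < 0 || i3 >= ni) return -1;
  return i1 + ni * (i2 + ni * i3);
}

// gather Cols (N*Vo) x (Cin*k^3) from x (N x Cin*Vi)
static void gather_cols(const arma::mat& x, arma::mat& Cols, int Cin, int ni,
                        int k, int s, int p) {
  const int no = out_size(ni, k, s, p);
  const int N = x.n_rows;
  Cols.zeros(static_cast<arma::uword>(N) * no * no * no, Cin * k * k * k);
  for (int k3 = 0; k3 < k; ++k3)
    for (int k2 = 0; k2 < k; ++k2)
      for (int k1 = 0; k1 < k; ++k1)
        for (int o3 = 0; o3 < no; ++o3)
          for (int o2 = 0; o2 < no; ++o2)
            for (int o1 = 0; o1 < no; ++o1) {
              const int vi = src_voxel(o1, o2, o3, k1, k2, k3, ni, s, p);
              if (vi < 0) continue;
              const int vo = o1 + no * (o2 + no * o3);
              for (int c = 0; c < Cin; ++c) {
                const int r = c + Cin * (k1 + k * (k2 + k * k3));
                std::memcpy(Cols.colptr(r) + static_cast<size_t>(N) * vo,
                            x.colptr(c + Cin * vi), N * sizeof(double));
              }
            }
}

// scatter-add adjoint: dCols (N*Vo) x (Cin*k^3) into dx (N x Cin*Vi)
static void scatter_cols(const arma::mat& dCols, arma::mat& dx, int Cin,
                         int ni, int k, int s, int p) {
  const int no = out_size(ni, k, s, p);
  const int N = dx.n_rows;
  for (int k3 = 0; k3 < k; ++k3)
    for (int k2 = 0; k2 < k; ++k2)
      for (int k1 = 0; k1 < k; ++k1)
        for (int o3 = 0; o3 < no; ++o3)
          for (int o2 = 0; o2 < no; ++o2)
            for (int o1 = 0; o1 < no; ++o1) {
              const int vi = src_voxel(o1, o2, o3, k1, k2, k3, ni, s, p);
              if (vi < 0) continue;
              const int vo = o1 + no * (o2 + no * o3);
              for (int c = 0; c < Cin; ++c) {
                const int r = c + Cin * (k1 + k * (k2 + k * k3));
                double* dst = dx.colptr(c + Cin * vi);
                const double* src = dCols.colptr(r) + static_cast<size_t>(N) * vo;
                for (int nn = 0; nn < N; ++nn) dst[nn] += src[nn];
              }
            }
}

// reorder activations N x (C*Vo) -> flat (N*Vo) x C
static void to_flat(const arma::mat& y, arma::mat& Yf, int C, int Vo) {
  const int N = y.n_rows;
  Yf.set_size(static_cast<arma::uword>(N) * Vo, C);
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < Vo; ++v)
      std::memcpy(Yf.colptr(c) + static_cast<size_t>(N) * v,
                  y.colptr(c + C * v), N * sizeof(double));
}

// reorder flat (N*Vo) x C -> activations N x (C*Vo)
static void from_flat(const arma::mat& Yf, arma::mat& y, int C, int Vo) {
  const int N = Yf.n_rows / Vo;
  y.set_size(N, static_cast<arma::uword>(C) * Vo);
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < Vo; ++v)
      std::memcpy(y.colptr(c + C * v),
                  Yf.colptr(c) + static_cast<size_t>(N) * v, N * sizeof(double));
}

// [[Rcpp::export]]
arma::mat conv3d_fwd_cpp(const arma::mat& x, const arma::mat& W,
                         const arma::vec& b, int Cin, int ni, int k, int s,
                         int p) {
  const int no = out_size(ni, k, s, p);
  const int Vo = no * no * no;
  const int Cout = W.n_rows;
  arma::mat Cols;
  gather_cols(x, Cols, Cin, ni, k, s, p);
  arma::mat Yf = Cols * W.t();
  Yf.each_row() += b.t();
  arma::mat y;
  from_flat(Yf, y, Cout, Vo);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(const arma::mat& x, const arma::mat& W, const arma::mat& dy,
                    int Cin, int ni, int k, int s, int p,
                    bool need_dx = true) {
  const int no = out_size(ni, k, s, p);
  const int Vo = no * no * no;
  const int Cout = W.n_rows;
  arma::mat Cols, dYf;
  gather_cols(x, Cols, Cin, ni, k, s, p);
  to_flat(dy, dYf, Cout, Vo);
  arma::mat dW = dYf.t() * Cols;
  arma::vec db = arma::sum(dYf, 0).t();
  arma::mat dx;
  if (need_dx) {
    arma::mat dCols = dYf * W;
    dx.zeros(x.n_rows, x.n_cols);
    scatter_cols(dCols, dx, Cin, ni, k, s, p);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Transposed conv: x N x (Cin*Vi) -> y N x (Cout*Vo), Vo from
// no = (ni-1)*s - 2p + k; W: Cin x (Cout*k^3).
// The adjoint conv maps spatial size no -> ni.
// [[Rcpp::export]]
arma::mat tconv3d_fwd_cpp(const arma::mat& x, const arma::mat& W,
                          const arma::vec& b, int Cin, int ni, int k, int s,
                          int p) {
  const int k3 = k * k * k;
  const int Cout = W.n_cols / k3;
  const int no = (ni - 1) * s - 2 * p + k;
  const int Vi = ni * ni * ni;
  arma::mat Xf;
  to_flat(x, Xf, Cin, Vi);
  arma::mat M = Xf * W;                              // (N*Vi) x (Cout*k^3)
  arma::mat y(x.n_rows, static_cast<arma::uword>(Cout) * no * no * no,
              arma::fill::zeros);
  scatter_cols(M, y, Cout, no, k, s, p);
  for (int c = 0; c < Cout; ++c)
    for (int v = 0; v < no * no * no; ++v)
      y.col(c + Cout * v) += b[c];
  return y;
}

// [[Rcpp::export]]
List tconv3d_bwd_cpp(const arma::mat& x, const arma::mat& W,
                     const arma::mat& dy, int Cin, int ni, int k, int s,
                     int p) {
  const int k3 = k * k * k;
  const int Cout = W.n_cols / k3;
  const int no = (ni - 1) * s - 2 * p + k;
  const int Vi = ni * ni * ni;
  arma::mat Colsd;
  gather_cols(dy, Colsd, Cout, no, k, s, p);         // (N*Vi) x (Cout*k^3)
  arma::mat Xf;
  to_flat(x, Xf, Cin, Vi);
  arma::mat dW = Xf.t() * Colsd;
  arma::mat dXf = Colsd * W.t();
  arma::mat dx;
  from_flat(dXf, dx, Cin, Vi);
  arma::vec db(Cout, arma::fill::zeros);
  for (int c = 0; c < Cout; ++c)
    for (int v = 0; v < no * no * no; ++v)
      db[c] += arma::accu(dy.col(c + Cout * v));
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
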