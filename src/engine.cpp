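// Compact CNN engine for the dual-consistency segmentation network.
//
// Feature maps are stored as (C x H*W*N) matrices: channel index fastest,
// then pixel l = i + j*H (column-major image), then batch index n.  This
// layout is bit-compatible with an R array of dim c(C, H, W, N), so maps
// cross the R boundary without permutation.  Convolutions run as im2col +
// GEMM; the engine is templated on the element type so training runs in
// single precision while gradient checks run in double.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#include <map>
#if defined(__GLIBC__)
#include <malloc.h>
#endif

// The engine allocates and frees many multi-megabyte scratch buffers per
// call; keep them on the heap instead of round-tripping through mmap so
// repeated training steps reuse warm pages.
static const bool malloc_tuned = []() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  return true;
}();
#include <vector>
#include <string>

using namespace Rcpp;

// crude accumulating profiler for the primitives; negligible overhead at
// call granularity, dumped via cpp_prof_dump()
static std::map<std::string, double> g_prof;
struct ScopeTimer {
  arma::wall_clock c; const char* k;
  explicit ScopeTimer(const char* k_) : k(k_) { c.tic(); }
  ~ScopeTimer() { g_prof[k] += c.toc(); }
};

template <typename T> using TMat = arma::Mat<T>;
template <typename T> using TCol = arma::Col<T>;

static const double LOG_CLAMP = 1e-8;   // floor inside log() for CE and KL
static const double DICE_SMOOTH = 1e-5; // Dice smoothing constant

// ---------------------------------------------------------------------------
// conversions R <-> arma

template <typename T>
TMat<T> mat_from_r(SEXP s) {
  NumericMatrix m(s);
  TMat<T> out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

template <typename T>
TCol<T> col_from_r(SEXP s) {
  NumericVector v(s);
  TCol<T> out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

template <typename T>
NumericMatrix mat_to_r(const TMat<T>& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

template <typename T>
NumericVector col_to_r(const TCol<T>& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// feature map (C, H*W*N) -> R array dim c(C, H, W, N)
template <typename T>
NumericVector fmap_to_r(const TMat<T>& m, int C, int H, int W, int N) {
  NumericVector out(m.n_elem);
  std::copy(m.begin(), m.end(), out.begin());
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return out;
}

// ---------------------------------------------------------------------------
// layer primitives

// 3x3 convolution, pad 1, stride 1.  The input is zero-padded once into a
// (H+2) x (W+2) canvas per image; each of the nine kernel taps is then a
// single GEMM on a pointer-shifted view of the padded buffer (the padding
// absorbs all boundary reads, and writes landing in padding are discarded
// when the result is cropped back).  Weight column order: channel fastest,
// then ki (row offset), then kj (col offset): column = c + C*(ki + 3*kj).

template <typename T>
TMat<T> pad1(const TMat<T>& X, int H, int W, int N) {
  ScopeTimer st_("pad1");
  const int C = X.n_rows, Hp = H + 2, Wp = W + 2;
  TMat<T> Xp(C, (size_t)Hp * Wp * N, arma::fill::zeros);
  const T* xp = X.memptr();
  T* pp = Xp.memptr();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j)
      std::copy(xp + (size_t)C * ((size_t)n * H * W + (size_t)j * H),
                xp + (size_t)C * ((size_t)n * H * W + (size_t)(j + 1) * H),
                pp + (size_t)C * ((size_t)n * Hp * Wp + (size_t)(j + 1) * Hp + 1));
  return Xp;
}

template <typename T>
TMat<T> unpad1(const TMat<T>& Xp, int H, int W, int N) {
  ScopeTimer st_("unpad1");
  const int C = Xp.n_rows, Hp = H + 2, Wp = W + 2;
  TMat<T> X(C, (size_t)H * W * N);
  const T* pp = Xp.memptr();
  T* xp = X.memptr();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j)
      std::copy(pp + (size_t)C * ((size_t)n * Hp * Wp + (size_t)(j + 1) * Hp + 1),
                pp + (size_t)C * ((size_t)n * Hp * Wp + (size_t)(j + 1) * Hp + 1 + H),
                xp + (size_t)C * ((size_t)n * H * W + (size_t)j * H));
  return X;
}

template <typename T>
TMat<T> conv3_fwd(const TMat<T>& X, const TMat<T>& Wm, const TCol<T>& b,
                  int H, int W, int N) {
  const int C = X.n_rows, Cout = Wm.n_rows, Hp = H + 2;
  TMat<T> Xp = pad1(X, H, W, N);
  TMat<T> Yp(Cout, Xp.n_cols);
  const size_t o0 = (size_t)Hp + 1, o1 = Xp.n_cols - Hp - 1;
  const size_t L = o1 - o0;
  {
    ScopeTimer st_("conv_gemm_f");
    for (int k = 0; k < 9; ++k) {
      const int di = k % 3 - 1, dj = k / 3 - 1;
      const long off = di + (long)dj * Hp;
      TMat<T> B(const_cast<T*>(Xp.memptr()) + (long)C * ((long)o0 + off),
                C, L, false, true);
      TMat<T> Z(Yp.memptr() + (size_t)Cout * o0, Cout, L, false, true);
      const TMat<T> Wk(Wm.colptr((size_t)k * C), Cout, C);
      if (k == 0) Z = Wk * B; else Z += Wk * B;  // first tap overwrites
    }
  }
  TMat<T> Y = unpad1(Yp, H, W, N);
  Y.each_col() += b;
  return Y;
}

template <typename T>
void conv3_bwd(const TMat<T>& Gy, const TMat<T>& X, const TMat<T>& Wm,
               int H, int W, int N, TMat<T>& gW, TCol<T>& gb, TMat<T>& gX,
               bool need_gx) {
  const int C = X.n_rows, Cout = Wm.n_rows, Hp = H + 2;
  gW.set_size(Wm.n_rows, Wm.n_cols);
  gb = arma::sum(Gy, 1);
  TMat<T> Xp = pad1(X, H, W, N);
  TMat<T> Gp = pad1(Gy, H, W, N);
  TMat<T> gXp;
  if (need_gx) gXp.zeros(C, Xp.n_cols);
  const size_t o0 = (size_t)Hp + 1, o1 = Xp.n_cols - Hp - 1;
  const size_t L = o1 - o0;
  TMat<T> Gwin(Gp.memptr() + (size_t)Cout * o0, Cout, L, false, true);
  ScopeTimer st_("conv_gemm_b");
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1, dj = k / 3 - 1;
    const long off = di + (long)dj * Hp;
    TMat<T> B(const_cast<T*>(Xp.memptr()) + (long)C * ((long)o0 + off),
              C, L, false, true);
    TMat<T> gWk(gW.colptr((size_t)k * C), Cout, C, false, true);
    gWk = Gwin * B.t();
    if (need_gx) {
      TMat<T> Zx(gXp.memptr() + (long)C * ((long)o0 + off), C, L, false, true);
      const TMat<T> Wk(const_cast<T*>(Wm.colptr((size_t)k * C)), Cout, C, false, true);
      Zx += Wk.t() * Gwin;
    }
  }
  if (need_gx) gX = unpad1(gXp, H, W, N);
}

template <typename T>
void relu_inplace(TMat<T>& X) {
  ScopeTimer st_("relu");
  X.transform([](T v) { return v > T(0) ? v : T(0); });
}

// backward through relu given the *output* Y (post-relu) and upstream grad
template <typename T>
void relu_bwd_inplace(TMat<T>& G, const TMat<T>& Y) {
  ScopeTimer st_("relu_b");
  T* g = G.memptr();
  const T* y = Y.memptr();
  for (size_t q = 0; q < G.n_elem; ++q)
    if (y[q] <= T(0)) g[q] = T(0);
}

// 2x2 max pooling, stride 2 (encoder downsampling)
template <typename T>
TMat<T> maxpool2_fwd(const TMat<T>& X, int H, int W, int N) {
  ScopeTimer st_("maxpool_f");
  const int C = X.n_rows, oh = H / 2, ow = W / 2;
  TMat<T> Y(C, (size_t)oh * ow * N);
  const T* xp = X.memptr();
  T* yp = Y.memptr();
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * H * W, yb = (size_t)n * oh * ow;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const T* s00 = xp + (size_t)C * (xb + (size_t)(2 * j) * H + 2 * i);
        const T* s10 = s00 + C;                  // i+1
        const T* s01 = xp + (size_t)C * (xb + (size_t)(2 * j + 1) * H + 2 * i);
        const T* s11 = s01 + C;
        T* d = yp + (size_t)C * (yb + (size_t)j * oh + i);
        for (int c = 0; c < C; ++c)
          d[c] = std::max(std::max(s00[c], s10[c]), std::max(s01[c], s11[c]));
      }
  }
  return Y;
}

// scatter gradient to the (first, in scan order) argmax of each 2x2 window
template <typename T>
TMat<T> maxpool2_bwd(const TMat<T>& G, const TMat<T>& X, int H, int W, int N) {
  ScopeTimer st_("maxpool_b");
  const int C = X.n_rows, oh = H / 2, ow = W / 2;
  TMat<T> gX(C, X.n_cols, arma::fill::zeros);
  const T* xp = X.memptr();
  const T* gp = G.memptr();
  T* op = gX.memptr();
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * H * W, yb = (size_t)n * oh * ow;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const size_t o00 = (size_t)C * (xb + (size_t)(2 * j) * H + 2 * i);
        const size_t o10 = o00 + C;
        const size_t o01 = (size_t)C * (xb + (size_t)(2 * j + 1) * H + 2 * i);
        const size_t o11 = o01 + C;
        const size_t og = (size_t)C * (yb + (size_t)j * oh + i);
        for (int c = 0; c < C; ++c) {
          const T v00 = xp[o00 + c], v10 = xp[o10 + c],
                  v01 = xp[o01 + c], v11 = xp[o11 + c];
          const T m = std::max(std::max(v00, v10), std::max(v01, v11));
          if (v00 == m)      op[o00 + c] += gp[og + c];
          else if (v10 == m) op[o10 + c] += gp[og + c];
          else if (v01 == m) op[o01 + c] += gp[og + c];
          else               op[o11 + c] += gp[og + c];
        }
      }
  }
  return gX;
}

// k x k pooling, stride k, floor output size (MSC branches)
template <typename T>
TMat<T> pool_fwd(const TMat<T>& X, int H, int W, int N, int k, int type) {
  ScopeTimer st_("pool");
  if (k == 1) return X;
  const int C = X.n_rows, oh = H / k, ow = W / k;
  TMat<T> Y(C, (size_t)oh * ow * N, arma::fill::zeros);
  const T* xp = X.memptr();
  T* yp = Y.memptr();
  const T inv = T(1) / T(k * k);
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * H * W, yb = (size_t)n * oh * ow;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        T* d = yp + (size_t)C * (yb + (size_t)j * oh + i);
        bool first = true;
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const T* s = xp + (size_t)C * (xb + (size_t)(j * k + dj) * H + i * k + di);
            if (type == 0) {            // average
              for (int c = 0; c < C; ++c) d[c] += s[c] * inv;
            } else {                    // max
              if (first) for (int c = 0; c < C; ++c) d[c] = s[c];
              else       for (int c = 0; c < C; ++c) d[c] = std::max(d[c], s[c]);
              first = false;
            }
          }
      }
  }
  return Y;
}

template <typename T>
TMat<T> pool_bwd(const TMat<T>& G, const TMat<T>& X, int H, int W, int N,
                 int k, int type) {
  if (k == 1) return G;
  const int C = X.n_rows, oh = H / k, ow = W / k;
  TMat<T> gX(C, X.n_cols, arma::fill::zeros);
  const T* xp = X.memptr();
  const T* gp = G.memptr();
  T* op = gX.memptr();
  const T inv = T(1) / T(k * k);
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * H * W, yb = (size_t)n * oh * ow;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const size_t og = (size_t)C * (yb + (size_t)j * oh + i);
        if (type == 0) {
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di) {
              T* o = op + (size_t)C * (xb + (size_t)(j * k + dj) * H + i * k + di);
              for (int c = 0; c < C; ++c) o[c] += gp[og + c] * inv;
            }
        } else {
          for (int c = 0; c < C; ++c) {
            T m = xp[(size_t)C * (xb + (size_t)(j * k) * H + i * k) + c];
            size_t am = (size_t)C * (xb + (size_t)(j * k) * H + i * k) + c;
            for (int dj = 0; dj < k; ++dj)
              for (int di = 0; di < k; ++di) {
                const size_t o = (size_t)C * (xb + (size_t)(j * k + dj) * H + i * k + di) + c;
                if (xp[o] > m) { m = xp[o]; am = o; }
              }
            op[am] += gp[og + c];
          }
        }
      }
  }
  return gX;
}

// axis interpolation table for resize
struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> w0; // weight of i0 (1 for nearest)
};

static AxisMap make_axis(int in, int out, int mode) {
  AxisMap a;
  a.i0.resize(out); a.i1.resize(out); a.w0.resize(out);
  const double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    if (mode == 1) {                          // nearest
      int idx = (int)std::floor((o + 0.5) * scale);
      idx = std::min(std::max(idx, 0), in - 1);
      a.i0[o] = a.i1[o] = idx; a.w0[o] = 1.0;
    } else {                                  // bilinear, align_corners = FALSE
      double s = (o + 0.5) * scale - 0.5;
      if (s < 0) s = 0;
      if (s > in - 1) s = in - 1;
      int f = (int)std::floor(s);
      a.i0[o] = f;
      a.i1[o] = std::min(f + 1, in - 1);
      a.w0[o] = 1.0 - (s - f);
    }
  }
  return a;
}

template <typename T>
TMat<T> resize_fwd(const TMat<T>& X, int H, int W, int N, int oh, int ow,
                   int mode) {
  ScopeTimer st_("resize_f");
  if (oh == H && ow == W) return X;
  const int C = X.n_rows;
  AxisMap ay = make_axis(H, oh, mode), ax = make_axis(W, ow, mode);
  TMat<T> Y(C, (size_t)oh * ow * N);
  const T* xp = X.memptr();
  T* yp = Y.memptr();
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * H * W, yb = (size_t)n * oh * ow;
    for (int j = 0; j < ow; ++j) {
      const int j0 = ax.i0[j], j1 = ax.i1[j];
      const T wj0 = (T)ax.w0[j], wj1 = (T)(1.0 - ax.w0[j]);
      for (int i = 0; i < oh; ++i) {
        const int i0 = ay.i0[i], i1 = ay.i1[i];
        const T wi0 = (T)ay.w0[i], wi1 = (T)(1.0 - ay.w0[i]);
        const T* s00 = xp + (size_t)C * (xb + (size_t)j0 * H + i0);
        const T* s10 = xp + (size_t)C * (xb + (size_t)j0 * H + i1);
        const T* s01 = xp + (size_t)C * (xb + (size_t)j1 * H + i0);
        const T* s11 = xp + (size_t)C * (xb + (size_t)j1 * H + i1);
        const T a = wi0 * wj0, b = wi1 * wj0, c2 = wi0 * wj1, d2 = wi1 * wj1;
        T* d = yp + (size_t)C * (yb + (size_t)j * oh + i);
        for (int c = 0; c < C; ++c)
          d[c] = a * s00[c] + b * s10[c] + c2 * s01[c] + d2 * s11[c];
      }
    }
  }
  return Y;
}

template <typename T>
TMat<T> resize_adj(const TMat<T>& G, int H, int W, int N, int oh, int ow,
                   int mode) {
  ScopeTimer st_("resize_a");
  // adjoint of resize_fwd: G lives on (oh, ow), output on (H, W)
  if (oh == H && ow == W) return G;
  const int C = G.n_rows;
  AxisMap ay = make_axis(H, oh, mode), ax = make_axis(W, ow, mode);
  TMat<T> Y(C, (size_t)H * W * N, arma::fill::zeros);
  const T* gp = G.memptr();
  T* yp = Y.memptr();
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * H * W, yb = (size_t)n * oh * ow;
    for (int j = 0; j < ow; ++j) {
      const int j0 = ax.i0[j], j1 = ax.i1[j];
      const T wj0 = (T)ax.w0[j], wj1 = (T)(1.0 - ax.w0[j]);
      for (int i = 0; i < oh; ++i) {
        const int i0 = ay.i0[i], i1 = ay.i1[i];
        const T wi0 = (T)ay.w0[i], wi1 = (T)(1.0 - ay.w0[i]);
        const T* g = gp + (size_t)C * (yb + (size_t)j * oh + i);
        T* d00 = yp + (size_t)C * (xb + (size_t)j0 * H + i0);
        T* d10 = yp + (size_t)C * (xb + (size_t)j0 * H + i1);
        T* d01 = yp + (size_t)C * (xb + (size_t)j1 * H + i0);
        T* d11 = yp + (size_t)C * (xb + (size_t)j1 * H + i1);
        const T a = wi0 * wj0, b = wi1 * wj0, c2 = wi0 * wj1, d2 = wi1 * wj1;
        for (int c = 0; c < C; ++c) {
          d00[c] += a * g[c]; d10[c] += b * g[c];
          d01[c] += c2 * g[c]; d11[c] += d2 * g[c];
        }
      }
    }
  }
  return Y;
}

template <typename T>
void softmax_inplace(TMat<T>& Z) {
  ScopeTimer st_("softmax");
  const int K = Z.n_rows;
  T* p = Z.memptr();
  const size_t n = Z.n_cols;
  for (size_t c = 0; c < n; ++c, p += K) {
    T m = p[0];
    for (int k = 1; k < K; ++k) m = std::max(m, p[k]);
    T s = 0;
    for (int k = 0; k < K; ++k) { p[k] = std::exp(p[k] - m); s += p[k]; }
    const T inv = T(1) / s;
    for (int k = 0; k < K; ++k) p[k] *= inv;
  }
}

// grad wrt logits from grad wrt softmax output, in place
template <typename T>
void softmax_bwd_inplace(TMat<T>& G, const TMat<T>& P) {
  const int K = P.n_rows;
  T* g = G.memptr();
  const T* p = P.memptr();
  const size_t n = P.n_cols;
  for (size_t c = 0; c < n; ++c, g += K, p += K) {
    T dot = 0;
    for (int k = 0; k < K; ++k) dot += g[k] * p[k];
    for (int k = 0; k < K; ++k) g[k] = p[k] * (g[k] - dot);
  }
}

// ---------------------------------------------------------------------------
// network definition

template <typename T>
struct Params {
  std::vector<TMat<T>> enc_w; std::vector<TCol<T>> enc_b;
  TMat<T> bott_w; TCol<T> bott_b;
  std::vector<TMat<T>> dec_w; std::vector<TCol<T>> dec_b;
  std::vector<TMat<T>> head_w; std::vector<TCol<T>> head_b; // index s-1
  bool has_msc = false;
  TMat<T> fuse_w; TCol<T> fuse_b;
  TMat<T> msc_w;  TCol<T> msc_b;
  TMat<T> fine_w; TCol<T> fine_b;
  int depth = 0, S = 0;
};

template <typename T>
Params<T> parse_params(List pl) {
  Params<T> P;
  while (pl.containsElementNamed(("enc_w" + std::to_string(P.depth)).c_str()))
    ++P.depth;
  for (int d = 0; d < P.depth; ++d) {
    P.enc_w.push_back(mat_from_r<T>(pl["enc_w" + std::to_string(d)]));
    P.enc_b.push_back(col_from_r<T>(pl["enc_b" + std::to_string(d)]));
    P.dec_w.push_back(mat_from_r<T>(pl["dec_w" + std::to_string(d)]));
    P.dec_b.push_back(col_from_r<T>(pl["dec_b" + std::to_string(d)]));
  }
  P.bott_w = mat_from_r<T>(pl["bott_w"]);
  P.bott_b = col_from_r<T>(pl["bott_b"]);
  while (pl.containsElementNamed(("head_w" + std::to_string(P.S + 1)).c_str()))
    ++P.S;
  for (int s = 1; s <= P.S; ++s) {
    P.head_w.push_back(mat_from_r<T>(pl["head_w" + std::to_string(s)]));
    P.head_b.push_back(col_from_r<T>(pl["head_b" + std::to_string(s)]));
  }
  if (pl.containsElementNamed("msc_w")) {
    P.has_msc = true;
    P.fuse_w = mat_from_r<T>(pl["fuse_w"]); P.fuse_b = col_from_r<T>(pl["fuse_b"]);
    P.msc_w  = mat_from_r<T>(pl["msc_w"]);  P.msc_b  = col_from_r<T>(pl["msc_b"]);
    P.fine_w = mat_from_r<T>(pl["fine_w"]); P.fine_b = col_from_r<T>(pl["fine_b"]);
  }
  return P;
}

struct RunCfg {
  int H, W, N, K, n_labeled;
  int pool_type, upsample;
  bool use_msc, use_hc, use_cfgc, cons_all, detach_p0, train_mode;
  double dropout, lambda, beta;
  std::vector<double> alpha;     // length S+1, alpha[0] for p_0
  std::vector<int> kernels;
  unsigned int seed;
  bool want_preds, want_features, want_grads, want_pgrads;
};

static RunCfg parse_cfg(List cfg) {
  RunCfg c;
  c.H = as<int>(cfg["H"]); c.W = as<int>(cfg["W"]); c.N = as<int>(cfg["N"]);
  c.K = as<int>(cfg["K"]); c.n_labeled = as<int>(cfg["n_labeled"]);
  c.pool_type = as<int>(cfg["pool_type"]);
  c.upsample = as<int>(cfg["upsample"]);
  c.use_msc = as<bool>(cfg["use_msc"]);
  c.use_hc = as<bool>(cfg["use_hc"]);
  c.use_cfgc = as<bool>(cfg["use_cfgc"]);
  c.cons_all = as<bool>(cfg["cons_all"]);
  c.detach_p0 = as<bool>(cfg["detach_p0"]);
  c.train_mode = as<bool>(cfg["train_mode"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.lambda = as<double>(cfg["lambda"]);
  c.beta = as<double>(cfg["beta"]);
  c.alpha = as<std::vector<double>>(cfg["alpha"]);
  c.kernels = as<std::vector<int>>(cfg["kernels"]);
  c.seed = (unsigned int)as<double>(cfg["seed"]);
  c.want_preds = as<bool>(cfg["want_preds"]);
  c.want_features = as<bool>(cfg["want_features"]);
  c.want_grads = as<bool>(cfg["want_grads"]);
  c.want_pgrads = cfg.containsElementNamed("want_pgrads") ?
    as<bool>(cfg["want_pgrads"]) : false;
  return c;
}

// input R array (H, W, Cin, N) -> (Cin, H*W*N)
template <typename T>
TMat<T> image_batch(NumericVector x, int H, int W, int C, int N) {
  TMat<T> X(C, (size_t)H * W * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* s = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int l = 0; l < H * W; ++l)
        X(c, (size_t)n * H * W + l) = (T)s[l];
    }
  return X;
}

// ---------------------------------------------------------------------------
// main engine

template <typename T>
List net_run(List params_r, NumericVector x_r, Nullable<IntegerVector> y_r,
             List cfg_r) {
  arma::wall_clock prof_clock;
  const bool profile = cfg_r.containsElementNamed("profile") &&
    as<bool>(cfg_r["profile"]);
  double t_prev = 0;
  prof_clock.tic();
  auto mark = [&](const char* what) {
    if (!profile) return;
    double now = prof_clock.toc();
    Rcpp::Rcout << what << ": " << (now - t_prev) * 1000 << " ms\n";
    t_prev = now;
  };
  Params<T> P = parse_params<T>(params_r);
  RunCfg cfg = parse_cfg(cfg_r);
  mark("parse");
  const int H = cfg.H, W = cfg.W, N = cfg.N, K = cfg.K, D = P.depth, S = P.S;
  const int HW = H * W;
  const bool msc = cfg.use_msc && P.has_msc;

  TMat<T> X0 = image_batch<T>(x_r, H, W, (int)(x_r.size() / ((size_t)HW * N)), N);

  // ---- encoder
  std::vector<TMat<T>> enc(D), pooled(D);
  std::vector<int> eh(D), ew(D);
  TMat<T> cur = X0;
  int ch = H, cw = W;
  for (int d = 0; d < D; ++d) {
    eh[d] = ch; ew[d] = cw;
    enc[d] = conv3_fwd(cur, P.enc_w[d], P.enc_b[d], ch, cw, N);
    relu_inplace(enc[d]);
    pooled[d] = maxpool2_fwd(enc[d], ch, cw, N);
    ch /= 2; cw /= 2;
    cur = pooled[d];
  }
mark("encoder");
  TMat<T> bott = conv3_fwd(cur, P.bott_w, P.bott_b, ch, cw, N);
  relu_inplace(bott);

  // ---- decoder (stage j at resolution H >> j); built deepest first
  std::vector<TMat<T>> dec(D), cat(D);
  TMat<T> up;
  for (int j = D - 1; j >= 0; --j) {
    const int th = H >> j, tw = W >> j;
    const TMat<T>& prev = (j == D - 1) ? bott : dec[j + 1];
    up = resize_fwd(prev, th / 2, tw / 2, N, th, tw, cfg.upsample);
    mark("  dec resize");
    cat[j] = arma::join_cols(up, enc[j]);
    mark("  dec join");
    dec[j] = conv3_fwd(cat[j], P.dec_w[j], P.dec_b[j], th, tw, N);
    mark("  dec conv");
    relu_inplace(dec[j]);
    mark("  dec relu");
  }

mark("decoder");
  // ---- multi-level heads: p_s from decoder stage j = D - s (deepest first)
  uint64_t rs = (((uint64_t)cfg.seed + 0x9E3779B97F4A7C15ULL) << 1) | 1;
  auto next_unif = [&rs]() {
    rs ^= rs << 13; rs ^= rs >> 7; rs ^= rs << 17;
    return (double)(rs >> 11) * (1.0 / 9007199254740992.0);
  };
  const bool do_drop = cfg.train_mode && cfg.dropout > 0;
  const T keep = (T)(1.0 - cfg.dropout);

  std::vector<TMat<T>> p(S + 1), head_in(S + 1), drop_mask(S + 1);
  for (int s = 1; s <= S; ++s) {
    const int j = D - s, th = H >> j, tw = W >> j;
    TMat<T> f = dec[j];
    if (do_drop) {
      TMat<T> m(f.n_rows, f.n_cols);
      for (size_t q = 0; q < m.n_elem; ++q)
        m[q] = next_unif() < cfg.dropout ? T(0) : T(1) / keep;
      drop_mask[s] = m;
      f %= m;
    }
    head_in[s] = f;
    TMat<T> z = P.head_w[s - 1] * f;
    z.each_col() += P.head_b[s - 1];
    TMat<T> zf = resize_fwd(z, th, tw, N, H, W, cfg.upsample);
    mark("  head resize");
    softmax_inplace(zf);
    mark("  head softmax");
    p[s] = std::move(zf);
  }

mark("heads");
  // ---- fine head: fuse the (up to) three shallowest decoder stages, MSC, 1x1
  int n_fuse = std::min(3, D);
  TMat<T> fuse_cat, fuse_out, msc_cat, msc_out;
  std::vector<TMat<T>> branch_pool(cfg.kernels.size());
  if (msc) {
    if (n_fuse == 1) {
      fuse_cat = dec[0];
    } else if (n_fuse == 2) {
      fuse_cat = arma::join_cols(
        dec[0], resize_fwd(dec[1], H >> 1, W >> 1, N, H, W, cfg.upsample));
    } else {
      fuse_cat = arma::join_cols(
        dec[0],
        resize_fwd(dec[1], H >> 1, W >> 1, N, H, W, cfg.upsample),
        resize_fwd(dec[2], H >> 2, W >> 2, N, H, W, cfg.upsample));
    }
    mark("  msc fusecat");
    fuse_out = P.fuse_w * fuse_cat;
    fuse_out.each_col() += P.fuse_b;
    relu_inplace(fuse_out);
    mark("  msc fuse1x1");
    {
      const int fc = fuse_out.n_rows;
      msc_cat.set_size(fc * cfg.kernels.size(), fuse_out.n_cols);
      for (size_t b = 0; b < cfg.kernels.size(); ++b) {
        const int k = cfg.kernels[b];
        branch_pool[b] = pool_fwd(fuse_out, H, W, N, k, cfg.pool_type);
        msc_cat.rows((size_t)b * fc, (size_t)(b + 1) * fc - 1) =
          resize_fwd(branch_pool[b], H / k, W / k, N, H, W, cfg.upsample);
      }
    }
    mark("  msc branches");
    msc_out = conv3_fwd(msc_cat, P.msc_w, P.msc_b, H, W, N);
    mark("  msc conv");
    relu_inplace(msc_out);
    TMat<T> z0 = P.fine_w * msc_out;
    z0.each_col() += P.fine_b;
    softmax_inplace(z0);
    p[0] = std::move(z0);
  }

mark("msc");
  List out;
  if (cfg.want_preds) {
    List preds(msc ? S + 1 : S);
    CharacterVector nm(msc ? S + 1 : S);
    int idx = 0;
    if (msc) { preds[idx] = fmap_to_r(p[0], K, H, W, N); nm[idx++] = "p0"; }
    for (int s = 1; s <= S; ++s) {
      preds[idx] = fmap_to_r(p[s], K, H, W, N);
      nm[idx++] = "p" + std::to_string(s);
    }
    preds.attr("names") = nm;
    out["preds"] = preds;
  }
  if (cfg.want_features) {
    List feats(D);
    for (int j = 0; j < D; ++j)
      feats[j] = fmap_to_r(dec[j], dec[j].n_rows, H >> j, W >> j, N);
    out["decoder_features"] = feats;
    if (msc) {
      out["fused"] = fmap_to_r(fuse_out, fuse_out.n_rows, H, W, N);
      out["msc_out"] = fmap_to_r(msc_out, msc_out.n_rows, H, W, N);
    }
  }

mark("outputs");
  // ------------------------------------------------------------------
  // losses
  const int Nl = cfg.n_labeled;
  const size_t Ll = (size_t)Nl * HW;
  const int u_start_img = cfg.cons_all ? 0 : Nl;
  const int Nu = N - u_start_img;
  const size_t u0 = (size_t)u_start_img * HW;

  double l_ce = 0, l_dice = 0, l_sup = 0, l_hc = 0, l_urc = 0, l_cr = 0;
  std::vector<TMat<T>> G(S + 1);   // grads wrt probability maps
  const bool wg = cfg.want_grads;
  if (wg) for (int s = 0; s <= S; ++s)
    if (s > 0 || msc) G[s].zeros(K, (size_t)HW * N);

  const int s_lo = msc ? 0 : 1;

  // supervised: 0.5*CE + 0.5*Dice per level, weighted by alpha
  if (Nl > 0 && y_r.isNotNull()) {
    IntegerVector y(y_r);
    for (int s = s_lo; s <= S; ++s) {
      const double a = cfg.alpha[s];
      if (a == 0) continue;
      const TMat<T>& ps = p[s];
      double ce = 0;
      // cross-entropy, mean over labeled pixels
      for (size_t q = 0; q < Ll; ++q) {
        const int yc = y[q];
        const double pv = std::max((double)ps(yc, q), LOG_CLAMP);
        ce -= std::log(pv);
        if (wg) G[s](yc, q) -= (T)(a * 0.5 / (pv * (double)Ll));
      }
      ce /= (double)Ll;
      // Dice, per image / per class, then averaged
      double dice = 0;
      for (int n = 0; n < Nl; ++n) {
        const size_t b0 = (size_t)n * HW;
        for (int c = 0; c < K; ++c) {
          double sp = 0, sy = 0, spy = 0;
          for (int l = 0; l < HW; ++l) {
            const double pv = ps(c, b0 + l);
            const int yv = (y[b0 + l] == c);
            sp += pv; sy += yv; spy += pv * yv;
          }
          const double den = sp + sy + DICE_SMOOTH;
          const double num = 2.0 * spy + DICE_SMOOTH;
          dice += 1.0 - num / den;
          if (wg) {
            const double sc = a * 0.5 / ((double)K * Nl);
            for (int l = 0; l < HW; ++l) {
              const int yv = (y[b0 + l] == c);
              const double d = -(2.0 * yv * den - num) / (den * den);
              G[s](c, b0 + l) += (T)(sc * d);
            }
          }
        }
      }
      dice /= (double)(K * Nl);
      l_sup += a * (0.5 * ce + 0.5 * dice);
      if (s == s_lo) { l_ce = ce; l_dice = dice; } // finest level, for logging
    }
  }

  // consistency terms on the unlabeled scope
  if (Nu > 0 && S >= 2 && (cfg.use_hc || cfg.use_cfgc)) {
    const size_t Un = (size_t)Nu * HW;
    TMat<T> pavg(K, Un, arma::fill::zeros);
    for (int s = 1; s <= S; ++s) pavg += p[s].cols(u0, u0 + Un - 1);
    pavg /= (T)S;

    if (cfg.use_hc) {
      std::vector<double> wpix(HW);
      for (int s = 1; s <= S; ++s) {
        const T* ps = p[s].memptr() + (size_t)K * u0;
        const T* pa = pavg.memptr();
        // per-pixel channel-summed squared difference and KL weight
        for (int n = 0; n < Nu; ++n) {
          double hc_img = 0, num = 0, den = 0;
          const size_t b0 = (size_t)n * HW;
          for (int l = 0; l < HW; ++l) {
            const T* pc = ps + (size_t)K * (b0 + l);
            const T* qc = pa + (size_t)K * (b0 + l);
            double m = 0, dkl = 0;
            for (int c = 0; c < K; ++c) {
              const double dv = (double)pc[c] - (double)qc[c];
              m += dv * dv;
              const double pv = std::max((double)pc[c], LOG_CLAMP);
              const double qv = std::max((double)qc[c], LOG_CLAMP);
              dkl += (double)pc[c] * std::log(pv / qv);
            }
            const double wv = std::exp(-dkl);
            wpix[l] = wv;
            hc_img += m; num += wv * m; den += wv;
          }
          l_hc += hc_img / HW / (double)(S * Nu);
          l_urc += (num / den) / (double)(S * Nu);
          if (wg && cfg.lambda > 0 && cfg.beta > 0) {
            // d L_urc / d p_s, with p_avg and w treated as constants
            const double sc = cfg.lambda * cfg.beta / (double)(S * Nu);
            T* gs = G[s].memptr() + (size_t)K * u0;
            for (int l = 0; l < HW; ++l) {
              const double f = sc * 2.0 * wpix[l] / den;
              const T* pc = ps + (size_t)K * (b0 + l);
              const T* qc = pa + (size_t)K * (b0 + l);
              T* gc = gs + (size_t)K * (b0 + l);
              for (int c = 0; c < K; ++c)
                gc[c] += (T)(f * ((double)pc[c] - (double)qc[c]));
            }
          }
        }
      }
    }

    if (cfg.use_cfgc && msc) {
      const TMat<T> diff = p[1].cols(u0, u0 + Un - 1) - p[0].cols(u0, u0 + Un - 1);
      double acc = 0;
      for (size_t q = 0; q < diff.n_elem; ++q) acc += (double)diff[q] * diff[q];
      l_cr = acc / (double)(HW * Nu);   // channel-sum, pixel-mean
      if (wg && cfg.lambda > 0 && cfg.beta < 1) {
        const double sc = cfg.lambda * (1.0 - cfg.beta) * 2.0 / (double)(HW * Nu);
        for (size_t q = 0; q < Un; ++q)
          for (int c = 0; c < K; ++c) {
            G[1](c, u0 + q) += (T)(sc * diff(c, q));
            if (!cfg.detach_p0) G[0](c, u0 + q) -= (T)(sc * diff(c, q));
          }
      }
    }
  }

  out["l_sup"] = l_sup; out["l_ce"] = l_ce; out["l_dice"] = l_dice;
  out["l_hc"] = l_hc; out["l_urc"] = l_urc; out["l_cr"] = l_cr;

mark("losses");
  if (!wg) return out;

  if (cfg.want_pgrads) {
    // gradients wrt the probability maps, before softmax backprop --
    // lets tests verify the loss-gradient formulas independently
    List pg(S + 1 - s_lo);
    CharacterVector nm(S + 1 - s_lo);
    int idx = 0;
    for (int s = s_lo; s <= S; ++s) {
      pg[idx] = fmap_to_r(G[s], K, H, W, N);
      nm[idx++] = "p" + std::to_string(s);
    }
    pg.attr("names") = nm;
    out["pmap_grads"] = pg;
  }

  // ------------------------------------------------------------------
  // backward
  std::vector<TMat<T>> gdec(D);
  for (int j = 0; j < D; ++j)
    gdec[j].zeros(dec[j].n_rows, dec[j].n_cols);

  List grads;

  // heads
  mark("  bwd pre");
  for (int s = 1; s <= S; ++s) {
    const int j = D - s, th = H >> j, tw = W >> j;
    softmax_bwd_inplace(G[s], p[s]);
    mark("  bwd head softmax");
    TMat<T> gz = resize_adj(G[s], th, tw, N, H, W, cfg.upsample);
    mark("  bwd head resizeadj");
    TMat<T> gW = gz * head_in[s].t();
    TCol<T> gb = arma::sum(gz, 1);
    TMat<T> gf = P.head_w[s - 1].t() * gz;
    if (do_drop) gf %= drop_mask[s];
    gdec[j] += gf;
    grads["head_w" + std::to_string(s)] = mat_to_r(gW);
    grads["head_b" + std::to_string(s)] = col_to_r(gb);
  }

  // fine head
  if (msc) {
    softmax_bwd_inplace(G[0], p[0]);
    TMat<T> gW = G[0] * msc_out.t();
    TCol<T> gb = arma::sum(G[0], 1);
    grads["fine_w"] = mat_to_r(gW);
    grads["fine_b"] = col_to_r(gb);
    TMat<T> gm = P.fine_w.t() * G[0];
    relu_bwd_inplace(gm, msc_out);
    TMat<T> gmw, gmx; TCol<T> gmb;
    conv3_bwd(gm, msc_cat, P.msc_w, H, W, N, gmw, gmb, gmx, true);
    grads["msc_w"] = mat_to_r(gmw);
    grads["msc_b"] = col_to_r(gmb);
    const int fc = fuse_out.n_rows;
    TMat<T> gfuse_out(fc, fuse_out.n_cols, arma::fill::zeros);
    for (size_t b = 0; b < cfg.kernels.size(); ++b) {
      const int k = cfg.kernels[b];
      TMat<T> gub = gmx.rows(b * fc, (b + 1) * fc - 1);
      TMat<T> gpb = resize_adj(gub, H / k, W / k, N, H, W, cfg.upsample);
      gfuse_out += pool_bwd(gpb, fuse_out, H, W, N, k, cfg.pool_type);
    }
    relu_bwd_inplace(gfuse_out, fuse_out);
    grads["fuse_w"] = mat_to_r(TMat<T>(gfuse_out * fuse_cat.t()));
    grads["fuse_b"] = col_to_r(TCol<T>(arma::sum(gfuse_out, 1)));
    TMat<T> gcatf = P.fuse_w.t() * gfuse_out;
    int row = 0;
    for (int j = 0; j < n_fuse; ++j) {
      const int cj = dec[j].n_rows;
      TMat<T> gj = gcatf.rows(row, row + cj - 1);
      row += cj;
      gdec[j] += resize_adj(gj, H >> j, W >> j, N, H, W, cfg.upsample);
    }
  }

mark("bwd_heads_msc");
  // decoder chain, shallowest to deepest
  TMat<T> gbott;
  for (int j = 0; j < D; ++j) {
    const int th = H >> j, tw = W >> j;
    TMat<T> g = gdec[j];
    relu_bwd_inplace(g, dec[j]);
    TMat<T> gW, gcat; TCol<T> gb;
    conv3_bwd(g, cat[j], P.dec_w[j], th, tw, N, gW, gb, gcat, true);
    grads["dec_w" + std::to_string(j)] = mat_to_r(gW);
    grads["dec_b" + std::to_string(j)] = col_to_r(gb);
    const int cprev = (j == D - 1) ? (int)bott.n_rows : (int)dec[j + 1].n_rows;
    TMat<T> gup = gcat.rows(0, cprev - 1);
    TMat<T> gskip = gcat.rows(cprev, gcat.n_rows - 1);
    TMat<T> gprev = resize_adj(gup, th / 2, tw / 2, N, th, tw, cfg.upsample);
    if (j == D - 1) gbott = gprev; else gdec[j + 1] += gprev;
    gdec[j] = std::move(gskip);  // reuse slot: now holds grad into enc[j]
  }

mark("bwd_decoder");
  // bottleneck
  relu_bwd_inplace(gbott, bott);
  {
    const int bh = H >> D, bw = W >> D;
    TMat<T> gW, gX; TCol<T> gb;
    conv3_bwd(gbott, pooled[D - 1], P.bott_w, bh, bw, N, gW, gb, gX, true);
    grads["bott_w"] = mat_to_r(gW);
    grads["bott_b"] = col_to_r(gb);
    gbott = std::move(gX);  // grad wrt pooled[D-1]
  }

  // encoder chain, deepest to shallowest
  TMat<T> gpool = gbott;
  for (int d = D - 1; d >= 0; --d) {
    TMat<T> ge = maxpool2_bwd(gpool, enc[d], eh[d], ew[d], N);
    ge += gdec[d];                    // skip-connection gradient
    relu_bwd_inplace(ge, enc[d]);
    const TMat<T>& input = (d == 0) ? X0 : pooled[d - 1];
    TMat<T> gW, gX; TCol<T> gb;
    conv3_bwd(ge, input, P.enc_w[d], eh[d], ew[d], N, gW, gb, gX, d > 0);
    grads["enc_w" + std::to_string(d)] = mat_to_r(gW);
    grads["enc_b" + std::to_string(d)] = col_to_r(gb);
    if (d > 0) gpool = std::move(gX);
  }

mark("bwd_encoder");
  out["grads"] = grads;
  return out;
}

// [[Rcpp::export]]
List cpp_net_run(List params, NumericVector x, Nullable<IntegerVector> y,
                 List cfg, std::string precision = "float") {
  if (precision == "double") return net_run<double>(params, x, y, cfg);
  return net_run<float>(params, x, y, cfg);
}

// ---------------------------------------------------------------------------
// standalone primitives (double precision, (H, W, C) arrays) used by the
// R-level msc_forward / fine_head compositions and their tests

static arma::mat array_to_fmap(NumericVector x, int& H, int& W, int& C) {
  IntegerVector dim = x.attr("dim");
  H = dim[0]; W = dim[1]; C = dim.size() > 2 ? dim[2] : 1;
  arma::mat X(C, (size_t)H * W);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < H * W; ++l)
      X(c, l) = x[l + (size_t)H * W * c];
  return X;
}

static NumericVector fmap_to_array(const arma::mat& X, int H, int W) {
  const int C = X.n_rows;
  NumericVector out((size_t)H * W * C);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < H * W; ++l)
      out[l + (size_t)H * W * c] = X(c, l);
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_3x3(NumericVector x, NumericMatrix w, NumericVector b) {
  int H, W, C;
  arma::mat X = array_to_fmap(x, H, W, C);
  arma::mat Wm = mat_from_r<double>(w);
  arma::vec bv = col_from_r<double>(b);
  arma::mat Y = conv3_fwd(X, Wm, bv, H, W, 1);
  return fmap_to_array(Y, H, W);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_1x1(NumericVector x, NumericMatrix w, NumericVector b) {
  int H, W, C;
  arma::mat X = array_to_fmap(x, H, W, C);
  arma::mat Y = mat_from_r<double>(w) * X;
  Y.each_col() += col_from_r<double>(b);
  return fmap_to_array(Y, H, W);
}

// [[Rcpp::export]]
NumericVector cpp_pool2d(NumericVector x, int k, std::string type = "avg") {
  int H, W, C;
  arma::mat X = array_to_fmap(x, H, W, C);
  arma::mat Y = pool_fwd(X, H, W, 1, k, type == "avg" ? 0 : 1);
  return fmap_to_array(Y, H / k, W / k);
}

// [[Rcpp::export]]
NumericVector cpp_resize2d(NumericVector x, int oh, int ow,
                           std::string mode = "bilinear") {
  int H, W, C;
  arma::mat X = array_to_fmap(x, H, W, C);
  arma::mat Y = resize_fwd(X, H, W, 1, oh, ow, mode == "bilinear" ? 0 : 1);
  return fmap_to_array(Y, oh, ow);
}

// [[Rcpp::export]]
NumericVector cpp_softmax_channels(NumericVector x) {
  int H, W, C;
  arma::mat X = array_to_fmap(x, H, W, C);
  softmax_inplace(X);
  return fmap_to_array(X, H, W);
}


// [[Rcpp::export]]
List cpp_prof_dump(bool reset = true) {
  List out;
  for (auto& kv : g_prof) out[kv.first] = kv.second;
  if (reset) g_prof.clear();
  return out;
}
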