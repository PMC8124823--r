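// Desk-scale convolutional feature extractor: three 3x3 conv blocks
// (8/16/32 channels) with 2x2 max-pooling and rectification, global average
// pooling, a 64-unit fully connected feature layer and a 2-unit softmax
// head. Trained with Adam on CPU; all loops are deterministic given the
// initial weights and the epoch permutations supplied from R.
//
// The im2col matrix is kept pixel-major (npix x 9C) so that filling,
// convolution (one GEMM per layer) and the col2im scatter all touch
// contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// colT(p, r) = in(i + dy, j + dx, c) with r = (c, dx, dy) and p the
// column-major pixel index of the (H-2) x (W-2) output.
static void im2colT(const cube& in, mat& colT) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = H - 2, Wo = W - 2;
  colT.set_size((uword)Ho * Wo, 9 * C);
  uword r = 0;
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy) {
        double* dst = colT.colptr(r++);
        for (int j = 0; j < Wo; ++j) {
          const double* src = in.slice_colptr(c, j + dx) + dy;
          std::memcpy(dst + (size_t)j * Ho, src, Ho * sizeof(double));
        }
      }
}

static void col2imT(const mat& dcolT, cube& out) {
  const int H = out.n_rows, W = out.n_cols, C = out.n_slices;
  const int Ho = H - 2, Wo = W - 2;
  out.zeros();
  uword r = 0;
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy) {
        const double* src = dcolT.colptr(r++);
        for (int j = 0; j < Wo; ++j) {
          double* dst = out.slice_colptr(c, j + dx) + dy;
          const double* s = src + (size_t)j * Ho;
          for (int i = 0; i < Ho; ++i) dst[i] += s[i];
        }
      }
}

// Z cube aliases are filled through a (npix x K) matrix view of the cube
// memory: one slice per output channel, contiguous.
static void conv_fwd(const cube& in, const mat& Wm, const vec& b, mat& colT,
                     cube& out) {
  const int Ho = in.n_rows - 2, Wo = in.n_cols - 2, K = Wm.n_rows;
  im2colT(in, colT);
  out.set_size(Ho, Wo, K);
  mat Zv(out.memptr(), (uword)Ho * Wo, K, false, true);
  Zv = colT * Wm.t();
  Zv.each_row() += b.t();
}

static void pool_fwd(const cube& in, cube& out, ucube& argmax) {
  const int Ho = in.n_rows / 2, Wo = in.n_cols / 2, K = in.n_slices;
  out.set_size(Ho, Wo, K);
  argmax.set_size(Ho, Wo, K);
  for (int k = 0; k < K; ++k) {
    const mat& sl = in.slice(k);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const uword rr = 2 * i + di, cc = 2 * j + dj;
            const double v = sl(rr, cc);
            if (v > best) { best = v; bi = rr + cc * in.n_rows; }
          }
        out(i, j, k) = best;
        argmax(i, j, k) = bi;
      }
  }
}

static void pool_bwd(const cube& d, const ucube& argmax, cube& out) {
  out.zeros();
  for (uword k = 0; k < d.n_slices; ++k)
    for (uword j = 0; j < d.n_cols; ++j)
      for (uword i = 0; i < d.n_rows; ++i)
        out.slice(k)(argmax(i, j, k)) += d(i, j, k);
}

struct Weights {
  mat W1, W2, W3, Wf1, Wf2;
  vec b1, b2, b3, bf1, bf2;
};

static Weights unpack(const Rcpp::List& w) {
  Weights out;
  out.W1 = Rcpp::as<mat>(w["W1"]);   out.b1 = Rcpp::as<vec>(w["b1"]);
  out.W2 = Rcpp::as<mat>(w["W2"]);   out.b2 = Rcpp::as<vec>(w["b2"]);
  out.W3 = Rcpp::as<mat>(w["W3"]);   out.b3 = Rcpp::as<vec>(w["b3"]);
  out.Wf1 = Rcpp::as<mat>(w["Wf1"]); out.bf1 = Rcpp::as<vec>(w["bf1"]);
  out.Wf2 = Rcpp::as<mat>(w["Wf2"]); out.bf2 = Rcpp::as<vec>(w["bf2"]);
  return out;
}

// Activations are reused across samples to avoid reallocation.
struct Acts {
  mat col1, col2, col3;
  cube Z1, Z2, Z3;          // conv outputs (reused for their gradients)
  cube P1, P2, P3;          // pooled, pre-rectifier
  cube R1, R2, R3;          // rectified
  ucube a1, a2, a3;
  vec g, u, h, p;
  mat dcol2, dcol3;
};

static void forward(const cube& x, const Weights& w, Acts& A) {
  conv_fwd(x, w.W1, w.b1, A.col1, A.Z1);
  pool_fwd(A.Z1, A.P1, A.a1);
  A.R1 = clamp(A.P1, 0.0, datum::inf);
  conv_fwd(A.R1, w.W2, w.b2, A.col2, A.Z2);
  pool_fwd(A.Z2, A.P2, A.a2);
  A.R2 = clamp(A.P2, 0.0, datum::inf);
  conv_fwd(A.R2, w.W3, w.b3, A.col3, A.Z3);
  pool_fwd(A.Z3, A.P3, A.a3);
  A.R3 = clamp(A.P3, 0.0, datum::inf);
  A.g.set_size(A.R3.n_slices);
  for (uword k = 0; k < A.R3.n_slices; ++k)
    A.g(k) = accu(A.R3.slice(k)) / A.R3.slice(k).n_elem;
  A.u = w.Wf1 * A.g + w.bf1;
  A.h = clamp(A.u, 0.0, datum::inf);
  vec z = w.Wf2 * A.h + w.bf2;
  vec zs = z - z.max();
  A.p = exp(zs) / accu(exp(zs));
}

static void backward(const Weights& w, Acts& A, int y, Weights& g) {
  vec dz = A.p;
  dz(y) -= 1.0;
  g.Wf2 += dz * A.h.t();
  g.bf2 += dz;
  vec dh = w.Wf2.t() * dz;
  vec du = dh % conv_to<vec>::from(A.u > 0);
  g.Wf1 += du * A.g.t();
  g.bf1 += du;
  vec dg = w.Wf1.t() * du;
  // GAP spread + rectifier mask, layer 3
  cube dR3(size(A.R3));
  for (uword k = 0; k < dR3.n_slices; ++k) {
    const double v = dg(k) / A.R3.slice(k).n_elem;
    dR3.slice(k) = v * conv_to<mat>::from(A.P3.slice(k) > 0);
  }
  pool_bwd(dR3, A.a3, A.Z3);                      // dZ3 into Z3 storage
  {
    mat dZv(A.Z3.memptr(), A.Z3.n_rows * A.Z3.n_cols, A.Z3.n_slices,
            false, true);
    g.W3 += dZv.t() * A.col3;
    g.b3 += sum(dZv, 0).t();
    A.dcol3 = dZv * w.W3;                         // npix x 9C
  }
  cube dR2(size(A.R2));
  col2imT(A.dcol3, dR2);
  for (uword k = 0; k < dR2.n_slices; ++k)
    dR2.slice(k) %= conv_to<mat>::from(A.P2.slice(k) > 0);
  pool_bwd(dR2, A.a2, A.Z2);
  {
    mat dZv(A.Z2.memptr(), A.Z2.n_rows * A.Z2.n_cols, A.Z2.n_slices,
            false, true);
    g.W2 += dZv.t() * A.col2;
    g.b2 += sum(dZv, 0).t();
    A.dcol2 = dZv * w.W2;
  }
  cube dR1(size(A.R1));
  col2imT(A.dcol2, dR1);
  for (uword k = 0; k < dR1.n_slices; ++k)
    dR1.slice(k) %= conv_to<mat>::from(A.P1.slice(k) > 0);
  pool_bwd(dR1, A.a1, A.Z1);
  {
    mat dZv(A.Z1.memptr(), A.Z1.n_rows * A.Z1.n_cols, A.Z1.n_slices,
            false, true);
    g.W1 += dZv.t() * A.col1;
    g.b1 += sum(dZv, 0).t();
  }
}

struct AdamState {
  Weights m, v;
  long t = 0;
};

static Weights zero_like(const Weights& w) {
  Weights g;
  g.W1 = zeros(size(w.W1)); g.b1 = zeros<vec>(w.b1.n_elem);
  g.W2 = zeros(size(w.W2)); g.b2 = zeros<vec>(w.b2.n_elem);
  g.W3 = zeros(size(w.W3)); g.b3 = zeros<vec>(w.b3.n_elem);
  g.Wf1 = zeros(size(w.Wf1)); g.bf1 = zeros<vec>(w.bf1.n_elem);
  g.Wf2 = zeros(size(w.Wf2)); g.bf2 = zeros<vec>(w.bf2.n_elem);
  return g;
}

template <class T>
static void adam_one(T& w, const T& g, T& m, T& v, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  T mh = m / (1 - std::pow(b1, (double)t));
  T vh = v / (1 - std::pow(b2, (double)t));
  w -= lr * mh / (sqrt(vh) + eps);
}

static void adam_step(Weights& w, const Weights& g, AdamState& st,
                      double lr) {
  ++st.t;
  adam_one(w.W1, g.W1, st.m.W1, st.v.W1, lr, st.t);
  adam_one(w.W2, g.W2, st.m.W2, st.v.W2, lr, st.t);
  adam_one(w.W3, g.W3, st.m.W3, st.v.W3, lr, st.t);
  adam_one(w.Wf1, g.Wf1, st.m.Wf1, st.v.Wf1, lr, st.t);
  adam_one(w.Wf2, g.Wf2, st.m.Wf2, st.v.Wf2, lr, st.t);
  adam_one(w.b1, g.b1, st.m.b1, st.v.b1, lr, st.t);
  adam_one(w.b2, g.b2, st.m.b2, st.v.b2, lr, st.t);
  adam_one(w.b3, g.b3, st.m.b3, st.v.b3, lr, st.t);
  adam_one(w.bf1, g.bf1, st.m.bf1, st.v.bf1, lr, st.t);
  adam_one(w.bf2, g.bf2, st.m.bf2, st.v.bf2, lr, st.t);
}

static void scale_grads(Weights& g, double s) {
  g.W1 *= s; g.b1 *= s; g.W2 *= s; g.b2 *= s; g.W3 *= s; g.b3 *= s;
  g.Wf1 *= s; g.bf1 *= s; g.Wf2 *= s; g.bf2 *= s;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericVector x4d, Rcpp::IntegerVector y01,
                         Rcpp::List weights, Rcpp::IntegerMatrix perms,
                         double lr, int batch) {
  Rcpp::IntegerVector dims = x4d.attr("dim");
  if (dims.size() != 4 || dims[2] != 3)
    Rcpp::stop("expected an (h, w, 3, n) image stack");
  const int H = dims[0], W = dims[1], N = dims[3];
  if ((int)y01.size() != N) Rcpp::stop("labels do not match the stack");
  if (perms.nrow() != N) Rcpp::stop("permutation matrix does not match n");
  Weights w = unpack(weights);
  AdamState st;
  st.m = zero_like(w);
  st.v = zero_like(w);
  const int epochs = perms.ncol();
  vec loss(epochs, fill::zeros);
  const size_t imsz = (size_t)H * W * 3;
  Acts A;
  for (int e = 0; e < epochs; ++e) {
    double total = 0.0;
    for (int start = 0; start < N; start += batch) {
      const int stop = std::min(start + batch, N);
      Weights g = zero_like(w);
      for (int s = start; s < stop; ++s) {
        const int i = perms(s, e) - 1;
        const cube x(const_cast<double*>(x4d.begin()) + imsz * i,
                     H, W, 3, false, true);
        forward(x, w, A);
        const int y = y01[i];
        total += -std::log(std::max(A.p(y), 1e-12));
        backward(w, A, y, g);
      }
      scale_grads(g, 1.0 / (stop - start));
      adam_step(w, g, st, lr);
    }
    loss(e) = total / N;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = Rcpp::List::create(
      Rcpp::Named("W1") = w.W1, Rcpp::Named("b1") = w.b1,
      Rcpp::Named("W2") = w.W2, Rcpp::Named("b2") = w.b2,
      Rcpp::Named("W3") = w.W3, Rcpp::Named("b3") = w.b3,
      Rcpp::Named("Wf1") = w.Wf1, Rcpp::Named("bf1") = w.bf1,
      Rcpp::Named("Wf2") = w.Wf2, Rcpp::Named("bf2") = w.bf2),
    Rcpp::Named("loss") = loss);
}

// [[Rcpp::export]]
arma::mat cnn_features_cpp(Rcpp::NumericVector x4d, Rcpp::List weights) {
  Rcpp::IntegerVector dims = x4d.attr("dim");
  if (dims.size() != 4 || dims[2] != 3)
    Rcpp::stop("expected an (h, w, 3, n) image stack");
  const int H = dims[0], W = dims[1], N = dims[3];
  Weights w = unpack(weights);
  const size_t imsz = (size_t)H * W * 3;
  mat out(N, w.Wf1.n_rows);
  Acts A;
  for (int i = 0; i < N; ++i) {
    const cube x(const_cast<double*>(x4d.begin()) + imsz * i,
                 H, W, 3, false, true);
    forward(x, w, A);
    out.row(i) = A.h.t();
  }
  return out;
}
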