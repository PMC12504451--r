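// Compact 2-D CNN engine: four (conv -> ReLU -> max-pool -> dropout)
// blocks, flatten, dropout, dense ReLU, dense sigmoid.  Convolutions use
// 'same' padding and are evaluated as im2col + GEMM over the whole batch;
// the backward pass mirrors the forward exactly.
//
// Activation layout: a feature map of C channels over an H x W grid for a
// batch of N images is a (C x H*W*N) matrix with element
// (c, n*H*W + w*H + h).  Flattening uses index c*H*W + w*H + h per image.
// Weight layout: conv weights are (F x kh*kw*C) with column index
// c*kh*kw + dy*kw + dx; dense weights are (units x fan_in).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// portable uniform in [0, 1) from a 32-bit Mersenne twister
inline double unif01(std::mt19937& gen) {
  return gen() * (1.0 / 4294967296.0);
}

struct ConvShape {
  int H, W, C, kh, kw, F, ph, pw;   // ph/pw: pool sizes
  int Hp, Wp;                       // post-pool dims
};

// Gather the im2col matrix (K x H*W*N) for one conv layer.
arma::mat im2col(const arma::mat& A, int H, int W, int C, int kh, int kw,
                 int N) {
  const int HW = H * W;
  const int K = kh * kw * C;
  const int pad_h = (kh - 1) / 2;
  const int pad_w = (kw - 1) / 2;
  arma::mat cols(K, (size_t)HW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * HW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t out = base + (size_t)w * H + h;
        for (int dy = 0; dy < kh; ++dy) {
          const int hh = h + dy - pad_h;
          if (hh < 0 || hh >= H) continue;
          for (int dx = 0; dx < kw; ++dx) {
            const int ww = w + dx - pad_w;
            if (ww < 0 || ww >= W) continue;
            const size_t in = base + (size_t)ww * H + hh;
            for (int c = 0; c < C; ++c)
              cols((size_t)c * kh * kw + dy * kw + dx, out) = A(c, in);
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add the adjoint of im2col back onto the input activations.
void col2im(const arma::mat& dcols, arma::mat& dA, int H, int W, int C,
            int kh, int kw, int N) {
  const int HW = H * W;
  const int pad_h = (kh - 1) / 2;
  const int pad_w = (kw - 1) / 2;
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * HW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t out = base + (size_t)w * H + h;
        for (int dy = 0; dy < kh; ++dy) {
          const int hh = h + dy - pad_h;
          if (hh < 0 || hh >= H) continue;
          for (int dx = 0; dx < kw; ++dx) {
            const int ww = w + dx - pad_w;
            if (ww < 0 || ww >= W) continue;
            const size_t in = base + (size_t)ww * H + hh;
            for (int c = 0; c < C; ++c)
              dA(c, in) += dcols((size_t)c * kh * kw + dy * kw + dx, out);
          }
        }
      }
    }
  }
}

// Max-pool over ReLU-ed activations (F x H*W*N) -> (F x Hp*Wp*N).
// Records the argmax column of the input for each pooled element, or the
// sentinel value A.n_cols when the pooled maximum is <= 0 (then the ReLU
// derivative is zero at the argmax, so no gradient flows back through
// that window and the backward pass can skip it entirely).
void maxpool(const arma::mat& A, int H, int W, int ph, int pw, int N,
             arma::mat& P, arma::umat& M) {
  const int F = A.n_rows;
  const int Hp = H / ph, Wp = W / pw;
  const int HW = H * W, HWp = Hp * Wp;
  const size_t sentinel = A.n_cols;
  P.set_size(F, (size_t)HWp * N);
  M.set_size(F, (size_t)HWp * N);
  for (int n = 0; n < N; ++n) {
    for (int wp = 0; wp < Wp; ++wp) {
      for (int hp = 0; hp < Hp; ++hp) {
        const size_t out = (size_t)n * HWp + (size_t)wp * Hp + hp;
        for (int f = 0; f < F; ++f) {
          double best = -std::numeric_limits<double>::infinity();
          size_t best_col = 0;
          for (int dx = 0; dx < pw; ++dx) {
            for (int dy = 0; dy < ph; ++dy) {
              const size_t in = (size_t)n * HW +
                (size_t)(wp * pw + dx) * H + (hp * ph + dy);
              const double v = A(f, in);
              if (v > best) { best = v; best_col = in; }
            }
          }
          P(f, out) = best;
          M(f, out) = best > 0 ? best_col : sentinel;
        }
      }
    }
  }
}

}  // namespace

// Forward (and optionally backward) pass over one batch.
//
// weights: W1,b1,...,W4,b4,Wd,bd,Wo,bo.  arch: H, W, kh, kw, pool_h,
// pool_w, filters, dense_units, dropout (5 rates).  X: H x W x N cube.
// y: 0/1 labels (1 = normal) or NULL for inference.  train: apply
// dropout (seeded, portable RNG).  want_grads: return gradients.
// [[Rcpp::export(name = ".cnn_run")]]
List cnn_run(const List& weights, const List& arch, const arma::cube& X,
             Nullable<NumericVector> y_, bool train, int seed,
             bool want_grads) {
  const IntegerVector kh = arch["kh"], kw = arch["kw"],
    ph = arch["pool_h"], pw = arch["pool_w"], Fv = arch["filters"];
  const int H0 = arch["H"], W0 = arch["W"];
  const NumericVector drop = arch["dropout"];
  const int nblock = Fv.size();
  const int N = X.n_slices;

  std::mt19937 gen((unsigned)seed);

  // unpack weights
  std::vector<arma::mat> Wc(nblock);
  std::vector<arma::vec> bc(nblock);
  for (int l = 0; l < nblock; ++l) {
    Wc[l] = as<arma::mat>(weights[2 * l]);
    bc[l] = as<arma::vec>(weights[2 * l + 1]);
  }
  arma::mat Wd = as<arma::mat>(weights[2 * nblock]);
  arma::vec bd = as<arma::vec>(weights[2 * nblock + 1]);
  arma::mat Wo = as<arma::mat>(weights[2 * nblock + 2]);
  arma::vec bo = as<arma::vec>(weights[2 * nblock + 3]);

  // input cube -> (1 x H*W*N)
  const int HW0 = H0 * W0;
  arma::mat A(1, (size_t)HW0 * N);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W0; ++w)
      for (int h = 0; h < H0; ++h)
        A(0, (size_t)n * HW0 + (size_t)w * H0 + h) = X(h, w, n);

  std::vector<ConvShape> shp(nblock);
  std::vector<arma::mat> cols_l(nblock);
  std::vector<arma::umat> M_l(nblock);
  std::vector<arma::mat> mask_l(nblock + 1);

  int H = H0, W = W0, C = 1;
  for (int l = 0; l < nblock; ++l) {
    ConvShape s;
    s.H = H; s.W = W; s.C = C; s.kh = kh[l]; s.kw = kw[l]; s.F = Fv[l];
    s.ph = ph[l]; s.pw = pw[l];
    s.Hp = s.H / s.ph; s.Wp = s.W / s.pw;
    if (s.Hp < 1 || s.Wp < 1)
      stop("pooling schedule incompatible with input shape at block %d", l + 1);
    shp[l] = s;

    cols_l[l] = im2col(A, s.H, s.W, s.C, s.kh, s.kw, N);
    arma::mat Z = Wc[l] * cols_l[l];
    Z.each_col() += bc[l];
    Z.transform([](double v) { return v > 0 ? v : 0.0; });   // ReLU in place
    arma::mat P; arma::umat M;
    maxpool(Z, s.H, s.W, s.ph, s.pw, N, P, M);
    M_l[l] = M;
    if (train && drop[l] > 0) {
      arma::mat mask(arma::size(P));
      const double keep = 1.0 - drop[l];
      for (arma::uword i = 0; i < mask.n_elem; ++i)
        mask(i) = unif01(gen) < keep ? 1.0 / keep : 0.0;
      mask_l[l] = mask;
      P %= mask;
    }
    A = P;
    H = s.Hp; W = s.Wp; C = s.F;
  }

  // flatten: (C x Hp*Wp*N) -> (C*Hp*Wp x N)
  const int HWl = H * W;
  const int flat = C * HWl;
  arma::mat Fl(flat, N);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < HWl; ++j)
      for (int c = 0; c < C; ++c)
        Fl((size_t)c * HWl + j, n) = A(c, (size_t)n * HWl + j);

  if (train && drop[nblock] > 0) {
    arma::mat mask(arma::size(Fl));
    const double keep = 1.0 - drop[nblock];
    for (arma::uword i = 0; i < mask.n_elem; ++i)
      mask(i) = unif01(gen) < keep ? 1.0 / keep : 0.0;
    mask_l[nblock] = mask;
    Fl %= mask;
  }

  if ((int)Wd.n_cols != flat)
    stop("dense layer expects fan-in %d but flatten produced %d",
         (int)Wd.n_cols, flat);

  arma::mat Zd = Wd * Fl;
  Zd.each_col() += bd;
  arma::mat Ad = Zd;
  Ad.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::rowvec zo = Wo.row(0) * Ad + bo(0);
  arma::rowvec scores = 1.0 / (1.0 + arma::exp(-zo));

  List out;
  out["scores"] = NumericVector(scores.begin(), scores.end());

  if (y_.isNotNull()) {
    arma::rowvec y = arma::conv_to<arma::rowvec>::from(
      as<arma::vec>(NumericVector(y_)));
    const double eps = 1e-12;
    arma::rowvec s = arma::clamp(scores, eps, 1.0 - eps);
    out["loss"] = -arma::mean(y % arma::log(s) +
                              (1.0 - y) % arma::log(1.0 - s));

    if (want_grads) {
      List g;
      arma::rowvec dzo = (s - y) / (double)N;
      g["Wo"] = arma::mat(dzo * Ad.t());
      g["bo"] = NumericVector::create(arma::accu(dzo));
      arma::mat dAd = Wo.t() * dzo;
      arma::mat dZd = dAd % arma::conv_to<arma::mat>::from(Zd > 0);
      g["Wd"] = arma::mat(dZd * Fl.t());
      g["bd"] = NumericVector(dZd.n_rows);
      {
        arma::vec rb = arma::sum(dZd, 1);
        g["bd"] = NumericVector(rb.begin(), rb.end());
      }
      arma::mat dFl = Wd.t() * dZd;
      if (train && drop[nblock] > 0) dFl %= mask_l[nblock];

      // unflatten
      arma::mat dP(C, (size_t)HWl * N, arma::fill::zeros);
      for (int n = 0; n < N; ++n)
        for (int j = 0; j < HWl; ++j)
          for (int c = 0; c < C; ++c)
            dP(c, (size_t)n * HWl + j) = dFl((size_t)c * HWl + j, n);

      for (int l = nblock - 1; l >= 0; --l) {
        const ConvShape& sS = shp[l];
        if (train && drop[l] > 0) dP %= mask_l[l];
        // pool + ReLU backward: route each pooled gradient to its argmax
        // unless the window's maximum was clipped by the ReLU (sentinel)
        const size_t ncol_in = (size_t)sS.H * sS.W * N;
        arma::mat dZ(sS.F, ncol_in, arma::fill::zeros);
        const arma::umat& M = M_l[l];
        for (arma::uword j = 0; j < dP.n_cols; ++j)
          for (arma::uword f = 0; f < (arma::uword)sS.F; ++f)
            if (M(f, j) != ncol_in) dZ(f, M(f, j)) += dP(f, j);
        g[std::string("W") + std::to_string(l + 1)] =
          arma::mat(dZ * cols_l[l].t());
        arma::vec rb = arma::sum(dZ, 1);
        g[std::string("b") + std::to_string(l + 1)] =
          NumericVector(rb.begin(), rb.end());
        if (l > 0) {
          arma::mat dcols = Wc[l].t() * dZ;
          arma::mat dA(sS.C, (size_t)sS.H * sS.W * N, arma::fill::zeros);
          col2im(dcols, dA, sS.H, sS.W, sS.C, sS.kh, sS.kw, N);
          dP = dA;
        }
      }
      out["grads"] = g;
    }
  }
  return out;
}
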