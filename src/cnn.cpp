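// CNN engine for the Diffuser/Elapser submodels: 5x5 "same" convolutions
// (stride 1, zero padding 2) via shift-copy im2col + one GEMM per layer
// over the whole mini-batch, 2D batch normalisation and ReLU after every
// layer except the last, MSE loss, exact backpropagation.  Single
// precision internally (the training signal is far above float noise);
// weight updates (Adam) live on the R side.
//
// A stack is an R list of layers; each layer is a list with
//   W     : (in_ch*25) x (out_ch) weight matrix, row index ch*25 + kc*5 + kr
//   b     : length-out_ch bias
//   bn    : logical, batch norm + ReLU present (all but final layer)
//   gamma, beta, rmean, rvar : length-out_ch batch-norm parameters/stats
// Activations are (N*H*W) x C matrices: image i occupies the row block
// [i*H*W, (i+1)*H*W), pixels in R's column-major order, one matrix column
// per channel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const int KS = 5, PAD = 2;

// batched im2col: fill `col` ((N*H*W) x (C*25)) from activations
// `acts` ((N*H*W) x C); zero padding outside each image
static void im2col_batch(const fmat& acts, int N, int H, int W, fmat& col) {
  const int HW = H * W;
  const int C = acts.n_cols;
  col.zeros();
  for (int ch = 0; ch < C; ++ch) {
    for (int kc = 0; kc < KS; ++kc) {
      for (int kr = 0; kr < KS; ++kr) {
        const int q = ch * KS * KS + kc * KS + kr;
        float* out = col.colptr(q);
        const float* in = acts.colptr(ch);
        const int dr = kr - PAD;           // input row = output row + dr
        const int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        const int len = r1 - r0 + 1;
        if (len <= 0) continue;
        for (int i = 0; i < N; ++i) {
          const int base = i * HW;
          for (int c = 0; c < W; ++c) {
            const int ic = c + kc - PAD;
            if (ic < 0 || ic >= W) continue;
            std::memcpy(out + base + c * H + r0,
                        in + base + ic * H + r0 + dr,
                        sizeof(float) * len);
          }
        }
      }
    }
  }
}

// transpose of im2col: scatter-add patch gradients `dcol` back onto dX
static void col2im_batch(const fmat& dcol, int N, int H, int W, fmat& dX) {
  const int HW = H * W;
  const int C = dX.n_cols;
  dX.zeros();
  for (int ch = 0; ch < C; ++ch) {
    for (int kc = 0; kc < KS; ++kc) {
      for (int kr = 0; kr < KS; ++kr) {
        const int q = ch * KS * KS + kc * KS + kr;
        const float* src = dcol.colptr(q);
        float* dst = dX.colptr(ch);
        const int dr = kr - PAD;
        const int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        const int len = r1 - r0 + 1;
        if (len <= 0) continue;
        for (int i = 0; i < N; ++i) {
          const int base = i * HW;
          for (int c = 0; c < W; ++c) {
            const int ic = c + kc - PAD;
            if (ic < 0 || ic >= W) continue;
            const float* s = src + base + c * H + r0;
            float* d = dst + base + ic * H + r0 + dr;
            for (int k = 0; k < len; ++k) d[k] += s[k];
          }
        }
      }
    }
  }
}

struct Layer {
  fmat W;
  fvec b, gamma, beta, rmean, rvar;
  bool bn;
};

static std::vector<Layer> read_layers(const List& layers) {
  std::vector<Layer> out(layers.size());
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    out[l].W = conv_to<fmat>::from(as<mat>(ly["W"]));
    out[l].b = conv_to<fvec>::from(as<vec>(ly["b"]));
    out[l].bn = as<bool>(ly["bn"]);
    if (out[l].bn) {
      out[l].gamma = conv_to<fvec>::from(as<vec>(ly["gamma"]));
      out[l].beta = conv_to<fvec>::from(as<vec>(ly["beta"]));
      out[l].rmean = conv_to<fvec>::from(as<vec>(ly["rmean"]));
      out[l].rvar = conv_to<fvec>::from(as<vec>(ly["rvar"]));
    }
  }
  return out;
}

// R list of (H x W x C) arrays -> (N*H*W) x C float matrix
static fmat stack_batch(const List& xb, int& H, int& W, int& C) {
  const int N = xb.size();
  NumericVector a0 = xb[0];
  IntegerVector dim = a0.attr("dim");
  H = dim[0]; W = dim[1]; C = dim.size() == 3 ? dim[2] : 1;
  const int HW = H * W;
  fmat out(N * HW, C);
  for (int i = 0; i < N; ++i) {
    NumericVector a = xb[i];
    const double* p = a.begin();
    for (int ch = 0; ch < C; ++ch) {
      float* dst = out.colptr(ch) + i * HW;
      const double* src = p + (size_t)ch * HW;
      for (int k = 0; k < HW; ++k) dst[k] = (float)src[k];
    }
  }
  return out;
}

static List unstack_batch(const fmat& acts, int N, int H, int W) {
  const int HW = H * W;
  const int C = acts.n_cols;
  List out(N);
  for (int i = 0; i < N; ++i) {
    NumericVector a(HW * C);
    for (int ch = 0; ch < C; ++ch) {
      const float* src = acts.colptr(ch) + i * HW;
      double* dst = a.begin() + (size_t)ch * HW;
      for (int k = 0; k < HW; ++k) dst[k] = (double)src[k];
    }
    a.attr("dim") = IntegerVector::create(H, W, C);
    out[i] = a;
  }
  return out;
}

static fmat conv_layer(const Layer& ly, const fmat& acts, int N, int H, int W) {
  fmat col(acts.n_rows, acts.n_cols * KS * KS);
  im2col_batch(acts, N, H, W, col);
  fmat z = col * ly.W;
  z.each_row() += ly.b.t();
  return z;
}

// Inference-mode forward pass (batch norm uses running statistics).
// [[Rcpp::export(name = ".cpp_cnn_predict")]]
List cpp_cnn_predict(List layers, List xbatch, double bn_eps) {
  std::vector<Layer> ls = read_layers(layers);
  int H, W, C;
  fmat acts = stack_batch(xbatch, H, W, C);
  const int N = xbatch.size();
  for (size_t l = 0; l < ls.size(); ++l) {
    fmat z = conv_layer(ls[l], acts, N, H, W);
    if (ls[l].bn) {
      for (uword ch = 0; ch < z.n_cols; ++ch) {
        const float sc = ls[l].gamma[ch] /
          std::sqrt(ls[l].rvar[ch] + (float)bn_eps);
        const float sh = ls[l].beta[ch] - sc * ls[l].rmean[ch];
        z.col(ch) = sc * z.col(ch) + sh;
      }
      z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    }
    acts = std::move(z);
  }
  return unstack_batch(acts, N, H, W);
}

// One training forward+backward pass over a mini-batch.  Batch norm uses
// batch statistics (biased variance for normalisation, unbiased pushed
// into the running stats with the given momentum).  Returns the MSE loss,
// per-layer gradients, and updated running statistics.
// [[Rcpp::export(name = ".cpp_cnn_train_batch")]]
List cpp_cnn_train_batch(List layers, List xbatch, List ybatch,
                         double bn_momentum, double bn_eps) {
  std::vector<Layer> ls = read_layers(layers);
  const int L = ls.size(), N = xbatch.size();
  int H, W, C;
  std::vector<fmat> acts(L + 1), xhat(L);
  std::vector<fvec> inv_std(L), new_rmean(L), new_rvar(L);
  acts[0] = stack_batch(xbatch, H, W, C);
  const double M = (double)acts[0].n_rows;   // N * H * W

  for (int l = 0; l < L; ++l) {
    fmat z = conv_layer(ls[l], acts[l], N, H, W);
    if (ls[l].bn) {
      fvec mu = conv_to<fvec>::from(mean(z, 0).t());
      z.each_row() -= mu.t();
      fvec var = conv_to<fvec>::from(mean(square(z), 0).t());
      inv_std[l] = 1.0f / sqrt(var + (float)bn_eps);
      new_rmean[l] = (1.0f - (float)bn_momentum) * ls[l].rmean +
        (float)bn_momentum * mu;
      const float ub = M > 1 ? (float)(M / (M - 1.0)) : 1.0f;
      new_rvar[l] = (1.0f - (float)bn_momentum) * ls[l].rvar +
        (float)bn_momentum * (ub * var);
      z.each_row() %= inv_std[l].t();
      xhat[l] = z;
      z.each_row() %= ls[l].gamma.t();
      z.each_row() += ls[l].beta.t();
      z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    }
    acts[l + 1] = std::move(z);
  }

  int Hy, Wy, Cy;
  fmat Y = stack_batch(ybatch, Hy, Wy, Cy);
  if (Hy != H || Wy != W || (uword)Cy != acts[L].n_cols)
    stop("target shape does not match the stack output");
  fmat diff = acts[L] - Y;
  const double T = (double)diff.n_elem;
  const double loss = accu(conv_to<mat>::from(square(diff))) / T;
  fmat dY = (float)(2.0 / T) * diff;

  List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    fmat dZ;
    fvec dgamma, dbeta;
    if (ls[l].bn) {
      fmat dA = dY;
      // ReLU mask from the stored post-activation output
      const fmat& a_out = acts[l + 1];
      for (uword k = 0; k < dA.n_elem; ++k)
        if (a_out[k] <= 0.0f) dA[k] = 0.0f;
      dgamma = conv_to<fvec>::from(sum(dA % xhat[l], 0).t());
      dbeta = conv_to<fvec>::from(sum(dA, 0).t());
      fmat dxh = dA;
      dxh.each_row() %= ls[l].gamma.t();
      frowvec m1 = mean(dxh, 0);
      frowvec m2 = mean(dxh % xhat[l], 0);
      dZ = dxh;
      dZ.each_row() -= m1;
      dZ -= xhat[l].each_row() % m2;
      dZ.each_row() %= inv_std[l].t();
    } else {
      dZ = dY;
    }
    fmat col(acts[l].n_rows, acts[l].n_cols * KS * KS);
    im2col_batch(acts[l], N, H, W, col);
    fmat dW = col.t() * dZ;
    fvec db = conv_to<fvec>::from(sum(dZ, 0).t());
    List g = List::create(
      _["dW"] = conv_to<mat>::from(dW),
      _["db"] = conv_to<vec>::from(db));
    if (ls[l].bn) {
      g["dgamma"] = conv_to<vec>::from(dgamma);
      g["dbeta"] = conv_to<vec>::from(dbeta);
      g["rmean"] = conv_to<vec>::from(new_rmean[l]);
      g["rvar"] = conv_to<vec>::from(new_rvar[l]);
    }
    grads[l] = g;
    if (l > 0) {
      fmat dcol = dZ * ls[l].W.t();
      fmat dX(acts[l].n_rows, acts[l].n_cols);
      col2im_batch(dcol, N, H, W, dX);
      dY = std::move(dX);
    }
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
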