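// Stacked 1-D convolutional autoencoder: forward pass, backpropagation and
// Adam training loop. Convolutions are evaluated as im2col gathers followed
// by BLAS sgemm; transposed convolutions reuse the same primitives through
// the adjoint relationship (tconv forward == conv backward-data).
//
// Weight layout (R side stores doubles, cast to float here):
//   conv  layer: W is out_ch x (in_ch * kernel), b is out_ch
//   tconv layer: W is in_ch  x (out_ch * kernel), b is out_ch
// i.e. a tconv stores the weights of its adjoint convolution.

#include <RcppArmadillo.h>
#include <random>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;

namespace {

struct LayerSpec {
  bool transposed;
  int in_ch, out_ch, kernel, stride, pad, out_pad;
  int act; // 0 linear, 1 relu, 2 sigmoid
};

int conv_out_len(int li, int k, int s, int p) {
  return (li + 2 * p - k) / s + 1;
}

int tconv_out_len(int li, int k, int s, int p, int op) {
  return (li - 1) * s - 2 * p + k + op;
}

// X: in_ch x Li  ->  col: (in_ch*K) x Lo, zero padded outside [0, Li)
void im2col(const fmat& X, int k, int s, int p, fmat& col) {
  const int ci = X.n_rows, li = X.n_cols;
  const int lo = conv_out_len(li, k, s, p);
  col.zeros(ci * k, lo);
  for (int kk = 0; kk < k; ++kk) {
    for (int lo_i = 0; lo_i < lo; ++lo_i) {
      const int src = lo_i * s + kk - p;
      if (src < 0 || src >= li) continue;
      for (int c = 0; c < ci; ++c) col(c * k + kk, lo_i) = X(c, src);
    }
  }
}

// scatter-add adjoint of im2col; dX: in_ch x Li
void col2im(const fmat& col, int ci, int li, int k, int s, int p, fmat& dX) {
  const int lo = col.n_cols;
  dX.zeros(ci, li);
  for (int kk = 0; kk < k; ++kk) {
    for (int lo_i = 0; lo_i < lo; ++lo_i) {
      const int dst = lo_i * s + kk - p;
      if (dst < 0 || dst >= li) continue;
      for (int c = 0; c < ci; ++c) dX(c, dst) += col(c * k + kk, lo_i);
    }
  }
}

// conv forward: Z = W * col(X), no bias/activation
fmat conv_fwd(const fmat& X, const fmat& W, int k, int s, int p) {
  fmat col;
  im2col(X, k, s, p, col);
  return W * col;
}

// conv backward-data: dX = col2im(W' * dZ)
fmat conv_bwd_data(const fmat& dZ, const fmat& W, int ci, int li,
                   int k, int s, int p) {
  fmat dcol = W.t() * dZ;
  fmat dX;
  col2im(dcol, ci, li, k, s, p, dX);
  return dX;
}

// conv weight gradient: dW = dZ * col(X)'
fmat conv_bwd_weight(const fmat& X, const fmat& dZ, int k, int s, int p) {
  fmat col;
  im2col(X, k, s, p, col);
  return dZ * col.t();
}

void apply_act(fmat& A, int act) {
  if (act == 1) {
    A.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
  } else if (act == 2) {
    A.for_each([](float& v) { v = 1.0f / (1.0f + std::exp(-v)); });
  }
}

// gradient through activation, using post-activation values A
void act_backward(fmat& dA, const fmat& A, int act) {
  if (act == 1) {
    dA.elem(arma::find(A <= 0.0f)).zeros();
  } else if (act == 2) {
    dA %= A % (1.0f - A);
  }
}

std::vector<LayerSpec> parse_layers(const Rcpp::List& layers) {
  std::vector<LayerSpec> specs;
  for (int i = 0; i < layers.size(); ++i) {
    Rcpp::List l = layers[i];
    LayerSpec s;
    std::string type = Rcpp::as<std::string>(l["type"]);
    s.transposed = (type == "tconv");
    s.in_ch = Rcpp::as<int>(l["in_ch"]);
    s.out_ch = Rcpp::as<int>(l["out_ch"]);
    s.kernel = Rcpp::as<int>(l["kernel"]);
    s.stride = Rcpp::as<int>(l["stride"]);
    s.pad = Rcpp::as<int>(l["pad"]);
    s.out_pad = Rcpp::as<int>(l["out_pad"]);
    std::string act = Rcpp::as<std::string>(l["activation"]);
    s.act = (act == "relu") ? 1 : (act == "sigmoid") ? 2 : 0;
    specs.push_back(s);
  }
  return specs;
}

struct Weights {
  std::vector<fmat> W;
  std::vector<fvec> b;
};

Weights parse_weights(const Rcpp::List& weights) {
  Weights w;
  for (int i = 0; i < weights.size(); ++i) {
    Rcpp::List l = weights[i];
    w.W.push_back(arma::conv_to<fmat>::from(
        Rcpp::as<arma::mat>(l["W"])));
    w.b.push_back(arma::conv_to<fvec>::from(
        Rcpp::as<arma::vec>(l["b"])));
  }
  return w;
}

// forward pass for one sample; keeps post-activation values per layer
// activations[0] is the input (1 x L), activations[i+1] the output of layer i
void forward_sample(const fvec& x, const std::vector<LayerSpec>& specs,
                    const Weights& w, std::vector<fmat>& activations) {
  activations.clear();
  fmat A(1, x.n_elem);
  A.row(0) = x.t();
  activations.push_back(A);
  for (size_t i = 0; i < specs.size(); ++i) {
    const LayerSpec& s = specs[i];
    fmat Z;
    if (!s.transposed) {
      Z = conv_fwd(A, w.W[i], s.kernel, s.stride, s.pad);
    } else {
      const int lo = tconv_out_len(A.n_cols, s.kernel, s.stride, s.pad,
                                   s.out_pad);
      Z = conv_bwd_data(A, w.W[i], s.out_ch, lo, s.kernel, s.stride, s.pad);
    }
    Z.each_col() += w.b[i];
    apply_act(Z, s.act);
    activations.push_back(Z);
    A = activations.back();
  }
}

// backward pass; fills gradients (same shapes as weights), returns nothing
void backward_sample(const std::vector<LayerSpec>& specs, const Weights& w,
                     const std::vector<fmat>& activations, fmat dA,
                     Weights& grad) {
  for (int i = (int)specs.size() - 1; i >= 0; --i) {
    const LayerSpec& s = specs[i];
    const fmat& A_in = activations[i];
    const fmat& A_out = activations[i + 1];
    act_backward(dA, A_out, s.act); // now dZ
    grad.b[i] += arma::sum(dA, 1);
    if (!s.transposed) {
      grad.W[i] += conv_bwd_weight(A_in, dA, s.kernel, s.stride, s.pad);
      if (i > 0)
        dA = conv_bwd_data(dA, w.W[i], s.in_ch, A_in.n_cols,
                           s.kernel, s.stride, s.pad);
    } else {
      // tconv: dW = X * col(dZ)', dX = conv_fwd(dZ)
      grad.W[i] += conv_bwd_weight(dA, A_in, s.kernel, s.stride, s.pad);
      if (i > 0)
        dA = conv_fwd(dA, w.W[i], s.kernel, s.stride, s.pad);
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_ae_forward")]]
arma::mat cpp_ae_forward(const arma::mat& X, const Rcpp::List& layers,
                         const Rcpp::List& weights) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  Weights w = parse_weights(weights);
  const int n = X.n_cols;
  fmat Xf = arma::conv_to<fmat>::from(X);
  arma::mat out;
  std::vector<fmat> acts;
  for (int j = 0; j < n; ++j) {
    forward_sample(Xf.col(j), specs, w, acts);
    const fmat& last = acts.back();
    if (j == 0) out.set_size(last.n_cols, n);
    out.col(j) = arma::conv_to<arma::vec>::from(last.row(0).t());
  }
  return out;
}

// loss and weight gradients at the current weights, for one sample —
// used by finite-difference correctness checks
// [[Rcpp::export(name = ".cpp_ae_grad")]]
Rcpp::List cpp_ae_grad(const arma::vec& x, const Rcpp::List& layers,
                       const Rcpp::List& weights) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  Weights w = parse_weights(weights);
  const int L = x.n_elem;
  fvec xf = arma::conv_to<fvec>::from(x);
  std::vector<fmat> acts;
  forward_sample(xf, specs, w, acts);
  fmat resid = acts.back();
  resid.row(0) -= xf.t();
  const double loss = arma::accu(arma::square(resid)) / (double)L;
  Weights grad;
  for (size_t i = 0; i < w.W.size(); ++i) {
    grad.W.push_back(arma::zeros<fmat>(w.W[i].n_rows, w.W[i].n_cols));
    grad.b.push_back(arma::zeros<fvec>(w.b[i].n_elem));
  }
  fmat dA = resid * (2.0f / (float)L);
  backward_sample(specs, w, acts, dA, grad);
  Rcpp::List out_grad(grad.W.size());
  for (size_t i = 0; i < grad.W.size(); ++i) {
    out_grad[i] = Rcpp::List::create(
        Rcpp::Named("W") = arma::conv_to<arma::mat>::from(grad.W[i]),
        Rcpp::Named("b") = arma::conv_to<arma::vec>::from(grad.b[i]));
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = out_grad);
}

// [[Rcpp::export(name = ".cpp_ae_train")]]
Rcpp::List cpp_ae_train(const arma::mat& X, const Rcpp::List& layers,
                        const Rcpp::List& weights, double lr, int epochs,
                        int batch_size, int seed) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  Weights w = parse_weights(weights);
  const int n = X.n_cols;
  const int L = X.n_rows;
  fmat Xf = arma::conv_to<fmat>::from(X);

  // Adam state
  Weights m, v;
  for (size_t i = 0; i < w.W.size(); ++i) {
    m.W.push_back(arma::zeros<fmat>(w.W[i].n_rows, w.W[i].n_cols));
    v.W.push_back(arma::zeros<fmat>(w.W[i].n_rows, w.W[i].n_cols));
    m.b.push_back(arma::zeros<fvec>(w.b[i].n_elem));
    v.b.push_back(arma::zeros<fvec>(w.b[i].n_elem));
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> loss_history(epochs);
  std::vector<fmat> acts;
  Weights grad;
  for (size_t i = 0; i < w.W.size(); ++i) {
    grad.W.push_back(arma::zeros<fmat>(w.W[i].n_rows, w.W[i].n_cols));
    grad.b.push_back(arma::zeros<fvec>(w.b[i].n_elem));
  }

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n);
      const int bs = end - start;
      for (size_t i = 0; i < w.W.size(); ++i) {
        grad.W[i].zeros();
        grad.b[i].zeros();
      }
      for (int bi = start; bi < end; ++bi) {
        const fvec x = Xf.col(order[bi]);
        forward_sample(x, specs, w, acts);
        const fmat& xhat = acts.back();
        fmat resid = xhat;
        resid.row(0) -= x.t();
        const double loss =
            arma::accu(arma::square(resid)) / (double)L;
        ep_loss += loss;
        // dL/dxhat for per-sample mean over the L elements, averaged
        // over the batch
        fmat dA = resid * (2.0f / (float)(L * bs));
        backward_sample(specs, w, acts, dA, grad);
      }
      // Adam update
      ++step;
      const float bc1 = 1.0f - std::pow(b1, (float)step);
      const float bc2 = 1.0f - std::pow(b2, (float)step);
      for (size_t i = 0; i < w.W.size(); ++i) {
        m.W[i] = b1 * m.W[i] + (1.0f - b1) * grad.W[i];
        v.W[i] = b2 * v.W[i] + (1.0f - b2) * arma::square(grad.W[i]);
        w.W[i] -= (float)lr * (m.W[i] / bc1) /
                  (arma::sqrt(v.W[i] / bc2) + eps);
        m.b[i] = b1 * m.b[i] + (1.0f - b1) * grad.b[i];
        v.b[i] = b2 * v.b[i] + (1.0f - b2) * arma::square(grad.b[i]);
        w.b[i] -= (float)lr * (m.b[i] / bc1) /
                  (arma::sqrt(v.b[i] / bc2) + eps);
      }
    }
    loss_history[ep] = ep_loss / n;
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List out_weights(w.W.size());
  for (size_t i = 0; i < w.W.size(); ++i) {
    out_weights[i] = Rcpp::List::create(
        Rcpp::Named("W") = arma::conv_to<arma::mat>::from(w.W[i]),
        Rcpp::Named("b") = arma::conv_to<arma::vec>::from(w.b[i]));
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = out_weights,
      Rcpp::Named("loss_history") = loss_history);
}
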