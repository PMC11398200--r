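// Training and inference kernels for the small feed-forward nets
// (1-D valid convolutions, max pooling, dropout, dense layers, softmax
// cross-entropy, Adam). Semantics mirror the plain-R reference
// implementation in R/nn.R, which the test suite uses as an oracle.
//
// Spatial activations use the same layout as the R reference:
// (n * len) x channels matrices, row (p - 1) * n + i for sample i at
// position p, so im2col gathers are contiguous row blocks and the
// flatten before the dense layers is a plain reshape.
//
// All randomness (batch shuffling, dropout masks) is drawn from R's RNG
// so a set.seed() in R makes fits reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Layer {
  std::string type;
  int kernel = 0, filters = 0, pool = 0, units = 0;
  double rate = 0.0;
  std::string act;
};

struct Cache {
  arma::mat M;        // conv im2col / dense input
  arma::umat relu;    // relu mask (conv, dense)
  arma::umat arg;     // maxpool argmax offset (0-based)
  arma::mat mask;     // dropout mask
  int in_len = 0, in_ch = 0;
};

std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> out;
  for (R_xlen_t i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    Layer L;
    L.type = as<std::string>(l["type"]);
    if (L.type == "conv1d") {
      L.kernel = as<int>(l["kernel"]);
      L.filters = as<int>(l["filters"]);
    } else if (L.type == "maxpool") {
      L.pool = as<int>(l["pool"]);
    } else if (L.type == "dense") {
      L.units = as<int>(l["units"]);
      L.act = as<std::string>(l["act"]);
    } else if (L.type == "dropout") {
      L.rate = as<double>(l["rate"]);
    }
    out.push_back(L);
  }
  return out;
}

// Forward pass; fills caches when training (for backward).
arma::mat forward(const std::vector<Layer>& layers,
                  const std::vector<arma::mat>& W,
                  const std::vector<arma::vec>& b,
                  const arma::mat& X, int n_out,
                  bool training, std::vector<Cache>* caches) {
  const int n = X.n_rows;
  int len = X.n_cols, ch = 1;
  arma::mat A(X.memptr(), (size_t)n * len, 1);
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& l = layers[i];
    if (l.type == "conv1d") {
      int lenp = len - l.kernel + 1;
      arma::mat M((size_t)n * lenp, (size_t)l.kernel * ch);
      for (int c = 0; c < ch; ++c)
        for (int j = 0; j < l.kernel; ++j)
          M.col((size_t)c * l.kernel + j) =
            A.submat((size_t)j * n, c, (size_t)(j + lenp) * n - 1, c);
      arma::mat Z = M * W[i];
      Z.each_row() += b[i].t();
      arma::umat relu = (Z > 0);
      Z %= arma::conv_to<arma::mat>::from(relu);
      if (training) {
        (*caches)[i].M = std::move(M);
        (*caches)[i].relu = std::move(relu);
        (*caches)[i].in_len = len;
        (*caches)[i].in_ch = ch;
      }
      A = std::move(Z);
      len = lenp; ch = l.filters;
    } else if (l.type == "maxpool") {
      int lenp = len / l.pool;
      arma::mat out((size_t)n * lenp, ch);
      arma::umat arg((size_t)n * lenp, ch, arma::fill::zeros);
      out.fill(-arma::datum::inf);
      for (int q = 0; q < lenp; ++q) {
        for (int o = 0; o < l.pool; ++o) {
          int pi = q * l.pool + o;
          arma::mat slice = A.rows((size_t)pi * n, (size_t)(pi + 1) * n - 1);
          arma::umat upd = slice >
            out.rows((size_t)q * n, (size_t)(q + 1) * n - 1);
          for (int c = 0; c < ch; ++c)
            for (int r = 0; r < n; ++r)
              if (upd(r, c)) {
                out((size_t)q * n + r, c) = slice(r, c);
                arg((size_t)q * n + r, c) = o;
              }
        }
      }
      if (training) {
        (*caches)[i].arg = std::move(arg);
        (*caches)[i].in_len = len;
        (*caches)[i].in_ch = ch;
      }
      A = std::move(out);
      len = lenp;
    } else if (l.type == "flatten") {
      if (training) {
        (*caches)[i].in_len = len;
        (*caches)[i].in_ch = ch;
      }
      A.reshape((size_t)n * len * ch, 1);
      len = len * ch; ch = 1;
    } else if (l.type == "dropout") {
      if (training && l.rate > 0) {
        arma::mat mask(A.n_rows, A.n_cols);
        double keep = 1.0 - l.rate;
        for (size_t k = 0; k < mask.n_elem; ++k)
          mask(k) = (unif_rand() >= l.rate) ? 1.0 / keep : 0.0;
        A %= mask;
        (*caches)[i].mask = std::move(mask);
      }
    } else if (l.type == "dense") {
      arma::mat Xm(A.memptr(), n, len);
      arma::mat Z = Xm * W[i];
      Z.each_row() += b[i].t();
      if (l.act == "relu") {
        arma::umat relu = (Z > 0);
        Z %= arma::conv_to<arma::mat>::from(relu);
        if (training) (*caches)[i].relu = std::move(relu);
      } else if (l.act == "softmax") {
        Z.each_col() -= arma::max(Z, 1);
        Z = arma::exp(Z);
        Z.each_col() /= arma::sum(Z, 1);
      }
      if (training) (*caches)[i].M = std::move(Xm);
      A = std::move(Z);
      A.reshape((size_t)n * l.units, 1);
      len = l.units;
    }
  }
  arma::mat out(A.memptr(), n, n_out);
  return out;
}

void backward(const std::vector<Layer>& layers,
              const std::vector<arma::mat>& W,
              std::vector<Cache>& caches,
              const arma::mat& dOut, int n,
              std::vector<arma::mat>& gW, std::vector<arma::vec>& gb) {
  arma::mat dA(dOut.memptr(), (size_t)n * dOut.n_cols, 1);
  for (int i = (int)layers.size() - 1; i >= 0; --i) {
    const Layer& l = layers[i];
    Cache& cache = caches[i];
    if (l.type == "dense") {
      arma::mat dZ(dA.memptr(), n, dA.n_elem / n);
      if (l.act == "relu")
        dZ %= arma::conv_to<arma::mat>::from(cache.relu);
      gW[i] = cache.M.t() * dZ;
      gb[i] = arma::sum(dZ, 0).t();
      arma::mat dX = dZ * W[i].t();
      dA = arma::mat(dX.memptr(), dX.n_elem, 1);
    } else if (l.type == "dropout") {
      if (cache.mask.n_elem > 0) {
        // same element order as at the forward pass; alias to dA's shape
        arma::mat m2(cache.mask.memptr(), dA.n_rows, dA.n_cols);
        dA %= m2;
      }
    } else if (l.type == "flatten") {
      dA.reshape((size_t)n * cache.in_len, cache.in_ch);
    } else if (l.type == "maxpool") {
      arma::mat dIn((size_t)n * cache.in_len, cache.in_ch,
                    arma::fill::zeros);
      int lenp = cache.in_len / l.pool;
      arma::mat dAm(dA.memptr(), (size_t)n * lenp, cache.in_ch);
      for (int q = 0; q < lenp; ++q)
        for (int c = 0; c < cache.in_ch; ++c)
          for (int r = 0; r < n; ++r) {
            int o = cache.arg((size_t)q * n + r, c);
            dIn((size_t)(q * l.pool + o) * n + r, c) +=
              dAm((size_t)q * n + r, c);
          }
      dA = std::move(dIn);
    } else if (l.type == "conv1d") {
      arma::mat dZ(dA.memptr(), cache.relu.n_rows, cache.relu.n_cols);
      dZ %= arma::conv_to<arma::mat>::from(cache.relu);
      gW[i] = cache.M.t() * dZ;
      gb[i] = arma::sum(dZ, 0).t();
      arma::mat dM = dZ * W[i].t();
      int lenp = dZ.n_rows / n;
      arma::mat dIn((size_t)n * cache.in_len, cache.in_ch,
                    arma::fill::zeros);
      for (int c = 0; c < cache.in_ch; ++c)
        for (int j = 0; j < l.kernel; ++j)
          dIn.submat((size_t)j * n, c, (size_t)(j + lenp) * n - 1, c) +=
            dM.col((size_t)c * l.kernel + j);
      dA = arma::vectorise(dIn);
    }
  }
}

void unpack_params(const List& params, std::vector<arma::mat>& W,
                   std::vector<arma::vec>& b) {
  for (R_xlen_t i = 0; i < params.size(); ++i) {
    if (Rf_isNull(params[i])) { W.emplace_back(); b.emplace_back(); continue; }
    List p = params[i];
    W.push_back(as<arma::mat>(p["W"]));
    b.push_back(as<arma::vec>(p["b"]));
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_nn_fit(List layers_spec, List params, const arma::mat& X,
                const arma::ivec& y_idx, int n_out, int epochs,
                int batch_size, double lr, double beta1, double beta2,
                double eps) {
  std::vector<Layer> layers = parse_layers(layers_spec);
  std::vector<arma::mat> W; std::vector<arma::vec> b;
  unpack_params(params, W, b);
  const int n = X.n_rows;
  arma::mat Y(n, n_out, arma::fill::zeros);
  for (int i = 0; i < n; ++i) Y(i, y_idx[i] - 1) = 1.0;

  std::vector<arma::mat> mW(W.size()), vW(W.size()), gW(W.size());
  std::vector<arma::vec> mb(b.size()), vb(b.size()), gb(b.size());
  for (size_t i = 0; i < W.size(); ++i) {
    if (W[i].n_elem == 0) continue;
    mW[i].zeros(W[i].n_rows, W[i].n_cols);
    vW[i].zeros(W[i].n_rows, W[i].n_cols);
    mb[i].zeros(b[i].n_elem);
    vb[i].zeros(b[i].n_elem);
  }
  long step = 0;
  std::vector<Cache> caches(layers.size());
  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = sample(n, n, false);  // R RNG, 1-based
    for (int start = 0; start < n; start += batch_size) {
      int bs = std::min(batch_size, n - start);
      arma::uvec idx(bs);
      for (int k = 0; k < bs; ++k) idx[k] = ord[start + k] - 1;
      arma::mat Xb = X.rows(idx);
      arma::mat Yb = Y.rows(idx);
      arma::mat P = forward(layers, W, b, Xb, n_out, true, &caches);
      arma::mat dOut = (P - Yb) / (double)bs;
      backward(layers, W, caches, dOut, bs, gW, gb);
      ++step;
      double corr1 = 1.0 - std::pow(beta1, (double)step);
      double corr2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t i = 0; i < W.size(); ++i) {
        if (W[i].n_elem == 0) continue;
        mW[i] = beta1 * mW[i] + (1 - beta1) * gW[i];
        vW[i] = beta2 * vW[i] + (1 - beta2) * (gW[i] % gW[i]);
        W[i] -= lr * (mW[i] / corr1) / (arma::sqrt(vW[i] / corr2) + eps);
        mb[i] = beta1 * mb[i] + (1 - beta1) * gb[i];
        vb[i] = beta2 * vb[i] + (1 - beta2) * (gb[i] % gb[i]);
        b[i] -= lr * (mb[i] / corr1) / (arma::sqrt(vb[i] / corr2) + eps);
      }
    }
  }
  List out(params.size());
  for (R_xlen_t i = 0; i < params.size(); ++i) {
    if (W[i].n_elem == 0) out[i] = R_NilValue;
    else out[i] = List::create(Named("W") = W[i], Named("b") = b[i]);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_nn_forward(List layers_spec, List params, const arma::mat& X,
                         int n_out) {
  std::vector<Layer> layers = parse_layers(layers_spec);
  std::vector<arma::mat> W; std::vector<arma::vec> b;
  unpack_params(params, W, b);
  return forward(layers, W, b, X, n_out, false, nullptr);
}
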