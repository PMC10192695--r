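// Small convolutional classifier:
//   conv(F1, 3x3) - ReLU - maxpool(2x2) - conv(F2, 3x3) - ReLU -
//   maxpool(2x2) - dropout - dense(U) - ReLU - dense(2) - softmax,
// trained with Adam on cross-entropy. Convolutions are valid (no padding)
// and run as im2col + GEMM. All randomness (init, shuffling, dropout) comes
// from a private mt19937 stream seeded by the caller, so training is
// reproducible independently of R's RNG.
//
// Feature maps are stored as (channels x H*W) matrices with spatial index
// s = h + H*w; input examples arrive as a flat array with element (c,h,w)
// of example e at offset e*C*H*W + c + C*h + C*H*w.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Geom { int C, H, W; };

static arma::mat im2col3(const arma::mat& X, const Geom& g) {
  const int Ho = g.H - 2, Wo = g.W - 2;
  arma::mat col(g.C * 9, (size_t)Ho * Wo);
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh) {
      const size_t p = oh + (size_t)Ho * ow;
      for (int dw = 0; dw < 3; ++dw)
        for (int dh = 0; dh < 3; ++dh) {
          const size_t s = (oh + dh) + (size_t)g.H * (ow + dw);
          const int roff = g.C * (dh + 3 * dw);
          for (int c = 0; c < g.C; ++c) col(c + roff, p) = X(c, s);
        }
    }
  return col;
}

static arma::mat col2im3(const arma::mat& dcol, const Geom& g) {
  const int Ho = g.H - 2, Wo = g.W - 2;
  arma::mat dX(g.C, (size_t)g.H * g.W, arma::fill::zeros);
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh) {
      const size_t p = oh + (size_t)Ho * ow;
      for (int dw = 0; dw < 3; ++dw)
        for (int dh = 0; dh < 3; ++dh) {
          const size_t s = (oh + dh) + (size_t)g.H * (ow + dw);
          const int roff = g.C * (dh + 3 * dw);
          for (int c = 0; c < g.C; ++c) dX(c, s) += dcol(c + roff, p);
        }
    }
  return dX;
}

static arma::mat maxpool2(const arma::mat& A, int H, int W,
                          arma::umat& argmax) {
  const int Hp = H / 2, Wp = W / 2, F = A.n_rows;
  arma::mat P(F, (size_t)Hp * Wp);
  argmax.set_size(F, (size_t)Hp * Wp);
  for (int pw = 0; pw < Wp; ++pw)
    for (int ph = 0; ph < Hp; ++ph) {
      const size_t q = ph + (size_t)Hp * pw;
      const size_t s00 = 2 * ph + (size_t)H * (2 * pw);
      const size_t cand[4] = { s00, s00 + 1, s00 + H, s00 + H + 1 };
      for (int f = 0; f < F; ++f) {
        double best = A(f, cand[0]); size_t bi = cand[0];
        for (int k = 1; k < 4; ++k)
          if (A(f, cand[k]) > best) { best = A(f, cand[k]); bi = cand[k]; }
        P(f, q) = best; argmax(f, q) = bi;
      }
    }
  return P;
}

static arma::mat unpool2(const arma::mat& dP, const arma::umat& argmax,
                         int H, int W) {
  arma::mat dA(dP.n_rows, (size_t)H * W, arma::fill::zeros);
  for (size_t q = 0; q < dP.n_cols; ++q)
    for (size_t f = 0; f < dP.n_rows; ++f)
      dA(f, argmax(f, q)) += dP(f, q);
  return dA;
}

// deterministic N(0,1) via Box-Muller on mt19937 uniforms
static double rnorm_det(std::mt19937& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double u1 = 0.0;
  while (u1 <= 1e-300) u1 = U(rng);
  const double u2 = U(rng);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

static arma::mat he_init(int rows, int cols, int fan_in, std::mt19937& rng) {
  arma::mat W(rows, cols);
  const double sd = std::sqrt(2.0 / (double)fan_in);
  for (size_t j = 0; j < W.n_cols; ++j)
    for (size_t i = 0; i < W.n_rows; ++i) W(i, j) = sd * rnorm_det(rng);
  return W;
}

struct Adam {
  arma::mat m, v;
  void init(const arma::mat& w) {
    m.zeros(w.n_rows, w.n_cols); v.zeros(w.n_rows, w.n_cols);
  }
  void step(arma::mat& w, const arma::mat& g, double lr, double t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    const arma::mat mhat = m / (1.0 - std::pow(0.9, t));
    const arma::mat vhat = v / (1.0 - std::pow(0.999, t));
    w -= lr * mhat / (arma::sqrt(vhat) + 1e-8);
  }
};

struct Net {
  Geom g0, g1p, g2p;           // input; after pool1; after pool2
  int F1, F2, U, D;
  arma::mat W1, W2, Wf1, Wf2;  // b* stored as 1-col mats
  arma::mat b1, b2, bf1, bf2;
};

static void net_dims(Net& net, int C, int H, int W, int F1, int F2, int U) {
  net.g0 = { C, H, W };
  net.F1 = F1; net.F2 = F2; net.U = U;
  net.g1p = { F1, (H - 2) / 2, (W - 2) / 2 };
  net.g2p = { F2, (net.g1p.H - 2) / 2, (net.g1p.W - 2) / 2 };
  net.D = F2 * net.g2p.H * net.g2p.W;
}

// forward through conv stack; returns flattened feature vector
static arma::vec forward_features(const Net& net, const arma::mat& X,
                                  arma::mat& A1, arma::umat& am1,
                                  arma::mat& P1, arma::mat& A2,
                                  arma::umat& am2, arma::mat& col1,
                                  arma::mat& col2) {
  col1 = im2col3(X, net.g0);
  A1 = net.W1 * col1;
  A1.each_col() += net.b1.col(0);
  A1.transform([](double z) { return z > 0.0 ? z : 0.0; });
  P1 = maxpool2(A1, net.g0.H - 2, net.g0.W - 2, am1);
  Geom g1 = { net.F1, net.g1p.H, net.g1p.W };
  col2 = im2col3(P1, g1);
  A2 = net.W2 * col2;
  A2.each_col() += net.b2.col(0);
  A2.transform([](double z) { return z > 0.0 ? z : 0.0; });
  arma::umat am;
  arma::mat P2 = maxpool2(A2, net.g1p.H - 2, net.g1p.W - 2, am2);
  return arma::vectorise(P2);
}

static arma::vec softmax2(const arma::vec& z) {
  const double m = z.max();
  arma::vec e = arma::exp(z - m);
  return e / arma::accu(e);
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector X, IntegerVector dims, IntegerVector y,
                   int F1, int F2, int U, double dropout, double lr,
                   int epochs, int batch_size, int seed) {
  const int C = dims[0], H = dims[1], W = dims[2], n = dims[3];
  Net net;
  net_dims(net, C, H, W, F1, F2, U);
  std::mt19937 rng((unsigned)seed);
  net.W1 = he_init(F1, C * 9, C * 9, rng);        net.b1.zeros(F1, 1);
  net.W2 = he_init(F2, F1 * 9, F1 * 9, rng);      net.b2.zeros(F2, 1);
  net.Wf1 = he_init(U, net.D, net.D, rng);        net.bf1.zeros(U, 1);
  net.Wf2 = he_init(2, U, U, rng);                net.bf2.zeros(2, 1);

  Adam aW1, aW2, aWf1, aWf2, ab1, ab2, abf1, abf2;
  aW1.init(net.W1); aW2.init(net.W2); aWf1.init(net.Wf1); aWf2.init(net.Wf2);
  ab1.init(net.b1); ab2.init(net.b2); abf1.init(net.bf1); abf2.init(net.bf2);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const size_t ex_len = (size_t)C * H * W;
  std::uniform_real_distribution<double> Udist(0.0, 1.0);
  NumericVector loss_hist(epochs);
  double adam_t = 0.0;
  const Geom g1 = { F1, net.g1p.H, net.g1p.W };
  const int H1 = H - 2, W1c = W - 2, H2 = net.g1p.H - 2, W2c = net.g1p.W - 2;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> J(0, i);
      std::swap(order[i], order[(int)J(rng)]);
    }
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int bs = std::min(batch_size, n - start);
      arma::mat gW1(arma::size(net.W1), arma::fill::zeros), gW2(arma::size(net.W2), arma::fill::zeros);
      arma::mat gWf1(arma::size(net.Wf1), arma::fill::zeros), gWf2(arma::size(net.Wf2), arma::fill::zeros);
      arma::mat gb1(arma::size(net.b1), arma::fill::zeros), gb2(arma::size(net.b2), arma::fill::zeros);
      arma::mat gbf1(arma::size(net.bf1), arma::fill::zeros), gbf2(arma::size(net.bf2), arma::fill::zeros);

      for (int bi = 0; bi < bs; ++bi) {
        const int e = order[start + bi];
        const arma::mat Xe(const_cast<double*>(&X[0]) + ex_len * e,
                           C, (size_t)H * W, false, true);
        arma::mat A1, P1, A2, col1, col2;
        arma::umat am1, am2;
        arma::vec feat = forward_features(net, Xe, A1, am1, P1, A2, am2, col1, col2);

        // dropout on the flattened conv features (inverted scaling)
        arma::vec mask(net.D, arma::fill::ones);
        if (dropout > 0.0) {
          for (int d = 0; d < net.D; ++d)
            mask(d) = Udist(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
          feat %= mask;
        }
        arma::vec z1 = net.Wf1 * feat + net.bf1.col(0);
        arma::vec h1 = arma::clamp(z1, 0.0, arma::datum::inf);
        arma::vec z2 = net.Wf2 * h1 + net.bf2.col(0);
        arma::vec p = softmax2(z2);
        const int yi = y[e];
        ep_loss += -std::log(std::max(p(yi), 1e-12));

        // backward
        arma::vec dz2 = p; dz2(yi) -= 1.0;
        gWf2 += dz2 * h1.t(); gbf2.col(0) += dz2;
        arma::vec dh1 = net.Wf2.t() * dz2;
        arma::vec dz1 = dh1 % arma::conv_to<arma::vec>::from(z1 > 0.0);
        gWf1 += dz1 * feat.t(); gbf1.col(0) += dz1;
        arma::vec dfeat = net.Wf1.t() * dz1;
        if (dropout > 0.0) dfeat %= mask;

        arma::mat dP2(dfeat.memptr(), F2, (size_t)net.g2p.H * net.g2p.W, false, true);
        arma::mat dA2 = unpool2(dP2, am2, H2, W2c);
        dA2 %= arma::conv_to<arma::mat>::from(A2 > 0.0);
        gW2 += dA2 * col2.t(); gb2.col(0) += arma::sum(dA2, 1);
        arma::mat dcol2 = net.W2.t() * dA2;
        arma::mat dP1 = col2im3(dcol2, g1);
        arma::mat dA1 = unpool2(dP1, am1, H1, W1c);
        dA1 %= arma::conv_to<arma::mat>::from(A1 > 0.0);
        gW1 += dA1 * col1.t(); gb1.col(0) += arma::sum(dA1, 1);
      }
      const double inv = 1.0 / (double)bs;
      adam_t += 1.0;
      aW1.step(net.W1, gW1 * inv, lr, adam_t);   ab1.step(net.b1, gb1 * inv, lr, adam_t);
      aW2.step(net.W2, gW2 * inv, lr, adam_t);   ab2.step(net.b2, gb2 * inv, lr, adam_t);
      aWf1.step(net.Wf1, gWf1 * inv, lr, adam_t); abf1.step(net.bf1, gbf1 * inv, lr, adam_t);
      aWf2.step(net.Wf2, gWf2 * inv, lr, adam_t); abf2.step(net.bf2, gbf2 * inv, lr, adam_t);
    }
    loss_hist[ep] = ep_loss / n;
  }

  return List::create(
    _["W1"] = net.W1, _["b1"] = net.b1, _["W2"] = net.W2, _["b2"] = net.b2,
    _["Wf1"] = net.Wf1, _["bf1"] = net.bf1, _["Wf2"] = net.Wf2, _["bf2"] = net.bf2,
    _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List weights, NumericVector X, IntegerVector dims,
                              int F1, int F2, int U) {
  const int C = dims[0], H = dims[1], W = dims[2], n = dims[3];
  Net net;
  net_dims(net, C, H, W, F1, F2, U);
  net.W1 = as<arma::mat>(weights["W1"]); net.b1 = as<arma::mat>(weights["b1"]);
  net.W2 = as<arma::mat>(weights["W2"]); net.b2 = as<arma::mat>(weights["b2"]);
  net.Wf1 = as<arma::mat>(weights["Wf1"]); net.bf1 = as<arma::mat>(weights["bf1"]);
  net.Wf2 = as<arma::mat>(weights["Wf2"]); net.bf2 = as<arma::mat>(weights["bf2"]);

  const size_t ex_len = (size_t)C * H * W;
  NumericMatrix out(n, 2);
  for (int e = 0; e < n; ++e) {
    const arma::mat Xe(const_cast<double*>(&X[0]) + ex_len * e,
                       C, (size_t)H * W, false, true);
    arma::mat A1, P1, A2, col1, col2;
    arma::umat am1, am2;
    arma::vec feat = forward_features(net, Xe, A1, am1, P1, A2, am2, col1, col2);
    arma::vec h1 = arma::clamp(net.Wf1 * feat + net.bf1.col(0), 0.0, arma::datum::inf);
    arma::vec p = softmax2(net.Wf2 * h1 + net.bf2.col(0));
    out(e, 0) = p(0); out(e, 1) = p(1);
  }
  return out;
}
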