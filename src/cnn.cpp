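// Small convolutional network trained by minibatch stochastic gradient
// descent. Architecture (fixed topology, configurable sizes):
//   conv1 -> ReLU -> maxpool(2x2,2) -> conv2 -> ReLU -> maxpool(2x2,2)
//   -> conv3 -> ReLU -> flatten -> fc1 -> ReLU -> dropout
//   -> fc2 -> ReLU -> dropout -> fc3(1) -> sigmoid
// Loss: binary cross-entropy; L2 weight decay on the fully connected
// layers only. All randomness (shuffling, dropout) comes from a private
// mt19937 stream so training is bit-reproducible given the seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Cfg {
  int input;                 // square input side
  ivec k, s, f;              // kernel, stride, filters per conv layer
  int u1, u2;                // fc widths
  double dropout, l2, lr;
  int batch;
  bool augment;              // random time-shift/reversal of training images
  // derived spatial sizes
  int o1, p1, o2, p2, o3, flat;
};

struct Params {
  mat cW1, cW2, cW3;         // (k*k*cin) x f
  vec cb1, cb2, cb3;
  mat fW1, fW2, fW3;         // in x out
  vec fb1, fb2, fb3;
};

Cfg read_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.input = Rcpp::as<int>(cfg["input"]);
  c.k = Rcpp::as<ivec>(cfg["kernel"]);
  c.s = Rcpp::as<ivec>(cfg["stride"]);
  c.f = Rcpp::as<ivec>(cfg["filters"]);
  Rcpp::IntegerVector fc = cfg["fc"];
  c.u1 = fc[0]; c.u2 = fc[1];
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.l2 = Rcpp::as<double>(cfg["l2"]);
  c.lr = Rcpp::as<double>(cfg["lr"]);
  c.batch = Rcpp::as<int>(cfg["batch"]);
  c.augment = Rcpp::as<bool>(cfg["augment"]);
  c.o1 = (c.input - c.k[0]) / c.s[0] + 1;
  c.p1 = c.o1 / 2;
  c.o2 = (c.p1 - c.k[1]) / c.s[1] + 1;
  c.p2 = c.o2 / 2;
  c.o3 = (c.p2 - c.k[2]) / c.s[2] + 1;
  c.flat = c.o3 * c.o3 * (int)c.f[2];
  if (c.o1 < 2 || c.o2 < 2 || c.o3 < 1)
    Rcpp::stop("input too small for the configured kernels/strides");
  return c;
}

Params read_params(const Rcpp::List& p) {
  Params w;
  w.cW1 = Rcpp::as<mat>(p["cW1"]); w.cb1 = Rcpp::as<vec>(p["cb1"]);
  w.cW2 = Rcpp::as<mat>(p["cW2"]); w.cb2 = Rcpp::as<vec>(p["cb2"]);
  w.cW3 = Rcpp::as<mat>(p["cW3"]); w.cb3 = Rcpp::as<vec>(p["cb3"]);
  w.fW1 = Rcpp::as<mat>(p["fW1"]); w.fb1 = Rcpp::as<vec>(p["fb1"]);
  w.fW2 = Rcpp::as<mat>(p["fW2"]); w.fb2 = Rcpp::as<vec>(p["fb2"]);
  w.fW3 = Rcpp::as<mat>(p["fW3"]); w.fb3 = Rcpp::as<vec>(p["fb3"]);
  return w;
}

Rcpp::List write_params(const Params& w) {
  return Rcpp::List::create(
    Rcpp::Named("cW1") = w.cW1, Rcpp::Named("cb1") = w.cb1,
    Rcpp::Named("cW2") = w.cW2, Rcpp::Named("cb2") = w.cb2,
    Rcpp::Named("cW3") = w.cW3, Rcpp::Named("cb3") = w.cb3,
    Rcpp::Named("fW1") = w.fW1, Rcpp::Named("fb1") = w.fb1,
    Rcpp::Named("fW2") = w.fW2, Rcpp::Named("fb2") = w.fb2,
    Rcpp::Named("fW3") = w.fW3, Rcpp::Named("fb3") = w.fb3);
}

mat im2col(const cube& in, int k, int s, int oh, int ow) {
  int c = in.n_slices;
  mat out(k * k * c, oh * ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      double* dst = out.colptr(j * oh + i);
      for (int ch = 0; ch < c; ++ch) {
        const mat& sl = in.slice(ch);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            *dst++ = sl(i * s + ki, j * s + kj);
      }
    }
  return out;
}

void col2im_add(cube& out, const mat& cols, int k, int s, int oh, int ow) {
  int c = out.n_slices;
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      const double* src = cols.colptr(j * oh + i);
      for (int ch = 0; ch < c; ++ch) {
        mat& sl = out.slice(ch);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            sl(i * s + ki, j * s + kj) += *src++;
      }
    }
}

// pre (f x positions) -> activation cube (oh x ow x f)
cube to_cube(const mat& pre, int oh, int ow) {
  cube out(oh, ow, pre.n_rows);
  for (uword f = 0; f < pre.n_rows; ++f)
    out.slice(f) = reshape(pre.row(f).t(), oh, ow);
  return out;
}

mat to_mat(const cube& a) {
  mat out(a.n_slices, a.n_rows * a.n_cols);
  for (uword f = 0; f < a.n_slices; ++f)
    out.row(f) = vectorise(a.slice(f)).t();
  return out;
}

cube maxpool(const cube& in, ucube& argmax) {
  int oh = in.n_rows / 2, ow = in.n_cols / 2, c = in.n_slices;
  cube out(oh, ow, c);
  argmax.set_size(oh, ow, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -datum::inf; uword bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            uword r = 2 * i + di, cc = 2 * j + dj;
            double v = in(r, cc, ch);
            if (v > best) { best = v; bidx = cc * in.n_rows + r; }
          }
        out(i, j, ch) = best;
        argmax(i, j, ch) = bidx;
      }
  return out;
}

void maxpool_back(cube& din, const cube& dout, const ucube& argmax) {
  for (uword ch = 0; ch < dout.n_slices; ++ch)
    for (uword j = 0; j < dout.n_cols; ++j)
      for (uword i = 0; i < dout.n_rows; ++i)
        din.slice(ch)(argmax(i, j, ch)) += dout(i, j, ch);
}

struct Fwd {
  mat cols1, pre1, cols2, pre2, cols3, pre3;
  cube a1, p1c, a2, p2c, a3;
  ucube am1, am2;
  vec flat, z1, a1f, z2, a2f, m1, m2;
  double z3, p;
};

double forward(const Cfg& c, const Params& w, const mat& img, Fwd& F,
               bool training, const vec& mask1, const vec& mask2) {
  cube in(c.input, c.input, 1);
  in.slice(0) = img;
  F.cols1 = im2col(in, c.k[0], c.s[0], c.o1, c.o1);
  F.pre1 = w.cW1.t() * F.cols1;
  F.pre1.each_col() += w.cb1;
  F.a1 = to_cube(F.pre1, c.o1, c.o1);
  F.a1.transform([](double v) { return v > 0 ? v : 0.0; });
  F.p1c = maxpool(F.a1, F.am1);
  F.cols2 = im2col(F.p1c, c.k[1], c.s[1], c.o2, c.o2);
  F.pre2 = w.cW2.t() * F.cols2;
  F.pre2.each_col() += w.cb2;
  F.a2 = to_cube(F.pre2, c.o2, c.o2);
  F.a2.transform([](double v) { return v > 0 ? v : 0.0; });
  F.p2c = maxpool(F.a2, F.am2);
  F.cols3 = im2col(F.p2c, c.k[2], c.s[2], c.o3, c.o3);
  F.pre3 = w.cW3.t() * F.cols3;
  F.pre3.each_col() += w.cb3;
  F.a3 = to_cube(F.pre3, c.o3, c.o3);
  F.a3.transform([](double v) { return v > 0 ? v : 0.0; });
  F.flat = vectorise(F.a3);
  F.z1 = w.fW1.t() * F.flat + w.fb1;
  F.a1f = clamp(F.z1, 0.0, datum::inf);
  F.m1 = training ? mask1 : vec(c.u1, fill::ones);
  F.a1f %= F.m1;
  F.z2 = w.fW2.t() * F.a1f + w.fb2;
  F.a2f = clamp(F.z2, 0.0, datum::inf);
  F.m2 = training ? mask2 : vec(c.u2, fill::ones);
  F.a2f %= F.m2;
  F.z3 = as_scalar(w.fW3.t() * F.a2f + w.fb3);
  F.p = 1.0 / (1.0 + std::exp(-F.z3));
  return F.p;
}

void backward(const Cfg& c, const Params& w, const Fwd& F, double dz3,
              Params& g) {
  g.fW3 += F.a2f * dz3;
  g.fb3 += dz3;
  vec da2f = w.fW3 * dz3;
  da2f %= F.m2;
  vec dz2 = da2f % conv_to<vec>::from(F.z2 > 0);
  g.fW2 += F.a1f * dz2.t();
  g.fb2 += dz2;
  vec da1f = w.fW2 * dz2;
  da1f %= F.m1;
  vec dz1 = da1f % conv_to<vec>::from(F.z1 > 0);
  g.fW1 += F.flat * dz1.t();
  g.fb1 += dz1;
  vec dflat = w.fW1 * dz1;
  cube da3(c.o3, c.o3, c.f[2]);
  std::memcpy(da3.memptr(), dflat.memptr(), sizeof(double) * dflat.n_elem);
  // relu on conv3
  mat dpre3 = to_mat(da3) % conv_to<mat>::from(F.pre3 > 0);
  g.cW3 += F.cols3 * dpre3.t();
  g.cb3 += sum(dpre3, 1);
  mat dcols3 = w.cW3 * dpre3;
  cube dp2(c.p2, c.p2, c.f[1], fill::zeros);
  col2im_add(dp2, dcols3, c.k[2], c.s[2], c.o3, c.o3);
  cube da2c(c.o2, c.o2, c.f[1], fill::zeros);
  maxpool_back(da2c, dp2, F.am2);
  mat dpre2 = to_mat(da2c) % conv_to<mat>::from(F.pre2 > 0);
  g.cW2 += F.cols2 * dpre2.t();
  g.cb2 += sum(dpre2, 1);
  mat dcols2 = w.cW2 * dpre2;
  cube dp1(c.p1, c.p1, c.f[0], fill::zeros);
  col2im_add(dp1, dcols2, c.k[1], c.s[1], c.o2, c.o2);
  cube da1c(c.o1, c.o1, c.f[0], fill::zeros);
  maxpool_back(da1c, dp1, F.am1);
  mat dpre1 = to_mat(da1c) % conv_to<mat>::from(F.pre1 > 0);
  g.cW1 += F.cols1 * dpre1.t();
  g.cb1 += sum(dpre1, 1);
}

Params zeros_like(const Params& w) {
  Params g;
  g.cW1 = zeros(size(w.cW1)); g.cb1 = zeros(size(w.cb1));
  g.cW2 = zeros(size(w.cW2)); g.cb2 = zeros(size(w.cb2));
  g.cW3 = zeros(size(w.cW3)); g.cb3 = zeros(size(w.cb3));
  g.fW1 = zeros(size(w.fW1)); g.fb1 = zeros(size(w.fb1));
  g.fW2 = zeros(size(w.fW2)); g.fb2 = zeros(size(w.fb2));
  g.fW3 = zeros(size(w.fW3)); g.fb3 = zeros(size(w.fb3));
  return g;
}

double accuracy(const Cfg& c, const Params& w, const cube& X, const vec& y) {
  Fwd F; vec dummy;
  int correct = 0;
  for (uword i = 0; i < X.n_slices; ++i) {
    double p = forward(c, w, X.slice(i), F, false, dummy, dummy);
    if ((p >= 0.5) == (y(i) >= 0.5)) ++correct;
  }
  return (double)correct / X.n_slices;
}

double unif(std::mt19937& gen) {
  return gen() * (1.0 / 4294967296.0);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List cfg_in, Rcpp::List params_in,
                         arma::cube train_x, arma::vec train_y,
                         arma::cube val_x, arma::vec val_y,
                         int epochs, int seed, bool keep_snapshots) {
  Cfg c = read_cfg(cfg_in);
  Params w = read_params(params_in);
  std::mt19937 gen((uint32_t)seed);
  int n = train_x.n_slices;
  mat history(epochs, 3);
  Rcpp::List snapshots(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from the private stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(gen() % (uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double loss_sum = 0;
    for (int start = 0; start < n; start += c.batch) {
      int bend = std::min(start + c.batch, n);
      int bsz = bend - start;
      Params g = zeros_like(w);
      Fwd F;
      for (int bi = start; bi < bend; ++bi) {
        int idx = order[bi];
        vec m1(c.u1), m2(c.u2);
        double keep = 1.0 - c.dropout;
        for (int u = 0; u < c.u1; ++u)
          m1(u) = (c.dropout > 0 && unif(gen) < c.dropout) ? 0.0 : 1.0 / keep;
        for (int u = 0; u < c.u2; ++u)
          m2(u) = (c.dropout > 0 && unif(gen) < c.dropout) ? 0.0 : 1.0 / keep;
        // augmentation: the signal is stationary within a window, so a
        // circular time shift (and time reversal) preserves the label
        mat xi = train_x.slice(idx);
        if (c.augment) {
          int sh = (int)(gen() % (uint32_t)c.input);
          bool flip = unif(gen) < 0.5;
          if (sh > 0)
            xi = join_rows(xi.cols(c.input - sh, c.input - 1),
                           xi.cols(0, c.input - sh - 1));
          if (flip) xi = fliplr(xi);
        }
        double p = forward(c, w, xi, F, true, m1, m2);
        double y = train_y(idx);
        double eps = 1e-12;
        loss_sum += -(y * std::log(p + eps) + (1 - y) * std::log(1 - p + eps));
        backward(c, w, F, (p - y), g);
      }
      double inv = 1.0 / bsz;
      w.cW1 -= c.lr * (g.cW1 * inv); w.cb1 -= c.lr * (g.cb1 * inv);
      w.cW2 -= c.lr * (g.cW2 * inv); w.cb2 -= c.lr * (g.cb2 * inv);
      w.cW3 -= c.lr * (g.cW3 * inv); w.cb3 -= c.lr * (g.cb3 * inv);
      w.fW1 -= c.lr * (g.fW1 * inv + c.l2 * w.fW1);
      w.fb1 -= c.lr * (g.fb1 * inv);
      w.fW2 -= c.lr * (g.fW2 * inv + c.l2 * w.fW2);
      w.fb2 -= c.lr * (g.fb2 * inv);
      w.fW3 -= c.lr * (g.fW3 * inv + c.l2 * w.fW3);
      w.fb3 -= c.lr * (g.fb3 * inv);
    }
    history(ep, 0) = loss_sum / n;
    history(ep, 1) = accuracy(c, w, train_x, train_y);
    history(ep, 2) = val_x.n_slices > 0 ? accuracy(c, w, val_x, val_y)
                                        : datum::nan;
    if (keep_snapshots) snapshots[ep] = write_params(w);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("history") = history,
    Rcpp::Named("final") = write_params(w),
    Rcpp::Named("snapshots") = snapshots);
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(Rcpp::List cfg_in, Rcpp::List params_in,
                          arma::cube images) {
  Cfg c = read_cfg(cfg_in);
  Params w = read_params(params_in);
  Fwd F; vec dummy;
  vec out(images.n_slices);
  for (uword i = 0; i < images.n_slices; ++i)
    out(i) = forward(c, w, images.slice(i), F, false, dummy, dummy);
  return out;
}
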