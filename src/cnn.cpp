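// Compact convolutional classifier for GADF images.
// Fixed topology: conv3x3(pad 1) -> ReLU -> maxpool2 -> conv3x3 -> ReLU
// -> maxpool2 -> global average pool -> dense -> ReLU -> dense -> sigmoid.
// Trained with Adam on binary cross-entropy, early stopping on validation
// loss.  All randomness (init, shuffling) comes from R's RNG so runs are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// im2col for 3x3, pad 1, stride 1: (9*C) x (H*W), col = i + H*j
mat im2col3(const cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(9 * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int row = ki + 3 * kj + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - 1;
            if (si < 0 || si >= H) continue;
            out(row, i + H * j) = x(si, sj, c);
          }
        }
      }
  return out;
}

// adjoint of im2col3: scatter-add columns back into an H x W x C cube
cube col2im3(const mat &cols, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int row = ki + 3 * kj + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - 1;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += cols(row, i + H * j);
          }
        }
      }
  return out;
}

cube conv3(const cube &x, const mat &W, const vec &b, mat &cols_out) {
  cols_out = im2col3(x);
  mat o = W * cols_out;           // F x (H*W)
  o.each_col() += b;
  cube out(x.n_rows, x.n_cols, W.n_rows);
  for (uword f = 0; f < W.n_rows; ++f)
    out.slice(f) = reshape(o.row(f).t(), x.n_rows, x.n_cols);
  return out;
}

// 2x2 max pooling, stride 2; records flat argmax per output cell
cube maxpool2(const cube &x, ucube &argmax) {
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  cube out(Ho, Wo, C);
  argmax.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const uword ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + x.n_rows * jj; }
          }
        out(i, j, c) = best;
        argmax(i, j, c) = bi;
      }
  return out;
}

cube maxpool2_back(const cube &g, const ucube &argmax, int H, int W) {
  cube out(H, W, g.n_slices, fill::zeros);
  for (uword c = 0; c < g.n_slices; ++c)
    for (uword j = 0; j < g.n_cols; ++j)
      for (uword i = 0; i < g.n_rows; ++i) {
        const uword flat = argmax(i, j, c);
        out(flat % H, flat / H, c) += g(i, j, c);
      }
  return out;
}

struct Net {
  mat W1, W2, Wd1, Wd2;
  vec b1, b2, bd1, bd2;
  int side, chan, f1, f2, h;

  std::vector<mat*> mats() { return {&W1, &W2, &Wd1, &Wd2}; }
  std::vector<vec*> vecs() { return {&b1, &b2, &bd1, &bd2}; }

  void init() {
    auto he = [](mat &m, int fan_in) {
      const double s = std::sqrt(2.0 / fan_in);
      for (uword i = 0; i < m.n_elem; ++i) m(i) = R::rnorm(0.0, s);
    };
    W1.set_size(f1, 9 * chan);  he(W1, 9 * chan);
    W2.set_size(f2, 9 * f1);    he(W2, 9 * f1);
    Wd1.set_size(h, f2);        he(Wd1, f2);
    Wd2.set_size(1, h);         he(Wd2, h);
    b1.zeros(f1); b2.zeros(f2); bd1.zeros(h); bd2.zeros(1);
  }

  // forward one image; if grads != nullptr, backprop (dz = p - y at the
  // logit) and accumulate parameter gradients into *grads
  double forward(const cube &x, double y, Net *grads) const {
    mat cols1, cols2;
    cube a1 = conv3(x, W1, b1, cols1);
    cube r1 = clamp(a1, 0.0, datum::inf);
    ucube am1;
    cube p1 = maxpool2(r1, am1);
    cube a2 = conv3(p1, W2, b2, cols2);
    cube r2 = clamp(a2, 0.0, datum::inf);
    ucube am2;
    cube p2 = maxpool2(r2, am2);
    vec gap(f2);
    for (int c = 0; c < f2; ++c) gap(c) = accu(p2.slice(c)) / p2.slice(c).n_elem;
    vec hpre = Wd1 * gap + bd1;
    vec hact = clamp(hpre, 0.0, datum::inf);
    const double z = as_scalar(Wd2 * hact + bd2);
    const double p = 1.0 / (1.0 + std::exp(-z));

    if (grads) {
      const double dz = p - y;
      grads->Wd2 += dz * hact.t();
      grads->bd2(0) += dz;
      vec dh = Wd2.t() * dz;
      dh.elem(find(hpre <= 0)).zeros();
      grads->Wd1 += dh * gap.t();
      grads->bd1 += dh;
      vec dgap = Wd1.t() * dh;
      cube dp2(p2.n_rows, p2.n_cols, f2);
      for (int c = 0; c < f2; ++c)
        dp2.slice(c).fill(dgap(c) / p2.slice(c).n_elem);
      cube dr2 = maxpool2_back(dp2, am2, r2.n_rows, r2.n_cols);
      dr2.elem(find(a2 <= 0)).zeros();
      mat d2(f2, dr2.n_rows * dr2.n_cols);
      for (int f = 0; f < f2; ++f)
        d2.row(f) = vectorise(dr2.slice(f)).t();
      grads->W2 += d2 * cols2.t();
      grads->b2 += sum(d2, 1);
      cube dp1 = col2im3(W2.t() * d2, p1.n_rows, p1.n_cols, f1);
      cube dr1 = maxpool2_back(dp1, am1, r1.n_rows, r1.n_cols);
      dr1.elem(find(a1 <= 0)).zeros();
      mat d1(f1, dr1.n_rows * dr1.n_cols);
      for (int f = 0; f < f1; ++f)
        d1.row(f) = vectorise(dr1.slice(f)).t();
      grads->W1 += d1 * cols1.t();
      grads->b1 += sum(d1, 1);
    }
    return p;
  }
};

// one flattened image row back to side x side x chan (column-major, as
// produced by as.vector() on an R array)
cube row_to_cube(const mat &X, uword r, int side, int chan) {
  cube x(side, side, chan);
  rowvec v = X.row(r);
  std::memcpy(x.memptr(), v.memptr(), sizeof(double) * v.n_elem);
  return x;
}

double bce(double p, double y) {
  const double eps = 1e-12;
  return -(y * std::log(p + eps) + (1 - y) * std::log(1 - p + eps));
}

Rcpp::List net_to_list(const Net &n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("Wd1") = n.Wd1, Rcpp::Named("bd1") = n.bd1,
      Rcpp::Named("Wd2") = n.Wd2, Rcpp::Named("bd2") = n.bd2);
}

Net net_from_list(const Rcpp::List &w, int side, int chan) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<vec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<vec>(w["b2"]);
  n.Wd1 = Rcpp::as<mat>(w["Wd1"]); n.bd1 = Rcpp::as<vec>(w["bd1"]);
  n.Wd2 = Rcpp::as<mat>(w["Wd2"]); n.bd2 = Rcpp::as<vec>(w["bd2"]);
  n.side = side; n.chan = chan;
  n.f1 = n.W1.n_rows; n.f2 = n.W2.n_rows; n.h = n.Wd1.n_rows;
  return n;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat &Xtr, const arma::vec &ytr,
                         const arma::mat &Xval, const arma::vec &yval,
                         int side, int chan, int f1, int f2, int h,
                         double lr, int batch, int max_epochs,
                         int patience) {
  Rcpp::RNGScope scope;
  const int n = Xtr.n_rows, nval = Xval.n_rows;
  Net net; net.side = side; net.chan = chan;
  net.f1 = f1; net.f2 = f2; net.h = h;
  net.init();

  Net g = net, m = net, v = net, best = net;
  auto zero_all = [](Net &a) {
    for (mat *p : a.mats()) p->zeros();
    for (vec *p : a.vecs()) p->zeros();
  };
  zero_all(m); zero_all(v);

  const double b1a = 0.9, b2a = 0.999, eps = 1e-8;
  double best_val = datum::inf;
  int wait = 0, t_adam = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    ++epochs_run;
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double tr_loss = 0.0;
    for (int start = 0; start < n; start += batch) {
      const int stop = std::min(n, start + batch);
      zero_all(g);
      for (int k = start; k < stop; ++k) {
        cube x = row_to_cube(Xtr, idx[k], side, chan);
        const double p = net.forward(x, ytr(idx[k]), &g);
        tr_loss += bce(p, ytr(idx[k]));
      }
      const double scale = 1.0 / (stop - start);
      ++t_adam;
      const double c1 = 1.0 - std::pow(b1a, t_adam);
      const double c2 = 1.0 - std::pow(b2a, t_adam);
      auto gm = g.mats(), mm = m.mats(), vm = v.mats(), nm = net.mats();
      for (size_t i = 0; i < gm.size(); ++i) {
        mat grad = (*gm[i]) * scale;
        *mm[i] = b1a * (*mm[i]) + (1 - b1a) * grad;
        *vm[i] = b2a * (*vm[i]) + (1 - b2a) * square(grad);
        *nm[i] -= lr * ((*mm[i]) / c1) / (sqrt((*vm[i]) / c2) + eps);
      }
      auto gv = g.vecs(), mv = m.vecs(), vv = v.vecs(), nv = net.vecs();
      for (size_t i = 0; i < gv.size(); ++i) {
        vec grad = (*gv[i]) * scale;
        *mv[i] = b1a * (*mv[i]) + (1 - b1a) * grad;
        *vv[i] = b2a * (*vv[i]) + (1 - b2a) * square(grad);
        *nv[i] -= lr * ((*mv[i]) / c1) / (sqrt((*vv[i]) / c2) + eps);
      }
    }
    tr_hist.push_back(tr_loss / n);

    double val_loss = 0.0;
    for (int k = 0; k < nval; ++k) {
      cube x = row_to_cube(Xval, k, side, chan);
      val_loss += bce(net.forward(x, yval(k), nullptr), yval(k));
    }
    val_loss /= std::max(1, nval);
    val_hist.push_back(val_loss);

    if (val_loss < best_val - 1e-6) {
      best_val = val_loss;
      best = net;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = net_to_list(best),
      Rcpp::Named("best_val_loss") = best_val,
      Rcpp::Named("epochs") = epochs_run,
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const Rcpp::List &weights, const arma::mat &X,
                          int side, int chan) {
  Net net = net_from_list(weights, side, chan);
  vec out(X.n_rows);
  for (uword r = 0; r < X.n_rows; ++r) {
    cube x = row_to_cube(X, r, side, chan);
    out(r) = net.forward(x, 0.0, nullptr);
  }
  return out;
}
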