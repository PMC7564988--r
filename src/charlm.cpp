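// Character-level LSTM language model: single recurrent layer between an
// embedding lookup and a dense softmax, trained with Adam on one-step-ahead
// character prediction. Single precision keeps the desk-scale training run
// fast on one CPU; weights are returned as double matrices for R.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;

struct Adam {
  fmat m, v;
  int t = 0;
  explicit Adam(const fmat &shape) :
    m(arma::size(shape), arma::fill::zeros),
    v(arma::size(shape), arma::fill::zeros) {}
  void step(fmat &w, const fmat &g, float lr) {
    ++t;
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * (g % g);
    float mc = 1.0f - std::pow(0.9f, (float)t);
    float vc = 1.0f - std::pow(0.999f, (float)t);
    w -= lr * (m / mc) / (arma::sqrt(v / vc) + 1e-7f);
  }
};

struct Caches {
  std::vector<fmat> gates;           // B x 4H post-activation, per t
  std::vector<fmat> cs, tanhcs, hs;  // B x H per t
  fmat Hdrop;                        // (B*L) x H (after dropout)
  fmat probs;                        // (B*L) x V
};

// [[Rcpp::export(name = ".charlm_train_cpp")]]
List charlm_train_cpp(IntegerMatrix inputs, IntegerMatrix targets,
                      int vocab, int embed, int hidden, double dropout,
                      int batch_size, int epochs, int seed, double lr0) {
  const int N = inputs.nrow(), L = inputs.ncol();
  const int H4 = 4 * hidden;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<float> unif(-1.0f, 1.0f);
  std::uniform_real_distribution<float> u01(0.0f, 1.0f);

  auto init = [&](int r, int c, float limit) {
    fmat w(r, c);
    for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = unif(rng) * limit;
    return w;
  };
  fmat E = init(vocab, embed, 0.05f);
  fmat Wx = init(embed, H4, std::sqrt(6.0f / (embed + H4)));
  fmat Wh = init(hidden, H4, std::sqrt(6.0f / (hidden + H4)));
  fmat b(1, H4, arma::fill::zeros);
  b.cols(hidden, 2 * hidden - 1).fill(1.0f);  // forget-gate bias
  fmat Wy = init(hidden, vocab, std::sqrt(6.0f / (hidden + vocab)));
  fmat by(1, vocab, arma::fill::zeros);

  Adam aE(E), aWx(Wx), aWh(Wh), ab(b), aWy(Wy), aby(by);

  // forward over one batch of row indices; train=true applies dropout and
  // fills BPTT caches; returns the gathered embedding rows (for dWx/dE)
  auto forward = [&](const std::vector<int> &rows, bool train, Caches *cache,
                     double *loss_out, double *correct_out) {
    const int B = (int)rows.size();
    fmat X(B * L, embed);
    for (int t = 0; t < L; ++t) {
      for (int i = 0; i < B; ++i) {
        X.row(t * B + i) = E.row(inputs(rows[i], t));
      }
    }
    fmat Xproj = X * Wx;
    fmat h(B, hidden, arma::fill::zeros), c(B, hidden, arma::fill::zeros);
    fmat Hd(B * L, hidden);
    if (cache) {
      cache->gates.assign(L, fmat());
      cache->cs.assign(L, fmat());
      cache->tanhcs.assign(L, fmat());
      cache->hs.assign(L, fmat());
    }
    const float keep = 1.0f - (float)dropout;
    for (int t = 0; t < L; ++t) {
      fmat g = Xproj.rows(t * B, t * B + B - 1);
      g += h * Wh;
      g.each_row() += b;
      // in-place gate activations: [i | f | g~ | o]
      auto gi = g.cols(0, hidden - 1);
      auto gf = g.cols(hidden, 2 * hidden - 1);
      auto gg = g.cols(2 * hidden, 3 * hidden - 1);
      auto go = g.cols(3 * hidden, H4 - 1);
      gi = 1.0f / (1.0f + arma::exp(-gi));
      gf = 1.0f / (1.0f + arma::exp(-gf));
      gg = arma::tanh(gg);
      go = 1.0f / (1.0f + arma::exp(-go));
      c = gf % c + gi % gg;
      fmat tc = arma::tanh(c);
      h = go % tc;
      auto out = Hd.rows(t * B, t * B + B - 1);
      if (train && dropout > 0) {
        fmat hd = h;
        for (arma::uword i = 0; i < hd.n_elem; ++i) {
          hd(i) = (u01(rng) < keep) ? hd(i) / keep : 0.0f;
        }
        out = hd;
      } else {
        out = h;
      }
      if (cache) {
        cache->gates[t] = std::move(g);
        cache->cs[t] = c;
        cache->tanhcs[t] = std::move(tc);
        cache->hs[t] = h;
      }
    }
    fmat logits = Hd * Wy;
    logits.each_row() += by;
    arma::fvec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    logits = arma::exp(logits);
    arma::fvec Z = arma::sum(logits, 1);
    logits.each_col() /= Z;  // now row-wise softmax probabilities

    double loss = 0.0, correct = 0.0;
    for (int t = 0; t < L; ++t) {
      for (int i = 0; i < B; ++i) {
        int y = targets(rows[i], t);
        loss -= std::log(std::max(logits(t * B + i, y), 1e-10f));
        arma::uword am;
        logits.row(t * B + i).max(am);
        if ((int)am == y) correct += 1.0;
      }
    }
    *loss_out = loss / (B * L);
    *correct_out = correct / (B * L);
    if (cache) {
      cache->Hdrop = std::move(Hd);
      cache->probs = std::move(logits);
    }
    return X;
  };

  // loss/accuracy over the whole dataset with the current weights,
  // dropout off
  auto evaluate = [&]() {
    double lsum = 0.0, asum = 0.0;
    int seen = 0;
    for (int s = 0; s < N; s += batch_size) {
      std::vector<int> rows;
      for (int i = s; i < std::min(N, s + batch_size); ++i) rows.push_back(i);
      double l, a;
      forward(rows, false, nullptr, &l, &a);
      lsum += l * rows.size();
      asum += a * rows.size();
      seen += (int)rows.size();
    }
    return std::make_pair(lsum / seen, asum / seen);
  };

  auto init_eval = evaluate();

  NumericVector ep_loss(epochs), ep_acc(epochs);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double lsum = 0.0, asum = 0.0;
    int seen = 0;
    for (int s = 0; s < N; s += batch_size) {
      std::vector<int> rows(order.begin() + s,
                            order.begin() + std::min(N, s + batch_size));
      const int B = (int)rows.size();
      Caches cache;
      double l, a;
      fmat X = forward(rows, true, &cache, &l, &a);
      lsum += l * B;
      asum += a * B;
      seen += B;

      // dlogits = (p - onehot) / (B*L)
      fmat dlog = std::move(cache.probs);
      const float scale = 1.0f / (float)(B * L);
      for (int t = 0; t < L; ++t) {
        for (int i = 0; i < B; ++i) {
          dlog(t * B + i, targets(rows[i], t)) -= 1.0f;
        }
      }
      dlog *= scale;
      fmat dWy = cache.Hdrop.t() * dlog;
      fmat dby = arma::sum(dlog, 0);
      fmat dHd = dlog * Wy.t();
      if (dropout > 0) {
        // gradient flows only through kept units (mask recovered from Hdrop)
        const float keep = 1.0f - (float)dropout;
        for (int t = 0; t < L; ++t) {
          const fmat &hs = cache.hs[t];
          for (int i = 0; i < B; ++i) {
            for (int j = 0; j < hidden; ++j) {
              float hd = cache.Hdrop(t * B + i, j);
              dHd(t * B + i, j) =
                (hd != 0.0f || hs(i, j) == 0.0f)
                  ? dHd(t * B + i, j) / keep : 0.0f;
            }
          }
        }
      }

      fmat dWh(hidden, H4, arma::fill::zeros);
      fmat db(1, H4, arma::fill::zeros);
      fmat dG(B * L, H4);
      fmat dh_next(B, hidden, arma::fill::zeros);
      fmat dc_next(B, hidden, arma::fill::zeros);
      for (int t = L - 1; t >= 0; --t) {
        fmat dh = dHd.rows(t * B, t * B + B - 1);
        dh += dh_next;
        const fmat &g = cache.gates[t];
        auto gi = g.cols(0, hidden - 1);
        auto gf = g.cols(hidden, 2 * hidden - 1);
        auto gg = g.cols(2 * hidden, 3 * hidden - 1);
        auto go = g.cols(3 * hidden, H4 - 1);
        const fmat &tc = cache.tanhcs[t];
        fmat dc = dh % go % (1.0f - tc % tc);
        dc += dc_next;
        auto dst = dG.rows(t * B, t * B + B - 1);
        if (t > 0) {
          dst.cols(hidden, 2 * hidden - 1) =
            (dc % cache.cs[t - 1]) % gf % (1.0f - gf);
        } else {
          dst.cols(hidden, 2 * hidden - 1).zeros();
        }
        dst.cols(0, hidden - 1) = (dc % gg) % gi % (1.0f - gi);
        dst.cols(2 * hidden, 3 * hidden - 1) = (dc % gi) % (1.0f - gg % gg);
        dst.cols(3 * hidden, H4 - 1) = (dh % tc) % go % (1.0f - go);
        const fmat dg = dst;  // materialized view
        if (t > 0) {
          dWh += cache.hs[t - 1].t() * dg;
        }
        db += arma::sum(dg, 0);
        dh_next = dg * Wh.t();
        dc_next = dc % gf;
      }
      fmat dWx = X.t() * dG;
      fmat dX = dG * Wx.t();
      fmat dE(vocab, embed, arma::fill::zeros);
      for (int t = 0; t < L; ++t) {
        for (int i = 0; i < B; ++i) {
          dE.row(inputs(rows[i], t)) += dX.row(t * B + i);
        }
      }

      const float lr = (float)lr0;
      aE.step(E, dE, lr);
      aWx.step(Wx, dWx, lr);
      aWh.step(Wh, dWh, lr);
      ab.step(b, db, lr);
      aWy.step(Wy, dWy, lr);
      aby.step(by, dby, lr);
    }
    ep_loss[epoch] = lsum / seen;
    ep_acc[epoch] = asum / seen;
    Rcpp::checkUserInterrupt();
  }

  auto final_eval = evaluate();

  auto toR = [](const fmat &w) {
    return wrap(arma::conv_to<arma::mat>::from(w));
  };
  return List::create(
    _["E"] = toR(E), _["Wx"] = toR(Wx), _["Wh"] = toR(Wh), _["b"] = toR(b),
    _["Wy"] = toR(Wy), _["by"] = toR(by),
    _["loss"] = ep_loss, _["accuracy"] = ep_acc,
    _["initial_loss"] = init_eval.first,
    _["initial_accuracy"] = init_eval.second,
    _["final_loss"] = final_eval.first,
    _["final_accuracy"] = final_eval.second
  );
}
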