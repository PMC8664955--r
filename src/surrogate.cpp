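// Compact embedding -> conv -> maxpool -> BiGRU -> dense network used as a
// trainable stand-in for hybrid CNN/RNN miRNA-target classifiers. Forward,
// backward and Adam are written out explicitly so that activations of every
// named layer can be captured on the exact forward pass that produces the
// prediction probability.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct Params {
  mat E;            // A x d embedding
  mat Wc; vec bc;   // (K*d) x F conv (im2col layout: col = k*d + j), F
  mat Wf, Uf; vec bf; // forward GRU: F x 3H, H x 3H, 3H (z | r | h blocks)
  mat Wb, Ub; vec bb; // backward GRU
  mat W1; vec b1;   // 2H x D1 dense
  mat W2; vec b2;   // D1 x 1
  mat Wm; vec bm;   // 2H x 4 masked-letter head (training only)
  int K = 0, pool = 0;
};

Params params_from_list(const List& lp) {
  Params p;
  p.E  = Rcpp::as<mat>(lp["E"]);
  p.Wc = Rcpp::as<mat>(lp["Wc"]); p.bc = Rcpp::as<vec>(lp["bc"]);
  p.Wf = Rcpp::as<mat>(lp["Wf"]); p.Uf = Rcpp::as<mat>(lp["Uf"]);
  p.bf = Rcpp::as<vec>(lp["bf"]);
  p.Wb = Rcpp::as<mat>(lp["Wb"]); p.Ub = Rcpp::as<mat>(lp["Ub"]);
  p.bb = Rcpp::as<vec>(lp["bb"]);
  p.W1 = Rcpp::as<mat>(lp["W1"]); p.b1 = Rcpp::as<vec>(lp["b1"]);
  p.W2 = Rcpp::as<mat>(lp["W2"]); p.b2 = Rcpp::as<vec>(lp["b2"]);
  p.Wm = Rcpp::as<mat>(lp["Wm"]); p.bm = Rcpp::as<vec>(lp["bm"]);
  p.K = Rcpp::as<int>(lp["kernel_len"]);
  p.pool = Rcpp::as<int>(lp["pool_len"]);
  return p;
}

List params_to_list(const Params& p) {
  return List::create(
    Named("E") = p.E, Named("Wc") = p.Wc, Named("bc") = p.bc,
    Named("Wf") = p.Wf, Named("Uf") = p.Uf, Named("bf") = p.bf,
    Named("Wb") = p.Wb, Named("Ub") = p.Ub, Named("bb") = p.bb,
    Named("W1") = p.W1, Named("b1") = p.b1,
    Named("W2") = p.W2, Named("b2") = p.b2,
    Named("Wm") = p.Wm, Named("bm") = p.bm,
    Named("kernel_len") = p.K, Named("pool_len") = p.pool);
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-clamp(x, -30.0, 30.0))); }

// One GRU direction over a B x F x T input sequence. States stored per
// timestep so the exact nonlinearity arguments are available to backward.
struct GruCache { cube Z, R, Hh, Hs; }; // each B x H x T

void gru_forward(const mat& W, const mat& U, const vec& b,
                 const cube& Xseq, GruCache& c) {
  const uword B = Xseq.n_rows, T = Xseq.n_slices;
  const uword H = U.n_rows;
  c.Z.set_size(B, H, T); c.R.set_size(B, H, T);
  c.Hh.set_size(B, H, T); c.Hs.set_size(B, H, T);
  mat Hprev(B, H, fill::zeros);
  const mat Wz = W.cols(0, H - 1), Wr = W.cols(H, 2 * H - 1), Wh = W.cols(2 * H, 3 * H - 1);
  const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uh = U.cols(2 * H, 3 * H - 1);
  const rowvec bz = b.subvec(0, H - 1).t(), br = b.subvec(H, 2 * H - 1).t(),
               bh = b.subvec(2 * H, 3 * H - 1).t();
  for (uword t = 0; t < T; ++t) {
    const mat& Xt = Xseq.slice(t);
    mat z = sigm(Xt * Wz + Hprev * Uz + repmat(bz, B, 1));
    mat r = sigm(Xt * Wr + Hprev * Ur + repmat(br, B, 1));
    mat hh = tanh(Xt * Wh + (r % Hprev) * Uh + repmat(bh, B, 1));
    mat Hnew = (1.0 - z) % Hprev + z % hh;
    c.Z.slice(t) = z; c.R.slice(t) = r; c.Hh.slice(t) = hh; c.Hs.slice(t) = Hnew;
    Hprev = Hnew;
  }
}

// Backward through one GRU direction. dHout holds the gradient arriving at
// the state emitted at each timestep; dXseq is filled, parameter grads added.
void gru_backward(const mat& W, const mat& U,
                  const cube& Xseq, const GruCache& c, const cube& dHout,
                  mat& dW, mat& dU, vec& db, cube& dXseq) {
  const uword B = Xseq.n_rows, T = Xseq.n_slices, H = U.n_rows;
  const mat Wz = W.cols(0, H - 1), Wr = W.cols(H, 2 * H - 1), Wh = W.cols(2 * H, 3 * H - 1);
  const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uh = U.cols(2 * H, 3 * H - 1);
  dW.zeros(W.n_rows, W.n_cols); dU.zeros(U.n_rows, U.n_cols); db.zeros(3 * H);
  dXseq.set_size(size(Xseq));
  mat dHnext(B, H, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    const mat& Xt = Xseq.slice(ti);
    const mat& z = c.Z.slice(ti); const mat& r = c.R.slice(ti);
    const mat& hh = c.Hh.slice(ti);
    mat Hprev = (ti == 0) ? mat(B, H, fill::zeros) : c.Hs.slice(ti - 1);
    mat dH = dHout.slice(ti) + dHnext;
    mat dz = dH % (hh - Hprev);
    mat dhh = dH % z;
    mat dHprev = dH % (1.0 - z);
    mat dHin = dhh % (1.0 - hh % hh);
    mat rH = r % Hprev;
    dW.cols(2 * H, 3 * H - 1) += Xt.t() * dHin;
    dU.cols(2 * H, 3 * H - 1) += rH.t() * dHin;
    db.subvec(2 * H, 3 * H - 1) += sum(dHin, 0).t();
    mat drH = dHin * Uh.t();
    mat dr = drH % Hprev;
    dHprev += drH % r;
    mat dZin = dz % z % (1.0 - z);
    mat dRin = dr % r % (1.0 - r);
    dW.cols(0, H - 1) += Xt.t() * dZin;
    dU.cols(0, H - 1) += Hprev.t() * dZin;
    db.subvec(0, H - 1) += sum(dZin, 0).t();
    dW.cols(H, 2 * H - 1) += Xt.t() * dRin;
    dU.cols(H, 2 * H - 1) += Hprev.t() * dRin;
    db.subvec(H, 2 * H - 1) += sum(dRin, 0).t();
    dHprev += dZin * Uz.t() + dRin * Ur.t();
    dXseq.slice(ti) = dZin * Wz.t() + dRin * Wr.t() + dHin * Wh.t();
    dHnext = dHprev;
  }
}

struct Cache {
  cube Emb;      // R x d x B
  cube Im2col;   // P x (K*d) x B
  cube Conv;     // P x F x B, post-ReLU
  Cube<uword> Arg; // T x F x B, argmax row within conv positions
  cube Xseq;     // B x F x T pooled features
  GruCache gf, gb;
  mat Fl;        // B x (T*2H)
  mat D1in, D1out, Drop; // B x D1
  vec out;       // B probabilities
};

void forward(const Params& p, const cube& X, Cache& c,
             bool training, double dropout, std::mt19937* rng) {
  const uword R = X.n_rows, B = X.n_slices;
  const uword d = p.E.n_cols, F = p.Wc.n_cols;
  const uword K = (uword)p.K, pool = (uword)p.pool;
  if (R < K) Rcpp::stop("input has fewer rows than the convolution kernel");
  const uword P = R - K + 1, T = P / pool;
  const uword H = p.Uf.n_rows;

  c.Emb.set_size(R, d, B);
  c.Im2col.set_size(P, K * d, B);
  c.Conv.set_size(P, F, B);
  c.Arg.set_size(T, F, B);
  c.Xseq.set_size(B, F, T);
  for (uword b = 0; b < B; ++b) {
    mat emb = X.slice(b) * p.E;
    c.Emb.slice(b) = emb;
    mat& ic = c.Im2col.slice(b);
    for (uword pos = 0; pos < P; ++pos)
      for (uword k = 0; k < K; ++k)
        ic(pos, span(k * d, k * d + d - 1)) = emb.row(pos + k);
    mat conv = ic * p.Wc;
    conv.each_row() += p.bc.t();
    conv = clamp(conv, 0.0, datum::inf); // ReLU
    c.Conv.slice(b) = conv;
    for (uword t = 0; t < T; ++t)
      for (uword f = 0; f < F; ++f) {
        uword best = t * pool;
        double bv = conv(best, f);
        for (uword q = 1; q < pool; ++q)
          if (conv(t * pool + q, f) > bv) { bv = conv(t * pool + q, f); best = t * pool + q; }
        c.Arg(t, f, b) = best;
        c.Xseq(b, f, t) = bv;
      }
  }

  gru_forward(p.Wf, p.Uf, p.bf, c.Xseq, c.gf);
  cube Xrev(size(c.Xseq));
  for (uword t = 0; t < T; ++t) Xrev.slice(t) = c.Xseq.slice(T - 1 - t);
  gru_forward(p.Wb, p.Ub, p.bb, Xrev, c.gb);

  // dense head reads the BiRNN output averaged over timesteps (global
  // average pooling over the sequence): evidence computed at any timestep
  // reaches the readout directly, while the 2H-wide summary keeps the
  // head too small to memorise training pairs
  c.Fl.zeros(B, 2 * H);
  for (uword t = 0; t < T; ++t) {
    c.Fl.cols(0, H - 1) += c.gf.Hs.slice(t);
    c.Fl.cols(H, 2 * H - 1) += c.gb.Hs.slice(t);
  }
  c.Fl /= (double)T;

  c.D1in = c.Fl * p.W1;
  c.D1in.each_row() += p.b1.t();
  c.D1out = clamp(c.D1in, 0.0, datum::inf);
  if (training && dropout > 0.0 && rng != nullptr) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    c.Drop.set_size(size(c.D1out));
    for (uword i = 0; i < c.Drop.n_elem; ++i)
      c.Drop(i) = unif(*rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
    c.D1out %= c.Drop;
  } else {
    c.Drop.reset();
  }
  mat o = c.D1out * p.W2;
  o.each_row() += p.b2.t();
  c.out = vectorise(sigm(o));
}

struct Grads {
  mat E, Wc, Wf, Uf, Wb, Ub, W1, W2, Wm;
  vec bc, bf, bb, b1, b2, bm;
};

// one masked-letter prediction: sample index, input row, true letter 0..3
struct MlmEntry { uword i, r, letter; };

// timestep whose receptive field centres closest to input row r
inline uword mlm_timestep(uword r, uword K, uword pool, uword T) {
  long center = (long)r - (long)((K - 1) / 2);
  if (center < 0) center = 0;
  uword t = (uword)center / pool;
  return std::min(t, T - 1);
}

double backward(const Params& p, const cube& X, const Cache& c, const vec& y,
                Grads& g, const std::vector<MlmEntry>& mlm = {},
                double mlm_weight = 0.0, double* mlm_loss_out = nullptr) {
  const uword R = X.n_rows, B = X.n_slices;
  const uword d = p.E.n_cols, F = p.Wc.n_cols;
  const uword K = (uword)p.K, pool = (uword)p.pool;
  const uword P = R - K + 1, T = P / pool, H = p.Uf.n_rows;

  vec pr = clamp(c.out, 1e-12, 1.0 - 1e-12);
  double loss = -mean(y % log(pr) + (1.0 - y) % log(1.0 - pr));
  vec dOut = (c.out - y) / (double)B; // sigmoid + BCE

  g.W2 = c.D1out.t() * dOut;
  g.b2 = vec(1); g.b2(0) = accu(dOut);
  mat dD1 = dOut * p.W2.t();
  if (!c.Drop.is_empty()) dD1 %= c.Drop;
  dD1 %= conv_to<mat>::from(c.D1in > 0.0);
  g.W1 = c.Fl.t() * dD1;
  g.b1 = sum(dD1, 0).t();
  mat dFl = dD1 * p.W1.t();

  cube dHf(B, H, T), dHb(B, H, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dFl.cols(0, H - 1) / (double)T;
    dHb.slice(t) = dFl.cols(H, 2 * H - 1) / (double)T; // symmetric over t
  }

  // masked-letter head: cross-entropy over the masked rows, read from the
  // BiRNN output at the timestep covering each row
  g.Wm.zeros(p.Wm.n_rows, p.Wm.n_cols); g.bm.zeros(p.bm.n_elem);
  if (!mlm.empty() && mlm_weight > 0.0) {
    const double wpe = mlm_weight / (double)mlm.size();
    double mloss = 0.0;
    for (const MlmEntry& e : mlm) {
      uword t = mlm_timestep(e.r, (uword)p.K, (uword)p.pool, T);
      rowvec h(2 * H);
      h.cols(0, H - 1) = c.gf.Hs.slice(t).row(e.i);
      // backward-direction state aligned with position t
      h.cols(H, 2 * H - 1) = c.gb.Hs.slice(T - 1 - t).row(e.i);
      rowvec logits = h * p.Wm + p.bm.t();
      logits -= logits.max();
      rowvec ex = exp(logits);
      rowvec pr = ex / accu(ex);
      mloss += -std::log(std::max(pr(e.letter), 1e-12)) * wpe;
      rowvec dlog = pr;
      dlog(e.letter) -= 1.0;
      dlog *= wpe;
      g.Wm += h.t() * dlog;
      g.bm += dlog.t();
      rowvec dh = dlog * p.Wm.t();
      dHf.slice(t).row(e.i) += dh.cols(0, H - 1);
      dHb.slice(T - 1 - t).row(e.i) += dh.cols(H, 2 * H - 1);
    }
    if (mlm_loss_out) *mlm_loss_out = mloss;
  } else if (mlm_loss_out) {
    *mlm_loss_out = 0.0;
  }

  cube Xrev(B, F, T);
  for (uword t = 0; t < T; ++t) Xrev.slice(t) = c.Xseq.slice(T - 1 - t);
  cube dXf, dXb;
  gru_backward(p.Wf, p.Uf, c.Xseq, c.gf, dHf, g.Wf, g.Uf, g.bf, dXf);
  gru_backward(p.Wb, p.Ub, Xrev, c.gb, dHb, g.Wb, g.Ub, g.bb, dXb);
  cube dXseq = dXf;
  for (uword t = 0; t < T; ++t) dXseq.slice(t) += dXb.slice(T - 1 - t);

  g.Wc.zeros(p.Wc.n_rows, p.Wc.n_cols); g.bc.zeros(F);
  g.E.zeros(p.E.n_rows, p.E.n_cols);
  for (uword b = 0; b < B; ++b) {
    mat dConv(P, F, fill::zeros);
    for (uword t = 0; t < T; ++t)
      for (uword f = 0; f < F; ++f)
        dConv(c.Arg(t, f, b), f) += dXseq(b, f, t);
    dConv %= conv_to<mat>::from(c.Conv.slice(b) > 0.0); // ReLU mask
    g.Wc += c.Im2col.slice(b).t() * dConv;
    g.bc += sum(dConv, 0).t();
    mat dIc = dConv * p.Wc.t();
    mat dEmb(R, d, fill::zeros);
    for (uword pos = 0; pos < P; ++pos)
      for (uword k = 0; k < K; ++k)
        dEmb.row(pos + k) += dIc(pos, span(k * d, k * d + d - 1));
    g.E += X.slice(b).t() * dEmb;
  }
  return loss;
}

void collect(Params& p, std::vector<mat*>& mats) {
  mats = { &p.E, &p.Wc, &p.Wf, &p.Uf, &p.Wb, &p.Ub, &p.W1, &p.W2, &p.Wm };
}
void collect_g(Grads& g, std::vector<mat*>& mats, std::vector<vec*>& vecs) {
  mats = { &g.E, &g.Wc, &g.Wf, &g.Uf, &g.Wb, &g.Ub, &g.W1, &g.W2, &g.Wm };
  vecs = { &g.bc, &g.bf, &g.bb, &g.b1, &g.b2, &g.bm };
}
void collect_v(Params& p, std::vector<vec*>& vecs) {
  vecs = { &p.bc, &p.bf, &p.bb, &p.b1, &p.b2, &p.bm };
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_surrogate_predict(const Rcpp::List& lp, const arma::cube& X) {
  Params p = params_from_list(lp);
  Cache c;
  forward(p, X, c, false, 0.0, nullptr);
  return c.out;
}

// [[Rcpp::export]]
Rcpp::List cpp_surrogate_capture(const Rcpp::List& lp, const arma::cube& X) {
  Params p = params_from_list(lp);
  Cache c;
  forward(p, X, c, false, 0.0, nullptr);
  const uword T = c.Xseq.n_slices, H = p.Uf.n_rows, B = X.n_slices;
  mat birnn(B, 2 * H);
  birnn.cols(0, H - 1) = c.gf.Hs.slice(T - 1);
  birnn.cols(H, 2 * H - 1) = c.gb.Hs.slice(T - 1);
  return List::create(
    Named("prob") = c.out,
    Named("embedding") = c.Emb,   // R x d x B
    Named("cnn") = c.Conv,        // P x F x B
    Named("pool") = c.Xseq,       // B x F x T
    Named("birnn") = birnn,       // B x 2H, final state per direction
    Named("dense1") = c.D1out,    // B x D1
    Named("dense2") = mat(c.out)); // B x 1
}

// [[Rcpp::export]]
Rcpp::List cpp_surrogate_grad(const Rcpp::List& lp, const arma::cube& X,
                              const arma::vec& y,
                              const Rcpp::IntegerMatrix& mlm_idx,
                              double mlm_weight) {
  Params p = params_from_list(lp);
  Cache c; Grads g;
  forward(p, X, c, false, 0.0, nullptr);
  std::vector<MlmEntry> mlm;
  for (int i = 0; i < mlm_idx.nrow(); ++i)
    mlm.push_back({(uword)mlm_idx(i, 0), (uword)mlm_idx(i, 1),
                   (uword)mlm_idx(i, 2)});
  double mloss = 0.0;
  double loss = backward(p, X, c, y, g, mlm, mlm_weight, &mloss);
  return List::create(
    Named("loss") = loss + mloss,
    Named("E") = g.E, Named("Wc") = g.Wc, Named("bc") = g.bc,
    Named("Wf") = g.Wf, Named("Uf") = g.Uf, Named("bf") = g.bf,
    Named("Wb") = g.Wb, Named("Ub") = g.Ub, Named("bb") = g.bb,
    Named("W1") = g.W1, Named("b1") = g.b1,
    Named("W2") = g.W2, Named("b2") = g.b2,
    Named("Wm") = g.Wm, Named("bm") = g.bm);
}

// [[Rcpp::export]]
Rcpp::List cpp_surrogate_train(const Rcpp::List& lp, const arma::cube& X,
                               const arma::vec& y, int epochs, int batch_size,
                               double lr, double dropout, int seed,
                               double clip, double weight_decay,
                               double input_mask_prob, double mlm_weight) {
  Params p = params_from_list(lp);
  const uword B = X.n_slices;
  std::mt19937 rng((unsigned)seed);

  std::vector<mat*> pm; collect(p, pm);
  std::vector<vec*> pv; collect_v(p, pv);
  std::vector<mat> mM, vM; std::vector<vec> mV, vV;
  for (auto* m : pm) { mM.emplace_back(size(*m), fill::zeros); vM.emplace_back(size(*m), fill::zeros); }
  for (auto* v : pv) { mV.emplace_back(size(*v), fill::zeros); vV.emplace_back(size(*v), fill::zeros); }
  const double b1a = 0.9, b2a = 0.999, eps = 1e-8;
  long step = 0;
  std::vector<double> losses, mlm_losses;

  std::vector<uword> idx(B);
  for (uword i = 0; i < B; ++i) idx[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double eploss = 0.0, epmlm = 0.0; int nb = 0;
    for (uword start = 0; start < B; start += (uword)batch_size) {
      uword end = std::min(B, start + (uword)batch_size);
      uword bs = end - start;
      cube Xb(X.n_rows, X.n_cols, bs);
      vec yb(bs);
      for (uword i = 0; i < bs; ++i) {
        Xb.slice(i) = X.slice(idx[start + i]);
        yb(i) = y(idx[start + i]);
      }
      std::vector<MlmEntry> mlm;
      if (input_mask_prob > 0.0) {
        // occlusion augmentation: mask non-pad rows to the N one-hot (the
        // same replacement the mutagenesis stage uses) and ask the
        // masked-letter head to reconstruct each masked letter
        std::uniform_real_distribution<double> unif(0.0, 1.0);
        const uword ncol = Xb.n_cols;
        for (uword i = 0; i < bs; ++i)
          for (uword r = 0; r < Xb.n_rows; ++r)
            if (unif(rng) < input_mask_prob) {
              rowvec row = Xb.slice(i).row(r);
              uword letter = row.index_max();
              if (accu(row) > 0.0 && letter < 4) { // a plain letter row
                Xb.slice(i).row(r).zeros();
                Xb(r, ncol - 1, i) = 1.0; // N column is last
                mlm.push_back({i, r, letter});
              }
            }
      }
      Cache c; Grads g;
      forward(p, Xb, c, true, dropout, &rng);
      double mloss = 0.0;
      eploss += backward(p, Xb, c, yb, g, mlm, mlm_weight, &mloss); ++nb;
      epmlm += mloss;

      std::vector<mat*> gm; std::vector<vec*> gv; collect_g(g, gm, gv);
      if (clip > 0) {
        double nrm2 = 0.0;
        for (auto* m : gm) nrm2 += accu(square(*m));
        for (auto* v : gv) nrm2 += accu(square(*v));
        double nrm = std::sqrt(nrm2);
        if (nrm > clip) {
          double s = clip / nrm;
          for (auto* m : gm) *m *= s;
          for (auto* v : gv) *v *= s;
        }
      }
      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2a, (double)step)) /
                    (1.0 - std::pow(b1a, (double)step));
      for (size_t i = 0; i < pm.size(); ++i) {
        mM[i] = b1a * mM[i] + (1 - b1a) * (*gm[i]);
        vM[i] = b2a * vM[i] + (1 - b2a) * square(*gm[i]);
        // decoupled weight decay on weight matrices only (not biases)
        *pm[i] -= corr * mM[i] / (sqrt(vM[i]) + eps) + lr * weight_decay * (*pm[i]);
      }
      for (size_t i = 0; i < pv.size(); ++i) {
        mV[i] = b1a * mV[i] + (1 - b1a) * (*gv[i]);
        vV[i] = b2a * vV[i] + (1 - b2a) * square(*gv[i]);
        *pv[i] -= corr * mV[i] / (sqrt(vV[i]) + eps);
      }
    }
    losses.push_back(eploss / std::max(nb, 1));
    mlm_losses.push_back(epmlm / std::max(nb, 1));
  }
  return List::create(Named("params") = params_to_list(p),
                      Named("loss") = losses,
                      Named("mlm_loss") = mlm_losses);
}
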