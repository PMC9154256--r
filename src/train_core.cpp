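// Compiled training core for the paired functional-similarity network.
// Mirrors the R reference implementation (forward_batch / backward_batch /
// adam_update); the R path stays available as engine = "r" and the test
// suite asserts the two agree on deterministic forward/gradient math.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Net {
  std::vector<mat> emb;          // per channel: V x d
  mat Wg; rowvec bg;             // gene dense
  mat Wh; rowvec bh; mat WT; rowvec bT; // highway
  mat Wp; rowvec bp;             // post-highway dense
  rowvec wout; double bout;      // head
};

Net net_from_list(const List& p) {
  Net n;
  List emb = p["embedding"];
  for (int i = 0; i < emb.size(); ++i) n.emb.push_back(as<mat>(emb[i]));
  List gene = p["gene"], hw = p["highway"], post = p["post"], head = p["head"];
  n.Wg = as<mat>(gene["W"]); n.bg = as<rowvec>(gene["b"]);
  n.Wh = as<mat>(hw["Wh"]); n.bh = as<rowvec>(hw["bh"]);
  n.WT = as<mat>(hw["WT"]); n.bT = as<rowvec>(hw["bT"]);
  n.Wp = as<mat>(post["W"]); n.bp = as<rowvec>(post["b"]);
  n.wout = as<mat>(head["W"]).row(0); n.bout = as<double>(head["b"]);
  return n;
}

List net_to_list(const Net& n, const CharacterVector& channels) {
  List emb(n.emb.size());
  for (size_t i = 0; i < n.emb.size(); ++i) emb[i] = wrap(n.emb[i]);
  emb.attr("names") = channels;
  return List::create(
    Named("embedding") = emb,
    Named("gene") = List::create(Named("W") = n.Wg, Named("b") = n.bg),
    Named("highway") = List::create(Named("Wh") = n.Wh, Named("bh") = n.bh,
                                    Named("WT") = n.WT, Named("bT") = n.bT),
    Named("post") = List::create(Named("W") = n.Wp, Named("b") = n.bp),
    Named("head") = List::create(Named("W") = n.wout, Named("b") = n.bout));
}

Net zeros_like(const Net& n) {
  Net z;
  for (const mat& e : n.emb) z.emb.push_back(mat(arma::size(e), arma::fill::zeros));
  z.Wg = mat(arma::size(n.Wg), arma::fill::zeros); z.bg = rowvec(n.bg.n_elem, arma::fill::zeros);
  z.Wh = mat(arma::size(n.Wh), arma::fill::zeros); z.bh = rowvec(n.bh.n_elem, arma::fill::zeros);
  z.WT = mat(arma::size(n.WT), arma::fill::zeros); z.bT = rowvec(n.bT.n_elem, arma::fill::zeros);
  z.Wp = mat(arma::size(n.Wp), arma::fill::zeros); z.bp = rowvec(n.bp.n_elem, arma::fill::zeros);
  z.wout = rowvec(n.wout.n_elem, arma::fill::zeros); z.bout = 0.0;
  return z;
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// max over annotation slots; A records the winning slot (0-based)
void pool(const arma::imat& I, const mat& E, const arma::uvec& rows,
          double pad_value, mat& P, arma::umat& A, arma::uword col_off) {
  const arma::uword n = rows.n_elem, t0 = I.n_cols, d = E.n_cols;
  for (arma::uword i = 0; i < n; ++i) {
    const arma::uword r = rows[i];
    if (I(r, 0) == 0) stop("A gene with no real annotations reached the network.");
    for (arma::uword j = 0; j < d; ++j) {
      double best = pad_value; arma::uword slot = 0;
      for (arma::uword l = 0; l < t0; ++l) {
        const int idx = I(r, l);
        if (idx == 0) break;
        const double v = E(idx - 1, j);
        if (v > best) { best = v; slot = l; }
      }
      P(i, col_off + j) = best;
      A(i, col_off + j) = slot;
    }
  }
}

mat dropout_mask(arma::uword n, arma::uword d, double p) {
  mat m(n, d);
  const double scale = 1.0 / (1.0 - p);
  for (arma::uword j = 0; j < d; ++j)
    for (arma::uword i = 0; i < n; ++i)
      m(i, j) = (R::unif_rand() >= p) ? scale : 0.0;
  return m;
}

struct LegCache {
  mat Z0, H, Hd;
  std::vector<arma::umat> A; // per channel argmax (n x d_emb)
  mat mask;                  // empty when no dropout
};

struct FwdCache {
  LegCache a, b;
  mat X, Hh, Tg, Xh, Xhd, P, Pd, mH, mP;
  vec s, score;
};

void leg_forward(const std::vector<arma::imat>& I, const arma::uvec& rows,
                 const Net& net, double pad_value, double p_drop, bool train,
                 LegCache& leg) {
  const arma::uword n = rows.n_elem;
  arma::uword dsum = 0;
  for (const mat& e : net.emb) dsum += e.n_cols;
  leg.Z0.set_size(n, dsum);
  leg.A.assign(net.emb.size(), arma::umat());
  arma::umat Aall(n, dsum);
  arma::uword off = 0;
  for (size_t c = 0; c < net.emb.size(); ++c) {
    pool(I[c], net.emb[c], rows, pad_value, leg.Z0, Aall, off);
    leg.A[c] = Aall.cols(off, off + net.emb[c].n_cols - 1);
    off += net.emb[c].n_cols;
  }
  mat pre = leg.Z0 * net.Wg.t();
  pre.each_row() += net.bg;
  leg.H = arma::clamp(pre, 0.0, arma::datum::inf);
  if (train && p_drop > 0) {
    leg.mask = dropout_mask(n, leg.H.n_cols, p_drop);
    leg.Hd = leg.H % leg.mask;
  } else {
    leg.mask.reset();
    leg.Hd = leg.H;
  }
}

void forward(const std::vector<arma::imat>& IA, const std::vector<arma::imat>& IB,
             const arma::uvec& rows, const Net& net, int task, double pad_value,
             double p_drop, bool train, FwdCache& fw) {
  leg_forward(IA, rows, net, pad_value, p_drop, train, fw.a);
  leg_forward(IB, rows, net, pad_value, p_drop, train, fw.b);
  fw.X = arma::join_rows(fw.a.Hd, fw.b.Hd);
  mat preh = fw.X * net.Wh.t(); preh.each_row() += net.bh;
  fw.Hh = sigmoid(preh);
  mat pret = fw.X * net.WT.t(); pret.each_row() += net.bT;
  fw.Tg = sigmoid(pret);
  fw.Xh = fw.Hh % fw.Tg + fw.X % (1.0 - fw.Tg);
  if (train && p_drop > 0) {
    fw.mH = dropout_mask(fw.Xh.n_rows, fw.Xh.n_cols, p_drop);
    fw.Xhd = fw.Xh % fw.mH;
  } else { fw.mH.reset(); fw.Xhd = fw.Xh; }
  mat prep = fw.Xhd * net.Wp.t(); prep.each_row() += net.bp;
  fw.P = arma::clamp(prep, 0.0, arma::datum::inf);
  if (train && p_drop > 0) {
    fw.mP = dropout_mask(fw.P.n_rows, fw.P.n_cols, p_drop);
    fw.Pd = fw.P % fw.mP;
  } else { fw.mP.reset(); fw.Pd = fw.P; }
  fw.s = fw.Pd * net.wout.t() + net.bout;
  fw.score = (task == 1) ? vec(1.0 / (1.0 + arma::exp(-fw.s))) : fw.s;
}

double loss_of(const vec& score, const vec& y, int task) {
  if (task == 1) {
    vec p = arma::clamp(score, 1e-12, 1.0 - 1e-12);
    return arma::mean(-(y % arma::log(p) + (1.0 - y) % arma::log(1.0 - p)));
  }
  return arma::mean(arma::square(score - y));
}

void scatter_emb(const arma::imat& I, const arma::umat& A, const mat& G,
                 const arma::uvec& rows, mat& gE) {
  const arma::uword n = rows.n_elem, d = G.n_cols;
  for (arma::uword j = 0; j < d; ++j)
    for (arma::uword i = 0; i < n; ++i) {
      const int idx = I(rows[i], A(i, j));
      if (idx > 0) gE(idx - 1, j) += G(i, j);
    }
}

void backward(const std::vector<arma::imat>& IA, const std::vector<arma::imat>& IB,
              const arma::uvec& rows, const vec& y, const FwdCache& fw,
              const Net& net, int task, bool need_emb, Net& g) {
  const double n = double(rows.n_elem);
  vec g_s = (task == 1) ? vec((fw.score - y) / n) : vec(2.0 * (fw.score - y) / n);
  g.wout = g_s.t() * fw.Pd;
  g.bout = arma::accu(g_s);
  mat dPd = g_s * net.wout;
  mat dP = fw.mP.n_elem ? mat(dPd % fw.mP) : dPd;
  mat dZp = dP % arma::conv_to<mat>::from(fw.P > 0);
  g.Wp = dZp.t() * fw.Xhd;
  g.bp = arma::sum(dZp, 0);
  mat dXhd = dZp * net.Wp;
  mat dXh = fw.mH.n_elem ? mat(dXhd % fw.mH) : dXhd;

  mat dHh = dXh % fw.Tg;
  mat dTg = dXh % (fw.Hh - fw.X);
  mat dZh = dHh % fw.Hh % (1.0 - fw.Hh);
  mat dZT = dTg % fw.Tg % (1.0 - fw.Tg);
  g.Wh = dZh.t() * fw.X; g.bh = arma::sum(dZh, 0);
  g.WT = dZT.t() * fw.X; g.bT = arma::sum(dZT, 0);
  mat dX = dXh % (1.0 - fw.Tg) + dZh * net.Wh + dZT * net.WT;

  const arma::uword dg = net.Wg.n_rows;
  g.Wg.zeros(); g.bg.zeros();
  for (mat& e : g.emb) e.zeros();
  for (int side = 0; side < 2; ++side) {
    const LegCache& leg = side == 0 ? fw.a : fw.b;
    const std::vector<arma::imat>& I = side == 0 ? IA : IB;
    mat dHd = side == 0 ? dX.cols(0, dg - 1) : dX.cols(dg, 2 * dg - 1);
    mat dH = leg.mask.n_elem ? mat(dHd % leg.mask) : dHd;
    mat dZg = dH % arma::conv_to<mat>::from(leg.H > 0);
    g.Wg += dZg.t() * leg.Z0;
    g.bg += arma::sum(dZg, 0);
    if (need_emb) {
      mat dZ0 = dZg * net.Wg;
      arma::uword off = 0;
      for (size_t c = 0; c < net.emb.size(); ++c) {
        const arma::uword d = net.emb[c].n_cols;
        scatter_emb(I[c], leg.A[c], dZ0.cols(off, off + d - 1), rows, g.emb[c]);
        off += d;
      }
    }
  }
}

struct Adam { Net m, v; long t = 0; };

inline void adam_step(mat& p, const mat& g, mat& m, mat& v, double lr,
                      double wd, double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * arma::square(g);
  p -= lr * ((m / c1) / (arma::sqrt(v / c2) + 1e-8) + wd * p);
}
inline void adam_step(rowvec& p, const rowvec& g, rowvec& m, rowvec& v,
                      double lr, double wd, double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * arma::square(g);
  p -= lr * ((m / c1) / (arma::sqrt(v / c2) + 1e-8) + wd * p);
}

void adam_update(Net& net, const Net& g, Adam& st, double lr, double wd,
                 double emb_scale, bool freeze_emb) {
  st.t += 1;
  const double c1 = 1.0 - std::pow(0.9, double(st.t));
  const double c2 = 1.0 - std::pow(0.999, double(st.t));
  if (!freeze_emb && emb_scale > 0)
    for (size_t c = 0; c < net.emb.size(); ++c)
      adam_step(net.emb[c], g.emb[c], st.m.emb[c], st.v.emb[c], lr * emb_scale, 0.0, c1, c2);
  adam_step(net.Wg, g.Wg, st.m.Wg, st.v.Wg, lr, wd, c1, c2);
  adam_step(net.bg, g.bg, st.m.bg, st.v.bg, lr, 0.0, c1, c2);
  adam_step(net.Wh, g.Wh, st.m.Wh, st.v.Wh, lr, wd, c1, c2);
  adam_step(net.bh, g.bh, st.m.bh, st.v.bh, lr, 0.0, c1, c2);
  adam_step(net.WT, g.WT, st.m.WT, st.v.WT, lr, wd, c1, c2);
  adam_step(net.bT, g.bT, st.m.bT, st.v.bT, lr, 0.0, c1, c2);
  adam_step(net.Wp, g.Wp, st.m.Wp, st.v.Wp, lr, wd, c1, c2);
  adam_step(net.bp, g.bp, st.m.bp, st.v.bp, lr, 0.0, c1, c2);
  adam_step(net.wout, g.wout, st.m.wout, st.v.wout, lr, wd, c1, c2);
  {
    st.m.bout = 0.9 * st.m.bout + 0.1 * g.bout;
    st.v.bout = 0.999 * st.v.bout + 0.001 * g.bout * g.bout;
    net.bout -= lr * (st.m.bout / c1) / (std::sqrt(st.v.bout / c2) + 1e-8);
  }
}

std::vector<arma::imat> imats(const List& l) {
  std::vector<arma::imat> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<arma::imat>(l[i]));
  return out;
}

} // namespace

// Runs the full minibatch training loop with Adam, dropout and (optionally)
// early stopping on a validation split. Index matrices are the padded
// per-channel annotation encodings of the ordered pairs; both orders of each
// pair are expected to be present already (order augmentation).
// [[Rcpp::export(name = ".train_core_cpp")]]
List train_core_cpp(List IA, List IB, NumericVector y,
                    List IAv, List IBv, NumericVector yv, bool has_val,
                    List params0, CharacterVector channels, int task,
                    double pad_value, double dropout, double lr,
                    double weight_decay, double emb_lr_scale, bool freeze_emb,
                    int batch_size, int max_epochs, int patience,
                    int monitor) { // 0 = validation loss, 1 = validation error rate
  Net net = net_from_list(params0);
  Adam st; st.m = zeros_like(net); st.v = zeros_like(net);
  Net grad = zeros_like(net);

  std::vector<arma::imat> ia = imats(IA), ib = imats(IB), iav, ibv;
  vec yy = as<vec>(y), yyv;
  if (has_val) { iav = imats(IAv); ibv = imats(IBv); yyv = as<vec>(yv); }
  const arma::uword n = yy.n_elem;
  arma::uvec all_val;
  if (has_val) all_val = arma::regspace<arma::uvec>(0, yyv.n_elem - 1);

  std::vector<double> hist_train, hist_val;
  double best_val = arma::datum::inf;
  Net best = net;
  int best_epoch = 0, wait = 0;
  FwdCache fw;

  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG for seed control
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = arma::uword(R::unif_rand() * double(i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double tl = 0.0;
    for (arma::uword s0 = 0; s0 < n; s0 += batch_size) {
      const arma::uword s1 = std::min<arma::uword>(s0 + batch_size, n) - 1;
      arma::uvec rows(s1 - s0 + 1);
      for (arma::uword k = 0; k < rows.n_elem; ++k) rows[k] = order[s0 + k];
      vec yb = yy.elem(rows);
      forward(ia, ib, rows, net, task, pad_value, dropout, true, fw);
      backward(ia, ib, rows, yb, fw, net, task, !freeze_emb && emb_lr_scale > 0, grad);
      adam_update(net, grad, st, lr, weight_decay, emb_lr_scale, freeze_emb);
      tl += loss_of(fw.score, yb, task) * double(rows.n_elem);
    }
    hist_train.push_back(tl / double(n));
    if (has_val) {
      forward(iav, ibv, all_val, net, task, pad_value, 0.0, false, fw);
      const double vl = loss_of(fw.score, yyv, task);
      hist_val.push_back(vl);
      double crit = vl;
      if (monitor == 1 && task == 1) {
        crit = arma::mean(arma::conv_to<vec>::from((fw.score >= 0.5) != (yyv >= 0.5)));
      }
      if (crit < best_val - 1e-6) {
        best_val = crit; best = net; best_epoch = epoch; wait = 0;
      } else if (++wait >= patience) break;
    } else {
      best = net; best_epoch = epoch;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    Named("params") = net_to_list(best, channels),
    Named("train_loss") = hist_train,
    Named("val_loss") = hist_val,
    Named("best_epoch") = best_epoch,
    Named("best_val") = has_val ? best_val : NA_REAL);
}

// Deterministic batched forward pass (no dropout) used at prediction time.
// [[Rcpp::export(name = ".forward_core_cpp")]]
NumericVector forward_core_cpp(List IA, List IB, List params,
                               int task, double pad_value) {
  Net net = net_from_list(params);
  std::vector<arma::imat> ia = imats(IA), ib = imats(IB);
  const arma::uword n = ia[0].n_rows;
  arma::uvec rows = arma::regspace<arma::uvec>(0, n - 1);
  FwdCache fw;
  forward(ia, ib, rows, net, task, pad_value, 0.0, false, fw);
  return wrap(fw.score);
}
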