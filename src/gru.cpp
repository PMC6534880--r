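// Stacked-GRU sequence model: teacher-forced forward/backward and a
// single sampling step.  Parameters arrive as an R list of matrices:
//   E            (V x emb)  token embedding
//   Wx<l>, Wh<l> (in x 3H), (H x 3H)  gate weights, order [z | r | n]
//   bx<l>, bh<l> (1 x 3H)   gate biases (separate input/hidden biases,
//                           needed for the reset-gated candidate term)
//   Wo, bo       (H x V), (1 x V)  output projection
// Gate equations (l = layer input x, h = previous hidden state):
//   z = sigmoid(x Wxz + bxz + h Whz + bhz)
//   r = sigmoid(x Wxr + bxr + h Whr + bhr)
//   n = tanh   (x Wxn + bxn + r .* (h Whn + bhn))
//   h' = (1 - z) .* n + z .* h
// The scalar objective is sum_b w_b * sum_t mask_bt * nll_bt / norm,
// which covers both maximum likelihood (w = 1, norm = #tokens) and the
// policy gradient (w = advantage, norm = batch size).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

struct GruParams {
  arma::mat E, Wo, bo;
  std::vector<arma::mat> Wx, Wh, bx, bh;
  int L, H, V, emb;
};

static GruParams unpack(const List& params, int layers, int hidden) {
  GruParams p;
  p.L = layers;
  p.H = hidden;
  p.E = as<arma::mat>(params["E"]);
  p.V = p.E.n_rows;
  p.emb = p.E.n_cols;
  for (int l = 1; l <= layers; ++l) {
    std::string s = std::to_string(l);
    p.Wx.push_back(as<arma::mat>(params["Wx" + s]));
    p.Wh.push_back(as<arma::mat>(params["Wh" + s]));
    p.bx.push_back(as<arma::mat>(params["bx" + s]));
    p.bh.push_back(as<arma::mat>(params["bh" + s]));
  }
  p.Wo = as<arma::mat>(params["Wo"]);
  p.bo = as<arma::mat>(params["bo"]);
  return p;
}

// One GRU cell step for layer l; stores gate activations if requested.
static arma::mat cell_forward(const GruParams& p, int l, const arma::mat& x,
                              const arma::mat& hprev, arma::mat* Zs,
                              arma::mat* Rs, arma::mat* Ns, arma::mat* Vs) {
  const int H = p.H;
  arma::mat ax = x * p.Wx[l];
  ax.each_row() += p.bx[l].row(0);
  arma::mat ah = hprev * p.Wh[l];
  ah.each_row() += p.bh[l].row(0);
  arma::mat z = sigmoid(ax.cols(0, H - 1) + ah.cols(0, H - 1));
  arma::mat r = sigmoid(ax.cols(H, 2 * H - 1) + ah.cols(H, 2 * H - 1));
  arma::mat v = ah.cols(2 * H, 3 * H - 1);
  arma::mat n = arma::tanh(ax.cols(2 * H, 3 * H - 1) + r % v);
  if (Zs) { *Zs = z; *Rs = r; *Ns = n; *Vs = v; }
  return (1.0 - z) % n + z % hprev;
}

// [[Rcpp::export]]
List cpp_gru_forward_backward(List params, int layers, int hidden,
                              IntegerMatrix input, IntegerMatrix target,
                              NumericMatrix mask, NumericVector weights,
                              double norm, bool compute_grad) {
  GruParams p = unpack(params, layers, hidden);
  const int B = input.nrow(), T = input.ncol(), H = p.H, V = p.V;
  const arma::mat maskM(mask.begin(), B, T, false);
  const arma::vec w(weights.begin(), B, false);

  // stored activations: [layer][t]
  std::vector<std::vector<arma::mat>> Zs(layers), Rs(layers), Ns(layers),
      Vs(layers), Hs(layers);
  std::vector<arma::mat> Xemb(T);
  for (int l = 0; l < layers; ++l) {
    Hs[l].resize(T + 1);
    Hs[l][0] = arma::zeros(B, H);
    if (compute_grad) {
      Zs[l].resize(T); Rs[l].resize(T); Ns[l].resize(T); Vs[l].resize(T);
    }
  }

  arma::vec seq_nll = arma::zeros(B);
  double loss = 0.0;
  arma::mat dWo, dbo;
  std::vector<arma::mat> dOut(T);  // dH at top layer from the loss
  if (compute_grad) {
    dWo = arma::zeros(arma::size(p.Wo));
    dbo = arma::zeros(arma::size(p.bo));
  }

  for (int t = 0; t < T; ++t) {
    arma::mat x(B, p.emb);
    for (int b = 0; b < B; ++b) x.row(b) = p.E.row(input(b, t));
    Xemb[t] = x;
    for (int l = 0; l < layers; ++l) {
      arma::mat h = cell_forward(
          p, l, l == 0 ? Xemb[t] : Hs[l - 1][t + 1], Hs[l][t],
          compute_grad ? &Zs[l][t] : nullptr, compute_grad ? &Rs[l][t] : nullptr,
          compute_grad ? &Ns[l][t] : nullptr, compute_grad ? &Vs[l][t] : nullptr);
      Hs[l][t + 1] = h;
    }
    // output + log-softmax + NLL at this step
    arma::mat logits = Hs[layers - 1][t + 1] * p.Wo;
    logits.each_row() += p.bo.row(0);
    arma::vec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    arma::mat ex = arma::exp(logits);
    arma::vec Zden = arma::sum(ex, 1);
    arma::mat prob = ex.each_col() / Zden;
    arma::vec lognorm = arma::log(Zden);
    arma::mat dO;
    if (compute_grad) dO = prob;
    for (int b = 0; b < B; ++b) {
      double m = maskM(b, t);
      if (m > 0.0) {
        int y = target(b, t);
        double nll = -(logits(b, y) - lognorm(b));
        seq_nll(b) += m * nll;
        loss += w(b) * m * nll / norm;
        if (compute_grad) dO(b, y) -= 1.0;
      }
      if (compute_grad) dO.row(b) *= w(b) * maskM(b, t) / norm;
    }
    if (compute_grad) {
      dWo += Hs[layers - 1][t + 1].t() * dO;
      dbo += arma::sum(dO, 0);
      dOut[t] = dO * p.Wo.t();
    }
  }

  List out = List::create(Named("loss") = loss,
                          Named("seq_nll") = NumericVector(seq_nll.begin(),
                                                           seq_nll.end()));
  if (!compute_grad) return out;

  // ---- backward through time, top layer first within each step ----
  arma::mat dE = arma::zeros(arma::size(p.E));
  std::vector<arma::mat> dWx(layers), dWh(layers), dbx(layers), dbh(layers),
      carry(layers);
  for (int l = 0; l < layers; ++l) {
    dWx[l] = arma::zeros(arma::size(p.Wx[l]));
    dWh[l] = arma::zeros(arma::size(p.Wh[l]));
    dbx[l] = arma::zeros(arma::size(p.bx[l]));
    dbh[l] = arma::zeros(arma::size(p.bh[l]));
    carry[l] = arma::zeros(B, H);
  }
  for (int t = T - 1; t >= 0; --t) {
    arma::mat dh_from_above = dOut[t];
    for (int l = layers - 1; l >= 0; --l) {
      arma::mat dh = dh_from_above + carry[l];
      const arma::mat &z = Zs[l][t], &r = Rs[l][t], &n = Ns[l][t],
                      &v = Vs[l][t], &hprev = Hs[l][t];
      const arma::mat& xin = (l == 0) ? Xemb[t] : Hs[l - 1][t + 1];
      arma::mat dn = dh % (1.0 - z);
      arma::mat dz = dh % (hprev - n);
      arma::mat dhprev = dh % z;
      arma::mat dan = dn % (1.0 - n % n);
      arma::mat dr = dan % v;
      arma::mat dv = dan % r;
      arma::mat daz = dz % z % (1.0 - z);
      arma::mat dar = dr % r % (1.0 - r);
      arma::mat dAx = arma::join_rows(daz, arma::join_rows(dar, dan));
      arma::mat dAh = arma::join_rows(daz, arma::join_rows(dar, dv));
      dWx[l] += xin.t() * dAx;
      dWh[l] += hprev.t() * dAh;
      dbx[l] += arma::sum(dAx, 0);
      dbh[l] += arma::sum(dAh, 0);
      dhprev += dAh * p.Wh[l].t();
      carry[l] = dhprev;
      dh_from_above = dAx * p.Wx[l].t();  // gradient w.r.t. layer input
    }
    for (int b = 0; b < B; ++b) dE.row(input(b, t)) += dh_from_above.row(b);
  }

  List grads;
  grads["E"] = wrap(dE);
  for (int l = 0; l < layers; ++l) {
    std::string s = std::to_string(l + 1);
    grads["Wx" + s] = wrap(dWx[l]);
    grads["Wh" + s] = wrap(dWh[l]);
    grads["bx" + s] = wrap(dbx[l]);
    grads["bh" + s] = wrap(dbh[l]);
  }
  grads["Wo"] = wrap(dWo);
  grads["bo"] = wrap(dbo);
  out["grads"] = grads;
  return out;
}

// One autoregressive step: previous token indices (0-based) and the
// stacked hidden state (B x L*H) in, token probabilities and the new
// hidden state out.
// [[Rcpp::export]]
List cpp_gru_step(List params, int layers, int hidden, IntegerVector prev,
                  NumericMatrix hstate) {
  GruParams p = unpack(params, layers, hidden);
  const int B = prev.size(), H = p.H;
  arma::mat h(hstate.begin(), B, layers * H);
  arma::mat x(B, p.emb);
  for (int b = 0; b < B; ++b) x.row(b) = p.E.row(prev[b]);
  arma::mat hnew(B, layers * H);
  for (int l = 0; l < layers; ++l) {
    arma::mat hl = cell_forward(p, l, x, h.cols(l * H, (l + 1) * H - 1),
                                nullptr, nullptr, nullptr, nullptr);
    hnew.cols(l * H, (l + 1) * H - 1) = hl;
    x = hl;
  }
  arma::mat logits = x * p.Wo;
  logits.each_row() += p.bo.row(0);
  logits.each_col() -= arma::max(logits, 1);
  arma::mat ex = arma::exp(logits);
  arma::mat prob = ex.each_col() / arma::sum(ex, 1);
  return List::create(Named("probs") = wrap(prob), Named("h") = wrap(hnew));
}
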