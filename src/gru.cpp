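// Bidirectional GRU sequence classifier: forward pass and full
// backpropagation-through-time gradients.
//
// Layout conventions:
//   X: cube (input_dim x batch x time); slice t is the frame at time t.
//   Per layer and direction: Wi (3H x D), Wh (3H x H), bi (3H), bh (3H),
//   gate row blocks ordered [reset; update; candidate] as in standard GRU
//   formulations with the candidate's hidden term gated by reset:
//     r = sigma(Wi_r x + bi_r + Wh_r h + bh_r)
//     z = sigma(Wi_z x + bi_z + Wh_z h + bh_z)
//     n = tanh(Wi_n x + bi_n + r .* (Wh_n h + bh_n))
//     h' = (1 - z) .* n + z .* h
//   Layer l > 0 consumes the time-aligned concatenation [h_fwd; h_bwd] of
//   layer l-1.  The head applies a linear map to the temporal mean of the
//   top layer's concatenated outputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

namespace {

struct DirCache {
  cube hout, hprev, r, z, n, hn;
};

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Run one GRU direction over the input cube; fills the cache.
void run_direction(const mat& Wi, const mat& Wh, const vec& bi,
                   const vec& bh, const cube& X, bool reverse,
                   DirCache& c) {
  const uword H = Wh.n_cols, N = X.n_cols, T = X.n_slices;
  c.hout.set_size(H, N, T);
  c.hprev.set_size(H, N, T);
  c.r.set_size(H, N, T);
  c.z.set_size(H, N, T);
  c.n.set_size(H, N, T);
  c.hn.set_size(H, N, T);
  mat h(H, N, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? (T - 1 - step) : step;
    mat a = Wi * X.slice(t);
    a.each_col() += bi;
    mat g = Wh * h;
    g.each_col() += bh;
    mat r = sigmoid(a.rows(0, H - 1) + g.rows(0, H - 1));
    mat z = sigmoid(a.rows(H, 2 * H - 1) + g.rows(H, 2 * H - 1));
    mat hn = g.rows(2 * H, 3 * H - 1);
    mat n = tanh(a.rows(2 * H, 3 * H - 1) + r % hn);
    c.hprev.slice(t) = h;
    c.r.slice(t) = r;
    c.z.slice(t) = z;
    c.n.slice(t) = n;
    c.hn.slice(t) = hn;
    h = (1.0 - z) % n + z % h;
    c.hout.slice(t) = h;
  }
}

// Backward through one direction.  dHout: gradient w.r.t. every output
// h_t.  Returns gradient w.r.t. the direction's input cube and fills the
// parameter gradients.
cube back_direction(const mat& Wi, const mat& Wh, const cube& X,
                    bool reverse, const DirCache& c, const cube& dHout,
                    mat& dWi, mat& dWh, vec& dbi, vec& dbh) {
  const uword H = Wh.n_cols, N = X.n_cols, T = X.n_slices;
  dWi.zeros(Wi.n_rows, Wi.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  dbi.zeros(3 * H);
  dbh.zeros(3 * H);
  cube dX(X.n_rows, N, T, fill::zeros);
  mat dh_next(H, N, fill::zeros);
  for (uword step = T; step-- > 0;) {
    uword t = reverse ? (T - 1 - step) : step;
    mat dh = dHout.slice(t) + dh_next;
    const mat& r = c.r.slice(t);
    const mat& z = c.z.slice(t);
    const mat& n = c.n.slice(t);
    const mat& hn = c.hn.slice(t);
    const mat& hprev = c.hprev.slice(t);
    mat dz = dh % (hprev - n);
    mat dan = (dh % (1.0 - z)) % (1.0 - n % n);
    mat dar = (dan % hn) % r % (1.0 - r);
    mat daz = dz % z % (1.0 - z);
    mat da = join_cols(dar, daz, dan);
    mat dg = join_cols(dar, daz, dan % r);
    dWi += da * X.slice(t).t();
    dWh += dg * hprev.t();
    dbi += sum(da, 1);
    dbh += sum(dg, 1);
    dX.slice(t) = Wi.t() * da;
    dh_next = dh % z + Wh.t() * dg;
  }
  return dX;
}

// Forward through the full stack; caches per layer/direction and the
// per-layer input cubes.
void forward_stack(const List& layers, const cube& X,
                   std::vector<DirCache>& cf, std::vector<DirCache>& cb,
                   std::vector<cube>& inputs, cube& top) {
  const int L = layers.size();
  cf.resize(L);
  cb.resize(L);
  inputs.resize(L);
  cube cur = X;
  for (int l = 0; l < L; ++l) {
    inputs[l] = cur;
    List lay = layers[l];
    List f = lay["fwd"], b = lay["bwd"];
    run_direction(as<mat>(f["Wi"]), as<mat>(f["Wh"]), as<vec>(f["bi"]),
                  as<vec>(f["bh"]), cur, false, cf[l]);
    run_direction(as<mat>(b["Wi"]), as<mat>(b["Wh"]), as<vec>(b["bi"]),
                  as<vec>(b["bh"]), cur, true, cb[l]);
    const uword H = cf[l].hout.n_rows, N = cur.n_cols, T = cur.n_slices;
    cube cat(2 * H, N, T);
    for (uword t = 0; t < T; ++t) {
      cat.slice(t) = join_cols(cf[l].hout.slice(t), cb[l].hout.slice(t));
    }
    cur = cat;
  }
  top = cur;
}

mat pooled_logits(const cube& top, const mat& headW, const vec& headb,
                  mat& feat) {
  feat = mean(top, 2);           // (2H x N)
  mat logits = headW * feat;     // (C x N)
  logits.each_col() += headb;
  return logits;
}

}  // namespace

// [[Rcpp::export(name = ".gru_forward_cpp")]]
List gru_forward_cpp(List layers, arma::mat headW, arma::vec headb,
                     arma::cube X) {
  std::vector<DirCache> cf, cb;
  std::vector<cube> inputs;
  cube top;
  forward_stack(layers, X, cf, cb, inputs, top);
  mat feat;
  mat logits = pooled_logits(top, headW, headb, feat);
  return List::create(_["logits"] = logits.t(), _["features"] = feat.t());
}

// [[Rcpp::export(name = ".gru_loss_grad_cpp")]]
List gru_loss_grad_cpp(List layers, arma::mat headW, arma::vec headb,
                       arma::cube X, arma::uvec y) {
  const uword N = X.n_cols, T = X.n_slices;
  std::vector<DirCache> cf, cb;
  std::vector<cube> inputs;
  cube top;
  forward_stack(layers, X, cf, cb, inputs, top);
  mat feat;
  mat logits = pooled_logits(top, headW, headb, feat);

  // softmax cross-entropy, mean over the batch
  mat shifted = logits.each_row() - max(logits, 0);
  mat expv = exp(shifted);
  rowvec denom = sum(expv, 0);
  mat probs = expv.each_row() / denom;
  double loss = 0.0;
  for (uword i = 0; i < N; ++i) {
    loss -= shifted(y[i], i) - std::log(denom[i]);
  }
  loss /= N;
  mat dlogits = probs;
  for (uword i = 0; i < N; ++i) dlogits(y[i], i) -= 1.0;
  dlogits /= static_cast<double>(N);

  mat dheadW = dlogits * feat.t();
  vec dheadb = sum(dlogits, 1);
  mat dfeat = headW.t() * dlogits;       // (2H x N)

  const int L = layers.size();
  // gradient w.r.t. top-layer outputs: mean pooling spreads dfeat / T
  const uword H2 = dfeat.n_rows;
  cube dcur(H2, N, T);
  mat per_t = dfeat / static_cast<double>(T);
  for (uword t = 0; t < T; ++t) dcur.slice(t) = per_t;

  List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    List lay = layers[l];
    List f = lay["fwd"], b = lay["bwd"];
    const uword H = as<mat>(f["Wh"]).n_cols;
    cube dHf(H, N, T), dHb(H, N, T);
    for (uword t = 0; t < T; ++t) {
      dHf.slice(t) = dcur.slice(t).rows(0, H - 1);
      dHb.slice(t) = dcur.slice(t).rows(H, 2 * H - 1);
    }
    mat dWi_f, dWh_f, dWi_b, dWh_b;
    vec dbi_f, dbh_f, dbi_b, dbh_b;
    cube dXf = back_direction(as<mat>(f["Wi"]), as<mat>(f["Wh"]),
                              inputs[l], false, cf[l], dHf, dWi_f, dWh_f,
                              dbi_f, dbh_f);
    cube dXb = back_direction(as<mat>(b["Wi"]), as<mat>(b["Wh"]),
                              inputs[l], true, cb[l], dHb, dWi_b, dWh_b,
                              dbi_b, dbh_b);
    grads[l] = List::create(
        _["fwd"] = List::create(_["Wi"] = dWi_f, _["Wh"] = dWh_f,
                                _["bi"] = dbi_f, _["bh"] = dbh_f),
        _["bwd"] = List::create(_["Wi"] = dWi_b, _["Wh"] = dWh_b,
                                _["bi"] = dbi_b, _["bh"] = dbh_b));
    dcur = dXf + dXb;
  }
  return List::create(_["loss"] = loss, _["logits"] = logits.t(),
                      _["layer_grads"] = grads, _["headW"] = dheadW,
                      _["headb"] = dheadb);
}
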