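// Batched LSTM encoder: forward pass and backpropagation through time.
// Sequences are padded row-wise (token id 0 = pad); a per-timestep mask
// carries hidden/cell state through pads so the state at t = T equals the
// state at each sequence's true length. The backward direction re-indexes
// tokens within each sequence's length, so both directions share one kernel.
// Gate layout in the stacked weight matrices is [input, forget, output, cell].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::mat sigmoid_m(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Token id (1-based, 0 = pad) for row r at logical step t of one direction.
static inline int token_at(const IntegerMatrix& tokens, const IntegerVector& lengths,
                           int r, int t, bool reverse) {
  int len = lengths[r];
  if (t >= len) return 0;
  int pos = reverse ? (len - 1 - t) : t;
  return tokens(r, pos);
}

static void embed_step(arma::mat& X, const arma::mat& Emb,
                       const IntegerMatrix& tokens, const IntegerVector& lengths,
                       int t, bool reverse) {
  int n = X.n_rows;
  for (int r = 0; r < n; ++r) {
    int id = token_at(tokens, lengths, r, t, reverse);
    if (id > 0) X.row(r) = Emb.row(id - 1); else X.row(r).zeros();
  }
}

struct DirCache {
  arma::cube I, F, O, G, C, H;  // n x hid x T, states post-mask
};

// Runs one direction; fills Hfinal (n x hid) and optionally the cache.
static void run_direction(const arma::mat& Emb, const arma::mat& W,
                          const arma::mat& U, const arma::vec& b,
                          const IntegerMatrix& tokens, const IntegerVector& lengths,
                          bool reverse, bool keep_cache,
                          arma::mat& Hfinal, DirCache* cache) {
  int n = tokens.nrow(), T = tokens.ncol();
  int hid = U.n_cols;
  arma::mat Hprev(n, hid, arma::fill::zeros), Cprev(n, hid, arma::fill::zeros);
  arma::mat X(n, Emb.n_cols);
  arma::vec mask(n);
  if (keep_cache) {
    cache->I.set_size(n, hid, T); cache->F.set_size(n, hid, T);
    cache->O.set_size(n, hid, T); cache->G.set_size(n, hid, T);
    cache->C.set_size(n, hid, T); cache->H.set_size(n, hid, T);
  }
  for (int t = 0; t < T; ++t) {
    embed_step(X, Emb, tokens, lengths, t, reverse);
    for (int r = 0; r < n; ++r) mask[r] = (t < lengths[r]) ? 1.0 : 0.0;
    arma::mat Z = X * W.t() + Hprev * U.t();
    Z.each_row() += b.t();
    arma::mat I = sigmoid_m(Z.cols(0, hid - 1));
    arma::mat F = sigmoid_m(Z.cols(hid, 2 * hid - 1));
    arma::mat O = sigmoid_m(Z.cols(2 * hid, 3 * hid - 1));
    arma::mat G = arma::tanh(Z.cols(3 * hid, 4 * hid - 1));
    arma::mat Cnew = F % Cprev + I % G;
    arma::mat Hnew = O % arma::tanh(Cnew);
    // carry previous state through padded steps
    Cnew.each_col() %= mask; Cnew += Cprev.each_col() % (1.0 - mask);
    Hnew.each_col() %= mask; Hnew += Hprev.each_col() % (1.0 - mask);
    if (keep_cache) {
      cache->I.slice(t) = I; cache->F.slice(t) = F; cache->O.slice(t) = O;
      cache->G.slice(t) = G; cache->C.slice(t) = Cnew; cache->H.slice(t) = Hnew;
    }
    Cprev = Cnew; Hprev = Hnew;
  }
  Hfinal = Hprev;
}

static List cache_to_list(const DirCache& c) {
  return List::create(_["I"] = c.I, _["F"] = c.F, _["O"] = c.O,
                      _["G"] = c.G, _["C"] = c.C, _["H"] = c.H);
}

static DirCache cache_from_list(const List& l) {
  DirCache c;
  c.I = as<arma::cube>(l["I"]); c.F = as<arma::cube>(l["F"]);
  c.O = as<arma::cube>(l["O"]); c.G = as<arma::cube>(l["G"]);
  c.C = as<arma::cube>(l["C"]); c.H = as<arma::cube>(l["H"]);
  return c;
}

// [[Rcpp::export]]
List lstm_forward_cpp(const arma::mat& Emb,
                      const arma::mat& W_f, const arma::mat& U_f, const arma::vec& b_f,
                      const arma::mat& W_b, const arma::mat& U_b, const arma::vec& b_b,
                      const IntegerMatrix& tokens, const IntegerVector& lengths,
                      bool bidirectional, bool keep_cache) {
  arma::mat Hf, Hb;
  DirCache cf, cb;
  run_direction(Emb, W_f, U_f, b_f, tokens, lengths, false, keep_cache, Hf,
                keep_cache ? &cf : nullptr);
  arma::mat Hout;
  if (bidirectional) {
    run_direction(Emb, W_b, U_b, b_b, tokens, lengths, true, keep_cache, Hb,
                  keep_cache ? &cb : nullptr);
    Hout = arma::join_rows(Hf, Hb);
  } else {
    Hout = Hf;
  }
  List out = List::create(_["H"] = Hout);
  if (keep_cache) {
    out["cache_f"] = cache_to_list(cf);
    if (bidirectional) out["cache_b"] = cache_to_list(cb);
  }
  return out;
}

// Backward through one direction; accumulates parameter gradients.
static void backward_direction(const arma::mat& Emb, const arma::mat& W,
                               const arma::mat& U,
                               const IntegerMatrix& tokens, const IntegerVector& lengths,
                               bool reverse, const DirCache& c,
                               arma::mat dh,  // n x hid, gradient at final state
                               arma::mat& dEmb, arma::mat& dW, arma::mat& dU,
                               arma::vec& db) {
  int n = tokens.nrow(), T = tokens.ncol();
  int hid = U.n_cols;
  arma::mat dc(n, hid, arma::fill::zeros);
  arma::mat X(n, Emb.n_cols);
  arma::vec mask(n);
  for (int t = T - 1; t >= 0; --t) {
    for (int r = 0; r < n; ++r) mask[r] = (t < lengths[r]) ? 1.0 : 0.0;
    arma::mat Cprev = (t > 0) ? arma::mat(c.C.slice(t - 1))
                              : arma::mat(n, hid, arma::fill::zeros);
    arma::mat Hprev = (t > 0) ? arma::mat(c.H.slice(t - 1))
                              : arma::mat(n, hid, arma::fill::zeros);
    const arma::mat I = c.I.slice(t), F = c.F.slice(t), O = c.O.slice(t),
                    G = c.G.slice(t);
    // cached C is post-mask: at active rows it is the new cell state
    arma::mat tanhC = arma::tanh(c.C.slice(t));
    arma::mat dtc = dh % O % (1.0 - tanhC % tanhC) + dc;
    arma::mat dzo = (dh % tanhC) % O % (1.0 - O);
    arma::mat dzf = (dtc % Cprev) % F % (1.0 - F);
    arma::mat dzi = (dtc % G) % I % (1.0 - I);
    arma::mat dzg = (dtc % I) % (1.0 - G % G);
    dzi.each_col() %= mask; dzf.each_col() %= mask;
    dzo.each_col() %= mask; dzg.each_col() %= mask;
    arma::mat dz = arma::join_rows(arma::join_rows(dzi, dzf),
                                   arma::join_rows(dzo, dzg));
    embed_step(X, Emb, tokens, lengths, t, reverse);
    dW += dz.t() * X;
    dU += dz.t() * Hprev;
    db += arma::sum(dz, 0).t();
    arma::mat dX = dz * W;
    for (int r = 0; r < n; ++r) {
      int id = token_at(tokens, lengths, r, t, reverse);
      if (id > 0 && mask[r] > 0.5) dEmb.row(id - 1) += dX.row(r);
    }
    arma::mat dh_prev = dz * U + (dh.each_col() % (1.0 - mask));
    arma::mat dc_prev = (dtc % F);
    dc_prev.each_col() %= mask;
    dc_prev += dc.each_col() % (1.0 - mask);
    dh = dh_prev; dc = dc_prev;
  }
}

// [[Rcpp::export]]
List lstm_backward_cpp(const arma::mat& Emb,
                       const arma::mat& W_f, const arma::mat& U_f,
                       const arma::mat& W_b, const arma::mat& U_b,
                       const IntegerMatrix& tokens, const IntegerVector& lengths,
                       bool bidirectional, const List& forward_out,
                       const arma::mat& dH) {
  int hid = U_f.n_cols;
  arma::mat dEmb(Emb.n_rows, Emb.n_cols, arma::fill::zeros);
  arma::mat dW_f(arma::size(W_f), arma::fill::zeros), dU_f(arma::size(U_f), arma::fill::zeros);
  arma::vec db_f(4 * hid, arma::fill::zeros);
  DirCache cf = cache_from_list(forward_out["cache_f"]);
  backward_direction(Emb, W_f, U_f, tokens, lengths, false, cf,
                     dH.cols(0, hid - 1), dEmb, dW_f, dU_f, db_f);
  if (bidirectional) {
    arma::mat dW_b(arma::size(W_b), arma::fill::zeros), dU_b(arma::size(U_b), arma::fill::zeros);
    arma::vec db_b(4 * hid, arma::fill::zeros);
    DirCache cb = cache_from_list(forward_out["cache_b"]);
    backward_direction(Emb, W_b, U_b, tokens, lengths, true, cb,
                       dH.cols(hid, 2 * hid - 1), dEmb, dW_b, dU_b, db_b);
    return List::create(_["dEmb"] = dEmb, _["dW_f"] = dW_f,
                        _["dU_f"] = dU_f, _["db_f"] = db_f,
                        _["dW_b"] = dW_b, _["dU_b"] = dU_b, _["db_b"] = db_b);
  }
  return List::create(_["dEmb"] = dEmb, _["dW_f"] = dW_f,
                      _["dU_f"] = dU_f, _["db_f"] = db_f);
}
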