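// Windowed transformer encoder for parcellated BOLD runs.
//
// Architecture (per forward pass):
//   tokens H0 = X' Wp + bp                      (T x d, one token per TR)
//   per block: windowed multi-head attention where each window's CLS token
//   and core BOLD tokens attend to the window's BOLD tokens plus `fringe`
//   tokens on each side; BOLD-token updates in overlapping windows are
//   averaged ("token fusion"); then a token-wise 2-layer ReLU MLP.
//   Residual connections around both sub-layers; no layer normalisation.
//   fingerprint = mean of final CLS states.
//
// The backward pass is derived by hand and checked against finite
// differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct EncCfg {
  int R, d, L, stride, fringe, blocks, heads, hidden;
  double dropout;
};

EncCfg parse_cfg(const Rcpp::List& cfg) {
  EncCfg c;
  c.R       = Rcpp::as<int>(cfg["n_regions"]);
  c.d       = Rcpp::as<int>(cfg["embed_dim"]);
  c.L       = Rcpp::as<int>(cfg["window_length"]);
  c.stride  = Rcpp::as<int>(cfg["window_stride"]);
  c.fringe  = Rcpp::as<int>(cfg["fringe_length"]);
  c.blocks  = Rcpp::as<int>(cfg["n_blocks"]);
  c.heads   = Rcpp::as<int>(cfg["n_heads"]);
  c.hidden  = Rcpp::as<int>(cfg["mlp_hidden"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  if (c.d % c.heads != 0) Rcpp::stop("embed_dim must be divisible by n_heads");
  return c;
}

struct BlockPar {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2;
};

struct Par {
  mat Wp, pos;           // Wp: R x d, pos: (L + 2*fringe) x d
  rowvec bp, cls0;
  std::vector<BlockPar> blk;
};

Par parse_params(const Rcpp::List& p, const EncCfg& c) {
  Par par;
  par.Wp   = Rcpp::as<mat>(p["Wp"]);
  par.bp   = Rcpp::as<rowvec>(p["bp"]);
  par.pos  = Rcpp::as<mat>(p["pos"]);
  par.cls0 = Rcpp::as<rowvec>(p["cls0"]);
  Rcpp::List blocks = p["blocks"];
  if ((int)blocks.size() != c.blocks) Rcpp::stop("param/block-count mismatch");
  for (int b = 0; b < c.blocks; ++b) {
    Rcpp::List bl = blocks[b];
    BlockPar bp;
    bp.Wq = Rcpp::as<mat>(bl["Wq"]); bp.Wk = Rcpp::as<mat>(bl["Wk"]);
    bp.Wv = Rcpp::as<mat>(bl["Wv"]); bp.Wo = Rcpp::as<mat>(bl["Wo"]);
    bp.W1 = Rcpp::as<mat>(bl["W1"]); bp.W2 = Rcpp::as<mat>(bl["W2"]);
    bp.bq = Rcpp::as<rowvec>(bl["bq"]); bp.bk = Rcpp::as<rowvec>(bl["bk"]);
    bp.bv = Rcpp::as<rowvec>(bl["bv"]); bp.bo = Rcpp::as<rowvec>(bl["bo"]);
    bp.b1 = Rcpp::as<rowvec>(bl["b1"]); bp.b2 = Rcpp::as<rowvec>(bl["b2"]);
    par.blk.push_back(bp);
  }
  return par;
}

void zero_like(const Par& par, Par& g) {
  g.Wp = zeros<mat>(par.Wp.n_rows, par.Wp.n_cols);
  g.bp = zeros<rowvec>(par.bp.n_elem);
  g.pos = zeros<mat>(par.pos.n_rows, par.pos.n_cols);
  g.cls0 = zeros<rowvec>(par.cls0.n_elem);
  g.blk.resize(par.blk.size());
  for (size_t b = 0; b < par.blk.size(); ++b) {
    const BlockPar& s = par.blk[b];
    BlockPar& t = g.blk[b];
    t.Wq = zeros<mat>(s.Wq.n_rows, s.Wq.n_cols);
    t.Wk = zeros<mat>(s.Wk.n_rows, s.Wk.n_cols);
    t.Wv = zeros<mat>(s.Wv.n_rows, s.Wv.n_cols);
    t.Wo = zeros<mat>(s.Wo.n_rows, s.Wo.n_cols);
    t.W1 = zeros<mat>(s.W1.n_rows, s.W1.n_cols);
    t.W2 = zeros<mat>(s.W2.n_rows, s.W2.n_cols);
    t.bq = zeros<rowvec>(s.bq.n_elem); t.bk = zeros<rowvec>(s.bk.n_elem);
    t.bv = zeros<rowvec>(s.bv.n_elem); t.bo = zeros<rowvec>(s.bo.n_elem);
    t.b1 = zeros<rowvec>(s.b1.n_elem); t.b2 = zeros<rowvec>(s.b2.n_elem);
  }
}

std::vector<int> window_starts(int T, int L, int stride) {
  std::vector<int> st;
  for (int s = 0; s + L <= T; s += stride) st.push_back(s);
  if (st.empty()) Rcpp::stop("time series shorter than window_length");
  if (st.back() + L < T) st.push_back(T - L);  // right-aligned tail window
  return st;
}

struct WinCache {
  uvec rf, core, rfoff, coreoff;
  mat Xq, Xkv, Q, K, V, O;      // O: concatenated head outputs (pre-Wo)
  std::vector<mat> A;           // per-head attention ((L+1) x nk)
  mat out;                      // post-Wo (post-dropout) update
  mat dropmask;                 // inverted-dropout mask on `out` (empty if off)
};

struct BlockCache {
  mat Hin, Cin;                 // block inputs
  mat Hmid, Cmid;               // post-attention/fusion, pre-MLP
  mat Hh, Ch;                   // ReLU hidden activations (post-dropout)
  mat Hhmask, Chmask;           // dropout masks on hidden (empty if off)
  vec counts;                   // per-token window coverage counts
  std::vector<WinCache> w;
};

struct RunCache {
  mat H0;
  const mat* X;
  int T, F;
  std::vector<int> starts;
  std::vector<BlockCache> b;
  mat Cfinal;
};

mat maybe_dropout(mat m, double p, mat& mask, bool training) {
  if (!training || p <= 0) { mask.reset(); return m; }
  mask = m; // shape
  for (uword i = 0; i < mask.n_elem; ++i)
    mask(i) = (R::unif_rand() < p) ? 0.0 : 1.0 / (1.0 - p);
  return m % mask;
}

// Forward pass; fills cache. Returns fingerprint as rowvec.
rowvec forward(const mat& X, const Par& par, const EncCfg& c,
               bool training, RunCache& rc,
               bool record_attention, Rcpp::List* attn_out) {
  const int T = X.n_cols;
  const int d = c.d, heads = c.heads, dh = d / heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  rc.X = &X;
  rc.T = T;
  rc.starts = window_starts(T, c.L, c.stride);
  rc.F = (int)rc.starts.size();
  const int F = rc.F;

  rc.H0 = X.t() * par.Wp;
  rc.H0.each_row() += par.bp;

  mat H = rc.H0;
  mat C = repmat(par.cls0, F, 1);

  rc.b.clear();
  rc.b.resize(c.blocks);

  for (int b = 0; b < c.blocks; ++b) {
    BlockCache& bc = rc.b[b];
    const BlockPar& bp = par.blk[b];
    bc.Hin = H;
    bc.Cin = C;
    bc.counts = zeros<vec>(T);
    bc.w.resize(F);
    mat accum = zeros<mat>(T, d);
    mat Cnew = C;
    Rcpp::List block_attn(record_attention ? F : 0);

    for (int f = 0; f < F; ++f) {
      WinCache& wc = bc.w[f];
      const int s = rc.starts[f];
      const int a0 = std::max(0, s - c.fringe);
      const int b0 = std::min(T, s + c.L + c.fringe);
      wc.rf   = regspace<uvec>(a0, b0 - 1);
      wc.core = regspace<uvec>(s, s + c.L - 1);
      wc.rfoff = conv_to<uvec>::from(
          conv_to<ivec>::from(wc.rf) - (s - c.fringe));
      wc.coreoff = conv_to<uvec>::from(
          conv_to<ivec>::from(wc.core) - (s - c.fringe));

      wc.Xkv = H.rows(wc.rf) + par.pos.rows(wc.rfoff);
      mat Xq_tok = H.rows(wc.core) + par.pos.rows(wc.coreoff);
      wc.Xq = join_cols(C.row(f), Xq_tok);   // (L+1) x d

      wc.Q = wc.Xq * bp.Wq; wc.Q.each_row() += bp.bq;
      wc.K = wc.Xkv * bp.Wk; wc.K.each_row() += bp.bk;
      wc.V = wc.Xkv * bp.Wv; wc.V.each_row() += bp.bv;

      wc.A.resize(heads);
      wc.O = zeros<mat>(c.L + 1, d);
      for (int h = 0; h < heads; ++h) {
        span cs(h * dh, (h + 1) * dh - 1);
        mat S = wc.Q.cols(cs) * wc.K.cols(cs).t() * scale;
        S.each_col() -= max(S, 1);
        mat A = exp(S);
        A.each_col() /= sum(A, 1);
        wc.A[h] = A;
        wc.O.cols(cs) = A * wc.V.cols(cs);
      }
      mat out = wc.O * bp.Wo;
      out.each_row() += bp.bo;
      out = maybe_dropout(out, c.dropout, wc.dropmask, training);
      wc.out = out;

      Cnew.row(f) += out.row(0);
      accum.rows(wc.core) += out.rows(1, c.L);
      bc.counts(wc.core) += 1.0;

      if (record_attention) {
        Rcpp::List heads_l(heads);
        for (int h = 0; h < heads; ++h)
          heads_l[h] = Rcpp::NumericVector(wc.A[h].row(0).begin(),
                                           wc.A[h].row(0).end());
        block_attn[f] = Rcpp::List::create(
            Rcpp::Named("cls_attention") = heads_l,
            Rcpp::Named("rf_start") = a0 + 1,   // 1-based inclusive for R
            Rcpp::Named("rf_end") = b0,
            Rcpp::Named("core_start") = s + 1,
            Rcpp::Named("core_end") = s + c.L);
      }
    }
    if (record_attention) (*attn_out)[b] = block_attn;

    bc.Hmid = bc.Hin + accum.each_col() / bc.counts;
    bc.Cmid = Cnew;

    // token-wise MLP with residual, applied to fused tokens and CLS states
    mat Hpre = bc.Hmid * bp.W1; Hpre.each_row() += bp.b1;
    bc.Hh = clamp(Hpre, 0.0, datum::inf);
    bc.Hh = maybe_dropout(bc.Hh, c.dropout, bc.Hhmask, training);
    H = bc.Hmid + bc.Hh * bp.W2;
    H.each_row() += bp.b2;

    mat Cpre = bc.Cmid * bp.W1; Cpre.each_row() += bp.b1;
    bc.Ch = clamp(Cpre, 0.0, datum::inf);
    bc.Ch = maybe_dropout(bc.Ch, c.dropout, bc.Chmask, training);
    C = bc.Cmid + bc.Ch * bp.W2;
    C.each_row() += bp.b2;
  }
  rc.Cfinal = C;
  return mean(C, 0);
}

// Backward pass: de (1 x d) is the loss gradient w.r.t. the fingerprint.
// Accumulates parameter gradients into g.
void backward(const RunCache& rc, const Par& par, const EncCfg& c,
              const rowvec& de, Par& g) {
  const int T = rc.T, F = rc.F, d = c.d, heads = c.heads, dh = d / heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  mat dC = repmat(de / (double)F, F, 1);
  mat dH = zeros<mat>(T, d);

  for (int b = c.blocks - 1; b >= 0; --b) {
    const BlockCache& bc = rc.b[b];
    const BlockPar& bp = par.blk[b];
    BlockPar& gb = g.blk[b];

    // MLP backward (CLS path)
    {
      mat dhid = dC * bp.W2.t();
      gb.W2 += bc.Ch.t() * dC;
      gb.b2 += sum(dC, 0);
      if (!bc.Chmask.is_empty()) dhid %= bc.Chmask;
      dhid.elem(find(bc.Ch == 0)).zeros();
      gb.W1 += bc.Cmid.t() * dhid;
      gb.b1 += sum(dhid, 0);
      dC = dC + dhid * bp.W1.t();   // gradient w.r.t. Cmid
    }
    // MLP backward (token path)
    {
      mat dhid = dH * bp.W2.t();
      gb.W2 += bc.Hh.t() * dH;
      gb.b2 += sum(dH, 0);
      if (!bc.Hhmask.is_empty()) dhid %= bc.Hhmask;
      dhid.elem(find(bc.Hh == 0)).zeros();
      gb.W1 += bc.Hmid.t() * dhid;
      gb.b1 += sum(dhid, 0);
      dH = dH + dhid * bp.W1.t();   // gradient w.r.t. Hmid
    }

    // fusion backward: Hmid = Hin + accum / counts
    mat dHin = dH;                       // residual branch
    mat daccum = dH.each_col() / bc.counts;
    mat dCin = zeros<mat>(F, d);

    for (int f = F - 1; f >= 0; --f) {
      const WinCache& wc = bc.w[f];
      mat dout = join_cols(dC.row(f), daccum.rows(wc.core));
      if (!wc.dropmask.is_empty()) dout %= wc.dropmask;

      gb.Wo += wc.O.t() * dout;
      gb.bo += sum(dout, 0);
      mat dO = dout * bp.Wo.t();

      mat dQ = zeros<mat>(c.L + 1, d);
      mat dK = zeros<mat>(wc.K.n_rows, d);
      mat dV = zeros<mat>(wc.V.n_rows, d);
      for (int h = 0; h < heads; ++h) {
        span cs(h * dh, (h + 1) * dh - 1);
        const mat& A = wc.A[h];
        mat dA = dO.cols(cs) * wc.V.cols(cs).t();
        dV.cols(cs) = A.t() * dO.cols(cs);
        mat dS = A % (dA.each_col() - sum(dA % A, 1));
        dQ.cols(cs) = dS * wc.K.cols(cs) * scale;
        dK.cols(cs) = dS.t() * wc.Q.cols(cs) * scale;
      }
      gb.Wq += wc.Xq.t() * dQ;  gb.bq += sum(dQ, 0);
      gb.Wk += wc.Xkv.t() * dK; gb.bk += sum(dK, 0);
      gb.Wv += wc.Xkv.t() * dV; gb.bv += sum(dV, 0);

      mat dXq = dQ * bp.Wq.t();
      mat dXkv = dK * bp.Wk.t() + dV * bp.Wv.t();

      dCin.row(f) += dXq.row(0);
      dHin.rows(wc.core) += dXq.rows(1, c.L);
      g.pos.rows(wc.coreoff) += dXq.rows(1, c.L);
      dHin.rows(wc.rf) += dXkv;
      g.pos.rows(wc.rfoff) += dXkv;
    }
    dCin += dC;   // residual path Cnew = Cin + cls updates
    dC = dCin;
    dH = dHin;
  }

  g.cls0 += sum(dC, 0);
  g.Wp += (*rc.X) * dH;
  g.bp += sum(dH, 0);
}

Rcpp::NumericVector asvec(const rowvec& v) {
  return Rcpp::NumericVector(v.begin(), v.end());
}

Rcpp::List par_to_list(const Par& g) {
  Rcpp::List blocks(g.blk.size());
  for (size_t b = 0; b < g.blk.size(); ++b) {
    const BlockPar& bb = g.blk[b];
    blocks[b] = Rcpp::List::create(
        Rcpp::Named("Wq") = bb.Wq, Rcpp::Named("bq") = asvec(bb.bq),
        Rcpp::Named("Wk") = bb.Wk, Rcpp::Named("bk") = asvec(bb.bk),
        Rcpp::Named("Wv") = bb.Wv, Rcpp::Named("bv") = asvec(bb.bv),
        Rcpp::Named("Wo") = bb.Wo, Rcpp::Named("bo") = asvec(bb.bo),
        Rcpp::Named("W1") = bb.W1, Rcpp::Named("b1") = asvec(bb.b1),
        Rcpp::Named("W2") = bb.W2, Rcpp::Named("b2") = asvec(bb.b2));
  }
  return Rcpp::List::create(
      Rcpp::Named("Wp") = g.Wp, Rcpp::Named("bp") = asvec(g.bp),
      Rcpp::Named("pos") = g.pos, Rcpp::Named("cls0") = asvec(g.cls0),
      Rcpp::Named("blocks") = blocks);
}

double cosdist(const rowvec& u, const rowvec& v) {
  return 1.0 - dot(u, v) / (norm(u) * norm(v));
}

// gradient of d(u, v) = 1 - cos(u, v) w.r.t. u
rowvec dcosdist_du(const rowvec& u, const rowvec& v) {
  double nu = norm(u), nv = norm(v);
  double cuv = dot(u, v) / (nu * nv);
  return -(v / (nu * nv) - cuv * u / (nu * nu));
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_encode(const arma::mat& X, Rcpp::List params, Rcpp::List cfg,
                      bool record_attention = false) {
  EncCfg c = parse_cfg(cfg);
  if ((int)X.n_rows != c.R) Rcpp::stop("run has %d regions, config expects %d",
                                       (int)X.n_rows, c.R);
  if (!X.is_finite()) Rcpp::stop("non-finite values in run matrix");
  Par par = parse_params(params, c);
  RunCache rc;
  Rcpp::List attn(c.blocks);
  rowvec e = forward(X, par, c, false, rc, record_attention, &attn);
  Rcpp::IntegerVector starts(rc.starts.size());
  for (size_t i = 0; i < rc.starts.size(); ++i) starts[i] = rc.starts[i] + 1;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("fingerprint") = Rcpp::NumericVector(e.begin(), e.end()),
      Rcpp::Named("cls_states") = rc.Cfinal,
      Rcpp::Named("n_windows") = rc.F,
      Rcpp::Named("window_starts") = starts);
  if (record_attention) out["attention"] = attn;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_triplet_grad(Rcpp::List Xs, const arma::imat& triplets,
                            Rcpp::List params, Rcpp::List cfg,
                            double margin, bool training = true) {
  EncCfg c = parse_cfg(cfg);
  Par par = parse_params(params, c);
  const int n = Xs.size();

  std::vector<mat> X(n);
  std::vector<RunCache> rc(n);
  mat E(n, c.d);
  for (int i = 0; i < n; ++i) {
    X[i] = Rcpp::as<mat>(Xs[i]);
    if ((int)X[i].n_rows != c.R) Rcpp::stop("run %d region-count mismatch", i + 1);
    rowvec e = forward(X[i], par, c, training, rc[i], false, nullptr);
    E.row(i) = e;
  }

  const int m = triplets.n_rows;
  mat dE = zeros<mat>(n, c.d);
  double loss = 0.0;
  int n_active = 0;
  for (int t = 0; t < m; ++t) {
    int a = triplets(t, 0) - 1, p = triplets(t, 1) - 1, ng = triplets(t, 2) - 1;
    rowvec ea = E.row(a), ep = E.row(p), en = E.row(ng);
    double dap = cosdist(ea, ep), dan = cosdist(ea, en);
    double l = dap - dan + margin;
    if (l > 0) {
      loss += l;
      ++n_active;
      dE.row(a) += dcosdist_du(ea, ep) - dcosdist_du(ea, en);
      dE.row(p) += dcosdist_du(ep, ea);
      dE.row(ng) -= dcosdist_du(en, ea);
    }
  }
  loss /= m;
  dE /= m;

  Par g;
  zero_like(par, g);
  for (int i = 0; i < n; ++i) {
    rowvec de = dE.row(i);
    if (any(de != 0)) backward(rc[i], par, c, de, g);
  }

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("n_active") = n_active,
      Rcpp::Named("embeddings") = E,
      Rcpp::Named("grads") = par_to_list(g));
}
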