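// Transformer core for MAE pretraining on 12-lead ECG patch grids.
//
// Single-threaded float32 forward/backward passes for a pre-LayerNorm ViT
// tower, used as both the MAE encoder (visible patches + classification
// token) and the MAE decoder (full 240-token grid with mask tokens), plus a
// two-layer sigmoid classification head for fine-tuning. Gradients are
// computed by hand-written reverse-mode passes; parameters cross the R/C++
// boundary as nested lists of double matrices and are cast to float here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float LN_EPS = 1e-6f;

// ---- parameter structures ----------------------------------------------

struct Block {
  frowvec ln1_g, ln1_b, qkv_b, proj_b, ln2_g, ln2_b, fc1_b, fc2_b;
  fmat qkv_W, proj_W, fc1_W, fc2_W;
};

struct Tower {
  fmat embed_W;      // in_dim x E
  frowvec embed_b;   // 1 x E
  std::vector<Block> blocks;
  frowvec norm_g, norm_b;
  int n_heads;
};

static fmat as_f(const Rcpp::NumericMatrix& m) {
  const mat d(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false);
  return conv_to<fmat>::from(d);
}

static frowvec as_frow(const Rcpp::NumericMatrix& m) {
  return as_f(m).row(0);
}

static Block load_block(const List& b) {
  Block blk;
  blk.ln1_g = as_frow(b["ln1_g"]); blk.ln1_b = as_frow(b["ln1_b"]);
  blk.qkv_W = as_f(b["qkv_W"]);    blk.qkv_b = as_frow(b["qkv_b"]);
  blk.proj_W = as_f(b["proj_W"]);  blk.proj_b = as_frow(b["proj_b"]);
  blk.ln2_g = as_frow(b["ln2_g"]); blk.ln2_b = as_frow(b["ln2_b"]);
  blk.fc1_W = as_f(b["fc1_W"]);    blk.fc1_b = as_frow(b["fc1_b"]);
  blk.fc2_W = as_f(b["fc2_W"]);    blk.fc2_b = as_frow(b["fc2_b"]);
  return blk;
}

static Tower load_tower(const List& p, int n_heads) {
  Tower t;
  t.embed_W = as_f(p["embed_W"]);
  t.embed_b = as_frow(p["embed_b"]);
  List blocks = p["blocks"];
  for (int i = 0; i < blocks.size(); ++i) {
    t.blocks.push_back(load_block(blocks[i]));
  }
  t.norm_g = as_frow(p["norm_g"]);
  t.norm_b = as_frow(p["norm_b"]);
  t.n_heads = n_heads;
  return t;
}

// gradient accumulators mirror the parameter structures
struct BlockGrad {
  frowvec ln1_g, ln1_b, qkv_b, proj_b, ln2_g, ln2_b, fc1_b, fc2_b;
  fmat qkv_W, proj_W, fc1_W, fc2_W;
  void init(const Block& b) {
    ln1_g = zeros<frowvec>(b.ln1_g.n_elem); ln1_b = ln1_g;
    qkv_b = zeros<frowvec>(b.qkv_b.n_elem);
    proj_b = zeros<frowvec>(b.proj_b.n_elem);
    ln2_g = zeros<frowvec>(b.ln2_g.n_elem); ln2_b = ln2_g;
    fc1_b = zeros<frowvec>(b.fc1_b.n_elem);
    fc2_b = zeros<frowvec>(b.fc2_b.n_elem);
    qkv_W = zeros<fmat>(size(b.qkv_W));
    proj_W = zeros<fmat>(size(b.proj_W));
    fc1_W = zeros<fmat>(size(b.fc1_W));
    fc2_W = zeros<fmat>(size(b.fc2_W));
  }
};

struct TowerGrad {
  fmat embed_W;
  frowvec embed_b, norm_g, norm_b;
  std::vector<BlockGrad> blocks;
  void init(const Tower& t) {
    embed_W = zeros<fmat>(size(t.embed_W));
    embed_b = zeros<frowvec>(t.embed_b.n_elem);
    norm_g = zeros<frowvec>(t.norm_g.n_elem);
    norm_b = zeros<frowvec>(t.norm_b.n_elem);
    blocks.resize(t.blocks.size());
    for (size_t i = 0; i < t.blocks.size(); ++i) blocks[i].init(t.blocks[i]);
  }
};

static Rcpp::NumericMatrix to_R(const fmat& m) {
  mat d = conv_to<mat>::from(m);
  return Rcpp::wrap(d);
}

static Rcpp::NumericMatrix to_R(const frowvec& v) {
  fmat m(1, v.n_elem);
  m.row(0) = v;
  return to_R(m);
}

static List grad_to_R(const TowerGrad& g) {
  List blocks(g.blocks.size());
  for (size_t i = 0; i < g.blocks.size(); ++i) {
    const BlockGrad& b = g.blocks[i];
    blocks[i] = List::create(
      Named("ln1_g") = to_R(b.ln1_g), Named("ln1_b") = to_R(b.ln1_b),
      Named("qkv_W") = to_R(b.qkv_W), Named("qkv_b") = to_R(b.qkv_b),
      Named("proj_W") = to_R(b.proj_W), Named("proj_b") = to_R(b.proj_b),
      Named("ln2_g") = to_R(b.ln2_g), Named("ln2_b") = to_R(b.ln2_b),
      Named("fc1_W") = to_R(b.fc1_W), Named("fc1_b") = to_R(b.fc1_b),
      Named("fc2_W") = to_R(b.fc2_W), Named("fc2_b") = to_R(b.fc2_b));
  }
  return List::create(
    Named("embed_W") = to_R(g.embed_W), Named("embed_b") = to_R(g.embed_b),
    Named("blocks") = blocks,
    Named("norm_g") = to_R(g.norm_g), Named("norm_b") = to_R(g.norm_b));
}

// ---- primitive layers ---------------------------------------------------

struct LNCache { fmat xhat; fvec inv_std; };

static fmat ln_fwd(const fmat& X, const frowvec& g, const frowvec& b,
                   LNCache& cache) {
  fvec mu = mean(X, 1);
  fmat Xc = X.each_col() - mu;
  fvec v = mean(square(Xc), 1);
  cache.inv_std = 1.0f / sqrt(v + LN_EPS);
  cache.xhat = Xc.each_col() % cache.inv_std;
  fmat Y = cache.xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static fmat ln_bwd(const fmat& dY, const LNCache& cache, const frowvec& g,
                   frowvec& dg, frowvec& db) {
  dg += sum(dY % cache.xhat, 0);
  db += sum(dY, 0);
  fmat dxhat = dY.each_row() % g;
  fvec m1 = mean(dxhat, 1);
  fvec m2 = mean(dxhat % cache.xhat, 1);
  fmat dX = dxhat.each_col() - m1;
  dX -= cache.xhat.each_col() % m2;
  dX.each_col() %= cache.inv_std;
  return dX;
}

static const float INV_SQRT2 = 0.70710678118654752f;
static const float INV_SQRT_2PI = 0.39894228040143268f;

static fmat gelu_fwd(const fmat& X) {
  fmat Y = X;
  Y.transform([](float x) {
    return 0.5f * x * (1.0f + std::erf(x * INV_SQRT2));
  });
  return Y;
}

static fmat gelu_bwd(const fmat& dY, const fmat& Xpre) {
  fmat D = Xpre;
  D.transform([](float x) {
    float cdf = 0.5f * (1.0f + std::erf(x * INV_SQRT2));
    float pdf = INV_SQRT_2PI * std::exp(-0.5f * x * x);
    return cdf + x * pdf;
  });
  return dY % D;
}

struct BlockCache {
  fmat X_in;          // block input (T x E)
  LNCache ln1, ln2;
  fmat A_in;          // LN1 output
  fmat QKV;           // T x 3E
  fcube P;            // attention probabilities, T x T x H
  fmat O;             // concatenated head outputs (pre-projection)
  fmat X_mid;         // after attention residual
  fmat M_in;          // LN2 output
  fmat H1pre, H1;     // MLP hidden pre/post GELU
};

static fmat block_fwd(const fmat& X, const Block& b, int H, BlockCache& c) {
  int T = X.n_rows, E = X.n_cols, Dh = E / H;
  float scale = 1.0f / std::sqrt((float)Dh);
  c.X_in = X;
  c.A_in = ln_fwd(X, b.ln1_g, b.ln1_b, c.ln1);
  c.QKV = c.A_in * b.qkv_W;
  c.QKV.each_row() += b.qkv_b;
  c.P.set_size(T, T, H);
  c.O.set_size(T, E);
  for (int h = 0; h < H; ++h) {
    fmat Q = c.QKV.cols(h * Dh, (h + 1) * Dh - 1);
    fmat K = c.QKV.cols(E + h * Dh, E + (h + 1) * Dh - 1);
    fmat V = c.QKV.cols(2 * E + h * Dh, 2 * E + (h + 1) * Dh - 1);
    fmat S = (Q * K.t()) * scale;
    S.each_col() -= max(S, 1);
    fmat Pm = exp(S);
    Pm.each_col() /= sum(Pm, 1);
    c.P.slice(h) = Pm;
    c.O.cols(h * Dh, (h + 1) * Dh - 1) = Pm * V;
  }
  fmat attn = c.O * b.proj_W;
  attn.each_row() += b.proj_b;
  c.X_mid = X + attn;
  c.M_in = ln_fwd(c.X_mid, b.ln2_g, b.ln2_b, c.ln2);
  c.H1pre = c.M_in * b.fc1_W;
  c.H1pre.each_row() += b.fc1_b;
  c.H1 = gelu_fwd(c.H1pre);
  fmat M = c.H1 * b.fc2_W;
  M.each_row() += b.fc2_b;
  return c.X_mid + M;
}

static fmat block_bwd(const fmat& dOut, const Block& b, int H,
                      const BlockCache& c, BlockGrad& g) {
  int E = c.X_in.n_cols, Dh = E / H;
  float scale = 1.0f / std::sqrt((float)Dh);
  // MLP branch
  fmat dM = dOut;                       // residual: dX_mid gets dOut too
  g.fc2_b += sum(dM, 0);
  g.fc2_W += c.H1.t() * dM;
  fmat dH1 = dM * b.fc2_W.t();
  fmat dH1pre = gelu_bwd(dH1, c.H1pre);
  g.fc1_b += sum(dH1pre, 0);
  g.fc1_W += c.M_in.t() * dH1pre;
  fmat dM_in = dH1pre * b.fc1_W.t();
  fmat dX_mid = ln_bwd(dM_in, c.ln2, b.ln2_g, g.ln2_g, g.ln2_b);
  dX_mid += dOut;
  // attention branch
  fmat dAttn = dX_mid;                  // residual: dX_in gets dX_mid too
  g.proj_b += sum(dAttn, 0);
  g.proj_W += c.O.t() * dAttn;
  fmat dO = dAttn * b.proj_W.t();
  fmat dQKV(c.QKV.n_rows, c.QKV.n_cols, fill::zeros);
  for (int h = 0; h < H; ++h) {
    fmat Q = c.QKV.cols(h * Dh, (h + 1) * Dh - 1);
    fmat K = c.QKV.cols(E + h * Dh, E + (h + 1) * Dh - 1);
    fmat V = c.QKV.cols(2 * E + h * Dh, 2 * E + (h + 1) * Dh - 1);
    const fmat& Pm = c.P.slice(h);
    fmat dOh = dO.cols(h * Dh, (h + 1) * Dh - 1);
    fmat dP = dOh * V.t();
    fmat dV = Pm.t() * dOh;
    fvec rowdot = sum(dP % Pm, 1);
    fmat dS = Pm % (dP.each_col() - rowdot);
    dQKV.cols(h * Dh, (h + 1) * Dh - 1) += (dS * K) * scale;
    dQKV.cols(E + h * Dh, E + (h + 1) * Dh - 1) += (dS.t() * Q) * scale;
    dQKV.cols(2 * E + h * Dh, 2 * E + (h + 1) * Dh - 1) += dV;
  }
  g.qkv_b += sum(dQKV, 0);
  g.qkv_W += c.A_in.t() * dQKV;
  fmat dA_in = dQKV * b.qkv_W.t();
  fmat dX = ln_bwd(dA_in, c.ln1, b.ln1_g, g.ln1_g, g.ln1_b);
  dX += dX_mid;
  return dX;
}

struct TowerCache {
  std::vector<BlockCache> blocks;
  LNCache ln_final;
};

// X0: embedded token matrix (tokens x E); returns normalized output tokens
static fmat tower_fwd(const fmat& X0, const Tower& t, TowerCache& c) {
  c.blocks.resize(t.blocks.size());
  fmat X = X0;
  for (size_t i = 0; i < t.blocks.size(); ++i) {
    X = block_fwd(X, t.blocks[i], t.n_heads, c.blocks[i]);
  }
  return ln_fwd(X, t.norm_g, t.norm_b, c.ln_final);
}

static fmat tower_bwd(const fmat& dY, const Tower& t, const TowerCache& c,
                      TowerGrad& g) {
  fmat dX = ln_bwd(dY, c.ln_final, t.norm_g, g.norm_g, g.norm_b);
  for (int i = (int)t.blocks.size() - 1; i >= 0; --i) {
    dX = block_bwd(dX, t.blocks[i], t.n_heads, c.blocks[i], g.blocks[i]);
  }
  return dX;
}

// ---- encoder embedding helpers ------------------------------------------

// patches: (n_tokens x patch_len) rows already restricted to visible set;
// vis0: 0-based grid indices of those rows. Returns [cls; embedded] matrix.
static fmat embed_tokens(const fmat& patches, const uvec& vis0,
                         const fmat& embed_W, const frowvec& embed_b,
                         const frowvec& cls, const fmat& pos) {
  fmat Xv = patches * embed_W;
  Xv.each_row() += embed_b;
  Xv += pos.rows(vis0);
  fmat X0(Xv.n_rows + 1, Xv.n_cols);
  X0.row(0) = cls;               // classification token carries no position
  X0.rows(1, Xv.n_rows) = Xv;
  return X0;
}

// ---- exported: encoder forward ------------------------------------------

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_encode(List enc_params, int n_heads,
                               Rcpp::NumericMatrix patches_vis,
                               Rcpp::IntegerVector vis0,
                               Rcpp::NumericMatrix pos_enc) {
  Tower enc = load_tower(enc_params, n_heads);
  frowvec cls = as_frow(enc_params["cls"]);
  uvec v = conv_to<uvec>::from(
    Rcpp::as<std::vector<int>>(vis0));
  fmat X0 = embed_tokens(as_f(patches_vis), v, enc.embed_W, enc.embed_b,
                         cls, as_f(pos_enc));
  TowerCache cache;
  return to_R(tower_fwd(X0, enc, cache));
}

// ---- exported: decoder forward ------------------------------------------

// tokens: (V+1) x E encoder outputs (row 0 = cls); returns 240 x patch_len
// predictions in canonical grid order.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_decode(List dec_params, int n_heads,
                               Rcpp::NumericMatrix tokens,
                               Rcpp::IntegerVector vis0, int n_grid,
                               Rcpp::NumericMatrix pos_dec) {
  Tower dec = load_tower(dec_params, n_heads);
  frowvec mask_token = as_frow(dec_params["mask_token"]);
  fmat head_W = as_f(dec_params["head_W"]);
  frowvec head_b = as_frow(dec_params["head_b"]);
  fmat tok = as_f(tokens);
  uvec v = conv_to<uvec>::from(Rcpp::as<std::vector<int>>(vis0));
  fmat Z = tok * dec.embed_W;
  Z.each_row() += dec.embed_b;
  int D = Z.n_cols;
  fmat F(n_grid + 1, D);
  F.each_row() = mask_token;
  F.row(0) = Z.row(0);
  for (size_t j = 0; j < v.n_elem; ++j) F.row(1 + v(j)) = Z.row(1 + j);
  F.rows(1, n_grid) += as_f(pos_dec);
  TowerCache cache;
  fmat G = tower_fwd(F, dec, cache);
  fmat pred = G * head_W;
  pred.each_row() += head_b;
  return to_R(fmat(pred.rows(1, n_grid)));
}

// ---- exported: MAE loss + gradients over a batch ------------------------

// patches: list of (n_grid x patch_len) matrices in canonical grid order;
// vis_list / mask_list: 0-based visible / masked indices per record.
// [[Rcpp::export]]
List cpp_mae_grad(List enc_params, List dec_params,
                  int enc_heads, int dec_heads,
                  List patches, List vis_list, List mask_list,
                  Rcpp::NumericMatrix pos_enc, Rcpp::NumericMatrix pos_dec,
                  bool normalize_per_patch, bool want_grad) {
  Tower enc = load_tower(enc_params, enc_heads);
  Tower dec = load_tower(dec_params, dec_heads);
  frowvec cls = as_frow(enc_params["cls"]);
  frowvec mask_token = as_frow(dec_params["mask_token"]);
  fmat dec_embed_W = dec.embed_W;
  fmat head_W = as_f(dec_params["head_W"]);
  frowvec head_b = as_frow(dec_params["head_b"]);
  fmat Penc = as_f(pos_enc), Pdec = as_f(pos_dec);

  TowerGrad g_enc, g_dec;
  fmat d_head_W; frowvec d_head_b, d_mask_token, d_cls;
  fmat d_dec_embed_W; frowvec d_dec_embed_b;
  if (want_grad) {
    g_enc.init(enc); g_dec.init(dec);
    d_head_W = zeros<fmat>(size(head_W));
    d_head_b = zeros<frowvec>(head_b.n_elem);
    d_mask_token = zeros<frowvec>(mask_token.n_elem);
    d_cls = zeros<frowvec>(cls.n_elem);
  }
  // tower embed grads live inside g_enc / g_dec (embed_W / embed_b)

  int B = patches.size();
  double total_loss = 0.0;
  TowerCache ec, dc;   // buffers reused across the batch (fixed shapes)
  for (int r = 0; r < B; ++r) {
    fmat P = as_f(patches[r]);                 // n_grid x patch_len
    uvec vis = conv_to<uvec>::from(
      Rcpp::as<std::vector<int>>(vis_list[r]));
    uvec msk = conv_to<uvec>::from(
      Rcpp::as<std::vector<int>>(mask_list[r]));
    int n_grid = P.n_rows;
    int V = vis.n_elem, M = msk.n_elem;
    fmat Pv = P.rows(vis);
    fmat X0 = embed_tokens(Pv, vis, enc.embed_W, enc.embed_b, cls, Penc);
    fmat Y = tower_fwd(X0, enc, ec);           // (V+1) x E
    fmat Z = Y * dec.embed_W;
    Z.each_row() += dec.embed_b;
    int D = Z.n_cols;
    fmat F(n_grid + 1, D);
    F.each_row() = mask_token;
    F.row(0) = Z.row(0);
    for (int j = 0; j < V; ++j) F.row(1 + vis(j)) = Z.row(1 + j);
    F.rows(1, n_grid) += Pdec;
    fmat G = tower_fwd(F, dec, dc);
    fmat pred = G * head_W;
    pred.each_row() += head_b;                 // (n_grid+1) x patch_len

    // masked-only mean squared error
    fmat target = P.rows(msk);
    if (normalize_per_patch) {
      fvec mu = mean(target, 1);
      fvec sd = stddev(target, 0, 1);
      sd.transform([](float s) { return s < 1e-6f ? 1.0f : s; });
      target.each_col() -= mu;
      target.each_col() /= sd;
    }
    fmat diff(M, P.n_cols);
    for (int j = 0; j < M; ++j) diff.row(j) = pred.row(1 + msk(j));
    diff -= target;
    double denom = (double)M * P.n_cols;
    total_loss += accu(conv_to<mat>::from(square(diff))) / denom;

    if (!want_grad) continue;
    float w = 2.0f / (float)(denom * B);
    fmat dPred(n_grid + 1, P.n_cols, fill::zeros);
    for (int j = 0; j < M; ++j) dPred.row(1 + msk(j)) = w * diff.row(j);
    d_head_b += sum(dPred, 0);
    d_head_W += G.t() * dPred;
    fmat dG = dPred * head_W.t();
    fmat dF = tower_bwd(dG, dec, dc, g_dec);
    // undo decoder positional add (constant) and scatter
    fmat dZ(Z.n_rows, D);
    dZ.row(0) = dF.row(0);
    for (int j = 0; j < V; ++j) dZ.row(1 + j) = dF.row(1 + vis(j));
    for (int j = 0; j < M; ++j) d_mask_token += dF.row(1 + msk(j));
    g_dec.embed_b += sum(dZ, 0);
    g_dec.embed_W += Y.t() * dZ;
    fmat dY = dZ * dec.embed_W.t();
    fmat dX0 = tower_bwd(dY, enc, ec, g_enc);
    d_cls += dX0.row(0);
    fmat dXv = dX0.rows(1, V);
    g_enc.embed_b += sum(dXv, 0);
    g_enc.embed_W += Pv.t() * dXv;
  }
  double loss = total_loss / B;
  if (!want_grad) return List::create(Named("loss") = loss);
  List ge = grad_to_R(g_enc);
  ge["cls"] = to_R(d_cls);
  List gd = grad_to_R(g_dec);
  gd["mask_token"] = to_R(d_mask_token);
  gd["head_W"] = to_R(d_head_W);
  gd["head_b"] = to_R(d_head_b);
  return List::create(Named("loss") = loss,
                      Named("grads") = List::create(Named("enc") = ge,
                                                    Named("dec") = gd));
}

// ---- classifier (encoder + two-FC sigmoid head) --------------------------

// pooled may pass through a fixed (non-trainable) centering/whitening
// transform fitted on the fine-tuning training features
static fmat clf_forward(const Tower& enc, const frowvec& cls,
                        const fmat& head_fc1_W, const frowvec& head_fc1_b,
                        const fmat& head_fc2_W, const frowvec& head_fc2_b,
                        const fmat& P, const fmat& Penc, bool cls_pool,
                        const frowvec& feat_mu, const fmat& feat_W,
                        bool use_whiten,
                        TowerCache& ec, fmat& Y, frowvec& pooled,
                        frowvec& h1pre, frowvec& h1) {
  int n_grid = P.n_rows;
  uvec all = regspace<uvec>(0, n_grid - 1);
  fmat X0 = embed_tokens(P, all, enc.embed_W, enc.embed_b, cls, Penc);
  Y = tower_fwd(X0, enc, ec);
  if (cls_pool) {
    pooled = Y.row(0);
  } else {
    pooled = mean(Y.rows(1, n_grid), 0);
  }
  if (use_whiten) pooled = (pooled - feat_mu) * feat_W;
  h1pre = pooled * head_fc1_W + head_fc1_b;
  fmat h1m = gelu_fwd(fmat(h1pre));
  h1 = h1m.row(0);
  fmat logits = h1 * head_fc2_W;
  logits.each_row() += head_fc2_b;
  return logits;  // 1 x K
}

// [[Rcpp::export]]
List cpp_clf_grad(List enc_params, List head_params, int enc_heads,
                  List patches, Rcpp::NumericMatrix labels,
                  Rcpp::NumericMatrix pos_enc, bool cls_pool,
                  Rcpp::NumericMatrix feat_mu, Rcpp::NumericMatrix feat_W,
                  bool use_whiten, bool want_grad) {
  Tower enc = load_tower(enc_params, enc_heads);
  frowvec cls = as_frow(enc_params["cls"]);
  fmat fc1_W = as_f(head_params["fc1_W"]);
  frowvec fc1_b = as_frow(head_params["fc1_b"]);
  fmat fc2_W = as_f(head_params["fc2_W"]);
  frowvec fc2_b = as_frow(head_params["fc2_b"]);
  fmat Penc = as_f(pos_enc);
  fmat lab = as_f(labels);                      // B x K
  frowvec fmu = use_whiten ? as_frow(feat_mu) : frowvec();
  fmat fW = use_whiten ? as_f(feat_W) : fmat();

  int B = patches.size(), K = fc2_W.n_cols;
  TowerGrad g_enc;
  fmat d_fc1_W, d_fc2_W; frowvec d_fc1_b, d_fc2_b, d_cls;
  if (want_grad) {
    g_enc.init(enc);
    d_fc1_W = zeros<fmat>(size(fc1_W)); d_fc1_b = zeros<frowvec>(fc1_b.n_elem);
    d_fc2_W = zeros<fmat>(size(fc2_W)); d_fc2_b = zeros<frowvec>(fc2_b.n_elem);
    d_cls = zeros<frowvec>(cls.n_elem);
  }
  fmat probs(B, K);
  double total_loss = 0.0;
  TowerCache ec;   // reused across the batch
  for (int r = 0; r < B; ++r) {
    fmat P = as_f(patches[r]);
    int n_grid = P.n_rows;
    fmat Y; frowvec pooled, h1pre, h1;
    fmat logits = clf_forward(enc, cls, fc1_W, fc1_b, fc2_W, fc2_b, P, Penc,
                              cls_pool, fmu, fW, use_whiten,
                              ec, Y, pooled, h1pre, h1);
    frowvec z = logits.row(0);
    frowvec y = lab.row(r);
    // numerically stable binary cross-entropy from logits
    for (int k = 0; k < K; ++k) {
      float zi = z(k);
      total_loss += (std::log1p(std::exp(-std::fabs(zi))) +
                     std::max(zi, 0.0f) - zi * y(k)) / K;
      probs(r, k) = 1.0f / (1.0f + std::exp(-zi));
    }
    if (!want_grad) continue;
    frowvec dlogits = (probs.row(r) - y) / (float)(K * B);
    d_fc2_b += dlogits;
    d_fc2_W += h1.t() * dlogits;
    frowvec dh1 = dlogits * fc2_W.t();
    fmat dh1pre = gelu_bwd(fmat(dh1), fmat(h1pre));
    d_fc1_b += dh1pre.row(0);
    d_fc1_W += pooled.t() * dh1pre.row(0);
    frowvec dpooled = dh1pre.row(0) * fc1_W.t();
    if (use_whiten) dpooled = dpooled * fW.t();
    fmat dY(Y.n_rows, Y.n_cols, fill::zeros);
    if (cls_pool) {
      dY.row(0) = dpooled;
    } else {
      for (int j = 1; j <= n_grid; ++j) dY.row(j) = dpooled / (float)n_grid;
    }
    fmat dX0 = tower_bwd(dY, enc, ec, g_enc);
    d_cls += dX0.row(0);
    fmat dXv = dX0.rows(1, n_grid);
    g_enc.embed_b += sum(dXv, 0);
    g_enc.embed_W += P.t() * dXv;
  }
  double loss = total_loss / B;
  List out = List::create(Named("loss") = loss,
                          Named("probs") = to_R(probs));
  if (want_grad) {
    List ge = grad_to_R(g_enc);
    ge["cls"] = to_R(d_cls);
    List gh = List::create(
      Named("fc1_W") = to_R(d_fc1_W), Named("fc1_b") = to_R(d_fc1_b),
      Named("fc2_W") = to_R(d_fc2_W), Named("fc2_b") = to_R(d_fc2_b));
    out["grads"] = List::create(Named("enc") = ge, Named("head") = gh);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_clf_predict(List enc_params, List head_params,
                                    int enc_heads, List patches,
                                    Rcpp::NumericMatrix pos_enc,
                                    bool cls_pool,
                                    Rcpp::NumericMatrix feat_mu,
                                    Rcpp::NumericMatrix feat_W,
                                    bool use_whiten) {
  Tower enc = load_tower(enc_params, enc_heads);
  frowvec cls = as_frow(enc_params["cls"]);
  fmat fc1_W = as_f(head_params["fc1_W"]);
  frowvec fc1_b = as_frow(head_params["fc1_b"]);
  fmat fc2_W = as_f(head_params["fc2_W"]);
  frowvec fc2_b = as_frow(head_params["fc2_b"]);
  fmat Penc = as_f(pos_enc);
  frowvec fmu = use_whiten ? as_frow(feat_mu) : frowvec();
  fmat fW = use_whiten ? as_f(feat_W) : fmat();
  int B = patches.size(), K = fc2_W.n_cols;
  fmat probs(B, K);
  TowerCache ec;   // reused across the batch
  for (int r = 0; r < B; ++r) {
    fmat P = as_f(patches[r]);
    fmat Y; frowvec pooled, h1pre, h1;
    fmat logits = clf_forward(enc, cls, fc1_W, fc1_b, fc2_W, fc2_b, P, Penc,
                              cls_pool, fmu, fW, use_whiten,
                              ec, Y, pooled, h1pre, h1);
    for (int k = 0; k < K; ++k) {
      probs(r, k) = 1.0f / (1.0f + std::exp(-logits(0, k)));
    }
  }
  return to_R(probs);
}

// ---- fused Adam / AdamW update ------------------------------------------

// Recursively updates params from grads over parallel nested lists of
// double matrices, matching named elements by name. Fresh parameter
// leaves are returned; the first/second-moment trees (m, v) are owned by
// the optimizer state and are updated in place to avoid re-allocating the
// full tree every step. Bias corrections use step counter t (1-based).
static List adam_rec(const List& p, const List& g, List m, List v,
                     SEXP lmult, double lr, double beta1, double beta2,
                     double bc1, double bc2, double eps, double wd) {
  Rcpp::List np(p.size());
  bool has_mult = !Rf_isNull(lmult);
  Rcpp::CharacterVector names = p.hasAttribute("names")
    ? Rcpp::CharacterVector(p.names()) : Rcpp::CharacterVector(0);
  for (int i = 0; i < p.size(); ++i) {
    SEXP pi = p[i];
    SEXP gi, mi, vi, li = R_NilValue;
    if (names.size() == p.size()) {
      std::string key = Rcpp::as<std::string>(names[i]);
      gi = g[key]; mi = m[key]; vi = v[key];
      if (has_mult) li = Rcpp::List(lmult)[key];
    } else {
      gi = g[i]; mi = m[i]; vi = v[i];
      if (has_mult) li = Rcpp::List(lmult)[i];
    }
    if (Rf_isMatrix(pi) || Rf_isNumeric(pi)) {
      Rcpp::NumericVector pv(Rcpp::clone(pi)), gv(gi);
      double* pm = REAL(mi);
      double* pvv = REAL(vi);
      double* pp = REAL(SEXP(pv));
      double* pg = REAL(SEXP(gv));
      double lri = lr * (has_mult ? Rcpp::as<double>(li) : 1.0);
      R_xlen_t n = pv.size();
      for (R_xlen_t k = 0; k < n; ++k) {
        double gk = pg[k];
        double mk = beta1 * pm[k] + (1 - beta1) * gk;
        double vk = beta2 * pvv[k] + (1 - beta2) * gk * gk;
        pm[k] = mk; pvv[k] = vk;
        pp[k] -= lri * ((mk / bc1) / (std::sqrt(vk / bc2) + eps) +
                        wd * pp[k]);
      }
      np[i] = pv;
    } else {
      np[i] = adam_rec(pi, gi, mi, vi, li, lr, beta1, beta2, bc1, bc2,
                       eps, wd);
    }
  }
  if (names.size() == p.size()) np.names() = names;
  return np;
}

// [[Rcpp::export]]
List cpp_adam_update(List params, List grads, List m, List v, int t,
                     double lr, double beta1, double beta2, double eps,
                     double weight_decay,
                     Rcpp::Nullable<List> lr_mult = R_NilValue) {
  double bc1 = 1 - std::pow(beta1, t);
  double bc2 = 1 - std::pow(beta2, t);
  SEXP lm = lr_mult.isNotNull() ? SEXP(lr_mult.get()) : R_NilValue;
  List p = adam_rec(params, grads, m, v, lm, lr, beta1, beta2, bc1, bc2,
                    eps, weight_decay);
  return List::create(Named("p") = p, Named("m") = m, Named("v") = v);
}
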