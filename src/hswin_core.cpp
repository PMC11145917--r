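// Single-precision compute core for the hybrid 3D Swin transformer.
//
// One call runs the full forward (and optionally backward) pass for a batch
// in float32, which roughly doubles dgemm-bound throughput on a single CPU
// core. The R implementation of the same graph (double precision) is kept
// as the reference; the test suite checks both routes agree.
//
// Index structures (permutations, masks, grouping indices) are precomputed
// in R (1-based) and passed in via the plan list.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

typedef std::map<std::string, fmat> ParamMap;

static const float LN_EPS_F = 1e-5f;
static const float NEG_MASK = -1e9f;

struct StagePlan {
  int N, ws, nwin;
  bool can_shift;
  uvec perm0, perm_s;      // 0-based
  fcube mask;              // (ws, ws, nwin) or empty
  uvec relidx;             // 0-based, length ws*ws
};

struct ConvPlan {
  uvec idx;                // 0-based, nvox*27 (column-major, col = kernel tap)
  ivec pd;                 // padded dims
  int dil;
};

struct Plan {
  ivec dims;
  int nvox, B, n_classes;
  ivec depths, sdims, heads, hidden;
  bool hybrid;
  int n_dil, conv_channels, fused_channels;
  umat embed_idx;          // (N1, P8), 0-based
  std::vector<umat> merge_idx;
  std::vector<StagePlan> stages;
  std::vector<ConvPlan> conv;
};

static uvec as_uvec0(SEXP x) {
  Rcpp::IntegerVector v(x);
  uvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (uword)(v[i] - 1);
  return out;
}

static umat as_umat0(SEXP x) {
  Rcpp::IntegerMatrix m(x);
  umat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (uword)(m(i, j) - 1);
  return out;
}

static fcube as_fcube(SEXP x) {
  Rcpp::NumericVector v(x);
  if (v.size() == 0) return fcube();
  Rcpp::IntegerVector d = v.attr("dim");
  fcube out(d[0], d[1], d[2]);
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static Plan parse_plan(const Rcpp::List& pl) {
  Plan p;
  p.dims = Rcpp::as<ivec>(pl["dims"]);
  p.nvox = Rcpp::as<int>(pl["nvox"]);
  p.B = Rcpp::as<int>(pl["B"]);
  p.n_classes = Rcpp::as<int>(pl["n_classes"]);
  p.depths = Rcpp::as<ivec>(pl["depths"]);
  p.sdims = Rcpp::as<ivec>(pl["sdims"]);
  p.heads = Rcpp::as<ivec>(pl["heads"]);
  p.hidden = Rcpp::as<ivec>(pl["hidden"]);
  p.hybrid = Rcpp::as<bool>(pl["hybrid"]);
  p.n_dil = Rcpp::as<int>(pl["n_dil"]);
  p.conv_channels = Rcpp::as<int>(pl["conv_channels"]);
  p.fused_channels = Rcpp::as<int>(pl["fused_channels"]);
  p.embed_idx = as_umat0(pl["embed_idx"]);
  Rcpp::List mi(pl["merge_idx"]);
  for (int s = 0; s < 3; ++s) p.merge_idx.push_back(as_umat0(mi[s]));
  Rcpp::List st(pl["stages"]);
  for (int s = 0; s < 4; ++s) {
    Rcpp::List e(st[s]);
    StagePlan sp;
    sp.N = Rcpp::as<int>(e["N"]);
    sp.ws = Rcpp::as<int>(e["ws"]);
    sp.nwin = Rcpp::as<int>(e["nwin"]);
    sp.can_shift = Rcpp::as<bool>(e["can_shift"]);
    sp.perm0 = as_uvec0(e["perm0"]);
    if (sp.can_shift) {
      sp.perm_s = as_uvec0(e["perm_s"]);
      sp.mask = as_fcube(e["mask"]);
    }
    sp.relidx = as_uvec0(e["relidx"]);
    p.stages.push_back(sp);
  }
  if (p.hybrid) {
    Rcpp::List cv(pl["conv"]);
    for (int k = 0; k < p.n_dil; ++k) {
      Rcpp::List e(cv[k]);
      ConvPlan c;
      c.idx = as_uvec0(e["idx"]);
      c.pd = Rcpp::as<ivec>(e["pd"]);
      c.dil = Rcpp::as<int>(e["dil"]);
      p.conv.push_back(c);
    }
  }
  return p;
}

static ParamMap parse_params(const Rcpp::List& params) {
  ParamMap P;
  Rcpp::CharacterVector nms = params.names();
  for (int i = 0; i < params.size(); ++i) {
    Rcpp::NumericVector v(params[i]);
    std::string nm = Rcpp::as<std::string>(nms[i]);
    SEXP dimA = v.attr("dim");
    fmat M;
    if (Rf_isNull(dimA)) {
      M.set_size(1, v.size());
      for (int k = 0; k < v.size(); ++k) M[k] = (float)v[k];
    } else {
      Rcpp::IntegerVector d(dimA);
      M.set_size(d[0], d[1]);
      for (int k = 0; k < v.size(); ++k) M[k] = (float)v[k];
    }
    P[nm] = M;
  }
  return P;
}

// ---- primitive layers ------------------------------------------------------

struct LnCache { fmat xhat, Y; fvec inv; };

static fmat linear_f(const fmat& X, const fmat& W, const fmat& b) {
  fmat Y = X * W;
  Y.each_row() += b.row(0);
  return Y;
}

static LnCache ln_fwd(const fmat& X, const fmat& g, const fmat& b) {
  LnCache c;
  fvec mu = mean(X, 1);
  fmat xc = X.each_col() - mu;
  fvec v = mean(square(xc), 1);
  c.inv = 1.0f / sqrt(v + LN_EPS_F);
  c.xhat = xc.each_col() % c.inv;
  c.Y = c.xhat.each_row() % g.row(0);
  c.Y.each_row() += b.row(0);
  return c;
}

static fmat ln_bwd(const fmat& dY, const LnCache& c, const fmat& g,
                   fmat& dg, fmat& db) {
  fmat dxhat = dY.each_row() % g.row(0);
  fvec rm1 = mean(dxhat, 1);
  fvec rm2 = mean(dxhat % c.xhat, 1);
  fmat dX = dxhat.each_col() - rm1;
  dX -= c.xhat.each_col() % rm2;
  dX.each_col() %= c.inv;
  dg = sum(dY % c.xhat, 0);
  db = sum(dY, 0);
  return dX;
}

static const float INV_SQRT2 = 0.70710678118654752f;
static const float INV_SQRT2PI = 0.39894228040143268f;

static fmat gelu_fwd_f(const fmat& X, fmat& Phi) {
  Phi.set_size(X.n_rows, X.n_cols);
  const float* xp = X.memptr();
  float* pp = Phi.memptr();
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i)
    pp[i] = 0.5f * (1.0f + std::erf(xp[i] * INV_SQRT2));
  return X % Phi;
}

static fmat gelu_bwd_f(const fmat& dY, const fmat& X, const fmat& Phi) {
  fmat out(X.n_rows, X.n_cols);
  const float* xp = X.memptr();
  const float* pp = Phi.memptr();
  const float* dp = dY.memptr();
  float* op = out.memptr();
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i) {
    float phi = INV_SQRT2PI * std::exp(-0.5f * xp[i] * xp[i]);
    op[i] = dp[i] * (pp[i] + xp[i] * phi);
  }
  return out;
}

// pack a (B*N x C) matrix into windows: cube (ws, dh, nwin*B*H),
// slice order window-fastest, then batch, then head
static fcube pack_cube(const fmat& M, const uvec& perm, int B, int N,
                       int ws, int nwin, int dh, int H) {
  fcube Q(ws, dh, (uword)(nwin * B * H));
  const int nwinB = nwin * B;
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < nwin; ++w)
      for (int t = 0; t < ws; ++t) {
        const uword src = (uword)b * N + perm[(uword)w * ws + t];
        for (int h = 0; h < H; ++h) {
          float* dst = Q.slice_memptr((uword)(h * nwinB + b * nwin + w));
          for (int d = 0; d < dh; ++d)
            dst[(uword)d * ws + t] = M(src, h * dh + d);
        }
      }
  return Q;
}

static fmat unpack_cube(const fcube& Q, const uvec& perm, int B, int N,
                        int ws, int nwin, int dh, int H) {
  const int C = dh * H;
  const int nwinB = nwin * B;
  fmat M((uword)B * N, C);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < nwin; ++w)
      for (int t = 0; t < ws; ++t) {
        const uword dst = (uword)b * N + perm[(uword)w * ws + t];
        for (int h = 0; h < H; ++h) {
          const float* src = Q.slice_memptr((uword)(h * nwinB + b * nwin + w));
          for (int d = 0; d < dh; ++d)
            M(dst, h * dh + d) = src[(uword)d * ws + t];
        }
      }
  return M;
}

// windowed attention forward with cached softmax probabilities
static fcube attn_fwd_f(const fcube& Q, const fcube& K, const fcube& V,
                        float scale, const fmat& relpos, const uvec& relidx,
                        const fcube& mask, int nwin, int B, int H,
                        fcube& P) {
  const uword ws = Q.n_rows, S = Q.n_slices;
  const uword nwinB = (uword)(nwin * B);
  const bool has_mask = mask.n_elem > 0;
  fcube out(ws, Q.n_cols, S);
  P.set_size(ws, ws, S);
  // per-head bias matrices from the relative-position table
  std::vector<fmat> bias((size_t)H);
  for (int h = 0; h < H; ++h) {
    fmat bh(ws, ws);
    for (uword i = 0; i < ws * ws; ++i) bh[i] = relpos(relidx[i], h);
    bias[(size_t)h] = bh;
  }
  fmat s(ws, ws);
  for (uword sl = 0; sl < S; ++sl) {
    const uword wb = sl % nwinB;
    const uword w = wb % (uword)nwin;
    const uword h = sl / nwinB;
    s = Q.slice(sl) * K.slice(sl).t() * scale;
    s += bias[(size_t)h];
    if (has_mask) s += mask.slice(w);
    fvec mx = max(s, 1);
    s.each_col() -= mx;
    s = exp(s);
    fvec rs = sum(s, 1);
    s.each_col() /= rs;
    P.slice(sl) = s;
    out.slice(sl) = s * V.slice(sl);
  }
  return out;
}

static void attn_bwd_f(const fcube& dOut, const fcube& Q, const fcube& K,
                       const fcube& V, const fcube& P, float scale,
                       const uvec& relidx, int nwin, int B, int H,
                       fcube& dQ, fcube& dK, fcube& dV, fmat& drel,
                       int nrel) {
  const uword ws = Q.n_rows, S = Q.n_slices;
  const uword nwinB = (uword)(nwin * B);
  dQ.set_size(size(Q)); dK.set_size(size(K)); dV.set_size(size(V));
  std::vector<fmat> dbias((size_t)H, fmat(ws, ws, fill::zeros));
  fmat dP(ws, ws), dS(ws, ws);
  for (uword sl = 0; sl < S; ++sl) {
    const uword h = sl / nwinB;
    dV.slice(sl) = P.slice(sl).t() * dOut.slice(sl);
    dP = dOut.slice(sl) * V.slice(sl).t();
    fvec rs = sum(dP % P.slice(sl), 1);
    dS = P.slice(sl) % (dP.each_col() - rs);
    dbias[(size_t)h] += dS;
    dQ.slice(sl) = dS * K.slice(sl) * scale;
    dK.slice(sl) = dS.t() * Q.slice(sl) * scale;
  }
  drel.zeros(nrel, H);
  for (int h = 0; h < H; ++h) {
    const fmat& bh = dbias[(size_t)h];
    for (uword i = 0; i < ws * ws; ++i) drel(relidx[i], h) += bh[i];
  }
}

// gather fine rows under a coarse grouping: (B*Nf x F) -> (B*Nc x P*F)
static fmat f2c(const fmat& M, const umat& idx, int B, int Nf) {
  const int Nc = idx.n_rows, P = idx.n_cols, F = M.n_cols;
  fmat out((uword)B * Nc, (uword)P * F);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int p = 0; p < P; ++p)
        for (int t = 0; t < Nc; ++t)
          out((uword)b * Nc + t, (uword)(p + f * P))
            = M((uword)b * Nf + idx(t, p), f);
  return out;
}

static fmat c2f(const fmat& M, const umat& idx, int B, int Nf) {
  const int Nc = idx.n_rows, P = idx.n_cols;
  const int F = M.n_cols / P;
  fmat out((uword)B * Nf, F);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int p = 0; p < P; ++p)
        for (int t = 0; t < Nc; ++t)
          out((uword)b * Nf + idx(t, p), f)
            = M((uword)b * Nc + t, (uword)(p + f * P));
  return out;
}

// ---- Swin block ------------------------------------------------------------

struct BlockCache {
  LnCache ln1, ln2;
  fcube Qc, Kc, Vc, P;
  fmat A, X, X1, gl_x, gl_phi;
  bool shifted;
};

static fmat block_fwd(const fmat& X, const ParamMap& P, const std::string& pre,
                      const StagePlan& sp, int B, int H, bool shifted,
                      bool train, BlockCache* cache) {
  const int C = X.n_cols, dh = C / H;
  const uvec& perm = shifted ? sp.perm_s : sp.perm0;
  static const fcube empty_mask;
  LnCache ln1 = ln_fwd(X, P.at(pre + ".ln1_g"), P.at(pre + ".ln1_b"));
  fmat qkv = linear_f(ln1.Y, P.at(pre + ".qkv_w"), P.at(pre + ".qkv_b"));
  fcube Qc = pack_cube(qkv.cols(0, C - 1), perm, B, sp.N, sp.ws, sp.nwin, dh, H);
  fcube Kc = pack_cube(qkv.cols(C, 2 * C - 1), perm, B, sp.N, sp.ws, sp.nwin, dh, H);
  fcube Vc = pack_cube(qkv.cols(2 * C, 3 * C - 1), perm, B, sp.N, sp.ws, sp.nwin, dh, H);
  fcube Pr;
  fcube outc = attn_fwd_f(Qc, Kc, Vc, 1.0f / std::sqrt((float)dh),
                          P.at(pre + ".relpos"), sp.relidx,
                          shifted ? sp.mask : empty_mask, sp.nwin, B, H, Pr);
  fmat A = unpack_cube(outc, perm, B, sp.N, sp.ws, sp.nwin, dh, H);
  fmat X1 = X + linear_f(A, P.at(pre + ".proj_w"), P.at(pre + ".proj_b"));
  LnCache ln2 = ln_fwd(X1, P.at(pre + ".ln2_g"), P.at(pre + ".ln2_b"));
  fmat f1 = linear_f(ln2.Y, P.at(pre + ".fc1_w"), P.at(pre + ".fc1_b"));
  fmat Phi;
  fmat g = gelu_fwd_f(f1, Phi);
  fmat X2 = X1 + linear_f(g, P.at(pre + ".fc2_w"), P.at(pre + ".fc2_b"));
  if (train && cache) {
    cache->ln1 = std::move(ln1); cache->ln2 = std::move(ln2);
    cache->Qc = std::move(Qc); cache->Kc = std::move(Kc);
    cache->Vc = std::move(Vc); cache->P = std::move(Pr);
    cache->A = std::move(A); cache->X = X; cache->X1 = std::move(X1);
    cache->gl_x = std::move(f1); cache->gl_phi = std::move(Phi);
    cache->shifted = shifted;
  }
  return X2;
}

static fmat block_bwd(const fmat& dX2, BlockCache& c, const ParamMap& P,
                      const std::string& pre, const StagePlan& sp, int B,
                      int H, ParamMap& G) {
  const int C = dX2.n_cols, dh = C / H;
  const uvec& perm = c.shifted ? sp.perm_s : sp.perm0;
  // MLP branch
  fmat gY = c.gl_x % c.gl_phi;
  G[pre + ".fc2_w"] = gY.t() * dX2;
  G[pre + ".fc2_b"] = sum(dX2, 0);
  fmat dg = dX2 * P.at(pre + ".fc2_w").t();
  fmat df1 = gelu_bwd_f(dg, c.gl_x, c.gl_phi);
  G[pre + ".fc1_w"] = c.ln2.Y.t() * df1;
  G[pre + ".fc1_b"] = sum(df1, 0);
  fmat dh2 = df1 * P.at(pre + ".fc1_w").t();
  fmat dg2, db2;
  fmat dX1 = dX2 + ln_bwd(dh2, c.ln2, P.at(pre + ".ln2_g"), dg2, db2);
  G[pre + ".ln2_g"] = dg2; G[pre + ".ln2_b"] = db2;
  // attention branch
  G[pre + ".proj_w"] = c.A.t() * dX1;
  G[pre + ".proj_b"] = sum(dX1, 0);
  fmat dA = dX1 * P.at(pre + ".proj_w").t();
  fcube dOut = pack_cube(dA, perm, B, sp.N, sp.ws, sp.nwin, dh, H);
  fcube dQ, dK, dV;
  fmat drel;
  attn_bwd_f(dOut, c.Qc, c.Kc, c.Vc, c.P, 1.0f / std::sqrt((float)dh),
             sp.relidx, sp.nwin, B, H, dQ, dK, dV, drel,
             P.at(pre + ".relpos").n_rows);
  G[pre + ".relpos"] = drel;
  fmat dqkv = join_rows(unpack_cube(dQ, perm, B, sp.N, sp.ws, sp.nwin, dh, H),
                        unpack_cube(dK, perm, B, sp.N, sp.ws, sp.nwin, dh, H),
                        unpack_cube(dV, perm, B, sp.N, sp.ws, sp.nwin, dh, H));
  G[pre + ".qkv_w"] = c.ln1.Y.t() * dqkv;
  G[pre + ".qkv_b"] = sum(dqkv, 0);
  fmat dhh = dqkv * P.at(pre + ".qkv_w").t();
  fmat dg1, db1;
  fmat dX = ln_bwd(dhh, c.ln1, P.at(pre + ".ln1_g"), dg1, db1);
  G[pre + ".ln1_g"] = dg1; G[pre + ".ln1_b"] = db1;
  return dX1 + dX;
}

// ---- full pass -------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List hswin_pass_cpp(const Rcpp::List& params, const Rcpp::List& plan_r,
                          const Rcpp::List& xs, const Rcpp::IntegerVector& y,
                          bool train) {
  Plan pl = parse_plan(plan_r);
  ParamMap P = parse_params(params);
  const int B = pl.B, nvox = pl.nvox;
  const bool do_grad = train && y.size() > 0;

  // stack input voxels sample-major
  fmat R((uword)B * nvox, 1);
  std::vector<Rcpp::NumericVector> xv;
  for (int b = 0; b < B; ++b) {
    Rcpp::NumericVector x(xs[b]);
    for (int i = 0; i < nvox; ++i) R((uword)b * nvox + i, 0) = (float)x[i];
  }

  // dilated-convolution front end
  fmat V;
  std::vector<fmat> conv_cols;
  fmat front_cat;             // pre-ReLU concat
  fmat fuse_in, fuse_pre;     // ReLU(concat), pre-ReLU fused
  if (pl.hybrid) {
    const int cc = pl.conv_channels;
    fmat cat((uword)B * nvox, (uword)pl.n_dil * cc);
    for (int k = 0; k < pl.n_dil; ++k) {
      const ConvPlan& cp = pl.conv[k];
      const int pn = cp.pd[0] * cp.pd[1] * cp.pd[2];
      fvec pad(pn, fill::zeros);
      fmat Xcol((uword)B * nvox, 27);
      for (int b = 0; b < B; ++b) {
        // zero-padded copy of the sample
        pad.zeros();
        const float* src = R.colptr(0) + (uword)b * nvox;
        const int dz = cp.dil;
        for (int x3 = 0; x3 < pl.dims[2]; ++x3)
          for (int x2 = 0; x2 < pl.dims[1]; ++x2) {
            const uword off_src = (uword)(x2 * pl.dims[0] + x3 * pl.dims[0] * pl.dims[1]);
            const uword off_dst = (uword)(dz + (x2 + dz) * cp.pd[0] +
                                          (x3 + dz) * cp.pd[0] * cp.pd[1]);
            std::memcpy(pad.memptr() + off_dst, src + off_src,
                        sizeof(float) * pl.dims[0]);
          }
        for (int t = 0; t < 27; ++t) {
          const uvec::elem_type* ip = cp.idx.memptr() + (uword)t * nvox;
          float* dst = Xcol.colptr(t) + (uword)b * nvox;
          for (int i = 0; i < nvox; ++i) dst[i] = pad[ip[i]];
        }
      }
      char nm[32];
      std::snprintf(nm, sizeof(nm), "front.conv%d", k + 1);
      fmat Yk = linear_f(Xcol, P.at(std::string(nm) + ".w"),
                         P.at(std::string(nm) + ".b"));
      cat.cols((uword)k * cc, (uword)(k + 1) * cc - 1) = Yk;
      if (do_grad) conv_cols.push_back(std::move(Xcol));
    }
    front_cat = std::move(cat);
    fuse_in = front_cat;
    fuse_in.transform([](float v) { return v > 0 ? v : 0.0f; });
    fuse_pre = linear_f(fuse_in, P.at("front.fuse.w"), P.at("front.fuse.b"));
    V = fuse_pre;
    V.transform([](float v) { return v > 0 ? v : 0.0f; });
  } else {
    V = R;
  }

  // patch embedding
  fmat Xtok = f2c(V, pl.embed_idx, B, nvox);
  fmat emb = linear_f(Xtok, P.at("embed.w"), P.at("embed.b"));
  LnCache eln = ln_fwd(emb, P.at("embed.ln_g"), P.at("embed.ln_b"));
  fmat X = eln.Y;

  // encoder
  std::vector<fmat> skips(3);
  std::vector<std::vector<BlockCache>> enc_bc(4);
  std::vector<LnCache> merge_ln(3);
  char pre[32];
  for (int s = 0; s < 4; ++s) {
    const StagePlan& sp = pl.stages[s];
    enc_bc[s].resize(pl.depths[s]);
    for (int i = 0; i < pl.depths[s]; ++i) {
      bool shifted = ((i + 1) % 2 == 0) && sp.can_shift;
      std::snprintf(pre, sizeof(pre), "enc%d.b%d", s + 1, i + 1);
      X = block_fwd(X, P, pre, sp, B, pl.heads[s], shifted, do_grad,
                    &enc_bc[s][i]);
    }
    if (s < 3) {
      skips[s] = X;
      fmat Xcat = f2c(X, pl.merge_idx[s], B, sp.N);
      std::snprintf(pre, sizeof(pre), "merge%d", s + 1);
      merge_ln[s] = ln_fwd(Xcat, P.at(std::string(pre) + ".ln_g"),
                           P.at(std::string(pre) + ".ln_b"));
      X = linear_f(merge_ln[s].Y, P.at(std::string(pre) + ".w"),
                   P.at(std::string(pre) + ".b"));
    }
  }

  // decoder
  std::vector<std::vector<BlockCache>> dec_bc(3);
  std::vector<fmat> dec_xin(3), dec_xcat(3);
  for (int s = 2; s >= 0; --s) {
    const StagePlan& sp = pl.stages[s];
    std::snprintf(pre, sizeof(pre), "dec%d", s + 1);
    if (do_grad) dec_xin[s] = X;
    fmat Yx = linear_f(X, P.at(std::string(pre) + ".expand_w"),
                       P.at(std::string(pre) + ".expand_b"));
    fmat Xup = c2f(Yx, pl.merge_idx[s], B, sp.N);
    fmat Xcat = join_rows(Xup, skips[s]);
    X = linear_f(Xcat, P.at(std::string(pre) + ".fuse_w"),
                 P.at(std::string(pre) + ".fuse_b"));
    if (do_grad) dec_xcat[s] = std::move(Xcat);
    dec_bc[s].resize(pl.depths[s]);
    for (int i = 0; i < pl.depths[s]; ++i) {
      bool shifted = ((i + 1) % 2 == 0) && sp.can_shift;
      std::snprintf(pre, sizeof(pre), "dec%d.b%d", s + 1, i + 1);
      X = block_fwd(X, P, pre, sp, B, pl.heads[s], shifted, do_grad,
                    &dec_bc[s][i]);
    }
  }

  // final expansion + head
  fmat Yf = linear_f(X, P.at("final.expand_w"), P.at("final.expand_b"));
  fmat Vout = c2f(Yf, pl.embed_idx, B, nvox);
  LnCache fln = ln_fwd(Vout, P.at("final.ln_g"), P.at("final.ln_b"));
  fmat logits = linear_f(fln.Y, P.at("head.w"), P.at("head.b"));

  if (!do_grad) {
    mat out = conv_to<mat>::from(logits);
    return Rcpp::List::create(Rcpp::Named("logits") = out);
  }

  // ---- loss: class-weighted voxel cross-entropy + per-patch soft Dice ------
  const uword n = logits.n_rows;
  fvec mx = max(logits, 1);
  fmat probs = exp(logits.each_col() - mx);
  fvec rs = sum(probs, 1);
  probs.each_col() /= rs;
  // foreground weight = background/foreground ratio of the batch, capped at 50
  double n_pos = 0;
  for (uword i = 0; i < n; ++i) n_pos += (y[i] == 1);
  double pw = 1.0;
  if (n_pos > 0) pw = std::min(50.0, std::max(1.0, ((double)n - n_pos) / n_pos));
  const double wsum = ((double)n - n_pos) + pw * n_pos;
  double ce = 0;
  fmat dlog(n, logits.n_cols, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    const int yi = y[i];
    const double wi = (yi == 1 ? pw : 1.0) / wsum;
    ce -= wi * std::log((double)probs(i, yi) + 1e-12);
    for (int k = 0; k < (int)logits.n_cols; ++k)
      dlog(i, k) = (float)((probs(i, k) - (k == yi ? 1.0f : 0.0f)) * wi);
  }
  double dice_loss = 0;
  int n_dice = 0;
  fvec dpf(n, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double I = 0, Sp = 0, Sg = 0;
    for (int i = 0; i < nvox; ++i) {
      const uword r = (uword)b * nvox + i;
      const double pf = probs(r, 1), g = y[r];
      I += pf * g; Sp += pf; Sg += g;
    }
    if (Sg == 0) continue;
    const double den = Sp + Sg + 1e-6;
    dice_loss += 1.0 - 2.0 * I / den;
    ++n_dice;
    for (int i = 0; i < nvox; ++i) {
      const uword r = (uword)b * nvox + i;
      dpf[r] = (float)(-(2.0 * y[r] / den - 2.0 * I / (den * den)));
    }
  }
  if (n_dice > 0) {
    dice_loss /= n_dice;
    dpf /= (float)n_dice;
    // back through softmax (only the foreground prob is touched)
    for (uword i = 0; i < n; ++i) {
      const float p1 = probs(i, 1), p0 = probs(i, 0);
      const float srow = dpf[i] * p1;
      dlog(i, 0) += p0 * (-srow);
      dlog(i, 1) += p1 * (dpf[i] - srow);
    }
  }

  // ---- backward -------------------------------------------------------------
  ParamMap G;
  G["head.w"] = fln.Y.t() * dlog;
  G["head.b"] = sum(dlog, 0);
  fmat dfln = dlog * P.at("head.w").t();
  fmat dgF, dbF;
  fmat dVout = ln_bwd(dfln, fln, P.at("final.ln_g"), dgF, dbF);
  G["final.ln_g"] = dgF; G["final.ln_b"] = dbF;
  fmat dYf = f2c(dVout, pl.embed_idx, B, nvox);
  G["final.expand_w"] = X.t() * dYf;
  G["final.expand_b"] = sum(dYf, 0);
  fmat dX = dYf * P.at("final.expand_w").t();

  std::vector<fmat> dskips(3);
  for (int s = 0; s < 3; ++s) {
    const StagePlan& sp = pl.stages[s];
    for (int i = pl.depths[s] - 1; i >= 0; --i) {
      std::snprintf(pre, sizeof(pre), "dec%d.b%d", s + 1, i + 1);
      dX = block_bwd(dX, dec_bc[s][i], P, pre, sp, B, pl.heads[s], G);
    }
    std::snprintf(pre, sizeof(pre), "dec%d", s + 1);
    G[std::string(pre) + ".fuse_w"] = dec_xcat[s].t() * dX;
    G[std::string(pre) + ".fuse_b"] = sum(dX, 0);
    fmat dcat = dX * P.at(std::string(pre) + ".fuse_w").t();
    const int D = pl.sdims[s];
    fmat dXup = dcat.cols(0, D - 1);
    dskips[s] = dcat.cols(D, 2 * D - 1);
    fmat dYx = f2c(dXup, pl.merge_idx[s], B, sp.N);
    G[std::string(pre) + ".expand_w"] = dec_xin[s].t() * dYx;
    G[std::string(pre) + ".expand_b"] = sum(dYx, 0);
    dX = dYx * P.at(std::string(pre) + ".expand_w").t();
  }

  for (int s = 3; s >= 0; --s) {
    const StagePlan& sp = pl.stages[s];
    if (s < 3) {
      std::snprintf(pre, sizeof(pre), "merge%d", s + 1);
      G[std::string(pre) + ".w"] = merge_ln[s].Y.t() * dX;
      G[std::string(pre) + ".b"] = sum(dX, 0);
      fmat dmln = dX * P.at(std::string(pre) + ".w").t();
      fmat dgM, dbM;
      fmat dXcat = ln_bwd(dmln, merge_ln[s], P.at(std::string(pre) + ".ln_g"),
                          dgM, dbM);
      G[std::string(pre) + ".ln_g"] = dgM;
      G[std::string(pre) + ".ln_b"] = dbM;
      dX = c2f(dXcat, pl.merge_idx[s], B, sp.N);
      dX += dskips[s];
    }
    for (int i = pl.depths[s] - 1; i >= 0; --i) {
      std::snprintf(pre, sizeof(pre), "enc%d.b%d", s + 1, i + 1);
      dX = block_bwd(dX, enc_bc[s][i], P, pre, sp, B, pl.heads[s], G);
    }
  }

  fmat dgE, dbE;
  fmat demb = ln_bwd(dX, eln, P.at("embed.ln_g"), dgE, dbE);
  G["embed.ln_g"] = dgE; G["embed.ln_b"] = dbE;
  G["embed.w"] = Xtok.t() * demb;
  G["embed.b"] = sum(demb, 0);

  if (pl.hybrid) {
    fmat dXtok = demb * P.at("embed.w").t();
    fmat dV = c2f(dXtok, pl.embed_idx, B, nvox);
    // through fused-conv ReLU
    fmat dfuse = dV;
    {
      const float* pre_p = fuse_pre.memptr();
      float* d = dfuse.memptr();
      for (uword i = 0; i < dfuse.n_elem; ++i)
        if (pre_p[i] <= 0) d[i] = 0;
    }
    G["front.fuse.w"] = fuse_in.t() * dfuse;
    G["front.fuse.b"] = sum(dfuse, 0);
    fmat dcat = dfuse * P.at("front.fuse.w").t();
    {
      const float* pre_p = front_cat.memptr();
      float* d = dcat.memptr();
      for (uword i = 0; i < dcat.n_elem; ++i)
        if (pre_p[i] <= 0) d[i] = 0;
    }
    const int cc = pl.conv_channels;
    for (int k = 0; k < pl.n_dil; ++k) {
      fmat dYk = dcat.cols((uword)k * cc, (uword)(k + 1) * cc - 1);
      char nm[32];
      std::snprintf(nm, sizeof(nm), "front.conv%d", k + 1);
      G[std::string(nm) + ".w"] = conv_cols[k].t() * dYk;
      G[std::string(nm) + ".b"] = sum(dYk, 0);
    }
  }

  // convert grads to doubles
  Rcpp::List Gout;
  for (ParamMap::const_iterator it = G.begin(); it != G.end(); ++it)
    Gout[it->first] = Rcpp::wrap(conv_to<mat>::from(it->second));
  return Rcpp::List::create(
    Rcpp::Named("loss") = ce + dice_loss, Rcpp::Named("ce") = ce,
    Rcpp::Named("dice_loss") = dice_loss, Rcpp::Named("grads") = Gout);
}
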