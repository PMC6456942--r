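// Fused single-precision forward/backward engine for one network branch
// (initial conv -> dense blocks with BN-ReLU-conv layers -> 1x1 transition
// conv + max pool -> final BN-ReLU -> flatten).
//
// The layer math mirrors the R reference implementation in R/nn-ops.R and
// R/network.R exactly; this engine exists because CPU training at realistic
// problem sizes is memory-bandwidth bound.  Three measures keep RAM traffic
// low: intermediates are float, convolutions run per example on an
// L2-resident padded tile (one streaming read of the input instead of one
// per kernel offset), and batchnorm caches only the normalized activations
// xhat — the post-ReLU activations a convolution needs during backward are
// recomputed on the fly from xhat while filling the tile.  Parameters and
// gradients cross the R boundary as doubles in the same nested-list layout
// the R path uses, so the Adam update and all tests are engine-agnostic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// ---- conversions -----------------------------------------------------------

static fmat as_fmat(SEXP x) {
    NumericMatrix m(x);
    fmat out(m.nrow(), m.ncol());
    std::copy(m.begin(), m.end(), out.begin());
    return out;
}

static fcube as_fcube(SEXP x) {
    NumericVector v(x);
    Rcpp::IntegerVector d = v.attr("dim");
    fcube out(d[0], d[1], d[2]);
    std::copy(v.begin(), v.end(), out.begin());
    return out;
}

static fvec as_fvec(SEXP x) {
    NumericVector v(x);
    fvec out(v.size());
    std::copy(v.begin(), v.end(), out.begin());
    return out;
}

static NumericVector wrap_fvec(const fvec& x) {
    NumericVector out(x.n_elem);
    std::copy(x.begin(), x.end(), out.begin());
    return out;
}

static NumericVector wrap_fcube(const fcube& x) {
    NumericVector out(x.n_elem);
    std::copy(x.begin(), x.end(), out.begin());
    out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols,
                                                  x.n_slices);
    return out;
}

// ---- batchnorm + ReLU (fused, single pass per direction) -------------------

struct BNParams {
    fvec gamma, beta, rm, rv;
};

static BNParams read_bn(const List& p) {
    BNParams b;
    b.gamma = as_fvec(p["gamma"]);
    b.beta = as_fvec(p["beta"]);
    b.rm = as_fvec(p["run_mean"]);
    b.rv = as_fvec(p["run_var"]);
    return b;
}

struct BNCache {
    fvec gamma, beta, inv_sd;
    fmat xhat;          // stored only in training mode
    fvec new_rm, new_rv;
};

// training: batch moments, xhat cached, running stats advanced; `out` gets
// relu(gamma * xhat + beta).
static void bn_relu_train(const fmat& x, const BNParams& p, BNCache& c,
                          fmat& out) {
    const uword C = x.n_rows, N = x.n_cols;
    fvec s1(C, fill::zeros), s2(C, fill::zeros);
    const float* xp = x.memptr();
    for (uword j = 0; j < N; ++j) {
        const float* col = xp + j * C;
        for (uword cc = 0; cc < C; ++cc) {
            s1[cc] += col[cc];
            s2[cc] += col[cc] * col[cc];
        }
    }
    fvec mu = s1 / (float)N;
    fvec v = s2 / (float)N - mu % mu;
    v = clamp(v, 0.0f, std::numeric_limits<float>::max());
    c.inv_sd = 1.0f / sqrt(v + BN_EPS);
    c.gamma = p.gamma;
    c.beta = p.beta;
    c.new_rm = (1.0f - BN_MOMENTUM) * p.rm + BN_MOMENTUM * mu;
    c.new_rv = (1.0f - BN_MOMENTUM) * p.rv + BN_MOMENTUM * v;
    c.xhat.set_size(C, N);
    out.set_size(C, N);
    float* xh = c.xhat.memptr();
    float* op = out.memptr();
    for (uword j = 0; j < N; ++j) {
        const float* col = xp + j * C;
        float* xhc = xh + j * C;
        float* oc = op + j * C;
        for (uword cc = 0; cc < C; ++cc) {
            const float h = (col[cc] - mu[cc]) * c.inv_sd[cc];
            xhc[cc] = h;
            const float z = p.gamma[cc] * h + p.beta[cc];
            oc[cc] = z > 0.0f ? z : 0.0f;
        }
    }
}

// evaluation: frozen running statistics, no cache, one multiply-add pass.
static void bn_relu_eval(const fmat& x, const BNParams& p, fmat& out) {
    const uword C = x.n_rows, N = x.n_cols;
    fvec isd = 1.0f / sqrt(p.rv + BN_EPS);
    fvec a = p.gamma % isd;
    fvec b2 = p.beta - a % p.rm;
    out.set_size(C, N);
    const float* xp = x.memptr();
    float* op = out.memptr();
    for (uword j = 0; j < N; ++j) {
        const float* col = xp + j * C;
        float* oc = op + j * C;
        for (uword cc = 0; cc < C; ++cc) {
            const float z = a[cc] * col[cc] + b2[cc];
            oc[cc] = z > 0.0f ? z : 0.0f;
        }
    }
}

struct BNGrad {
    fmat dx;
    fvec dgamma, dbeta;
};

// backward through ReLU and batchnorm; the ReLU mask is recomputed from
// xhat (z = gamma*xhat + beta > 0).
static BNGrad bn_relu_bwd(const fmat& dy, const BNCache& c) {
    const uword C = dy.n_rows, N = dy.n_cols;
    BNGrad g;
    g.dgamma.zeros(C);
    g.dbeta.zeros(C);
    const float* dyp = dy.memptr();
    const float* xh = c.xhat.memptr();
    for (uword j = 0; j < N; ++j) {
        const float* dc = dyp + j * C;
        const float* xc = xh + j * C;
        for (uword cc = 0; cc < C; ++cc) {
            if (c.gamma[cc] * xc[cc] + c.beta[cc] > 0.0f) {
                g.dgamma[cc] += dc[cc] * xc[cc];
                g.dbeta[cc] += dc[cc];
            }
        }
    }
    // mean over columns of d(xhat) and d(xhat)*xhat, in closed form
    fvec m1 = c.gamma % g.dbeta / (float)N;
    fvec m2 = c.gamma % g.dgamma / (float)N;
    g.dx.set_size(C, N);
    float* dxp = g.dx.memptr();
    for (uword j = 0; j < N; ++j) {
        const float* dc = dyp + j * C;
        const float* xc = xh + j * C;
        float* oc = dxp + j * C;
        for (uword cc = 0; cc < C; ++cc) {
            const float dz = (c.gamma[cc] * xc[cc] + c.beta[cc] > 0.0f)
                ? dc[cc] : 0.0f;
            oc[cc] = c.inv_sd[cc] *
                (c.gamma[cc] * dz - m1[cc] - xc[cc] * m2[cc]);
        }
    }
    return g;
}

// ---- convolution on per-example padded tiles -------------------------------

// Optional reconstruction of a convolution's input from a BN cache: the
// input was relu(gamma*xhat + beta), recomputed while filling the tile.
struct Recon {
    const BNCache* bn = nullptr;
};

static void fill_tile(fmat& Xp, const fmat& X, const Recon& rc,
                      const uword i, const int L, const int pad) {
    const uword C = X.n_rows;
    const float* src = X.memptr() + (uword)i * L * C;
    float* dst = Xp.memptr() + (uword)pad * C;
    if (rc.bn == nullptr) {
        std::copy(src, src + (uword)L * C, dst);
    } else {
        const fvec& gamma = rc.bn->gamma;
        const fvec& beta = rc.bn->beta;
        for (uword j = 0; j < (uword)L; ++j)
            for (uword cc = 0; cc < C; ++cc) {
                const float z = gamma[cc] * src[j * C + cc] + beta[cc];
                dst[j * C + cc] = z > 0.0f ? z : 0.0f;
            }
    }
}

// Y(:, i*L + j) = b + sum_d W_d * Xin(:, i*L + j + d - pad), with zero
// padding at example boundaries; Xin is X itself or the BN reconstruction.
static void conv_fwd_f(const fmat& X, const Recon& rc, const fcube& W,
                       const fvec& b, const int n, const int L, fmat& Y) {
    const int k = W.n_slices;
    const int pad = (k - 1) / 2;
    const uword C = X.n_rows;
    Y.set_size(W.n_rows, X.n_cols);
    fmat Xp(C, L + 2 * pad, fill::zeros);
    for (int i = 0; i < n; ++i) {
        fill_tile(Xp, X, rc, i, L, pad);
        auto Yi = Y.cols((uword)i * L, (uword)i * L + L - 1);
        Yi.each_col() = b;
        for (int d = 0; d < k; ++d)
            Yi += W.slice(d) * Xp.cols(d, d + L - 1);
    }
}

struct ConvGrad {
    fmat dx;
    fcube dW;
    fvec db;
};

static ConvGrad conv_bwd_f(const fmat& X, const Recon& rc, const fcube& W,
                           const fmat& dY, const int n, const int L,
                           const bool want_dx) {
    const int k = W.n_slices;
    const int pad = (k - 1) / 2;
    const uword C = X.n_rows;
    ConvGrad g;
    g.dW.zeros(W.n_rows, W.n_cols, k);
    g.db = sum(dY, 1);
    if (want_dx) g.dx.set_size(C, X.n_cols);
    fmat Xp(C, L + 2 * pad, fill::zeros);
    fmat dXp(C, L + 2 * pad);
    for (int i = 0; i < n; ++i) {
        fill_tile(Xp, X, rc, i, L, pad);
        const auto dYi = dY.cols((uword)i * L, (uword)i * L + L - 1);
        if (want_dx) dXp.zeros();
        for (int d = 0; d < k; ++d) {
            g.dW.slice(d) += dYi * Xp.cols(d, d + L - 1).t();
            if (want_dx) dXp.cols(d, d + L - 1) += W.slice(d).t() * dYi;
        }
        if (want_dx)
            g.dx.cols((uword)i * L, (uword)i * L + L - 1) =
                dXp.cols(pad, pad + L - 1);
    }
    return g;
}

// ---- pooling ---------------------------------------------------------------

static fmat pool_fwd_f(const fmat& x, const int n, const int L,
                       const int pool, Mat<unsigned char>& sel) {
    const int Lq = L / pool;
    const uword C = x.n_rows;
    fmat out(C, (uword)n * Lq);
    sel.set_size(C, (uword)n * Lq);
    for (int i = 0; i < n; ++i)
        for (int q = 0; q < Lq; ++q) {
            const uword t = (uword)i * Lq + q;
            const uword b0 = (uword)i * L + (uword)q * pool;
            for (uword cc = 0; cc < C; ++cc) {
                float best = x(cc, b0);
                unsigned char bs = 0;
                for (int s = 1; s < pool; ++s) {
                    const float v = x(cc, b0 + s);
                    if (v > best) { best = v; bs = (unsigned char)s; }
                }
                out(cc, t) = best;
                sel(cc, t) = bs;
            }
        }
    return out;
}

static fmat pool_bwd_f(const fmat& dy, const Mat<unsigned char>& sel,
                       const int n, const int L, const int pool) {
    const int Lq = L / pool;
    const uword C = dy.n_rows;
    fmat dx(C, (uword)n * L, fill::zeros);
    for (int i = 0; i < n; ++i)
        for (int q = 0; q < Lq; ++q) {
            const uword t = (uword)i * Lq + q;
            const uword b0 = (uword)i * L + (uword)q * pool;
            for (uword cc = 0; cc < C; ++cc)
                dx(cc, b0 + sel(cc, t)) = dy(cc, t);
        }
    return dx;
}

// ---- whole-branch engine ---------------------------------------------------

struct Workspace {
    fmat x0;                 // branch input (conv0's input)
    int n, L0, pool, nblocks, nlayers;
    std::vector<std::vector<BNCache>> blocks;      // [block][layer]
    std::vector<BNCache> trans_bn;
    std::vector<Mat<unsigned char>> trans_sel;
    std::vector<int> trans_Lin;
    BNCache bn_final;
    int Lfinal;
};

// [[Rcpp::export]]
List cpp_branch_fwd(const List bp, const NumericMatrix x_, const int n,
                    const int L0, const int pool, const int nblocks,
                    const int nlayers, const bool training) {
    Rcpp::XPtr<Workspace> ws(new Workspace());
    ws->n = n; ws->L0 = L0; ws->pool = pool;
    ws->nblocks = nblocks; ws->nlayers = nlayers;
    ws->x0 = as_fmat(x_);

    const List conv0 = bp["conv0"];
    fmat x;
    conv_fwd_f(ws->x0, Recon(), as_fcube(conv0["W"]), as_fvec(conv0["b"]),
               n, L0, x);
    int L = L0;
    ws->blocks.resize(nblocks);
    ws->trans_bn.resize(nblocks);
    ws->trans_sel.resize(nblocks);
    ws->trans_Lin.resize(nblocks);
    fmat out, h, xc;
    for (int b = 0; b < nblocks; ++b) {
        const List block = bp[std::string("block") + std::to_string(b + 1)];
        ws->blocks[b].resize(nlayers);
        for (int l = 0; l < nlayers; ++l) {
            const List layer = block[l];
            const List conv = layer["conv"];
            const BNParams p = read_bn(layer["bn"]);
            if (training) {
                bn_relu_train(x, p, ws->blocks[b][l], out);
            } else {
                bn_relu_eval(x, p, out);
            }
            conv_fwd_f(out, Recon(), as_fcube(conv["W"]), as_fvec(conv["b"]),
                       n, L, h);
            x = join_vert(x, h);
        }
        const List trans = bp[std::string("trans") + std::to_string(b + 1)];
        const List tconv = trans["conv"];
        const BNParams tp = read_bn(trans["bn"]);
        if (training) {
            bn_relu_train(x, tp, ws->trans_bn[b], out);
        } else {
            bn_relu_eval(x, tp, out);
        }
        conv_fwd_f(out, Recon(), as_fcube(tconv["W"]), as_fvec(tconv["b"]),
                   n, L, xc);
        ws->trans_Lin[b] = L;
        x = pool_fwd_f(xc, n, L, pool, ws->trans_sel[b]);
        L /= pool;
    }
    const BNParams fp = read_bn(bp["bn_final"]);
    if (training) {
        bn_relu_train(x, fp, ws->bn_final, out);
    } else {
        bn_relu_eval(x, fp, out);
    }
    ws->Lfinal = L;

    // flatten: feature (i, c + j*C) = out(c, i*L + j), matching the R path
    const uword C = out.n_rows;
    NumericMatrix feat(n, C * L);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < L; ++j)
            for (uword cc = 0; cc < C; ++cc)
                feat(i, cc + (uword)j * C) = out(cc, (uword)i * L + j);

    List res = List::create(Named("feat") = feat);
    if (training) {
        res["ws"] = ws;
        // updated batchnorm running statistics, shaped like the param tree
        List upd;
        for (int b = 0; b < nblocks; ++b) {
            List bu;
            for (int l = 0; l < nlayers; ++l) {
                const BNCache& c = ws->blocks[b][l];
                bu[std::string("l") + std::to_string(l + 1)] = List::create(
                    Named("bn") = List::create(
                        Named("run_mean") = wrap_fvec(c.new_rm),
                        Named("run_var") = wrap_fvec(c.new_rv)));
            }
            upd[std::string("block") + std::to_string(b + 1)] = bu;
            upd[std::string("trans") + std::to_string(b + 1)] = List::create(
                Named("bn") = List::create(
                    Named("run_mean") = wrap_fvec(ws->trans_bn[b].new_rm),
                    Named("run_var") = wrap_fvec(ws->trans_bn[b].new_rv)));
        }
        upd["bn_final"] = List::create(
            Named("run_mean") = wrap_fvec(ws->bn_final.new_rm),
            Named("run_var") = wrap_fvec(ws->bn_final.new_rv));
        res["bn_updates"] = upd;
    }
    return res;
}

// [[Rcpp::export]]
List cpp_branch_bwd(const List bp, SEXP ws_, const NumericMatrix dfeat_) {
    Rcpp::XPtr<Workspace> ws(ws_);
    const int n = ws->n;
    const int pool = ws->pool;
    int L = ws->Lfinal;
    const uword C = ws->bn_final.xhat.n_rows;

    fmat dx(C, (uword)n * L);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < L; ++j)
            for (uword cc = 0; cc < C; ++cc)
                dx(cc, (uword)i * L + j) = dfeat_(i, cc + (uword)j * C);

    List grads;
    {
        BNGrad g = bn_relu_bwd(dx, ws->bn_final);
        grads["bn_final"] = List::create(
            Named("gamma") = wrap_fvec(g.dgamma),
            Named("beta") = wrap_fvec(g.dbeta));
        dx = std::move(g.dx);
    }
    for (int b = ws->nblocks - 1; b >= 0; --b) {
        const int Lin = ws->trans_Lin[b];
        const List trans = bp[std::string("trans") + std::to_string(b + 1)];
        const List tconv = trans["conv"];
        fmat dxc = pool_bwd_f(dx, ws->trans_sel[b], n, Lin, pool);
        // the transition conv consumed relu(bn(block output)): reconstruct
        // that input from the cached xhat while tiling
        Recon rc;
        rc.bn = &ws->trans_bn[b];
        ConvGrad cg = conv_bwd_f(ws->trans_bn[b].xhat, rc,
                                 as_fcube(tconv["W"]), dxc, n, Lin, true);
        BNGrad bg = bn_relu_bwd(cg.dx, ws->trans_bn[b]);
        grads[std::string("trans") + std::to_string(b + 1)] = List::create(
            Named("bn") = List::create(Named("gamma") = wrap_fvec(bg.dgamma),
                                       Named("beta") = wrap_fvec(bg.dbeta)),
            Named("conv") = List::create(Named("W") = wrap_fcube(cg.dW),
                                         Named("b") = wrap_fvec(cg.db)));
        dx = std::move(bg.dx);

        const List block = bp[std::string("block") + std::to_string(b + 1)];
        std::vector<List> lg(ws->nlayers);
        for (int l = ws->nlayers - 1; l >= 0; --l) {
            const List layer = block[l];
            const List conv = layer["conv"];
            const BNCache& c = ws->blocks[b][l];
            const uword c_in = c.xhat.n_rows;
            const uword g_ch = dx.n_rows - c_in;
            fmat dh = dx.rows(c_in, c_in + g_ch - 1);
            dx = dx.rows(0, c_in - 1);
            Recon rc2;
            rc2.bn = &c;
            ConvGrad cg2 = conv_bwd_f(c.xhat, rc2, as_fcube(conv["W"]), dh,
                                      n, Lin, true);
            BNGrad bg2 = bn_relu_bwd(cg2.dx, c);
            dx += bg2.dx;
            lg[l] = List::create(
                Named("bn") = List::create(
                    Named("gamma") = wrap_fvec(bg2.dgamma),
                    Named("beta") = wrap_fvec(bg2.dbeta)),
                Named("conv") = List::create(Named("W") = wrap_fcube(cg2.dW),
                                             Named("b") = wrap_fvec(cg2.db)));
        }
        List ordered;
        for (int l = 0; l < ws->nlayers; ++l)
            ordered[std::string("l") + std::to_string(l + 1)] = lg[l];
        grads[std::string("block") + std::to_string(b + 1)] = ordered;
    }
    {
        const List conv0 = bp["conv0"];
        ConvGrad cg = conv_bwd_f(ws->x0, Recon(), as_fcube(conv0["W"]), dx,
                                 n, ws->L0, false);
        grads["conv0"] = List::create(Named("W") = wrap_fcube(cg.dW),
                                      Named("b") = wrap_fvec(cg.db));
    }
    return grads;
}
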