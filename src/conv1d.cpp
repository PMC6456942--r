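// 1-D "same" convolution over channel-major batches.
//
// A batch of n signals, each with C channels and L positions, is stored as a
// C x (n*L) matrix whose columns are positions, grouped example-major.  With
// this layout each per-offset contribution is one contiguous GEMM, which is
// what makes CPU training of the network feasible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Copy X into a zero-padded layout with pad columns on each side of every
// example block: C x (n * (L + 2*pad)).
static mat pad_batch(const mat& X, const int n, const int L, const int pad) {
    const int Lp = L + 2 * pad;
    mat Xp(X.n_rows, (uword)n * Lp, fill::zeros);
    for (int i = 0; i < n; ++i) {
        Xp.cols((uword)i * Lp + pad, (uword)i * Lp + pad + L - 1) =
            X.cols((uword)i * L, (uword)i * L + L - 1);
    }
    return Xp;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_fwd(const arma::mat& X, const arma::cube& W,
                         const arma::vec& bias, const int n, const int L) {
    const int k = W.n_slices;
    const int pad = (k - 1) / 2;
    const int Lp = L + 2 * pad;
    const uword C_out = W.n_rows;

    if (k == 1) {
        mat Y = W.slice(0) * X;
        Y.each_col() += bias;
        return Y;
    }

    const mat Xp = pad_batch(X, n, L, pad);
    const uword M = (uword)n * Lp - (k - 1);
    // Yt column t = sum_d W_d * Xp[, t + d]; valid outputs sit at
    // t = i*Lp + j for j in [0, L): all of Xp[, t..t+k-1] stays inside
    // example i's padded block, so no cross-example leakage.
    mat Yt(C_out, M, fill::zeros);
    for (int d = 0; d < k; ++d)
        Yt += W.slice(d) * Xp.cols(d, d + M - 1);

    mat Y(C_out, (uword)n * L);
    for (int i = 0; i < n; ++i)
        Y.cols((uword)i * L, (uword)i * L + L - 1) =
            Yt.cols((uword)i * Lp, (uword)i * Lp + L - 1);
    Y.each_col() += bias;
    return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::mat& X, const arma::cube& W,
                          const arma::mat& dY, const int n, const int L) {
    const int k = W.n_slices;
    const int pad = (k - 1) / 2;
    const int Lp = L + 2 * pad;
    const uword C_in = X.n_rows;
    const uword C_out = W.n_rows;

    if (k == 1) {
        cube dW(C_out, C_in, 1);
        dW.slice(0) = dY * X.t();
        mat dX = W.slice(0).t() * dY;
        vec db = sum(dY, 1);
        return Rcpp::List::create(Rcpp::Named("dx") = dX,
                                  Rcpp::Named("dW") = dW,
                                  Rcpp::Named("db") = db);
    }

    const mat Xp = pad_batch(X, n, L, pad);
    const uword M = (uword)n * Lp - (k - 1);

    // scatter dY into the padded-output layout
    mat dYt(C_out, M, fill::zeros);
    for (int i = 0; i < n; ++i)
        dYt.cols((uword)i * Lp, (uword)i * Lp + L - 1) =
            dY.cols((uword)i * L, (uword)i * L + L - 1);

    cube dW(C_out, C_in, k);
    mat dXp(C_in, (uword)n * Lp, fill::zeros);
    for (int d = 0; d < k; ++d) {
        dW.slice(d) = dYt * Xp.cols(d, d + M - 1).t();
        dXp.cols(d, d + M - 1) += W.slice(d).t() * dYt;
    }

    mat dX(C_in, (uword)n * L);
    for (int i = 0; i < n; ++i)
        dX.cols((uword)i * L, (uword)i * L + L - 1) =
            dXp.cols((uword)i * Lp + pad, (uword)i * Lp + pad + L - 1);

    vec db = sum(dY, 1);
    return Rcpp::List::create(Rcpp::Named("dx") = dX,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
}
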