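// Hot numerical kernels of the encoder: batched self-attention (forward
// and backward), GELU and LayerNorm. Batches are sample-major stacks of
// B blocks of L rows; heads are column blocks of width hidden/H.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// padAdd: B x L additive mask (0 for real tokens, large negative for pads).
// [[Rcpp::export]]
List cpp_attention_forward(const arma::mat& Q, const arma::mat& K,
                           const arma::mat& V, int B, int L, int H,
                           const arma::mat& padAdd) {
    int h = Q.n_cols;
    int dk = h / H;
    double scale = 1.0 / std::sqrt((double)dk);
    arma::mat A(Q.n_rows, h);
    arma::cube P(L, L, (size_t)B * H);
    for (int b = 0; b < B; ++b) {
        arma::uword r0 = (arma::uword)b * L;
        arma::rowvec pad = padAdd.row(b);
        bool hasPad = arma::any(pad < -1.0);
        for (int j = 0; j < H; ++j) {
            arma::uword c0 = (arma::uword)j * dk;
            arma::mat Qb = Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
            arma::mat Kb = K.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
            arma::mat S = Qb * Kb.t() * scale;
            if (hasPad) S.each_row() += pad;
            S.each_col() -= arma::max(S, 1);
            arma::mat E = arma::exp(S);
            E.each_col() /= arma::sum(E, 1);
            P.slice((size_t)b * H + j) = E;
            A.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
                E * V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
        }
    }
    return List::create(Named("A") = A, Named("P") = P);
}

// [[Rcpp::export]]
List cpp_attention_backward(const arma::mat& dA, const arma::mat& Q,
                            const arma::mat& K, const arma::mat& V,
                            const arma::cube& P, int B, int L, int H) {
    int h = Q.n_cols;
    int dk = h / H;
    double scale = 1.0 / std::sqrt((double)dk);
    arma::mat dQ(Q.n_rows, h, arma::fill::zeros);
    arma::mat dK(Q.n_rows, h, arma::fill::zeros);
    arma::mat dV(Q.n_rows, h, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
        arma::uword r0 = (arma::uword)b * L;
        for (int j = 0; j < H; ++j) {
            arma::uword c0 = (arma::uword)j * dk;
            const arma::mat& Pm = P.slice((size_t)b * H + j);
            arma::mat dAb = dA.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
            arma::mat Vb = V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
            arma::mat dP = dAb * Vb.t();
            dV.submat(r0, c0, r0 + L - 1, c0 + dk - 1) = Pm.t() * dAb;
            arma::mat dS = Pm % (dP - arma::repmat(arma::sum(Pm % dP, 1),
                                                   1, L));
            dQ.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
                dS * K.submat(r0, c0, r0 + L - 1, c0 + dk - 1) * scale;
            dK.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
                dS.t() * Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1) * scale;
        }
    }
    return List::create(Named("dQ") = dQ, Named("dK") = dK,
                        Named("dV") = dV);
}

static inline double phi_cdf(double x) {
    return 0.5 * std::erfc(-x * M_SQRT1_2);
}
static inline double phi_pdf(double x) {
    return std::exp(-0.5 * x * x) * 0.3989422804014327;
}

// [[Rcpp::export]]
List cpp_gelu_forward(const arma::mat& Z) {
    arma::mat Phi(Z.n_rows, Z.n_cols);
    for (arma::uword i = 0; i < Z.n_elem; ++i) Phi(i) = phi_cdf(Z(i));
    return List::create(Named("y") = Z % Phi, Named("Phi") = Phi);
}

// [[Rcpp::export]]
arma::mat cpp_gelu_grad(const arma::mat& Z, const arma::mat& Phi) {
    arma::mat G(Z.n_rows, Z.n_cols);
    for (arma::uword i = 0; i < Z.n_elem; ++i)
        G(i) = Phi(i) + Z(i) * phi_pdf(Z(i));
    return G;
}

// [[Rcpp::export]]
List cpp_layernorm_forward(const arma::mat& x, const arma::vec& g,
                           const arma::vec& b, double eps) {
    arma::vec mu = arma::mean(x, 1);
    arma::mat xc = x.each_col() - mu;
    arma::vec invstd = 1.0 / arma::sqrt(arma::mean(xc % xc, 1) + eps);
    arma::mat xhat = xc.each_col() % invstd;
    arma::mat y = xhat.each_row() % g.t();
    y.each_row() += b.t();
    return List::create(Named("y") = y, Named("xhat") = xhat,
                        Named("invstd") = invstd);
}

// [[Rcpp::export]]
List cpp_layernorm_backward(const arma::mat& dy, const arma::mat& xhat,
                            const arma::vec& invstd, const arma::vec& g) {
    arma::mat dxhat = dy.each_row() % g.t();
    arma::vec m1 = arma::mean(dxhat, 1);
    arma::vec m2 = arma::mean(dxhat % xhat, 1);
    arma::mat dx = dxhat;
    dx.each_col() -= m1;
    dx -= xhat.each_col() % m2;
    dx.each_col() %= invstd;
    return List::create(Named("dx") = dx,
                        Named("dg") = arma::sum(dy % xhat, 0).t(),
                        Named("db") = arma::sum(dy, 0).t());
}
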