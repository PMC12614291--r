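#include <Rcpp.h>
using namespace Rcpp;

// im2col for 3x3 convolutions on a channels-last activation matrix.
// x: (BHW x C) activations, rowmap: (BHW x 9) 1-based row indices of the nine
// spatial neighbours (0 encodes a zero-padded position). Returns the patch
// matrix (BHW x 9*C) with columns ordered channel-major: (c-1)*9 + k.
// [[Rcpp::export]]
NumericMatrix im2col0(const NumericMatrix& x, const IntegerMatrix& rowmap) {
    const int n = x.nrow(), C = x.ncol(), K = rowmap.ncol();
    NumericMatrix out(n, K * C);
    for (int c = 0; c < C; ++c) {
        const double* xc = &x(0, c);
        for (int k = 0; k < K; ++k) {
            double* oc = &out(0, c * K + k);
            const int* rm = &rowmap(0, k);
            for (int i = 0; i < n; ++i) {
                int j = rm[i];
                oc[i] = (j > 0) ? xc[j - 1] : 0.0;
            }
        }
    }
    return out;
}

// Adjoint of im2col0: scatter-add the patch-matrix gradient back onto the
// activation gradient (BHW x C).
// [[Rcpp::export]]
NumericMatrix col2im0(const NumericMatrix& g, const IntegerMatrix& rowmap,
                      const int C) {
    const int n = g.nrow(), K = rowmap.ncol();
    NumericMatrix out(n, C);
    for (int c = 0; c < C; ++c) {
        double* oc = &out(0, c);
        for (int k = 0; k < K; ++k) {
            const double* gc = &g(0, c * K + k);
            const int* rm = &rowmap(0, k);
            for (int i = 0; i < n; ++i) {
                int j = rm[i];
                if (j > 0) oc[j - 1] += gc[i];
            }
        }
    }
    return out;
}

// Row gather: out[i, ] = x[rows[i] - 1, ] (rows are 1-based, 0 reads zeros).
// [[Rcpp::export]]
NumericMatrix gather_rows(const NumericMatrix& x, const IntegerVector& rows) {
    const int n = rows.size(), C = x.ncol();
    NumericMatrix out(n, C);
    for (int c = 0; c < C; ++c) {
        const double* xc = &x(0, c);
        double* oc = &out(0, c);
        for (int i = 0; i < n; ++i) {
            int j = rows[i];
            oc[i] = (j > 0) ? xc[j - 1] : 0.0;
        }
    }
    return out;
}

// Adjoint of gather_rows: scatter-add g rows into an (n_out x C) zero matrix.
// [[Rcpp::export]]
NumericMatrix scatter_rows_add(const NumericMatrix& g,
                               const IntegerVector& rows, const int n_out) {
    const int n = rows.size(), C = g.ncol();
    NumericMatrix out(n_out, C);
    for (int c = 0; c < C; ++c) {
        const double* gc = &g(0, c);
        double* oc = &out(0, c);
        for (int i = 0; i < n; ++i) {
            int j = rows[i];
            if (j > 0) oc[j - 1] += gc[i];
        }
    }
    return out;
}

// y = x + b broadcast over rows (bias per column/channel).
// [[Rcpp::export]]
NumericMatrix add_bias(const NumericMatrix& x, const NumericVector& b) {
    const int n = x.nrow(), C = x.ncol();
    NumericMatrix out(n, C);
    for (int c = 0; c < C; ++c) {
        const double* xc = &x(0, c);
        double* oc = &out(0, c);
        const double bc = b[c];
        for (int i = 0; i < n; ++i) oc[i] = xc[i] + bc;
    }
    return out;
}

// SiLU forward; returns y = x * sigmoid(x) with sigmoid(x) attached for the
// backward pass.
// [[Rcpp::export]]
List silu_fwd(const NumericMatrix& x) {
    const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
    NumericMatrix y(x.nrow(), x.ncol()), s(x.nrow(), x.ncol());
    const double* xp = x.begin();
    double* yp = y.begin();
    double* sp = s.begin();
    for (R_xlen_t i = 0; i < n; ++i) {
        double si = 1.0 / (1.0 + std::exp(-xp[i]));
        sp[i] = si;
        yp[i] = xp[i] * si;
    }
    return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericMatrix silu_bwd(const NumericMatrix& g, const NumericMatrix& x,
                       const NumericMatrix& s) {
    const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
    NumericMatrix out(x.nrow(), x.ncol());
    const double* gp = g.begin();
    const double* xp = x.begin();
    const double* sp = s.begin();
    double* op = out.begin();
    for (R_xlen_t i = 0; i < n; ++i) {
        op[i] = gp[i] * sp[i] * (1.0 + xp[i] * (1.0 - sp[i]));
    }
    return out;
}

// Group normalization forward. x: (B*hw x C) sample-major rows; grp: 1-based
// group index per channel (equal group sizes). Returns the normalized+affine
// output, the pre-affine xhat, and per-(sample, group) inverse SDs.
// [[Rcpp::export]]
List gn_fwd(const NumericMatrix& x, const int hw, const IntegerVector& grp,
            const int G, const NumericVector& gamma,
            const NumericVector& beta, const double eps) {
    const int n = x.nrow(), C = x.ncol(), B = n / hw;
    const double cnt = (double)hw * C / G;
    NumericMatrix m(B, G), q(B, G);
    for (int c = 0; c < C; ++c) {
        const int g = grp[c] - 1;
        const double* xc = &x(0, c);
        for (int b = 0; b < B; ++b) {
            double sm = 0.0, sq = 0.0;
            const double* xb = xc + (R_xlen_t)b * hw;
            for (int i = 0; i < hw; ++i) { sm += xb[i]; sq += xb[i] * xb[i]; }
            m(b, g) += sm; q(b, g) += sq;
        }
    }
    NumericMatrix sinv(B, G);
    for (int b = 0; b < B; ++b) {
        for (int g = 0; g < G; ++g) {
            double mu = m(b, g) / cnt;
            double var = q(b, g) / cnt - mu * mu;
            if (var < 0) var = 0;
            m(b, g) = mu;
            sinv(b, g) = 1.0 / std::sqrt(var + eps);
        }
    }
    NumericMatrix xhat(n, C), y(n, C);
    for (int c = 0; c < C; ++c) {
        const int g = grp[c] - 1;
        const double* xc = &x(0, c);
        double* hc = &xhat(0, c);
        double* yc = &y(0, c);
        const double gm = gamma[c], bt = beta[c];
        for (int b = 0; b < B; ++b) {
            const double mu = m(b, g), si = sinv(b, g);
            const R_xlen_t off = (R_xlen_t)b * hw;
            for (int i = 0; i < hw; ++i) {
                double h = (xc[off + i] - mu) * si;
                hc[off + i] = h;
                yc[off + i] = gm * h + bt;
            }
        }
    }
    return List::create(_["y"] = y, _["xhat"] = xhat, _["sinv"] = sinv);
}

// Group normalization backward; returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List gn_bwd(const NumericMatrix& g, const NumericMatrix& xhat,
            const NumericMatrix& sinv, const int hw,
            const IntegerVector& grp, const int G,
            const NumericVector& gamma) {
    const int n = g.nrow(), C = g.ncol(), B = n / hw;
    const double cnt = (double)hw * C / G;
    NumericMatrix md(B, G), cg(B, G);
    NumericVector dgamma(C), dbeta(C);
    for (int c = 0; c < C; ++c) {
        const int gi = grp[c] - 1;
        const double gm = gamma[c];
        const double* gc = &g(0, c);
        const double* hc = &xhat(0, c);
        double sg = 0.0, sb = 0.0;
        for (int b = 0; b < B; ++b) {
            const R_xlen_t off = (R_xlen_t)b * hw;
            double s1 = 0.0, s2 = 0.0;
            for (int i = 0; i < hw; ++i) {
                const double dxh = gc[off + i] * gm;
                s1 += dxh;
                s2 += dxh * hc[off + i];
                sg += gc[off + i] * hc[off + i];
                sb += gc[off + i];
            }
            md(b, gi) += s1; cg(b, gi) += s2;
        }
        dgamma[c] = sg; dbeta[c] = sb;
    }
    for (int b = 0; b < B; ++b) {
        for (int gi = 0; gi < G; ++gi) {
            md(b, gi) /= cnt;
            cg(b, gi) /= cnt;
        }
    }
    NumericMatrix dx(n, C);
    for (int c = 0; c < C; ++c) {
        const int gi = grp[c] - 1;
        const double gm = gamma[c];
        const double* gc = &g(0, c);
        const double* hc = &xhat(0, c);
        double* dc = &dx(0, c);
        for (int b = 0; b < B; ++b) {
            const double si = sinv(b, gi), mdv = md(b, gi), cgv = cg(b, gi);
            const R_xlen_t off = (R_xlen_t)b * hw;
            for (int i = 0; i < hw; ++i) {
                dc[off + i] = si * (gc[off + i] * gm - mdv -
                                    hc[off + i] * cgv);
            }
        }
    }
    return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                        _["dbeta"] = dbeta);
}
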