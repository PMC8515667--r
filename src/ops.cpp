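#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Column-major image tensors throughout: dim = (H, W, C).
// im2col row index o = oh + ow * Ho; column index = kh + kw*k + c*k*k.
// Zero padding; reflect padding is applied in R before calling with pad = 0.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
    const int Ho = (H + 2 * pad - k) / stride + 1;
    const int Wo = (W + 2 * pad - k) / stride + 1;
    NumericMatrix out(Ho * Wo, k * k * C);
    const double *px = x.begin();
    // valid output range for a kernel offset kk: o*stride + kk - pad in [0, n)
    auto lastValid = [](int n, int kk, int stride, int pad) {
        return (n - 1 + pad - kk) / stride;
    };
    auto firstValid = [](int kk, int stride, int pad) {
        int num = pad - kk;
        return num <= 0 ? 0 : (num + stride - 1) / stride;
    };
    for (int c = 0; c < C; ++c) {
        const double *plane = px + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
            const int ow0 = firstValid(kw, stride, pad);
            const int ow1 = std::min(Wo - 1, lastValid(W, kw, stride, pad));
            for (int kh = 0; kh < k; ++kh) {
                const int col = kh + kw * k + c * k * k;
                const int oh0 = firstValid(kh, stride, pad);
                const int oh1 = std::min(Ho - 1,
                                         lastValid(H, kh, stride, pad));
                double *pout = &out(0, col);
                for (int ow = ow0; ow <= ow1; ++ow) {
                    const int iw = ow * stride + kw - pad;
                    const double *pcol = plane + (R_xlen_t)iw * H +
                        (oh0 * stride + kh - pad);
                    double *prow = pout + (R_xlen_t)ow * Ho;
                    if (stride == 1) {
                        std::memcpy(prow + oh0, pcol,
                                    (oh1 - oh0 + 1) * sizeof(double));
                    } else {
                        for (int oh = oh0; oh <= oh1; ++oh)
                            prow[oh] = pcol[(R_xlen_t)(oh - oh0) * stride];
                    }
                }
            }
        }
    }
    return out;
}

// Adjoint of cpp_im2col: scatter-add columns back into an (H, W, C) image.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
    const int Ho = (H + 2 * pad - k) / stride + 1;
    const int Wo = (W + 2 * pad - k) / stride + 1;
    NumericVector out((R_xlen_t)H * W * C);
    double *px = out.begin();
    auto lastValid = [](int n, int kk, int stride, int pad) {
        return (n - 1 + pad - kk) / stride;
    };
    auto firstValid = [](int kk, int stride, int pad) {
        int num = pad - kk;
        return num <= 0 ? 0 : (num + stride - 1) / stride;
    };
    for (int c = 0; c < C; ++c) {
        double *plane = px + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
            const int ow0 = firstValid(kw, stride, pad);
            const int ow1 = std::min(Wo - 1, lastValid(W, kw, stride, pad));
            for (int kh = 0; kh < k; ++kh) {
                const int col = kh + kw * k + c * k * k;
                const int oh0 = firstValid(kh, stride, pad);
                const int oh1 = std::min(Ho - 1,
                                         lastValid(H, kh, stride, pad));
                const double *pin = &cols(0, col);
                for (int ow = ow0; ow <= ow1; ++ow) {
                    const int iw = ow * stride + kw - pad;
                    double *pcol = plane + (R_xlen_t)iw * H +
                        (oh0 * stride + kh - pad);
                    const double *prow = pin + (R_xlen_t)ow * Ho;
                    for (int oh = oh0; oh <= oh1; ++oh)
                        pcol[(R_xlen_t)(oh - oh0) * stride] += prow[oh];
                }
            }
        }
    }
    out.attr("dim") = IntegerVector::create(H, W, C);
    return out;
}

static inline double trilinear(const double *v, const int *dim,
                               double fx, double fy, double fz) {
    int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
        z0 = (int)std::floor(fz);
    if (x0 > dim[0] - 2) x0 = dim[0] - 2;
    if (y0 > dim[1] - 2) y0 = dim[1] - 2;
    if (z0 > dim[2] - 2) z0 = dim[2] - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    const double dx = fx - x0, dy = fy - y0, dz = fz - z0;
    const R_xlen_t sx = 1, sy = dim[0], sz = (R_xlen_t)dim[0] * dim[1];
    const R_xlen_t b = x0 * sx + y0 * sy + z0 * sz;
    const int nx = dim[0] > 1 ? 1 : 0, ny = dim[1] > 1 ? 1 : 0,
              nz = dim[2] > 1 ? 1 : 0;
    double c00 = v[b] * (1 - dx) + v[b + nx * sx] * dx;
    double c10 = v[b + ny * sy] * (1 - dx) + v[b + nx * sx + ny * sy] * dx;
    double c01 = v[b + nz * sz] * (1 - dx) + v[b + nx * sx + nz * sz] * dx;
    double c11 = v[b + ny * sy + nz * sz] * (1 - dx) +
                 v[b + nx * sx + ny * sy + nz * sz] * dx;
    double c0 = c00 * (1 - dy) + c10 * dy;
    double c1 = c01 * (1 - dy) + c11 * dy;
    return c0 * (1 - dz) + c1 * dz;
}

// Gamma index per reference voxel: offsets are pre-sorted by ascending
// Euclidean norm so the distance term gives an exact early-exit bound.
// refpos: n x 3 world coordinates (mm); offsets: m x 3 (mm); offnorm2: mm^2.
// [[Rcpp::export]]
NumericVector cpp_gamma_search(NumericVector refdose, NumericMatrix refpos,
                               NumericVector evalvol, IntegerVector evaldim,
                               NumericVector evalspacing,
                               NumericVector evalorigin,
                               NumericMatrix offsets, NumericVector offnorm2,
                               double dta, NumericVector deltaD) {
    const R_xlen_t n = refdose.size();
    const int m = offsets.nrow();
    const double dta2 = dta * dta;
    const double *v = evalvol.begin();
    int dim[3] = {evaldim[0], evaldim[1], evaldim[2]};
    double lo[3], hi[3], sp[3], orig[3];
    for (int a = 0; a < 3; ++a) {
        sp[a] = evalspacing[a];
        orig[a] = evalorigin[a];
        lo[a] = orig[a] - 1e-9;
        hi[a] = orig[a] + sp[a] * (dim[a] - 1) + 1e-9;
    }
    NumericVector gamma(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const double Dr = refdose[i];
        const double dd2 = deltaD[i] * deltaD[i];
        const double p0 = refpos(i, 0), p1 = refpos(i, 1), p2 = refpos(i, 2);
        double best = R_PosInf;
        for (int j = 0; j < m; ++j) {
            const double dterm = offnorm2[j] / dta2;
            if (dterm >= best) break;  // offsets sorted: no improvement ahead
            const double q0 = p0 + offsets(j, 0), q1 = p1 + offsets(j, 1),
                         q2 = p2 + offsets(j, 2);
            if (q0 < lo[0] || q0 > hi[0] || q1 < lo[1] || q1 > hi[1] ||
                q2 < lo[2] || q2 > hi[2])
                continue;
            const double De = trilinear(v, dim, (q0 - orig[0]) / sp[0],
                                        (q1 - orig[1]) / sp[1],
                                        (q2 - orig[2]) / sp[2]);
            const double diff = De - Dr;
            double g2;
            if (dd2 > 0) g2 = dterm + diff * diff / dd2;
            else g2 = (diff == 0.0) ? dterm : R_PosInf;
            if (g2 < best) best = g2;
        }
        gamma[i] = std::sqrt(best);
    }
    return gamma;
}
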