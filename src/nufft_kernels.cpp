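#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Modified Bessel function I0, Abramowitz & Stegun 9.8.1/9.8.2
static double bessel_i0(double x) {
    double ax = std::fabs(x);
    if (ax < 3.75) {
        double t = x / 3.75;
        t *= t;
        return 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
               t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
    }
    double t = 3.75 / ax;
    return (std::exp(ax) / std::sqrt(ax)) *
           (0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
            t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
            t * (-0.01647633 + t * 0.00392377))))))));
}

// Kaiser-Bessel kernel value at distance d (grid units), width W
static inline double kb_weight(double d, double halfw, double beta, double i0beta) {
    double r = d / halfw;
    double arg = 1.0 - r * r;
    if (arg <= 0.0) return 0.0;
    return bessel_i0(beta * std::sqrt(arg)) / i0beta;
}

struct KernelLine {
    int idx[16];     // wrapped grid indices
    double w[16];    // kernel weights
    int n;
};

static inline void kernel_line(double u, int ngrid, double halfw, double beta,
                               double i0beta, KernelLine &kl) {
    int lo = (int)std::ceil(u - halfw);
    int hi = (int)std::floor(u + halfw);
    kl.n = 0;
    for (int p = lo; p <= hi && kl.n < 16; ++p) {
        double wv = kb_weight(u - (double)p, halfw, beta, i0beta);
        if (wv <= 0.0) continue;
        int q = p % ngrid;
        if (q < 0) q += ngrid;
        kl.idx[kl.n] = q;
        kl.w[kl.n] = wv;
        kl.n++;
    }
}

// Spread complex sample values onto a 3D grid (adjoint interpolation).
// u: S x 3 sample coordinates in grid index units (0-based, wrapped mod dims).
// [[Rcpp::export]]
ComplexVector kb_spread3(NumericMatrix u, ComplexVector vals,
                         IntegerVector dims, double width, double beta) {
    const int S = u.nrow();
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double halfw = width / 2.0;
    const double i0beta = bessel_i0(beta);
    std::vector<double> re((size_t)nx * ny * nz, 0.0), im((size_t)nx * ny * nz, 0.0);
    KernelLine kx, ky, kz;
    for (int s = 0; s < S; ++s) {
        kernel_line(u(s, 0), nx, halfw, beta, i0beta, kx);
        kernel_line(u(s, 1), ny, halfw, beta, i0beta, ky);
        kernel_line(u(s, 2), nz, halfw, beta, i0beta, kz);
        double vr = vals[s].r, vi = vals[s].i;
        for (int c = 0; c < kz.n; ++c) {
            size_t offz = (size_t)kz.idx[c] * nx * ny;
            double wz = kz.w[c];
            for (int b = 0; b < ky.n; ++b) {
                size_t offy = offz + (size_t)ky.idx[b] * nx;
                double wyz = wz * ky.w[b];
                for (int a = 0; a < kx.n; ++a) {
                    double w = wyz * kx.w[a];
                    size_t o = offy + kx.idx[a];
                    re[o] += w * vr;
                    im[o] += w * vi;
                }
            }
        }
    }
    ComplexVector out((size_t)nx * ny * nz);
    for (size_t j = 0; j < re.size(); ++j) {
        out[j].r = re[j];
        out[j].i = im[j];
    }
    return out;
}

// Interpolate a 3D complex grid at off-grid sample coordinates.
// [[Rcpp::export]]
ComplexVector kb_interp3(ComplexVector grid, IntegerVector dims,
                         NumericMatrix u, double width, double beta) {
    const int S = u.nrow();
    const int nx = dims[0], ny = dims[1];
    const double halfw = width / 2.0;
    const double i0beta = bessel_i0(beta);
    ComplexVector out(S);
    KernelLine kx, ky, kz;
    for (int s = 0; s < S; ++s) {
        kernel_line(u(s, 0), nx, halfw, beta, i0beta, kx);
        kernel_line(u(s, 1), ny, halfw, beta, i0beta, ky);
        kernel_line(u(s, 2), dims[2], halfw, beta, i0beta, kz);
        double ar = 0.0, ai = 0.0;
        for (int c = 0; c < kz.n; ++c) {
            size_t offz = (size_t)kz.idx[c] * nx * ny;
            double wz = kz.w[c];
            for (int b = 0; b < ky.n; ++b) {
                size_t offy = offz + (size_t)ky.idx[b] * nx;
                double wyz = wz * ky.w[b];
                for (int a = 0; a < kx.n; ++a) {
                    double w = wyz * kx.w[a];
                    size_t o = offy + kx.idx[a];
                    ar += w * grid[o].r;
                    ai += w * grid[o].i;
                }
            }
        }
        out[s].r = ar;
        out[s].i = ai;
    }
    return out;
}
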