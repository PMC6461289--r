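#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Closed-form 3D Fourier transform of a sum of rotated, translated ellipsoid
// indicators, evaluated on a Cartesian frequency grid.
//
// For a unit-intensity ellipsoid with semi-axes (a,b,c), rotation R and
// centre x0, the continuous FT at frequency k (cycles/mm) is
//   F(k) = 4*pi*a*b*c * (sin u - u cos u)/u^3 * exp(-2*pi*i k.x0),
//   u = 2*pi * || diag(a,b,c) R^T k ||.
// The u -> 0 limit of the envelope is 1/3, so F(0) = (4/3)*pi*a*b*c.
//
// kx: uniformly spaced ascending frequency vector along x; ky/kz: per-axis
// frequency vectors in the desired output ordering; xmap: 0-based output
// position along x for each kx index (identity for centered storage, the
// inverse fftshift permutation to emit DFT order directly).
// B: per object, the 3x3 matrix diag(semi_axes) %*% t(R) flattened row-major.
// centre: per object, world-space centre (mm). amp0: intensity * 4*pi*a*b*c.
// The translation phase ramp along x is advanced by a complex recurrence
// (one rotation per sample), halving the trigonometric work per voxel.
// [[Rcpp::export]]
ComplexVector cpp_ellipsoid_kspace(NumericVector kx, NumericVector ky,
                                   NumericVector kz, IntegerVector xmap,
                                   List B, List centre, NumericVector amp0) {
    const R_xlen_t nx = kx.size(), ny = ky.size(), nz = kz.size();
    const int nobj = B.size();
    ComplexVector out(nx * ny * nz);
    const double TWO_PI = 2.0 * M_PI;
    const double dkx = nx > 1 ? kx[1] - kx[0] : 0.0;

    std::vector<double> Bm(9 * nobj), cx(nobj), cy(nobj), cz(nobj);
    std::vector<double> stepc(nobj), steps(nobj);
    for (int o = 0; o < nobj; ++o) {
        NumericMatrix b = B[o];
        for (int r = 0; r < 3; ++r)
            for (int s = 0; s < 3; ++s) Bm[9 * o + 3 * r + s] = b(r, s);
        NumericVector c = centre[o];
        cx[o] = c[0]; cy[o] = c[1]; cz[o] = c[2];
        const double dphi = -TWO_PI * cx[o] * dkx;
        stepc[o] = std::cos(dphi);
        steps[o] = std::sin(dphi);
    }

    std::vector<double> re_line(nx), im_line(nx);
    for (R_xlen_t iz = 0; iz < nz; ++iz) {
        const double fz = kz[iz];
        for (R_xlen_t iy = 0; iy < ny; ++iy) {
            const double fy = ky[iy];
            std::fill(re_line.begin(), re_line.end(), 0.0);
            std::fill(im_line.begin(), im_line.end(), 0.0);
            for (int o = 0; o < nobj; ++o) {
                const double *bb = &Bm[9 * o];
                const double p1 = bb[1] * fy + bb[2] * fz;
                const double p2 = bb[4] * fy + bb[5] * fz;
                const double p3 = bb[7] * fy + bb[8] * fz;
                const double phi0 =
                    -TWO_PI * (cx[o] * kx[0] + cy[o] * fy + cz[o] * fz);
                double pc = std::cos(phi0), ps = std::sin(phi0);
                const double sc = stepc[o], ss = steps[o];
                for (R_xlen_t ix = 0; ix < nx; ++ix) {
                    const double fx = kx[ix];
                    const double K1 = bb[0] * fx + p1;
                    const double K2 = bb[3] * fx + p2;
                    const double K3 = bb[6] * fx + p3;
                    const double u =
                        TWO_PI * std::sqrt(K1 * K1 + K2 * K2 + K3 * K3);
                    double env;
                    if (u < 1e-4) {
                        env = (1.0 / 3.0) - u * u / 30.0;
                    } else {
                        env = (std::sin(u) - u * std::cos(u)) / (u * u * u);
                    }
                    const double a = amp0[o] * env;
                    re_line[ix] += a * pc;
                    im_line[ix] += a * ps;
                    const double pc2 = pc * sc - ps * ss;
                    ps = pc * ss + ps * sc;
                    pc = pc2;
                }
            }
            const R_xlen_t base = nx * (iy + ny * iz);
            for (R_xlen_t ix = 0; ix < nx; ++ix) {
                out[base + xmap[ix]].r = re_line[ix];
                out[base + xmap[ix]].i = im_line[ix];
            }
        }
    }
    return out;
}

// Brute-force partial-volume rasterization: fraction of each voxel covered by
// the union of ellipsoids, estimated on a regular sub-voxel lattice with
// `subdivisions` points per axis (offsets at sub-cell centres).
//
// xc/yc/zc: voxel-centre coordinates per axis (mm). M: per object, the 3x3
// quadric matrix R diag(1/a^2,1/b^2,1/c^2) R^T; membership is
// (p - c)^T M (p - c) <= 1. h: voxel dimensions (mm).
// [[Rcpp::export]]
NumericVector cpp_rasterize(NumericVector xc, NumericVector yc,
                            NumericVector zc, List M, List centre,
                            NumericVector h, int subdivisions) {
    const R_xlen_t nx = xc.size(), ny = yc.size(), nz = zc.size();
    const int nobj = M.size(), s = subdivisions;
    NumericVector out(nx * ny * nz);

    std::vector<double> Mm(9 * nobj), cx(nobj), cy(nobj), cz(nobj);
    for (int o = 0; o < nobj; ++o) {
        NumericMatrix m = M[o];
        for (int r = 0; r < 3; ++r)
            for (int t = 0; t < 3; ++t) Mm[9 * o + 3 * r + t] = m(r, t);
        NumericVector c = centre[o];
        cx[o] = c[0]; cy[o] = c[1]; cz[o] = c[2];
    }
    std::vector<double> offx(s), offy(s), offz(s);
    for (int t = 0; t < s; ++t) {
        const double f = (t + 0.5) / s - 0.5;
        offx[t] = f * h[0]; offy[t] = f * h[1]; offz[t] = f * h[2];
    }
    const double w = 1.0 / (double(s) * s * s);

    R_xlen_t idx = 0;
    for (R_xlen_t iz = 0; iz < nz; ++iz) {
        for (R_xlen_t iy = 0; iy < ny; ++iy) {
            for (R_xlen_t ix = 0; ix < nx; ++ix, ++idx) {
                int cnt = 0;
                for (int tz = 0; tz < s; ++tz) {
                    const double pz = zc[iz] + offz[tz];
                    for (int ty = 0; ty < s; ++ty) {
                        const double py = yc[iy] + offy[ty];
                        for (int tx = 0; tx < s; ++tx) {
                            const double px = xc[ix] + offx[tx];
                            bool inside = false;
                            for (int o = 0; o < nobj && !inside; ++o) {
                                const double *mm = &Mm[9 * o];
                                const double d1 = px - cx[o];
                                const double d2 = py - cy[o];
                                const double d3 = pz - cz[o];
                                const double q =
                                    d1 * (mm[0] * d1 + mm[1] * d2 + mm[2] * d3) +
                                    d2 * (mm[3] * d1 + mm[4] * d2 + mm[5] * d3) +
                                    d3 * (mm[6] * d1 + mm[7] * d2 + mm[8] * d3);
                                inside = q <= 1.0;
                            }
                            if (inside) ++cnt;
                        }
                    }
                }
                out[idx] = cnt * w;
            }
        }
    }
    return out;
}

// Histogram of v over [lo, hi] with nbins equal bins (values clamped into the
// edge bins). Used to bracket quantile searches on large volumes.
// [[Rcpp::export]]
IntegerVector cpp_count_hist(NumericVector v, double lo, double hi, int nbins) {
    IntegerVector cnt(nbins);
    const double scale = nbins / (hi - lo);
    for (R_xlen_t i = 0; i < v.size(); ++i) {
        int b = int((v[i] - lo) * scale);
        if (b < 0) b = 0;
        if (b >= nbins) b = nbins - 1;
        ++cnt[b];
    }
    return cnt;
}

// Extract values of v lying in [a, b]; also count values strictly above b.
// [[Rcpp::export]]
List cpp_extract_range(NumericVector v, double a, double b) {
    R_xlen_t n_in = 0, n_above = 0;
    for (R_xlen_t i = 0; i < v.size(); ++i) {
        if (v[i] > b) ++n_above;
        else if (v[i] >= a) ++n_in;
    }
    NumericVector out(n_in);
    R_xlen_t j = 0;
    for (R_xlen_t i = 0; i < v.size(); ++i)
        if (v[i] <= b && v[i] >= a) out[j++] = v[i];
    return List::create(_["values"] = out, _["n_above"] = double(n_above));
}
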