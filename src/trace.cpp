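#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Incremental voxel traversal (Amanatides-Woo flavour of Siddon's
// algorithm).  Voxel (i,j,k), 0-based, occupies the half-open box
// [org + i*h, org + (i+1)*h) per axis; chords below `drop` mm are
// discarded to keep the system matrix sparse.
//
// The grid is passed as n (3 ints), h (voxel size, mm, isotropic) and
// org (corner, mm).  Directions need not be normalized; chord lengths
// are returned in mm.

static const double CHORD_DROP = 1e-6;

struct Hit {
    std::vector<int> idx;     // 1-based linear voxel index (R order)
    std::vector<double> len;  // chord length, mm
};

// Clip the ray p0 + t*u (u unit) against the grid box; returns false on miss.
static bool clip_box(const double* p0, const double* u,
                     const int* n, double h, const double* org,
                     double& t0, double& t1) {
    t0 = 0.0;
    t1 = std::numeric_limits<double>::infinity();
    for (int a = 0; a < 3; ++a) {
        double lo = org[a], hi = org[a] + n[a] * h;
        if (std::fabs(u[a]) < 1e-14) {
            if (p0[a] < lo || p0[a] >= hi) return false;
        } else {
            double ta = (lo - p0[a]) / u[a];
            double tb = (hi - p0[a]) / u[a];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
        }
    }
    // allow rays that start inside (t0 may be < 0 for two-sided segments:
    // callers pass entry points upstream of the grid, so keep t0 >= 0)
    return t1 > t0 + 1e-12;
}

static void trace_one(const double* p0, const double* d,
                      const int* n, double h, const double* org,
                      Hit& out) {
    double norm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (norm <= 0.0) stop("ray direction must be nonzero");
    double u[3] = { d[0] / norm, d[1] / norm, d[2] / norm };

    double t0, t1;
    if (!clip_box(p0, u, n, h, org, t0, t1)) return;

    // entry point nudged inside
    double eps = 1e-9 * (t1 - t0 + 1.0);
    double t = t0 + eps;
    int ijk[3];
    for (int a = 0; a < 3; ++a) {
        double c = (p0[a] + t * u[a] - org[a]) / h;
        int i = (int)std::floor(c);
        if (i < 0) i = 0;
        if (i >= n[a]) i = n[a] - 1;
        ijk[a] = i;
    }

    int step[3];
    double tMax[3], tDelta[3];
    for (int a = 0; a < 3; ++a) {
        if (u[a] > 1e-14) {
            step[a] = 1;
            tDelta[a] = h / u[a];
            tMax[a] = ((ijk[a] + 1) * h + org[a] - p0[a]) / u[a];
        } else if (u[a] < -1e-14) {
            step[a] = -1;
            tDelta[a] = -h / u[a];
            tMax[a] = (ijk[a] * h + org[a] - p0[a]) / u[a];
        } else {
            step[a] = 0;
            tDelta[a] = std::numeric_limits<double>::infinity();
            tMax[a] = std::numeric_limits<double>::infinity();
        }
    }

    double tcur = t0;
    while (tcur < t1 - 1e-12) {
        int a = 0;
        if (tMax[1] < tMax[a]) a = 1;
        if (tMax[2] < tMax[a]) a = 2;
        double tnext = tMax[a] < t1 ? tMax[a] : t1;
        double chord = tnext - tcur;
        if (chord > CHORD_DROP) {
            int lin = ijk[0] + n[0] * (ijk[1] + n[1] * ijk[2]) + 1;
            out.idx.push_back(lin);
            out.len.push_back(chord);
        }
        tcur = tnext;
        if (tMax[a] >= t1) break;
        ijk[a] += step[a];
        if (ijk[a] < 0 || ijk[a] >= n[a]) break;
        tMax[a] += tDelta[a];
    }
}

// [[Rcpp::export(name = ".cpp_trace_ray")]]
List cpp_trace_ray(NumericVector p0, NumericVector d,
                   IntegerVector n, double h, NumericVector org) {
    Hit out;
    trace_one(REAL(p0), REAL(d), INTEGER(n), h, REAL(org), out);
    return List::create(_["index"] = wrap(out.idx),
                        _["length"] = wrap(out.len));
}

// Trace many rays; returns COO triplets for sparse-matrix assembly plus
// each ray's total in-grid path length.
// [[Rcpp::export(name = ".cpp_trace_rays")]]
List cpp_trace_rays(NumericMatrix P0, NumericMatrix D,
                    IntegerVector n, double h, NumericVector org) {
    int m = P0.nrow();
    std::vector<int> ri, ci;
    std::vector<double> xv;
    NumericVector rowlen(m);
    Hit out;
    double p0[3], d[3];
    for (int p = 0; p < m; ++p) {
        out.idx.clear();
        out.len.clear();
        for (int a = 0; a < 3; ++a) { p0[a] = P0(p, a); d[a] = D(p, a); }
        trace_one(p0, d, INTEGER(n), h, REAL(org), out);
        double tot = 0.0;
        for (size_t q = 0; q < out.idx.size(); ++q) {
            ri.push_back(p + 1);
            ci.push_back(out.idx[q]);
            xv.push_back(out.len[q]);
            tot += out.len[q];
        }
        rowlen[p] = tot;
    }
    return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                        _["x"] = wrap(xv), _["rowLength"] = rowlen);
}

// Line integrals of a voxel field along many rays (the WEPL oracle used
// by the simulator): sum over traversed voxels of chord * value.
// [[Rcpp::export(name = ".cpp_line_integrals")]]
NumericVector cpp_line_integrals(NumericMatrix P0, NumericMatrix D,
                                 NumericVector values,
                                 IntegerVector n, double h,
                                 NumericVector org) {
    int m = P0.nrow();
    NumericVector res(m);
    Hit out;
    double p0[3], d[3];
    const double* v = REAL(values);
    for (int p = 0; p < m; ++p) {
        out.idx.clear();
        out.len.clear();
        for (int a = 0; a < 3; ++a) { p0[a] = P0(p, a); d[a] = D(p, a); }
        trace_one(p0, d, INTEGER(n), h, REAL(org), out);
        double s = 0.0;
        for (size_t q = 0; q < out.idx.size(); ++q)
            s += out.len[q] * v[out.idx[q] - 1];
        res[p] = s;
    }
    return res;
}
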