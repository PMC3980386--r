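#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Vertices of the additively weighted Voronoi diagram by 4-subset
// enumeration.  A vertex is the center of a sphere tangent to four atom
// spheres (|p - p_i| = r_i + c) that contains no other atom in the weighted
// sense (|p - p_j| - r_j >= c for all j).  Subtracting pairs of tangency
// equations gives a linear system A p = d + e c; substituting p(c) back
// into one tangency equation leaves a quadratic in the clearance c, so
// each 4-subset contributes at most two candidate vertices.
//
// Enumeration is pruned by the necessary condition that the centers of two
// generators of a vertex with clearance <= cmax lie within
// r_i + r_j + 2*cmax of each other.  With cmax = Inf the scan is exhaustive.
//
// If any candidate that passes the empty-sphere test is tangent (within
// degen_tol) to a fifth sphere, the configuration is degenerate and the
// caller is told to perturb; this also subsumes duplicate detection, since
// two distinct 4-subsets can only produce coincident vertices in that case.

static inline double det3(const double m[9]) {
    return m[0] * (m[4] * m[8] - m[5] * m[7])
         - m[1] * (m[3] * m[8] - m[5] * m[6])
         + m[2] * (m[3] * m[7] - m[4] * m[6]);
}

// solve 3x3 system m x = b by Cramer's rule; returns false when |det| tiny
static bool solve3(const double m[9], const double b[3], double x[3],
                   double scale) {
    double d = det3(m);
    if (std::fabs(d) < 1e-12 * scale) return false;
    double t[9];
    for (int col = 0; col < 3; ++col) {
        for (int k = 0; k < 9; ++k) t[k] = m[k];
        t[col] = b[0]; t[col + 3] = b[1]; t[col + 6] = b[2];
        x[col] = det3(t) / d;
    }
    return true;
}

// [[Rcpp::export]]
List cpp_aw_voronoi_vertices(NumericMatrix centers, NumericVector radii,
                             NumericVector box_lo, NumericVector box_hi,
                             double max_clearance, double empty_tol,
                             double degen_tol) {
    const int n = centers.nrow();
    std::vector<double> px(n), py(n), pz(n), rr(n);
    for (int i = 0; i < n; ++i) {
        px[i] = centers(i, 0); py[i] = centers(i, 1); pz[i] = centers(i, 2);
        rr[i] = radii[i];
    }
    double diag = 0.0;
    for (int k = 0; k < 3; ++k) {
        double s = box_hi[k] - box_lo[k];
        diag += s * s;
    }
    diag = std::sqrt(diag);
    double cmax = std::min(max_clearance, diag);

    // pairwise-distance prune cutoff per pair: r_i + r_j + 2*cmax
    std::vector< std::vector<int> > nb(n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
            double cut = rr[i] + rr[j] + 2.0 * cmax;
            if (dx * dx + dy * dy + dz * dz <= cut * cut)
                nb[i].push_back(j);
        }
    }

    std::vector<double> vx, vy, vz, vc;
    std::vector<int> g1, g2, g3, g4;
    bool degenerate = false;

    double coord_scale = std::max(1.0, diag);

    for (int i = 0; i < n && !degenerate; ++i) {
        const std::vector<int>& ni = nb[i];
        const int m = (int) ni.size();
        for (int a = 0; a < m && !degenerate; ++a) {
            int j = ni[a];
            for (int b = a + 1; b < m && !degenerate; ++b) {
                int k = ni[b];
                {   // prune: j,k must also be close enough
                    double dx = px[j] - px[k], dy = py[j] - py[k],
                           dz = pz[j] - pz[k];
                    double cut = rr[j] + rr[k] + 2.0 * cmax;
                    if (dx * dx + dy * dy + dz * dz > cut * cut) continue;
                }
                for (int c0 = b + 1; c0 < m && !degenerate; ++c0) {
                    int l = ni[c0];
                    bool ok = true;
                    int others[2] = { j, k };
                    for (int t = 0; t < 2 && ok; ++t) {
                        int q = others[t];
                        double dx = px[q] - px[l], dy = py[q] - py[l],
                               dz = pz[q] - pz[l];
                        double cut = rr[q] + rr[l] + 2.0 * cmax;
                        if (dx * dx + dy * dy + dz * dz > cut * cut) ok = false;
                    }
                    if (!ok) continue;

                    int idx[4] = { i, j, k, l };
                    // rows from pairs (i, q): 2(p_q - p_i) . p - 2(r_i - r_q) c
                    //   = r_i^2 - r_q^2 - |p_i|^2 + |p_q|^2
                    double A[9], e[3], d[3];
                    double pi2 = px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i];
                    for (int row = 0; row < 3; ++row) {
                        int q = idx[row + 1];
                        A[row * 3 + 0] = 2.0 * (px[q] - px[i]);
                        A[row * 3 + 1] = 2.0 * (py[q] - py[i]);
                        A[row * 3 + 2] = 2.0 * (pz[q] - pz[i]);
                        e[row] = 2.0 * (rr[i] - rr[q]);
                        double pq2 = px[q] * px[q] + py[q] * py[q] + pz[q] * pz[q];
                        d[row] = rr[i] * rr[i] - rr[q] * rr[q] - pi2 + pq2;
                    }
                    double u[3], v[3];
                    if (!solve3(A, d, u, coord_scale)) continue; // coplanar-degenerate subset
                    if (!solve3(A, e, v, coord_scale)) continue;
                    // p(c) = u + v c; tangency to sphere i:
                    // |u + v c - p_i|^2 = (r_i + c)^2
                    double wx = u[0] - px[i], wy = u[1] - py[i], wz = u[2] - pz[i];
                    double qa = v[0] * v[0] + v[1] * v[1] + v[2] * v[2] - 1.0;
                    double qb = 2.0 * (wx * v[0] + wy * v[1] + wz * v[2] - rr[i]);
                    double qc = wx * wx + wy * wy + wz * wz - rr[i] * rr[i];
                    double roots[2]; int nroot = 0;
                    if (std::fabs(qa) < 1e-14) {
                        if (std::fabs(qb) > 1e-14) { roots[nroot++] = -qc / qb; }
                    } else {
                        double disc = qb * qb - 4.0 * qa * qc;
                        if (disc >= 0.0) {
                            double sq = std::sqrt(disc);
                            roots[nroot++] = (-qb - sq) / (2.0 * qa);
                            roots[nroot++] = (-qb + sq) / (2.0 * qa);
                        }
                    }
                    double rmin = std::min(std::min(rr[i], rr[j]),
                                           std::min(rr[k], rr[l]));
                    // merge the subset's two roots when they coincide
                    // (double root of the tangency quadratic)
                    if (nroot == 2 && std::fabs(roots[0] - roots[1]) < 1e-9)
                        nroot = 1;
                    for (int t = 0; t < nroot; ++t) {
                        double cc = roots[t];
                        if (!std::isfinite(cc)) continue;
                        if (cc > cmax || cc < -rmin) continue;
                        double X = u[0] + v[0] * cc, Y = u[1] + v[1] * cc,
                               Z = u[2] + v[2] * cc;
                        if (X < box_lo[0] || X > box_hi[0] ||
                            Y < box_lo[1] || Y > box_hi[1] ||
                            Z < box_lo[2] || Z > box_hi[2]) continue;
                        // empty-sphere test with early exit
                        bool empty = true, tangent5 = false;
                        for (int q = 0; q < n; ++q) {
                            if (q == i || q == j || q == k || q == l) continue;
                            double dx = X - px[q], dy = Y - py[q], dz = Z - pz[q];
                            double wd = std::sqrt(dx * dx + dy * dy + dz * dz) - rr[q];
                            if (wd < cc - empty_tol) { empty = false; break; }
                            if (std::fabs(wd - cc) < degen_tol) tangent5 = true;
                        }
                        if (!empty) continue;
                        if (tangent5) { degenerate = true; break; }
                        // NOTE: vertices of *different* subsets may lie
                        // arbitrarily close after perturbation of a
                        // high-order degeneracy; they are distinct diagram
                        // vertices carrying distinct generator triples and
                        // must all be kept, or edge connectivity is lost.
                        vx.push_back(X); vy.push_back(Y); vz.push_back(Z);
                        vc.push_back(cc);
                        g1.push_back(i + 1); g2.push_back(j + 1);
                        g3.push_back(k + 1); g4.push_back(l + 1);
                    }
                }
            }
        }
    }

    const int nv = (int) vx.size();
    NumericMatrix pos(nv, 3);
    NumericVector clearance(nv);
    IntegerMatrix gens(nv, 4);
    for (int t = 0; t < nv; ++t) {
        pos(t, 0) = vx[t]; pos(t, 1) = vy[t]; pos(t, 2) = vz[t];
        clearance[t] = vc[t];
        gens(t, 0) = g1[t]; gens(t, 1) = g2[t];
        gens(t, 2) = g3[t]; gens(t, 3) = g4[t];
    }
    return List::create(_["position"] = pos, _["clearance"] = clearance,
                        _["generators"] = gens,
                        _["degenerate"] = degenerate);
}

// Occupancy of a regular cube grid: 1 where the cube center lies strictly
// inside at least one sphere.  Cube centers are origin + (i + 1/2) a.
// Spheres are prefiltered per (x, y) column, mirroring a column-parallel
// accumulation; counts are integers so the result is order-independent.
// [[Rcpp::export]]
IntegerVector cpp_grid_occupancy(NumericVector origin, IntegerVector dims,
                                 double a, NumericMatrix centers,
                                 NumericVector radii) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int ns = centers.nrow();
    IntegerVector occ((R_xlen_t) nx * ny * nz);
    std::vector<double> cx(ns), cy(ns), cz(ns), r2(ns);
    for (int s = 0; s < ns; ++s) {
        cx[s] = centers(s, 0); cy[s] = centers(s, 1); cz[s] = centers(s, 2);
        r2[s] = radii[s] * radii[s];
    }
    std::vector<double> col_rz2, col_cz;
    for (int ix = 0; ix < nx; ++ix) {
        double x = origin[0] + (ix + 0.5) * a;
        for (int iy = 0; iy < ny; ++iy) {
            double y = origin[1] + (iy + 0.5) * a;
            col_rz2.clear(); col_cz.clear();
            for (int s = 0; s < ns; ++s) {
                double dx = x - cx[s], dy = y - cy[s];
                double rest = r2[s] - dx * dx - dy * dy;
                if (rest > 0.0) { col_rz2.push_back(rest); col_cz.push_back(cz[s]); }
            }
            if (col_rz2.empty()) continue;
            const int nc = (int) col_rz2.size();
            R_xlen_t base = (R_xlen_t) ix + (R_xlen_t) nx * iy;
            for (int iz = 0; iz < nz; ++iz) {
                double z = origin[2] + (iz + 0.5) * a;
                for (int s = 0; s < nc; ++s) {
                    double dz = z - col_cz[s];
                    if (dz * dz < col_rz2[s]) {
                        occ[base + (R_xlen_t) nx * ny * iz] = 1;
                        break;
                    }
                }
            }
        }
    }
    return occ;
}
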