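#include "knotfold.h"
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// geometry helpers on real-valued points

static inline Pt pt(double x, double y, double z) { Pt p = {{x, y, z}}; return p; }
static inline Pt psub(const Pt &a, const Pt &b) { return pt(a[0]-b[0], a[1]-b[1], a[2]-b[2]); }
static inline Pt padd(const Pt &a, const Pt &b) { return pt(a[0]+b[0], a[1]+b[1], a[2]+b[2]); }
static inline Pt pscale(const Pt &a, double s) { return pt(a[0]*s, a[1]*s, a[2]*s); }
static inline double pdot(const Pt &a, const Pt &b) { return a[0]*b[0] + a[1]*b[1] + a[2]*b[2]; }
static inline Pt pcross(const Pt &a, const Pt &b) {
    return pt(a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]);
}
static inline double pnorm(const Pt &a) { return std::sqrt(pdot(a, a)); }

// Conservative segment-triangle intersection: returns true whenever the
// segment p-q might intersect the closed triangle a-b-c (doubt counts as an
// intersection, which can only prevent a KMT deletion, never corrupt one).
static bool seg_tri_maybe(const Pt &p, const Pt &q,
                          const Pt &a, const Pt &b, const Pt &c, double eps) {
    Pt n = pcross(psub(b, a), psub(c, a));
    double nn = pnorm(n);
    if (nn < eps) return true;                 // degenerate triangle: be safe
    n = pscale(n, 1.0 / nn);
    double sp = pdot(n, psub(p, a));
    double sq = pdot(n, psub(q, a));
    if ((sp > eps && sq > eps) || (sp < -eps && sq < -eps)) return false;
    // candidate points where the segment meets the triangle's plane slab
    Pt cand[3];
    int ncand = 0;
    if (std::fabs(sp) <= eps && std::fabs(sq) <= eps) {
        // coplanar: test both endpoints and the midpoint region via 2D overlap
        cand[ncand++] = p;
        cand[ncand++] = q;
    } else if (std::fabs(sp - sq) < eps) {
        cand[ncand++] = p;
        cand[ncand++] = q;
    } else {
        double t = sp / (sp - sq);
        if (t < -eps || t > 1 + eps) return false;
        cand[ncand++] = padd(p, pscale(psub(q, p), std::min(1.0, std::max(0.0, t))));
    }
    // 2D point-in-triangle (projected onto the triangle plane), conservative
    Pt u = psub(b, a), v = psub(c, a);
    double uu = pdot(u, u), vv = pdot(v, v), uv = pdot(u, v);
    double det = uu * vv - uv * uv;
    if (std::fabs(det) < eps) return true;
    for (int k = 0; k < ncand; ++k) {
        Pt w = psub(cand[k], a);
        double wu = pdot(w, u), wv = pdot(w, v);
        double s = (vv * wu - uv * wv) / det;
        double t = (uu * wv - uv * wu) / det;
        if (s >= -eps && t >= -eps && s + t <= 1 + eps) return true;
    }
    if (ncand == 2) {
        // coplanar segment may cross the triangle without an endpoint inside:
        // test 2D crossings with the triangle edges
        const Pt *tri[3] = { &a, &b, &c };
        for (int e = 0; e < 3; ++e) {
            const Pt &e1 = *tri[e], &e2 = *tri[(e + 1) % 3];
            // closest-approach of two segments below eps counts as crossing
            Pt d1 = psub(cand[1], cand[0]), d2 = psub(e2, e1), r = psub(cand[0], e1);
            double a11 = pdot(d1, d1), a22 = pdot(d2, d2), a12 = pdot(d1, d2);
            double b1 = pdot(d1, r), b2 = pdot(d2, r);
            double den = a11 * a22 - a12 * a12;
            double s, t;
            if (std::fabs(den) < 1e-14) { s = 0; t = (a22 > 0) ? b2 / a22 : 0; }
            else {
                s = (a12 * b2 - a22 * b1) / den;
                t = (a11 * b2 - a12 * b1) / den;
            }
            s = std::min(1.0, std::max(0.0, s));
            t = std::min(1.0, std::max(0.0, t));
            Pt diff = psub(padd(cand[0], pscale(d1, s)), padd(e1, pscale(d2, t)));
            if (pnorm(diff) < eps) return true;
        }
    }
    return false;
}

// ---------------------------------------------------------------------------
// chain closure

// minimal distance between segments p1-p2 and q1-q2
static double seg_seg_dist(const Pt &p1, const Pt &p2, const Pt &q1, const Pt &q2) {
    Pt d1 = psub(p2, p1), d2 = psub(q2, q1), r = psub(p1, q1);
    double a11 = pdot(d1, d1), a22 = pdot(d2, d2), a12 = pdot(d1, d2);
    double b1 = pdot(d1, r), b2 = pdot(d2, r);
    double den = a11 * a22 - a12 * a12;
    double s, t;
    if (std::fabs(den) < 1e-14) { s = 0; t = (a22 > 0) ? b2 / a22 : 0; }
    else {
        s = (a12 * b2 - a22 * b1) / den;
        t = (a11 * b2 - a12 * b1) / den;
    }
    s = std::min(1.0, std::max(0.0, s));
    t = std::min(1.0, std::max(0.0, t));
    // re-clamp the other parameter after clamping one
    Pt ps = padd(p1, pscale(d1, s));
    t = (a22 > 0) ? std::min(1.0, std::max(0.0, pdot(d2, psub(ps, q1)) / a22)) : t;
    Pt qt = padd(q1, pscale(d2, t));
    s = (a11 > 0) ? std::min(1.0, std::max(0.0, pdot(d1, psub(qt, p1)) / a11)) : s;
    ps = padd(p1, pscale(d1, s));
    return pnorm(psub(ps, qt));
}

// rotate unit vector d by angle a about unit axis u (Rodrigues)
static Pt rotate_about(const Pt &d, const Pt &u, double a) {
    double ca = std::cos(a), sa = std::sin(a);
    Pt term1 = pscale(d, ca);
    Pt term2 = pscale(pcross(u, d), sa);
    Pt term3 = pscale(u, pdot(u, d) * (1 - ca));
    Pt r = padd(padd(term1, term2), term3);
    return pscale(r, 1.0 / pnorm(r));
}

// Extend both termini radially outward from the chain centroid to a sphere of
// radius 3x the maximal centroid distance and join them by an arc on that
// sphere. Lattice chains often have beads exactly on the outgoing ray, so the
// extension directions are deterministically perturbed (in increasing steps)
// until every closure segment keeps a clear margin from the chain and from the
// other closure segments; the first collision-free closure is returned.
std::vector<Pt> close_chain_pts(const std::vector<Pt> &chain) {
    size_t n = chain.size();
    Pt c = pt(0, 0, 0);
    for (size_t i = 0; i < n; ++i) c = padd(c, chain[i]);
    c = pscale(c, 1.0 / (double)n);
    double ext = 1.0;
    for (size_t i = 0; i < n; ++i) ext = std::max(ext, pnorm(psub(chain[i], c)));
    double R = 3.0 * ext;
    const double margin = 0.05;

    Pt base[2];
    const Pt ends[2] = { chain[n - 1], chain[0] };
    for (int k = 0; k < 2; ++k) {
        Pt d = psub(ends[k], c);
        if (pnorm(d) < 1e-9) d = pt(0.12345, 0.54321, 0.83219);  // jittered direction
        base[k] = pscale(d, 1.0 / pnorm(d));
    }
    for (int jit = 0; jit < 200; ++jit) {
        Pt dirs[2];
        for (int k = 0; k < 2; ++k) {
            if (jit == 0) { dirs[k] = base[k]; continue; }
            Pt any = std::fabs(base[k][0]) < 0.9 ? pt(1, 0, 0) : pt(0, 1, 0);
            Pt u = pcross(base[k], any);
            u = pscale(u, 1.0 / pnorm(u));
            double spin = 2.3999632297286533 * (jit + 2 * k);
            Pt u2 = rotate_about(u, base[k], spin);
            dirs[k] = rotate_about(base[k], u2, 0.02 + 0.01 * jit);
        }
        std::vector<Pt> add;
        add.push_back(padd(c, pscale(dirs[0], R)));   // radial extension, last bead
        double cosang = std::min(1.0, std::max(-1.0, pdot(dirs[0], dirs[1])));
        double ang = std::acos(cosang);
        Pt axis = pcross(dirs[0], dirs[1]);
        if (pnorm(axis) < 1e-9) {
            if (ang > 1.0) {
                // antipodal termini: route the arc through a fixed perpendicular
                Pt any = std::fabs(dirs[0][0]) < 0.9 ? pt(1, 0, 0) : pt(0, 1, 0);
                Pt perp = pcross(dirs[0], any);
                add.push_back(padd(c, pscale(pscale(perp, 1.0 / pnorm(perp)), R)));
            }
        } else if (ang > 1e-6) {
            int nseg = (int)std::ceil(ang / (M_PI / 3.0));
            for (int k = 1; k < nseg; ++k) {
                double t = (double)k / nseg;
                double s0 = std::sin((1 - t) * ang) / std::sin(ang);
                double s1 = std::sin(t * ang) / std::sin(ang);
                Pt w = padd(pscale(dirs[0], s0), pscale(dirs[1], s1));
                add.push_back(padd(c, pscale(pscale(w, 1.0 / pnorm(w)), R)));
            }
        }
        add.push_back(padd(c, pscale(dirs[1], R)));   // radial extension, first bead

        // collision audit of the closure path (chain end -> add[...] -> chain start)
        std::vector<Pt> path;
        path.push_back(chain[n - 1]);
        for (size_t k = 0; k < add.size(); ++k) path.push_back(add[k]);
        path.push_back(chain[0]);
        bool ok = true;
        for (size_t s = 0; s + 1 < path.size() && ok; ++s) {
            for (size_t i = 0; i + 1 < n && ok; ++i) {
                // skip chain segments incident to the shared terminus vertex
                if (s == 0 && i + 1 == n - 1) continue;
                if (s + 2 == path.size() && i == 0) continue;
                if (seg_seg_dist(path[s], path[s + 1], chain[i], chain[i + 1]) < margin)
                    ok = false;
            }
            for (size_t s2 = s + 2; s2 + 1 < path.size() && ok; ++s2)
                if (seg_seg_dist(path[s], path[s + 1], path[s2], path[s2 + 1]) < margin)
                    ok = false;
        }
        if (!ok) continue;
        std::vector<Pt> poly(chain);
        for (size_t k = 0; k < add.size(); ++k) poly.push_back(add[k]);
        return poly;
    }
    Rcpp::stop("chain closure failed: no collision-free closure found");
}

// closed-polygon simplicity check (non-adjacent segment pairs keep a gap)
static bool polygon_simple(const std::vector<Pt> &poly, double eps) {
    int m = (int)poly.size();
    for (int i = 0; i < m; ++i) {
        for (int j = i + 2; j < m; ++j) {
            if (i == 0 && j == m - 1) continue;    // adjacent around the wrap
            const Pt &p1 = poly[i], &p2 = poly[(i + 1) % m];
            const Pt &q1 = poly[j], &q2 = poly[(j + 1) % m];
            Pt d1 = psub(p2, p1), d2 = psub(q2, q1), r = psub(p1, q1);
            double a11 = pdot(d1, d1), a22 = pdot(d2, d2), a12 = pdot(d1, d2);
            double b1 = pdot(d1, r), b2 = pdot(d2, r);
            double den = a11 * a22 - a12 * a12;
            double s, t;
            if (std::fabs(den) < 1e-14) { s = 0; t = (a22 > 0) ? b2 / a22 : 0; }
            else {
                s = (a12 * b2 - a22 * b1) / den;
                t = (a11 * b2 - a12 * b1) / den;
            }
            s = std::min(1.0, std::max(0.0, s));
            t = std::min(1.0, std::max(0.0, t));
            Pt diff = psub(padd(p1, pscale(d1, s)), padd(q1, pscale(d2, t)));
            if (pnorm(diff) < eps) return false;
        }
    }
    return true;
}

// ---------------------------------------------------------------------------
// KMT reduction

std::vector<Pt> kmt_reduce_pts(std::vector<Pt> poly) {
    const double eps = 1e-7;
    bool changed = true;
    while (changed && poly.size() > 3) {
        changed = false;
        for (int i = 0; i < (int)poly.size() && poly.size() > 3; ++i) {
            int m = (int)poly.size();
            int ip = (i - 1 + m) % m, in = (i + 1) % m;
            const Pt a = poly[ip], b = poly[i], cc = poly[in];
            Pt cr = pcross(psub(b, a), psub(cc, b));
            if (pnorm(cr) < eps) {            // collinear vertex: always removable
                poly.erase(poly.begin() + i);
                changed = true;
                --i;
                continue;
            }
            bool blocked = false;
            for (int j = 0; j < m && !blocked; ++j) {
                if (j == ip || j == i) continue;          // the two edges at b
                Pt p = poly[j], q = poly[(j + 1) % m];
                // The neighbouring edges share vertex a (edge ending at a) or
                // vertex c (edge starting at c); trim the shared endpoint so a
                // mere vertex-touch does not block the deletion. A non-adjacent
                // edge passing exactly through a or c would make the polygon
                // non-simple, so trimming loses no genuine obstruction.
                if ((j + 1) % m == ip) q = padd(q, pscale(psub(p, q), 1e-4));
                if (j == in)           p = padd(p, pscale(psub(q, p), 1e-4));
                if (seg_tri_maybe(p, q, a, b, cc, eps)) blocked = true;
            }
            if (!blocked) {
                poly.erase(poly.begin() + i);
                changed = true;
                --i;
            }
        }
    }
    return poly;
}

// ---------------------------------------------------------------------------
// Alexander determinant |Delta(-1)| from a generic projection

struct CrossEvent {
    int edge;        // edge index the event lies on
    double t;        // parameter along the edge
    int crossing;    // crossing id
    bool over;
};

static bool ce_order(const CrossEvent &a, const CrossEvent &b) {
    if (a.edge != b.edge) return a.edge < b.edge;
    return a.t < b.t;
}

// returns -1 on a degenerate projection (caller retries another direction)
static long long alex_one_direction(const std::vector<Pt> &poly, const Pt &dir) {
    int m = (int)poly.size();
    // orthonormal basis
    Pt d = pscale(dir, 1.0 / pnorm(dir));
    Pt any = std::fabs(d[0]) < 0.9 ? pt(1, 0, 0) : pt(0, 1, 0);
    Pt e1 = pcross(d, any); e1 = pscale(e1, 1.0 / pnorm(e1));
    Pt e2 = pcross(d, e1);
    std::vector<double> px(m), py(m), ph(m);
    double scale = 1.0;
    for (int i = 0; i < m; ++i) {
        px[i] = pdot(poly[i], e1);
        py[i] = pdot(poly[i], e2);
        ph[i] = pdot(poly[i], d);
        scale = std::max(scale, std::fabs(px[i]) + std::fabs(py[i]));
    }
    const double eps = 1e-9 * scale;
    std::vector<CrossEvent> events;
    int n_cross = 0;
    for (int i = 0; i < m; ++i) {
        int i2 = (i + 1) % m;
        for (int j = i + 2; j < m; ++j) {
            if (i == 0 && j == m - 1) continue;
            int j2 = (j + 1) % m;
            double rx = px[i2] - px[i], ry = py[i2] - py[i];
            double sx = px[j2] - px[j], sy = py[j2] - py[j];
            double den = rx * sy - ry * sx;
            double qpx = px[j] - px[i], qpy = py[j] - py[i];
            if (std::fabs(den) < 1e-12 * scale * scale) {
                // parallel in projection; only overlapping collinear images are
                // degenerate (disjoint collinear segments are common on the
                // lattice and cross nowhere)
                double cr = qpx * ry - qpy * rx;
                double rlen2 = rx * rx + ry * ry;
                if (std::fabs(cr) < eps * std::sqrt(std::max(rlen2, 1e-30))) {
                    if (rlen2 < 1e-30) return -1;       // edge projects to a point
                    double s0 = (qpx * rx + qpy * ry) / rlen2;
                    double s1 = ((px[j2] - px[i]) * rx + (py[j2] - py[i]) * ry) / rlen2;
                    double lo = std::min(s0, s1), hi = std::max(s0, s1);
                    if (hi > -1e-9 && lo < 1 + 1e-9) return -1;   // images overlap
                }
                continue;
            }
            double t = (qpx * sy - qpy * sx) / den;
            double u = (qpx * ry - qpy * rx) / den;
            const double be = 1e-7;
            if (t < -be || t > 1 + be || u < -be || u > 1 + be) continue;
            if (t < be || t > 1 - be || u < be || u > 1 - be) return -1;  // near a vertex
            double hi = ph[i] + t * (ph[i2] - ph[i]);
            double hj = ph[j] + u * (ph[j2] - ph[j]);
            if (std::fabs(hi - hj) < eps) return -1;
            CrossEvent ei, ej;
            ei.edge = i; ei.t = t; ei.crossing = n_cross; ei.over = hi > hj;
            ej.edge = j; ej.t = u; ej.crossing = n_cross; ej.over = hj > hi;
            events.push_back(ei);
            events.push_back(ej);
            ++n_cross;
        }
    }
    if (n_cross == 0) return 1;
    std::sort(events.begin(), events.end(), ce_order);
    // walk the closed curve, splitting arcs at underpasses
    int n = n_cross;
    std::vector<int> over_arc(n, -1), under_in(n, -1), under_out(n, -1);
    int arc = 0;
    for (size_t k = 0; k < events.size(); ++k) {
        const CrossEvent &ev = events[k];
        if (ev.over) over_arc[ev.crossing] = arc % n;
        else {
            under_in[ev.crossing] = arc % n;
            ++arc;
            under_out[ev.crossing] = arc % n;
        }
    }
    // arc count equals underpass count; the wrap merges the last arc with arc 0
    if (arc != n) return -1;   // should not happen
    if (n == 1) return 1;
    // Alexander matrix at t = -1; |det| of any (n-1) minor
    int nm = n - 1;
    std::vector<std::vector<long double> > M(nm, std::vector<long double>(nm, 0.0L));
    for (int cidx = 0; cidx < nm; ++cidx) {     // drop the last crossing row
        int row = cidx;
        int cols[3] = { over_arc[cidx], under_in[cidx], under_out[cidx] };
        long double vals[3] = { 2.0L, -1.0L, -1.0L };
        for (int k = 0; k < 3; ++k)
            if (cols[k] < nm) M[row][cols[k]] += vals[k];  // drop the last arc column
    }
    // fraction-free-ish Gaussian elimination in long double
    long double det = 1.0L;
    for (int i = 0; i < nm; ++i) {
        int piv = -1;
        long double best = 0.0L;
        for (int r = i; r < nm; ++r)
            if (std::fabs((double)M[r][i]) > (double)best) { best = std::fabs((double)M[r][i]); piv = r; }
        if (piv < 0 || best < 1e-9) return 0;   // singular: determinant 0 (composite-like)
        if (piv != i) { std::swap(M[piv], M[i]); det = -det; }
        det *= M[i][i];
        for (int r = i + 1; r < nm; ++r) {
            long double f = M[r][i] / M[i][i];
            for (int cc2 = i; cc2 < nm; ++cc2) M[r][cc2] -= f * M[i][cc2];
        }
    }
    long double ad = std::fabs((double)det);
    return (long long)(ad + 0.5L);
}

// deterministic sequence of generic projection directions
static Pt projection_dir(int k) {
    double g = 0.6180339887498949 * (k + 3);
    double z = 1.0 - 2.0 * (g - std::floor(g));
    double phi = 2.3999632297286533 * (k + 3);
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    return pt(r * std::cos(phi), r * std::sin(phi), z);
}

int alexander_det_poly(const std::vector<Pt> &poly_in, int n_dirs) {
    // drop (near-)duplicate consecutive vertices; they carry no geometry
    std::vector<Pt> poly;
    poly.reserve(poly_in.size());
    for (size_t i = 0; i < poly_in.size(); ++i)
        if (poly.empty() || pnorm(psub(poly_in[i], poly.back())) > 1e-9)
            poly.push_back(poly_in[i]);
    if (poly.size() > 1 && pnorm(psub(poly.back(), poly.front())) < 1e-9)
        poly.pop_back();
    if (poly.size() < 3) return 1;
    std::vector<long long> got;
    int attempts = 0;
    while ((int)got.size() < n_dirs && attempts < 60) {
        long long v = alex_one_direction(poly, projection_dir(attempts));
        ++attempts;
        if (v >= 0) got.push_back(v);
    }
    if ((int)got.size() < n_dirs)
        stop("knot projection remained degenerate after %d attempts", attempts);
    for (size_t k = 1; k < got.size(); ++k)
        if (got[k] != got[0])
            stop("Alexander determinant disagrees between projection directions");
    long long v = got[0];
    if (v > 2147483647LL) v = 2147483647LL;
    return (int)v;
}

int chain_alexander(const std::vector<Vec3> &chain) {
    std::vector<Pt> c(chain.size());
    for (size_t i = 0; i < chain.size(); ++i)
        c[i] = pt(chain[i][0], chain[i][1], chain[i][2]);
    std::vector<Pt> closed = close_chain_pts(c);
    std::vector<Pt> red = kmt_reduce_pts(closed);
    return alexander_det_poly(red, 3);
}

// ---------------------------------------------------------------------------
// exports

static std::vector<Pt> mat_to_pts(const NumericMatrix &m) {
    std::vector<Pt> v(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) v[i] = pt(m(i,0), m(i,1), m(i,2));
    return v;
}
static NumericMatrix pts_to_mat(const std::vector<Pt> &v) {
    NumericMatrix m((int)v.size(), 3);
    for (size_t i = 0; i < v.size(); ++i)
        for (int c = 0; c < 3; ++c) m((int)i, c) = v[i][c];
    return m;
}

// [[Rcpp::export(name = ".close_chain_cpp")]]
NumericMatrix close_chain_cpp(NumericMatrix chain) {
    std::vector<Pt> poly = close_chain_pts(mat_to_pts(chain));
    if (!polygon_simple(poly, 1e-9))
        stop("chain closure produced a self-intersecting polygon");
    return pts_to_mat(poly);
}

// [[Rcpp::export(name = ".kmt_reduce_cpp")]]
NumericMatrix kmt_reduce_cpp(NumericMatrix poly) {
    return pts_to_mat(kmt_reduce_pts(mat_to_pts(poly)));
}

// [[Rcpp::export(name = ".alexander_det_cpp")]]
int alexander_det_cpp(NumericMatrix poly, int n_dirs) {
    return alexander_det_poly(mat_to_pts(poly), n_dirs);
}

// closure + KMT + Alexander determinant for an open lattice chain
// [[Rcpp::export(name = ".chain_alexander_cpp")]]
int chain_alexander_cpp(IntegerMatrix conf) {
    std::vector<Vec3> chain(conf.nrow());
    for (int i = 0; i < conf.nrow(); ++i)
        chain[i] = v3(conf(i,0), conf(i,1), conf(i,2));
    return chain_alexander(chain);
}

// batch knottedness classification (one determinant per conformation)
// [[Rcpp::export(name = ".batch_alexander_cpp")]]
IntegerVector batch_alexander_cpp(List confs) {
    int n = confs.size();
    IntegerVector out(n);
    for (int k = 0; k < n; ++k) {
        IntegerMatrix conf = confs[k];
        std::vector<Vec3> chain(conf.nrow());
        for (int i = 0; i < conf.nrow(); ++i)
            chain[i] = v3(conf(i,0), conf(i,1), conf(i,2));
        out[k] = chain_alexander(chain);
        if (k % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

static bool sub_knotted(const std::vector<Vec3> &chain, int s, int e) {
    std::vector<Vec3> sub(chain.begin() + s, chain.begin() + e + 1);
    return chain_alexander(sub) != 1;
}

// Minimal knotted segment by alternating end deletion with re-closure.
// Returns 1-based (start, end); (0, 0) if the chain is not knotted.
// [[Rcpp::export(name = ".knot_core_cpp")]]
IntegerVector knot_core_cpp(IntegerMatrix conf) {
    std::vector<Vec3> chain(conf.nrow());
    for (int i = 0; i < conf.nrow(); ++i)
        chain[i] = v3(conf(i,0), conf(i,1), conf(i,2));
    int N = (int)chain.size();
    if (chain_alexander(chain) == 1) return IntegerVector::create(0, 0);
    int s = 0, e = N - 1;
    bool progress = true;
    while (progress && e - s + 1 > 4) {
        progress = false;
        if (e - s + 1 > 4 && sub_knotted(chain, s + 1, e)) { ++s; progress = true; }
        if (e - s + 1 > 4 && sub_knotted(chain, s, e - 1)) { --e; progress = true; }
        Rcpp::checkUserInterrupt();
    }
    return IntegerVector::create(s + 1, e + 1);
}
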