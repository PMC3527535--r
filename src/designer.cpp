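#include "knotfold.h"
using namespace Rcpp;

// Random self-avoiding chain growth (uniform among legal extensions, restart
// on dead ends). The chain is grown from `origin`; when `reverse_order` the
// grown chain is returned reversed, so the grown origin becomes the last bead.
// With `wall`, all sites must keep z >= 1.
// [[Rcpp::export(name = ".grow_saw_cpp")]]
IntegerMatrix grow_saw_cpp(int n, IntegerVector origin, bool wall,
                           bool reverse_order, double seed, int max_restarts) {
    KfRng rng((uint64_t)seed);
    Vec3 o = v3(origin[0], origin[1], origin[2]);
    for (int attempt = 0; attempt < max_restarts; ++attempt) {
        std::vector<Vec3> chain;
        std::unordered_map<uint64_t, int> occ;
        chain.push_back(o);
        occ[site_key(o)] = 0;
        bool dead = false;
        while ((int)chain.size() < n && !dead) {
            Vec3 cur = chain.back();
            Vec3 cand[6];
            int nc = 0;
            for (int d = 0; d < 6; ++d) {
                Vec3 t = cur + UNIT_STEPS[d];
                if (wall && t[2] < 1) continue;
                if (occ.count(site_key(t))) continue;
                cand[nc++] = t;
            }
            if (nc == 0) { dead = true; break; }
            Vec3 nxt = cand[rng.randint(nc)];
            occ[site_key(nxt)] = (int)chain.size();
            chain.push_back(nxt);
        }
        if (dead) continue;
        IntegerMatrix m(n, 3);
        for (int i = 0; i < n; ++i) {
            const Vec3 &p = chain[reverse_order ? (n - 1 - i) : i];
            for (int c = 0; c < 3; ++c) m(i, c) = p[c];
        }
        return m;
    }
    stop("self-avoiding chain growth failed after %d restarts", max_restarts);
}

// ---------------------------------------------------------------------------
// constrained simulated annealing for native-structure design

struct DesignTarget {
    int n_contacts;      // exact native contact count
    int sum_sep;         // exact sum of |i-j| over contacts (contact order * count)
    int det;             // Alexander determinant class (1 unknot, 3 trefoil)
    int win_s, win_e;    // 1-based target knotted-core window (0 = none)
    int n_win;           // contacts with both beads inside the window (-1 = none)
    int body_from;       // 1-based first bead of the compact body
    int box_d1, box_d2, box_d3;   // sorted target bbox extents of the body (-1 = none)
    bool bead1_extend;   // bead 1 must sit outside the body's bounding box
    bool have_ref;       // overlap constraints against a reference site set
    int n_coincide;      // beads required to sit on reference sites
    int max_runs;        // max number of contiguous off-reference segments
};

struct PenaltyParts {
    double cheap, knot, core;
    double total() const { return cheap + knot + core; }
};

struct Designer {
    int N;
    DesignTarget tgt;
    double w_ncon, w_sum, w_box, w_ext, w_win, w_knot, w_core, w_ov, w_runs;
    double cheap_cutoff;
    bool core_on;
    std::unordered_map<uint64_t, char> ref_sites;

    double cheap_penalty(const std::vector<Vec3> &pos) const {
        int n = (int)pos.size();
        int ncon = 0, sumsep = 0, nwin = 0;
        for (int i = 0; i < n; ++i)
            for (int j = i + 3; j < n; ++j)
                if (l1norm(pos[i] - pos[j]) == 1) {
                    ++ncon;
                    sumsep += j - i;
                    if (tgt.win_s > 0 && i + 1 >= tgt.win_s && j + 1 <= tgt.win_e) ++nwin;
                }
        double p = w_ncon * std::abs(ncon - tgt.n_contacts);
        if (tgt.sum_sep >= 0) p += w_sum * std::abs(sumsep - tgt.sum_sep);
        if (tgt.n_win >= 0) p += w_win * std::abs(nwin - tgt.n_win);
        if (tgt.box_d1 >= 0) {
            int lo[3] = { INT32_MAX, INT32_MAX, INT32_MAX };
            int hi[3] = { INT32_MIN, INT32_MIN, INT32_MIN };
            for (int i = tgt.body_from - 1; i < n; ++i)
                for (int c = 0; c < 3; ++c) {
                    lo[c] = std::min(lo[c], pos[i][c]);
                    hi[c] = std::max(hi[c], pos[i][c]);
                }
            int ex[3] = { hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2] };
            std::sort(ex, ex + 3);
            int tg[3] = { tgt.box_d1, tgt.box_d2, tgt.box_d3 };
            for (int c = 0; c < 3; ++c) p += w_box * std::max(0, ex[c] - tg[c]);
            if (tgt.bead1_extend) {
                const Vec3 &b1 = pos[0];
                bool inside = b1[0] >= lo[0] && b1[0] <= hi[0] &&
                              b1[1] >= lo[1] && b1[1] <= hi[1] &&
                              b1[2] >= lo[2] && b1[2] <= hi[2];
                if (inside) p += w_ext;
            }
        }
        if (tgt.have_ref) {
            int coincide = 0, runs = 0;
            bool in_run = false;
            for (int i = 0; i < n; ++i) {
                if (ref_sites.count(site_key(pos[i]))) { ++coincide; in_run = false; }
                else { if (!in_run) ++runs; in_run = true; }
            }
            p += w_ov * std::abs(coincide - tgt.n_coincide);
            if (tgt.max_runs >= 0) p += w_runs * std::max(0, runs - tgt.max_runs);
        }
        return p;
    }

    PenaltyParts penalty(const std::vector<Vec3> &pos) const {
        PenaltyParts pp;
        pp.cheap = cheap_penalty(pos);
        pp.knot = w_knot;
        pp.core = core_on ? w_core * 10.0 : 0.0;
        if (pp.cheap <= cheap_cutoff) {
            int det = chain_alexander(pos);
            pp.knot = (det == tgt.det) ? 0.0 : w_knot;
            if (core_on) {
                if (det == 3 && tgt.win_s > 0) {
                    // greedy end-deletion core localization
                    int s = 0, e = (int)pos.size() - 1;
                    bool progress = true;
                    while (progress && e - s + 1 > 4) {
                        progress = false;
                        std::vector<Vec3> sub(pos.begin() + s + 1, pos.begin() + e + 1);
                        if (chain_alexander(sub) != 1) { ++s; progress = true; }
                        std::vector<Vec3> sub2(pos.begin() + s, pos.begin() + e);
                        if (e - s + 1 > 4 && chain_alexander(sub2) != 1) { --e; progress = true; }
                    }
                    pp.core = w_core * (std::abs(s + 1 - tgt.win_s) + std::abs(e + 1 - tgt.win_e));
                } else if (tgt.win_s > 0) {
                    pp.core = w_core * 10.0;
                } else pp.core = 0.0;
            }
        }
        return pp;
    }
};

// `frozen_lo`..`frozen_hi` (1-based, 0 = none) pins a bead range: proposals
// touching it are discarded (the annealer is a search heuristic, not an
// equilibrium sampler, so proposal symmetry is not required here).
// [[Rcpp::export(name = ".design_anneal_cpp")]]
List design_anneal_cpp(IntegerMatrix init, List target, NumericVector weights,
                       Nullable<IntegerMatrix> ref_conf, double t_start, double t_end,
                       double steps, double p_crank, double cheap_cutoff,
                       bool core_on, double seed,
                       int frozen_lo = 0, int frozen_hi = 0) {
    Designer D;
    D.N = init.nrow();
    D.tgt.n_contacts = as<int>(target["n_contacts"]);
    D.tgt.sum_sep = as<int>(target["sum_sep"]);
    D.tgt.det = as<int>(target["det"]);
    D.tgt.win_s = as<int>(target["win_s"]);
    D.tgt.win_e = as<int>(target["win_e"]);
    D.tgt.n_win = as<int>(target["n_win"]);
    D.tgt.body_from = as<int>(target["body_from"]);
    IntegerVector box = target["box"];
    if (box.size() == 3) {
        IntegerVector b = clone(box).sort();
        D.tgt.box_d1 = b[0]; D.tgt.box_d2 = b[1]; D.tgt.box_d3 = b[2];
    } else D.tgt.box_d1 = D.tgt.box_d2 = D.tgt.box_d3 = -1;
    D.tgt.bead1_extend = as<bool>(target["bead1_extend"]);
    D.tgt.have_ref = ref_conf.isNotNull();
    D.tgt.n_coincide = as<int>(target["n_coincide"]);
    D.tgt.max_runs = as<int>(target["max_runs"]);
    if (D.tgt.have_ref) {
        IntegerMatrix rc(ref_conf);
        for (int i = 0; i < rc.nrow(); ++i)
            D.ref_sites[site_key(v3(rc(i,0), rc(i,1), rc(i,2)))] = 1;
    }
    D.w_ncon = weights["ncon"]; D.w_sum = weights["sum"]; D.w_box = weights["box"];
    D.w_ext = weights["ext"];   D.w_win = weights["win"]; D.w_knot = weights["knot"];
    D.w_core = weights["core"]; D.w_ov = weights["ov"];   D.w_runs = weights["runs"];
    D.cheap_cutoff = cheap_cutoff;
    D.core_on = core_on;

    LatticeChain ch;
    IntegerMatrix dummy(0, 2);
    ch.init(init, dummy, MODE_BULK, -1, p_crank);
    KfRng rng((uint64_t)seed);

    PenaltyParts cur = D.penalty(ch.pos);
    std::vector<Vec3> best = ch.pos;
    PenaltyParts bestp = cur;
    long long nsteps = (long long)steps;
    double cool = (t_end < t_start && nsteps > 1)
                      ? std::pow(t_end / t_start, 1.0 / (double)(nsteps - 1)) : 1.0;
    double T = t_start;

    for (long long t = 0; t < nsteps && bestp.total() > 0; ++t, T *= cool) {
        int beads[2];
        Vec3 np[2];
        int nmove = ch.propose(rng, beads, np);
        if (nmove == 0) continue;
        if (frozen_lo > 0) {
            bool touches = false;
            for (int m = 0; m < nmove; ++m)
                if (beads[m] + 1 >= frozen_lo && beads[m] + 1 <= frozen_hi) touches = true;
            if (touches) continue;
        }
        Vec3 old[2];
        for (int m = 0; m < nmove; ++m) {
            old[m] = ch.pos[beads[m]];
            ch.clear_cell(old[m]);
        }
        for (int m = 0; m < nmove; ++m) {
            ch.pos[beads[m]] = np[m];
            ch.set_cell(np[m], beads[m]);
        }
        PenaltyParts cand = D.penalty(ch.pos);
        double dE = cand.total() - cur.total();
        if (dE <= 0 || rng.unif() < std::exp(-dE / T)) {
            cur = cand;
            if (cand.total() < bestp.total()) { bestp = cand; best = ch.pos; }
        } else {
            for (int m = 0; m < nmove; ++m) ch.clear_cell(ch.pos[beads[m]]);
            for (int m = 0; m < nmove; ++m) {
                ch.pos[beads[m]] = old[m];
                ch.set_cell(old[m], beads[m]);
            }
        }
        if ((t & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }

    IntegerMatrix out(D.N, 3), fin(D.N, 3);
    for (int i = 0; i < D.N; ++i)
        for (int c = 0; c < 3; ++c) {
            out(i, c) = best[i][c];
            fin(i, c) = ch.pos[i][c];
        }
    return List::create(
        _["conformation"] = out,
        _["penalty"] = bestp.total(),
        _["cheap"] = bestp.cheap,
        _["knot"] = bestp.knot,
        _["core"] = bestp.core,
        _["final"] = fin);
}
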