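#include "knotfold.h"
using namespace Rcpp;

// Chain state initialisation. `start` is an N x 3 integer matrix (bead order),
// `native_pairs` an M x 2 matrix of 1-based bead indices.
void LatticeChain::init(const IntegerMatrix &start, const IntegerMatrix &native_pairs,
                        int mode_, int anchored_, double p_crank_) {
    N = start.nrow();
    if (N > 64 && native_pairs.nrow() > 0)
        stop("chains longer than 64 beads are not supported with a native contact map");
    if (N > 120) stop("chains longer than 120 beads are not supported by the engine");
    mode = mode_;
    anchored = anchored_;
    p_crank = p_crank_;
    steps_since_check = 0;
    pos.resize(N);
    grid.assign(1 << 21, 0);
    for (int i = 0; i < N; ++i) {
        pos[i] = v3(start(i, 0), start(i, 1), start(i, 2));
        set_cell(pos[i], i);
    }
    natbit.assign(N, 0ULL);
    nat_partners.assign(N, std::vector<int>());
    n_native = native_pairs.nrow();
    for (int k = 0; k < n_native; ++k) {
        int a = native_pairs(k, 0) - 1, b = native_pairs(k, 1) - 1;
        natbit[a] |= (1ULL << b);
        natbit[b] |= (1ULL << a);
        nat_partners[a].push_back(b);
        nat_partners[b].push_back(a);
    }
    recount();
}

void LatticeChain::recount() {
    formed_native = 0;
    total_contacts = 0;
    for (int i = 0; i < N; ++i) {
        for (int d = 0; d < 6; ++d) {
            int j = occupant(pos[i] + UNIT_STEPS[d]);
            if (j <= i + 1) continue;             // each pair once; bonded pairs excluded
            ++total_contacts;                      // lattice parity ensures |i-j| >= 3
            if (is_native_pair(i, j)) ++formed_native;
        }
    }
}

// Bulk drift control: when the chain wanders towards the grid edge, shift it
// back onto its centroid. Every observable is translation invariant.
void LatticeChain::recenter_if_needed() {
    if (mode != MODE_BULK) return;
    int mx = 0;
    for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c) mx = std::max(mx, std::abs(pos[i][c]));
    if (mx <= 40) return;
    long cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < N; ++i) { cx += pos[i][0]; cy += pos[i][1]; cz += pos[i][2]; }
    Vec3 shift = v3((int)(cx / N), (int)(cy / N), (int)(cz / N));
    for (int i = 0; i < N; ++i) clear_cell(pos[i]);
    for (int i = 0; i < N; ++i) {
        pos[i] = pos[i] - shift;
        set_cell(pos[i], i);
    }
}

double LatticeChain::rg2() const {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < N; ++i) { cx += pos[i][0]; cy += pos[i][1]; cz += pos[i][2]; }
    cx /= N; cy /= N; cz /= N;
    double s = 0;
    for (int i = 0; i < N; ++i) {
        double dx = pos[i][0] - cx, dy = pos[i][1] - cy, dz = pos[i][2] - cz;
        s += dx * dx + dy * dy + dz * dz;
    }
    return s / N;
}

// Shared acceptance step for a candidate displacing beads `beads[0..nmove-1]`
// to `newpos`. Candidate legality (vacancy, wall) has been checked already.
bool LatticeChain::try_move(const int *beads, const Vec3 *newpos, int nmove,
                            double T, KfRng &rng) {
    // contact change from neighbour scans around old and new sites
    int d_total = 0, d_native = 0;
    for (int m = 0; m < nmove; ++m) {
        int b = beads[m];
        for (int d = 0; d < 6; ++d) {
            int j = occupant(pos[b] + UNIT_STEPS[d]);
            if (j < 0) continue;
            bool moved_j = false;
            for (int m2 = 0; m2 < nmove; ++m2) if (beads[m2] == j) moved_j = true;
            if (moved_j || std::abs(j - b) <= 1) continue;
            --d_total;
            if (is_native_pair(b, j)) --d_native;
        }
    }
    // tentative occupancy: remove moved beads, then probe new sites
    for (int m = 0; m < nmove; ++m) clear_cell(pos[beads[m]]);
    for (int m = 0; m < nmove; ++m) {
        int b = beads[m];
        for (int d = 0; d < 6; ++d) {
            int j = occupant(newpos[m] + UNIT_STEPS[d]);
            if (j < 0 || std::abs(j - b) <= 1) continue;
            ++d_total;
            if (is_native_pair(b, j)) ++d_native;
        }
    }
    // moved-moved pairs (|i-j| == 1 for the crankshaft pair: never contacts)
    double dE = -(double)d_native;   // epsilon = -1
    bool accept = (dE <= 0.0) || (rng.unif() < std::exp(-dE / T));
    if (accept) {
        for (int m = 0; m < nmove; ++m) {
            pos[beads[m]] = newpos[m];
            set_cell(newpos[m], beads[m]);
        }
        total_contacts += d_total;
        formed_native += d_native;
    } else {
        for (int m = 0; m < nmove; ++m) set_cell(pos[beads[m]], beads[m]);
    }
    return accept;
}

// One elementary proposal (1 MCS). The proposal mechanism is symmetric:
// positions/beads are drawn uniformly over fixed index ranges, infeasible
// draws count as rejected attempts, end-move targets are drawn uniformly over
// the vacant neighbours of the pivot (a set whose size is invariant under the
// move itself), so detailed balance holds for the Metropolis chain.
int LatticeChain::propose(KfRng &rng, int *beads, Vec3 *np) {
    if (rng.unif() < p_crank) {
        // crankshaft about the axis through beads i, i+3
        int i = rng.randint(N - 3);
        Vec3 ax = pos[i + 3] - pos[i];
        if (l1norm(ax) != 1) return 0;
        int rot = rng.randint(3);                   // 90, 180, 270 degrees
        for (int m = 0; m < 2; ++m) {
            Vec3 v = pos[i + 1 + m] - pos[i];
            // component along axis stays; rotate perpendicular part about ax
            int a = (ax[0] != 0) ? 0 : (ax[1] != 0 ? 1 : 2);
            int sgn = ax[a] > 0 ? 1 : -1;
            int u = (a + 1) % 3, w = (a + 2) % 3;
            int vu = v[u], vw = v[w];
            Vec3 r = v;
            if (rot == 1) { r[u] = -vu; r[w] = -vw; }                 // 180
            else if (rot == 0) { r[u] = -sgn * vw; r[w] =  sgn * vu; } // +90
            else              { r[u] =  sgn * vw; r[w] = -sgn * vu; } // -90
            np[m] = pos[i] + r;
        }
        if (np[0] == pos[i + 1] && np[1] == pos[i + 2]) return 0;
        beads[0] = i + 1; beads[1] = i + 2;
        for (int m = 0; m < 2; ++m) {
            if (!site_ok(np[m])) return 0;
            int o = occupant(np[m]);
            if (o >= 0 && o != i + 1 && o != i + 2) return 0;
        }
        return 2;
    }
    int b = rng.randint(N);
    beads[0] = b;
    if (b == 0 || b == N - 1) {
        if (b == anchored) return 0;                // tethered terminus never end-moves
        int pivot = (b == 0) ? 1 : N - 2;
        Vec3 cand[6];
        int ncand = 0;
        for (int d = 0; d < 6; ++d) {
            Vec3 t = pos[pivot] + UNIT_STEPS[d];
            if (!site_ok(t)) continue;
            if (occupant(t) >= 0) continue;        // current site is occupied too
            cand[ncand++] = t;
        }
        if (ncand == 0) return 0;
        np[0] = cand[rng.randint(ncand)];
        return 1;
    }
    // corner flip of an interior bead
    Vec3 e1 = pos[b] - pos[b - 1], e2 = pos[b + 1] - pos[b];
    if (e1[0]*e2[0] + e1[1]*e2[1] + e1[2]*e2[2] != 0) return 0;  // collinear bonds
    np[0] = pos[b - 1] + (pos[b + 1] - pos[b]);
    if (!site_ok(np[0])) return 0;
    if (occupant(np[0]) >= 0) return 0;
    return 1;
}

bool LatticeChain::attempt(double T, KfRng &rng) {
    if (++steps_since_check >= 256) {
        steps_since_check = 0;
        recenter_if_needed();
    }
    int beads[2];
    Vec3 np[2];
    int nmove = propose(rng, beads, np);
    if (nmove == 0) return false;
    return try_move(beads, np, nmove, T, rng);
}

// ---------------------------------------------------------------------------
// exported helpers

static void check_conf(const IntegerMatrix &conf) {
    int n = conf.nrow();
    if (conf.ncol() != 3) stop("conformation must be an N x 3 integer matrix");
    std::unordered_map<uint64_t, int> seen;
    for (int i = 0; i < n; ++i) {
        Vec3 p = v3(conf(i,0), conf(i,1), conf(i,2));
        std::unordered_map<uint64_t, int>::const_iterator it = seen.find(site_key(p));
        if (it != seen.end())
            stop("excluded-volume violation: beads %d and %d share a lattice site",
                 it->second + 1, i + 1);
        seen[site_key(p)] = i;
        if (i > 0) {
            Vec3 d = p - v3(conf(i-1,0), conf(i-1,1), conf(i-1,2));
            if (l1norm(d) != 1)
                stop("broken bond between beads %d and %d (not unit lattice step)", i, i + 1);
        }
    }
}

// [[Rcpp::export(name = ".validate_conf_cpp")]]
void validate_conf_cpp(IntegerMatrix conf) { check_conf(conf); }

// Exhaustive contact enumeration: non-bonded nearest lattice neighbours with
// |i - j| >= 3, returned as an M x 2 matrix of 1-based indices (i < j).
// [[Rcpp::export(name = ".compute_contacts_cpp")]]
IntegerMatrix compute_contacts_cpp(IntegerMatrix conf) {
    check_conf(conf);
    int n = conf.nrow();
    std::vector<std::pair<int,int> > out;
    for (int i = 0; i < n; ++i)
        for (int j = i + 3; j < n; ++j) {
            int dx = conf(i,0)-conf(j,0), dy = conf(i,1)-conf(j,1), dz = conf(i,2)-conf(j,2);
            if (std::abs(dx) + std::abs(dy) + std::abs(dz) == 1)
                out.push_back(std::make_pair(i + 1, j + 1));
        }
    IntegerMatrix m((int)out.size(), 2);
    for (size_t k = 0; k < out.size(); ++k) {
        m(k, 0) = out[k].first;
        m(k, 1) = out[k].second;
    }
    return m;
}

// Enumerate all legal single-attempt candidates from a conformation
// (for reversibility / proposal-set tests on short chains). Returns a list of
// N x 3 matrices, one per distinct reachable candidate conformation.
// [[Rcpp::export(name = ".enumerate_moves_cpp")]]
List enumerate_moves_cpp(IntegerMatrix conf, int mode, int anchored) {
    LatticeChain ch;
    IntegerMatrix dummy(0, 2);
    ch.init(conf, dummy, mode, anchored - 1, 0.0);
    int N = ch.N;
    std::vector<std::vector<Vec3> > results;
    std::vector<std::vector<Vec3> > base(1, ch.pos);

    // candidate acceptance helper
    struct Cand {
        static void add(std::vector<std::vector<Vec3> > &res, const std::vector<Vec3> &p) {
            for (size_t k = 0; k < res.size(); ++k) if (res[k] == p) return;
            res.push_back(p);
        }
    };
    // single-bead moves
    for (int b = 0; b < N; ++b) {
        if (b == anchored - 1) continue;
        if (b == 0 || b == N - 1) {
            int pivot = (b == 0) ? 1 : N - 2;
            for (int d = 0; d < 6; ++d) {
                Vec3 t = ch.pos[pivot] + UNIT_STEPS[d];
                if (!ch.site_ok(t) || ch.occupant(t) >= 0) continue;
                std::vector<Vec3> p = ch.pos; p[b] = t;
                Cand::add(results, p);
            }
        } else {
            Vec3 e1 = ch.pos[b] - ch.pos[b-1], e2 = ch.pos[b+1] - ch.pos[b];
            if (e1[0]*e2[0] + e1[1]*e2[1] + e1[2]*e2[2] != 0) continue;
            Vec3 t = ch.pos[b-1] + (ch.pos[b+1] - ch.pos[b]);
            if (!ch.site_ok(t) || ch.occupant(t) >= 0) continue;
            std::vector<Vec3> p = ch.pos; p[b] = t;
            Cand::add(results, p);
        }
    }
    // crankshafts
    for (int i = 0; i + 3 < N; ++i) {
        Vec3 ax = ch.pos[i+3] - ch.pos[i];
        if (l1norm(ax) != 1) continue;
        for (int rot = 0; rot < 3; ++rot) {
            Vec3 np[2];
            bool ok = true;
            for (int m = 0; m < 2; ++m) {
                Vec3 v = ch.pos[i+1+m] - ch.pos[i];
                int a = (ax[0] != 0) ? 0 : (ax[1] != 0 ? 1 : 2);
                int sgn = ax[a] > 0 ? 1 : -1;
                int u = (a + 1) % 3, w = (a + 2) % 3;
                int vu = v[u], vw = v[w];
                Vec3 r = v;
                if (rot == 1) { r[u] = -vu; r[w] = -vw; }
                else if (rot == 0) { r[u] = -sgn * vw; r[w] =  sgn * vu; }
                else              { r[u] =  sgn * vw; r[w] = -sgn * vu; }
                np[m] = ch.pos[i] + r;
            }
            if (np[0] == ch.pos[i+1] && np[1] == ch.pos[i+2]) continue;
            for (int m = 0; m < 2 && ok; ++m) {
                if (!ch.site_ok(np[m])) ok = false;
                else {
                    int o = ch.occupant(np[m]);
                    if (o >= 0 && o != i+1 && o != i+2) ok = false;
                }
            }
            if (!ok) continue;
            std::vector<Vec3> p = ch.pos; p[i+1] = np[0]; p[i+2] = np[1];
            Cand::add(results, p);
        }
    }
    List out(results.size());
    for (size_t k = 0; k < results.size(); ++k) {
        IntegerMatrix m(N, 3);
        for (int i = 0; i < N; ++i)
            for (int c = 0; c < 3; ++c) m(i, c) = results[k][i][c];
        out[k] = m;
    }
    (void)base;
    return out;
}

// Draw `n_attempts` proposals from a fixed conformation (no acceptance step);
// returns candidates as a list, with NULL for no-move attempts.
// [[Rcpp::export(name = ".propose_moves_cpp")]]
List propose_moves_cpp(IntegerMatrix conf, int mode, int anchored,
                       double p_crank, double seed, int n_attempts) {
    check_conf(conf);
    LatticeChain ch;
    IntegerMatrix dummy(0, 2);
    ch.init(conf, dummy, mode, anchored - 1, p_crank);
    KfRng rng((uint64_t)seed);
    List out(n_attempts);
    for (int k = 0; k < n_attempts; ++k) {
        int beads[2]; Vec3 np[2];
        int nmove = ch.propose(rng, beads, np);
        if (nmove == 0) { out[k] = R_NilValue; continue; }
        IntegerMatrix m(ch.N, 3);
        for (int i = 0; i < ch.N; ++i)
            for (int c = 0; c < 3; ++c) m(i, c) = ch.pos[i][c];
        for (int mv = 0; mv < nmove; ++mv)
            for (int c = 0; c < 3; ++c) m(beads[mv], c) = np[mv][c];
        out[k] = m;
    }
    return out;
}
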