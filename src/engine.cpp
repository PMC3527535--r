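#include "knotfold.h"
using namespace Rcpp;

// Fixed-temperature Metropolis folding run.
//
// start:        N x 3 integer start conformation
// native_pairs: M x 2 native contact map (1-based)
// anchored:     1-based anchored bead (0 = none)
// Records a trajectory row every `record_interval` attempted moves and an
// optional coordinate snapshot every `snapshot_interval` attempts.
// Stops at the first passage to Q = 1 when `stop_at_fold` is true.
// [[Rcpp::export(name = ".run_mc_cpp")]]
List run_mc_cpp(IntegerMatrix start, IntegerMatrix native_pairs, double temperature,
                double max_steps, double record_interval, double snapshot_interval,
                int mode, int anchored, double p_crank, double seed,
                bool stop_at_fold, bool debug_checks) {
    LatticeChain ch;
    ch.init(start, native_pairs, mode, anchored - 1, p_crank);
    KfRng rng((uint64_t)seed);
    long long steps = (long long)max_steps;
    long long rec = (long long)record_interval;
    long long snap = (long long)snapshot_interval;

    std::vector<double> r_time, r_E, r_Q, r_rg;
    std::vector<int> r_nn;
    std::vector<int> snap_xyz;
    std::vector<double> snap_time;
    std::vector<int> snap_formed;
    long long n_accept = 0;

    int n_native = ch.n_native;
    bool folded = false;
    double fpt = NA_REAL;

    // record the state at attempt t
    struct Rec {
        static void row(LatticeChain &c, long long t, std::vector<double> &rt,
                        std::vector<double> &re, std::vector<double> &rq,
                        std::vector<double> &rr, std::vector<int> &rn) {
            rt.push_back((double)t);
            re.push_back(-(double)c.formed_native);
            rq.push_back(c.n_native > 0 ? (double)c.formed_native / c.n_native : NA_REAL);
            rr.push_back(std::sqrt(c.rg2()));
            rn.push_back(c.total_contacts - c.formed_native);
        }
    };

    Rec::row(ch, 0, r_time, r_E, r_Q, r_rg, r_nn);
    if (stop_at_fold && n_native > 0 && ch.formed_native == n_native) {
        folded = true;
        fpt = 0;
    } else {
        for (long long t = 1; t <= steps; ++t) {
            if (ch.attempt(temperature, rng)) ++n_accept;
            if (stop_at_fold && ch.formed_native == n_native && n_native > 0) {
                folded = true;
                fpt = (double)t;
                Rec::row(ch, t, r_time, r_E, r_Q, r_rg, r_nn);
                break;
            }
            if (rec > 0 && t % rec == 0) {
                Rec::row(ch, t, r_time, r_E, r_Q, r_rg, r_nn);
                if (debug_checks) {
                    int fm = ch.formed_native, tc = ch.total_contacts;
                    ch.recount();
                    if (fm != ch.formed_native || tc != ch.total_contacts)
                        stop("incremental contact bookkeeping diverged at step %lld", t);
                }
            }
            if (snap > 0 && t % snap == 0) {
                for (int i = 0; i < ch.N; ++i)
                    for (int c = 0; c < 3; ++c) snap_xyz.push_back(ch.pos[i][c]);
                snap_time.push_back((double)t);
                snap_formed.push_back(ch.formed_native);
            }
            if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
        }
    }

    int nr = (int)r_time.size();
    NumericMatrix traj(nr, 5);
    for (int i = 0; i < nr; ++i) {
        traj(i, 0) = r_time[i]; traj(i, 1) = r_E[i]; traj(i, 2) = r_Q[i];
        traj(i, 3) = r_rg[i];   traj(i, 4) = r_nn[i];
    }
    IntegerMatrix fin(ch.N, 3);
    for (int i = 0; i < ch.N; ++i)
        for (int c = 0; c < 3; ++c) fin(i, c) = ch.pos[i][c];
    int ns = (int)snap_time.size();
    IntegerMatrix snaps(ns, 3 * ch.N);
    for (int s = 0; s < ns; ++s)
        for (int k = 0; k < 3 * ch.N; ++k) snaps(s, k) = snap_xyz[(size_t)s * 3 * ch.N + k];

    return List::create(
        _["trajectory"] = traj,
        _["folded"] = folded,
        _["fpt"] = fpt,
        _["final"] = fin,
        _["n_accept"] = (double)n_accept,
        _["snapshots"] = snaps,
        _["snapshot_time"] = NumericVector(snap_time.begin(), snap_time.end()),
        _["snapshot_formed"] = IntegerVector(snap_formed.begin(), snap_formed.end()));
}

// Replica-exchange (parallel tempering) sampling.
//
// starts: list of K start conformations (one per replica)
// temps:  strictly increasing temperature grid of length K
// Each sweep advances every replica by `sweep_attempts` elementary moves and
// then attempts `swaps_per_sweep` exchanges between randomly chosen adjacent
// temperature pairs. E/Q/Rg are sampled once per sweep at every temperature.
// [[Rcpp::export(name = ".run_re_cpp")]]
List run_re_cpp(List starts, IntegerMatrix native_pairs, NumericVector temps,
                double sweep_attempts, int n_sweeps, int swaps_per_sweep,
                int mode, int anchored, double p_crank, double seed) {
    int K = temps.size();
    if (starts.size() != K) stop("need one start conformation per temperature");
    std::vector<LatticeChain> reps(K);
    for (int k = 0; k < K; ++k) {
        IntegerMatrix s = starts[k];
        reps[k].init(s, native_pairs, mode, anchored - 1, p_crank);
    }
    KfRng rng((uint64_t)seed);
    std::vector<int> rep_at(K);          // replica index occupying temperature slot
    for (int k = 0; k < K; ++k) rep_at[k] = k;

    long long sweep = (long long)sweep_attempts;
    NumericMatrix sE(n_sweeps, K), sQ(n_sweeps, K), sRg(n_sweeps, K);
    IntegerMatrix repHist(n_sweeps, K);
    std::vector<double> attempts(K - 1, 0.0), accepts(K - 1, 0.0);

    for (int sw = 0; sw < n_sweeps; ++sw) {
        for (int ti = 0; ti < K; ++ti) {
            LatticeChain &c = reps[rep_at[ti]];
            double T = temps[ti];
            for (long long t = 0; t < sweep; ++t) c.attempt(T, rng);
        }
        for (int a = 0; a < swaps_per_sweep; ++a) {
            int j = (K > 1) ? rng.randint(K - 1) : 0;
            if (K < 2) break;
            double Ei = -(double)reps[rep_at[j]].formed_native;
            double Ej = -(double)reps[rep_at[j + 1]].formed_native;
            double delta = (1.0 / temps[j] - 1.0 / temps[j + 1]) * (Ei - Ej);
            attempts[j] += 1;
            if (delta >= 0 || rng.unif() < std::exp(delta)) {
                std::swap(rep_at[j], rep_at[j + 1]);
                accepts[j] += 1;
            }
        }
        for (int ti = 0; ti < K; ++ti) {
            LatticeChain &c = reps[rep_at[ti]];
            sE(sw, ti) = -(double)c.formed_native;
            sQ(sw, ti) = c.n_native > 0 ? (double)c.formed_native / c.n_native : NA_REAL;
            sRg(sw, ti) = std::sqrt(c.rg2());
            repHist(sw, ti) = rep_at[ti] + 1;
        }
        Rcpp::checkUserInterrupt();
    }
    NumericVector acc(K > 1 ? K - 1 : 0);
    for (int j = 0; j + 1 < K; ++j)
        acc[j] = attempts[j] > 0 ? accepts[j] / attempts[j] : NA_REAL;
    return List::create(
        _["energy"] = sE, _["q"] = sQ, _["rg"] = sRg,
        _["swap_acceptance"] = acc, _["replica_history"] = repHist);
}
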