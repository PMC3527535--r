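#ifndef KNOTFOLD_H
#define KNOTFOLD_H

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>

// ---- deterministic RNG (xoshiro256**, seeded via splitmix64) ----
// Self-contained so that trajectories are bit-reproducible across platforms;
// std::uniform_* distributions are implementation-defined and are avoided.
struct KfRng {
    uint64_t s[4];
    explicit KfRng(uint64_t seed) {
        // splitmix64 expansion of the seed
        for (int i = 0; i < 4; ++i) {
            seed += 0x9E3779B97f4A7C15ULL;
            uint64_t z = seed;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t next() {
        const uint64_t result = rotl(s[1] * 5, 7) * 9;
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    // uniform double in [0, 1)
    inline double unif() { return (next() >> 11) * 0x1.0p-53; }
    // unbiased integer in 0..n-1
    inline int randint(int n) {
        uint64_t x, r;
        const uint64_t nn = (uint64_t)n;
        do { x = next(); r = x % nn; } while (x - r > UINT64_MAX - nn + 1);
        return (int)r;
    }
};

typedef std::array<int, 3> Vec3;

inline Vec3 v3(int x, int y, int z) { Vec3 v = {{x, y, z}}; return v; }
inline Vec3 operator+(const Vec3 &a, const Vec3 &b) { return v3(a[0]+b[0], a[1]+b[1], a[2]+b[2]); }
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return v3(a[0]-b[0], a[1]-b[1], a[2]-b[2]); }
inline bool operator==(const Vec3 &a, const Vec3 &b) { return a[0]==b[0] && a[1]==b[1] && a[2]==b[2]; }
inline int l1norm(const Vec3 &a) { return std::abs(a[0]) + std::abs(a[1]) + std::abs(a[2]); }

// site hashing: coordinates fit in +/- 2^20 lattice units
inline uint64_t site_key(const Vec3 &p) {
    const uint64_t off = 1ULL << 20;
    return (((uint64_t)(p[0] + (int)off)) << 42) |
           (((uint64_t)(p[1] + (int)off)) << 21) |
            ((uint64_t)(p[2] + (int)off));
}

static const Vec3 UNIT_STEPS[6] = {
    {{1,0,0}}, {{-1,0,0}}, {{0,1,0}}, {{0,-1,0}}, {{0,0,1}}, {{0,0,-1}}
};

// folding setups
enum SetupMode { MODE_BULK = 0, MODE_PLANE = 1, MODE_POINT = 2 };

// Core lattice-chain simulator state shared by the MC engine and the designer.
// Occupancy lives on a dense 128^3 grid (2 MB per chain); in bulk mode the
// chain is recentred on its centroid whenever it wanders, which no observable
// depends on. A chain that somehow escapes the grid stops the run loudly.
struct LatticeChain {
    static const int GRID_HALF = 64;                 // coords must stay in (-64, 64)
    int N;
    std::vector<Vec3> pos;
    std::vector<uint8_t> grid;                       // 0 = empty, bead index + 1
    std::vector<uint64_t> natbit;                    // native partner bitmask per bead (N <= 64)
    std::vector<std::vector<int>> nat_partners;      // native partner lists
    int n_native;
    int formed_native;
    int total_contacts;
    int mode;           // SetupMode
    int anchored;       // 0-based bead index, -1 if none
    double p_crank;
    int steps_since_check;

    static inline int gidx(const Vec3 &p) {
        unsigned ix = (unsigned)(p[0] + GRID_HALF);
        unsigned iy = (unsigned)(p[1] + GRID_HALF);
        unsigned iz = (unsigned)(p[2] + GRID_HALF);
        if ((ix | iy | iz) >= 128u)
            Rcpp::stop("chain left the simulation grid (coordinate beyond +/-63)");
        return (int)((ix << 14) | (iy << 7) | iz);
    }
    // 0-based occupant of a site, or -1 when vacant
    inline int occupant(const Vec3 &p) const { return (int)grid[gidx(p)] - 1; }
    inline void set_cell(const Vec3 &p, int bead) { grid[gidx(p)] = (uint8_t)(bead + 1); }
    inline void clear_cell(const Vec3 &p) { grid[gidx(p)] = 0; }
    void recenter_if_needed();                       // bulk drift control

    void init(const Rcpp::IntegerMatrix &start, const Rcpp::IntegerMatrix &native_pairs,
              int mode_, int anchored_, double p_crank_);
    bool site_ok(const Vec3 &p) const {  // steric wall
        return mode != MODE_PLANE || p[2] >= 1;
    }
    inline bool is_native_pair(int a, int b) const {
        return n_native > 0 && ((natbit[a] >> b) & 1ULL);
    }
    void recount();                                  // from-scratch contact tally
    // draw one elementary proposal; returns number of displaced beads (0 = no-move)
    int propose(KfRng &rng, int *beads, Vec3 *newpos);
    // one elementary attempt at temperature T; returns true if accepted
    bool attempt(double T, KfRng &rng);
    double rg2() const;                              // squared gyration radius (lattice units)
    bool try_move(const int *beads, const Vec3 *newpos, int nmove, double T, KfRng &rng);
};

// ---- knot machinery (knot.cpp) ----
typedef std::array<double, 3> Pt;
std::vector<Pt> close_chain_pts(const std::vector<Pt> &chain);
std::vector<Pt> kmt_reduce_pts(std::vector<Pt> poly);
int alexander_det_poly(const std::vector<Pt> &poly, int n_dirs);
int chain_alexander(const std::vector<Vec3> &chain);  // close + KMT + determinant

#endif
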