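// Canonical k-mer de Bruijn graph with tip clipping, bubble popping and
// unitig extraction. k is odd (no odd-length DNA palindromes, so canonical
// orientation is always well defined) and may exceed 32: k-mers are held
// in 128-bit integers.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include "srwalk_common.h"

using namespace Rcpp;

typedef unsigned __int128 u128;

struct U128Hash {
    size_t operator()(u128 x) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        uint64_t z = lo ^ (hi * 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return (size_t)(z ^ (z >> 31));
    }
};

struct DBG {
    int k;
    std::unordered_map<u128, uint32_t, U128Hash> cov; // canonical k-mer -> count
};

static inline u128 kmask(int k) {
    if (k >= 64) return ~(u128)0;
    return ((u128)1 << (2 * k)) - 1;
}

static inline u128 rc_kmer(u128 x, int k) {
    u128 r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | ((u128)3 - (x & 3));
        x >>= 2;
    }
    return r;
}

static inline u128 canon(u128 x, int k) {
    u128 r = rc_kmer(x, k);
    return x < r ? x : r;
}

static std::string decode_kmer(u128 x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = "ACGT"[(int)(x & 3)]; x >>= 2; }
    return s;
}

// [[Rcpp::export]]
SEXP cpp_dbg_build(CharacterVector reads, int k) {
    if (k % 2 == 0) stop("k must be odd");
    if (k < 11 || k > 63) stop("k must be in [11, 63]");
    DBG* g = new DBG();
    g->k = k;
    u128 mask = kmask(k);
    for (int i = 0; i < reads.size(); ++i) {
        const char* s = CHAR(STRING_ELT(reads, i));
        int n = (int)strlen(s);
        u128 x = 0; int run = 0;
        for (int j = 0; j < n; ++j) {
            int c = base_code(s[j]);
            if (c < 0) { run = 0; x = 0; continue; }
            x = ((x << 2) | (u128)c) & mask;
            if (++run >= k) g->cov[canon(x, k)]++;
        }
    }
    return XPtr<DBG>(g, true);
}

// [[Rcpp::export]]
List cpp_dbg_stats(SEXP xp) {
    XPtr<DBG> g(xp);
    double total = 0;
    for (auto& kv : g->cov) total += kv.second;
    return List::create(_["k"] = g->k, _["n_nodes"] = (double)g->cov.size(),
                        _["n_occurrences"] = total);
}

// [[Rcpp::export]]
double cpp_dbg_cov(SEXP xp, std::string kmer) {
    XPtr<DBG> g(xp);
    if ((int)kmer.size() != g->k) stop("k-mer length mismatch");
    u128 x = 0;
    for (char c : kmer) {
        int b = base_code(c);
        if (b < 0) return 0;
        x = (x << 2) | (u128)b;
    }
    auto it = g->cov.find(canon(x, g->k));
    return it == g->cov.end() ? 0.0 : (double)it->second;
}

// [[Rcpp::export]]
CharacterVector cpp_dbg_kmers(SEXP xp) {
    XPtr<DBG> g(xp);
    std::vector<u128> keys;
    keys.reserve(g->cov.size());
    for (auto& kv : g->cov) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector out(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) out[i] = decode_kmer(keys[i], g->k);
    return out;
}

// oriented-kmer successors: append base b on the right
static int successors(const DBG& g, u128 o, u128 mask, u128 out[4]) {
    int n = 0;
    for (int b = 0; b < 4; ++b) {
        u128 y = ((o << 2) | (u128)b) & mask;
        if (g.cov.count(canon(y, g.k))) out[n++] = y;
    }
    return n;
}
static int predecessors(const DBG& g, u128 o, u128 mask, u128 out[4]) {
    int n = 0;
    int shift = 2 * (g.k - 1);
    for (int b = 0; b < 4; ++b) {
        u128 y = (o >> 2) | ((u128)b << shift);
        if (g.cov.count(canon(y, g.k))) out[n++] = y;
    }
    return n;
}

struct Unitig {
    std::string seq;
    std::vector<u128> nodes;   // canonical nodes along the path
    u128 left, right;          // oriented end k-mers in seq orientation
    double mean_cov;
};

// Maximal non-branching paths; deterministic (seeded from sorted node list).
static std::vector<Unitig> build_unitigs(const DBG& g) {
    int k = g.k;
    u128 mask = kmask(k);
    std::vector<u128> keys;
    keys.reserve(g.cov.size());
    for (auto& kv : g.cov) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    std::unordered_set<u128, U128Hash> visited;
    std::vector<Unitig> out;
    u128 nb[4], pb[4];

    for (u128 start : keys) {
        if (visited.count(start)) continue;
        visited.insert(start);
        // extend right from orientation o, then left via the reverse complement
        std::string right_ext, left_ext_rc;
        std::vector<u128> right_nodes, left_nodes_rc;
        for (int side = 0; side < 2; ++side) {
            u128 o = (side == 0) ? start : rc_kmer(start, k);
            while (true) {
                int ns = successors(g, o, mask, nb);
                if (ns != 1) break;
                u128 s = nb[0];
                u128 cs = canon(s, k);
                if (visited.count(cs)) break;
                int np = predecessors(g, s, mask, pb);
                if (np != 1) break;
                visited.insert(cs);
                char base = "ACGT"[(int)(s & 3)];
                if (side == 0) { right_ext.push_back(base); right_nodes.push_back(cs); }
                else { left_ext_rc.push_back(base); left_nodes_rc.push_back(cs); }
                o = s;
            }
        }
        Unitig u;
        u.seq = revcomp(left_ext_rc) + decode_kmer(start, k) + right_ext;
        u.nodes.assign(left_nodes_rc.rbegin(), left_nodes_rc.rend());
        u.nodes.push_back(start);
        u.nodes.insert(u.nodes.end(), right_nodes.begin(), right_nodes.end());
        double tot = 0;
        for (u128 n : u.nodes) tot += g.cov.at(n);
        u.mean_cov = tot / u.nodes.size();
        // oriented end k-mers in the orientation of the spelled sequence
        u128 l = 0, r = 0;
        for (int i = 0; i < k; ++i) l = (l << 2) | (u128)base_code(u.seq[i]);
        for (size_t i = u.seq.size() - k; i < u.seq.size(); ++i) r = (r << 2) | (u128)base_code(u.seq[i]);
        u.left = l; u.right = r;
        out.push_back(std::move(u));
    }
    return out;
}

// Remove dead-end paths shorter than tip_len (bp) whose coverage is lower
// than the competing branch at their junction; then collapse bubbles:
// branches diverging at a junction and reconverging at the same node are
// reduced to the highest-coverage arm when the arms are >= bubble_identity
// identical. Iterated to a fixpoint (bounded sweeps).

static double arm_identity(const std::string& a, const std::string& b) {
    // identity = 1 - edit_distance / max(len)
    size_t n = a.size(), m = b.size();
    if (n == 0 || m == 0) return 0.0;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
    for (size_t i = 1; i <= n; ++i) {
        cur[0] = (int)i;
        for (size_t j = 1; j <= m; ++j) {
            int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            d = std::min(d, prev[j] + 1);
            d = std::min(d, cur[j - 1] + 1);
            cur[j] = d;
        }
        std::swap(prev, cur);
    }
    return 1.0 - (double)prev[m] / (double)std::max(n, m);
}

// [[Rcpp::export]]
void cpp_dbg_simplify(SEXP xp, int tip_len, double bubble_identity, int min_count) {
    XPtr<DBG> g(xp);
    int k = g->k;
    u128 mask = kmask(k);
    u128 nb[4], pb[4], sb[4];
    const int max_sweeps = 10;
    const int max_arm_nodes = 300;

    if (min_count > 1) {
        for (auto it = g->cov.begin(); it != g->cov.end();) {
            if ((int)it->second < min_count) it = g->cov.erase(it);
            else ++it;
        }
    }

    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
        bool changed = false;

        // --- tips ---
        {
            std::vector<Unitig> us = build_unitigs(*g);
            std::vector<u128> to_del;
            for (const Unitig& u : us) {
                if ((int)u.seq.size() >= tip_len) continue;
                int np = predecessors(*g, u.left, mask, pb);
                int ns = successors(*g, u.right, mask, nb);
                bool left_dead = (np == 0), right_dead = (ns == 0);
                if (left_dead == right_dead) continue; // isolated or internal
                // junction node beyond the attached end
                u128 attach = left_dead ? nb[0] : pb[0];
                int natt = left_dead ? ns : np;
                if (natt != 1) continue; // attaches to several nodes: not a simple tip
                // competing branches into/out of the attachment node
                double alt = -1.0;
                u128 ourend = left_dead ? u.right : u.left;
                int nsib = left_dead ? predecessors(*g, attach, mask, sb)
                                     : successors(*g, attach, mask, sb);
                for (int i = 0; i < nsib; ++i) {
                    if (sb[i] == ourend) continue;
                    alt = std::max(alt, (double)g->cov.at(canon(sb[i], k)));
                }
                if (alt < 0) continue; // no alternative branch
                if (u.mean_cov < alt) for (u128 n : u.nodes) to_del.push_back(n);
            }
            for (u128 n : to_del) { g->cov.erase(n); changed = true; }
        }

        // --- bubbles ---
        {
            // collect branching oriented k-mers from unitig right ends
            std::vector<Unitig> us = build_unitigs(*g);
            std::vector<u128> junctions;
            for (const Unitig& u : us) {
                if (successors(*g, u.right, mask, nb) >= 2) junctions.push_back(u.right);
                u128 lrc = rc_kmer(u.left, k);
                if (successors(*g, lrc, mask, nb) >= 2) junctions.push_back(lrc);
            }
            std::sort(junctions.begin(), junctions.end());
            junctions.erase(std::unique(junctions.begin(), junctions.end()), junctions.end());

            for (u128 j : junctions) {
                int nar = successors(*g, j, mask, nb);
                if (nar < 2) continue;
                // dominant arm = highest-coverage first node (ties: smaller)
                int dom = 0;
                double domc = -1;
                for (int a = 0; a < nar; ++a) {
                    double c = g->cov.at(canon(nb[a], k));
                    if (c > domc || (c == domc && nb[a] < nb[dom])) { domc = c; dom = a; }
                }
                // walk the dominant path straight through in/out-branches,
                // always taking the highest-coverage successor
                std::unordered_map<u128, int, U128Hash> dom_pos;
                std::string dom_seq;
                double dom_tot = 0;
                {
                    u128 t = nb[dom];
                    for (int step = 0; step < max_arm_nodes; ++step) {
                        u128 ct = canon(t, k);
                        if (dom_pos.count(ct)) break; // loop
                        dom_pos[ct] = step;
                        dom_seq.push_back("ACGT"[(int)(t & 3)]);
                        dom_tot += g->cov.at(ct);
                        int ns2 = successors(*g, t, mask, sb);
                        if (ns2 == 0) break;
                        int bi = 0; double bc = -1;
                        for (int s2 = 0; s2 < ns2; ++s2) {
                            double c2 = g->cov.at(canon(sb[s2], k));
                            if (c2 > bc || (c2 == bc && sb[s2] < sb[bi])) { bc = c2; bi = s2; }
                        }
                        t = sb[bi];
                    }
                }
                double dom_mean = dom_pos.empty() ? 0 : dom_tot / dom_pos.size();
                // minor arms: pop when they rejoin the dominant path with
                // high identity, or clip when they dead-end as a short
                // lower-coverage tip
                for (int a = 0; a < nar; ++a) {
                    if (a == dom) continue;
                    u128 t = nb[a];
                    std::vector<u128> walked;
                    std::string seq2;
                    double tot = 0;
                    int rejoin = -1;
                    bool dead = false;
                    for (int step = 0; step < max_arm_nodes; ++step) {
                        u128 ct = canon(t, k);
                        auto hit = dom_pos.find(ct);
                        if (hit != dom_pos.end()) { rejoin = hit->second; break; }
                        seq2.push_back("ACGT"[(int)(t & 3)]);
                        walked.push_back(ct);
                        tot += g->cov.at(ct);
                        int ns2 = successors(*g, t, mask, sb);
                        if (ns2 == 0) { dead = true; break; }
                        int bi = 0; double bc = -1;
                        for (int s2 = 0; s2 < ns2; ++s2) {
                            double c2 = g->cov.at(canon(sb[s2], k));
                            if (c2 > bc || (c2 == bc && sb[s2] < sb[bi])) { bc = c2; bi = s2; }
                        }
                        t = sb[bi];
                    }
                    if (walked.empty()) continue;
                    double mean2 = tot / walked.size();
                    bool drop = false;
                    if (rejoin >= 0) {
                        if (mean2 <= dom_mean &&
                            arm_identity(seq2, dom_seq.substr(0, rejoin)) >= bubble_identity)
                            drop = true;
                    } else if (dead) {
                        if ((int)walked.size() + k - 1 < tip_len && mean2 < dom_mean)
                            drop = true;
                    }
                    if (drop) {
                        for (u128 n : walked)
                            if (!dom_pos.count(n) && g->cov.count(n)) {
                                g->cov.erase(n);
                                changed = true;
                            }
                    }
                }
            }
        }

        if (!changed) break;
    }
}

// [[Rcpp::export]]
CharacterVector cpp_dbg_unitigs(SEXP xp, int min_len) {
    XPtr<DBG> g(xp);
    std::vector<Unitig> us = build_unitigs(*g);
    std::vector<std::string> seqs;
    for (Unitig& u : us) {
        if ((int)u.seq.size() < min_len) continue;
        std::string rc = revcomp(u.seq);
        seqs.push_back(u.seq <= rc ? u.seq : rc); // canonical orientation
    }
    std::sort(seqs.begin(), seqs.end(), [](const std::string& a, const std::string& b) {
        if (a.size() != b.size()) return a.size() > b.size();
        return a < b;
    });
    return wrap(seqs);
}
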