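#ifndef SRWALK_COMMON_H
#define SRWALK_COMMON_H

#include <string>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <cctype>
#include <cstring>
#include <cmath>

// 2-bit base codes: A=0, C=1, G=2, T=3; -1 for anything else (N, gaps).
inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    case 'N': return 'N'; case 'n': return 'n';
    default: return 'N';
    }
}

inline std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp_base(c);
    return r;
}

inline bool is_lower(char c) { return c >= 'a' && c <= 'z'; }
inline char upcase(char c) { return (char)std::toupper((unsigned char)c); }

// Standard genetic code indexed by 2-bit codon (b1*16 + b2*4 + b3).
static const char GENCODE64[65] =
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

// Translate dna[off..] in steps of 3; unknown codons become 'X'.
inline std::string translate_frame(const std::string& dna, int off) {
    std::string out;
    int n = (int)dna.size();
    out.reserve((n - off) / 3 + 1);
    for (int i = off; i + 2 < n; i += 3) {
        int a = base_code(dna[i]), b = base_code(dna[i + 1]), c = base_code(dna[i + 2]);
        if (a < 0 || b < 0 || c < 0) out.push_back('X');
        else out.push_back(GENCODE64[a * 16 + b * 4 + c]);
    }
    return out;
}

// Amino-acid code 0..19 (alphabetical over ACDEFGHIKLMNPQRSTVWY); -1 otherwise.
inline int aa_code(char c) {
    static const char* AAS = "ACDEFGHIKLMNPQRSTVWY";
    const char* p = strchr(AAS, upcase(c));
    if (!p || !c) return -1;
    return (int)(p - AAS);
}

// Simple deterministic RNG (splitmix64 seeded xorshift) used by the simulator
// so results are identical across platforms and C++ standard libraries.
struct SimRng {
    uint64_t s;
    explicit SimRng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {
        next(); next();
    }
    uint64_t next() {
        uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    // Box-Muller; deterministic given the stream.
    double norm() {
        double u1 = unif(), u2 = unif();
        if (u1 < 1e-300) u1 = 1e-300;
        return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
    }
    int64_t below(int64_t n) { return (int64_t)(unif() * n) % n; }
};

#endif
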