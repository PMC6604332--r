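// Paired-end short-read simulator in the style of wgsim: uniform fragment
// start, truncated-normal insert length, mate 1 forward from the fragment
// start, mate 2 reverse-complement from the fragment end. Sequencing
// substitution errors at base_error per base; haplotype mutations at
// mutation_rate per base of which indel_fraction are 1 bp indels (with the
// default mutation rate of 0 no indels are produced, as in the reference
// protocol). Read names carry the true fragment coordinates
// (sim_<start>_<end>_<i>, 1-based inclusive) for downstream truth checks.

#include <Rcpp.h>
#include "srwalk_common.h"

using namespace Rcpp;

static void draw_read(const std::string& genome, int64_t start, int64_t end, bool rev,
                      int read_len, double base_error, double mutation_rate,
                      double indel_fraction, SimRng& rng, std::string& out) {
    out.clear();
    int64_t L = (int64_t)genome.size();
    int64_t t = 0; // offset along the fragment in read direction
    auto tmpl = [&](int64_t off) -> char {
        int64_t pos = rev ? (end - 1 - off) : (start + off);
        if (pos < 0 || pos >= L) return "ACGT"[rng.below(4)];
        char c = genome[pos];
        return rev ? comp_base(upcase(c)) : upcase(c);
    };
    while ((int)out.size() < read_len) {
        char c = tmpl(t);
        bool mut = mutation_rate > 0 && rng.unif() < mutation_rate;
        if (mut && rng.unif() < indel_fraction) {
            if (rng.unif() < 0.5) { out.push_back("ACGT"[rng.below(4)]); continue; } // insertion
            t++; c = tmpl(t);                                                       // deletion
        } else if (mut) {
            int b = base_code(c); if (b < 0) b = 0;
            c = "ACGT"[(b + 1 + rng.below(3)) % 4];
        }
        if (rng.unif() < base_error) { // sequencing substitution
            int b = base_code(c); if (b < 0) b = 0;
            c = "ACGT"[(b + 1 + rng.below(3)) % 4];
        }
        out.push_back(c);
        t++;
    }
}

// [[Rcpp::export]]
List cpp_simulate_pairs(std::string genome, double n_pairs, int read_len,
                        double insert_mean, double insert_sd,
                        double base_error, double mutation_rate,
                        double indel_fraction, double seed) {
    int64_t L = (int64_t)genome.size();
    int64_t n = (int64_t)n_pairs;
    SimRng rng((uint64_t)seed);
    CharacterVector ids(n), s1(n), s2(n);
    std::string r1, r2;
    for (int64_t i = 0; i < n; ++i) {
        int64_t flen;
        do {
            flen = (int64_t)llround(insert_mean + insert_sd * rng.norm());
        } while (flen < 2 * read_len || flen > L);
        int64_t start = rng.below(L - flen + 1);
        int64_t end = start + flen;
        draw_read(genome, start, end, false, read_len, base_error, mutation_rate, indel_fraction, rng, r1);
        draw_read(genome, start, end, true,  read_len, base_error, mutation_rate, indel_fraction, rng, r2);
        ids[i] = "sim_" + std::to_string(start + 1) + "_" + std::to_string(end) + "_" + std::to_string(i + 1);
        s1[i] = r1;
        s2[i] = r2;
    }
    return List::create(_["id"] = ids, _["seq1"] = s1, _["seq2"] = s2);
}
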