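// DUST low-complexity masking: windowed triplet-composition score
// S = sum_t c_t (c_t - 1) / 2 / (w - 3); positions in any window with
// S > level/10 are lowercased, masked intervals merged when separated by
// at most `linker` bases.

#include <Rcpp.h>
#include "srwalk_common.h"

using namespace Rcpp;

// [[Rcpp::export]]
std::string cpp_dust_mask(std::string seq, int window, int level, int linker) {
    int n = (int)seq.size();
    if (window < 3) stop("window must be >= 3");
    int w = std::min(window, n);
    if (w < 4) return seq; // no scoreable window (w - 3 < 1)
    double thr = level / 10.0;

    // triplet code at position i (triplet seq[i..i+2]); -1 if any non-ACGT
    int nt = n - 2;
    std::vector<int> trip(nt);
    for (int i = 0; i < nt; ++i) {
        int a = base_code(seq[i]), b = base_code(seq[i + 1]), c = base_code(seq[i + 2]);
        trip[i] = (a < 0 || b < 0 || c < 0) ? -1 : (a * 16 + b * 4 + c);
    }

    std::vector<std::pair<int, int>> ivs; // half-open masked intervals
    int counts[64] = {0};
    long long num = 0; // sum over t of C(c_t, 2)
    int wt = w - 2;    // triplets per window
    auto add = [&](int t) { if (t >= 0) { num += counts[t]; counts[t]++; } };
    auto del = [&](int t) { if (t >= 0) { counts[t]--; num -= counts[t]; } };
    for (int i = 0; i < wt && i < nt; ++i) add(trip[i]);
    for (int i = 0; i + w <= n; ++i) {
        if (i > 0) { del(trip[i - 1]); add(trip[i + wt - 1]); }
        double score = (double)num / (double)(w - 3);
        if (score > thr) {
            if (!ivs.empty() && ivs.back().second >= i) ivs.back().second = i + w;
            else ivs.push_back({i, i + w});
        }
    }
    // merge within linker
    std::vector<std::pair<int, int>> merged;
    for (auto& iv : ivs) {
        if (!merged.empty() && iv.first - merged.back().second <= linker)
            merged.back().second = std::max(merged.back().second, iv.second);
        else merged.push_back(iv);
    }
    for (auto& iv : merged)
        for (int i = iv.first; i < iv.second; ++i)
            seq[i] = (char)std::tolower((unsigned char)seq[i]);
    return seq;
}
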