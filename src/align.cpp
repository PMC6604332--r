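// Spliced alignment of a probe (protein or DNA) to a genomic contig.
// Seeded chaining: exact seeds (>=5 aa in translated space, >=12 nt in DNA
// space) are extended to maximal exact matches, chained allowing
// intron-scale gaps on the contig axis only (free when flanked by GT..AG,
// small constant penalty otherwise), and inter-anchor gaps within an exon
// are filled by global DP (BLOSUM62 for protein extension; identities only
// are counted towards the similarity score).

#include <Rcpp.h>
#include <unordered_map>
#include "srwalk_common.h"

using namespace Rcpp;

static const int SEED_AA = 5;
static const int SEED_NT = 12;
static const int MAX_INTRON = 20000;
static const int MIN_INTRON = 40;   // smaller contig gaps are treated as within-exon
static const int MAX_ANCHORS = 5000;

// BLOSUM62 over ACDEFGHIKLMNPQRSTVWY
static const int BL62[20][20] = {
    { 4, 0,-2,-1,-2, 0,-2,-1,-1,-1,-1,-2,-1,-1,-1, 1, 0, 0,-3,-2},
    { 0, 9,-3,-4,-2,-3,-3,-1,-3,-1,-1,-3,-3,-3,-3,-1,-1,-1,-2,-2},
    {-2,-3, 6, 2,-3,-1,-1,-3,-1,-4,-3, 1,-1, 0,-2, 0,-1,-3,-4,-3},
    {-1,-4, 2, 5,-3,-2, 0,-3, 1,-3,-2, 0,-1, 2, 0, 0,-1,-2,-3,-2},
    {-2,-2,-3,-3, 6,-3,-1, 0,-3, 0, 0,-3,-4,-3,-3,-2,-2,-1, 1, 3},
    { 0,-3,-1,-2,-3, 6,-2,-4,-2,-4,-3, 0,-2,-2,-2, 0,-2,-3,-2,-3},
    {-2,-3,-1, 0,-1,-2, 8,-3,-1,-3,-2, 1,-2, 0, 0,-1,-2,-3,-2, 2},
    {-1,-1,-3,-3, 0,-4,-3, 4,-3, 2, 1,-3,-3,-3,-3,-2,-1, 3,-3,-1},
    {-1,-3,-1, 1,-3,-2,-1,-3, 5,-2,-1, 0,-1, 1, 2, 0,-1,-2,-3,-2},
    {-1,-1,-4,-3, 0,-4,-3, 2,-2, 4, 2,-3,-3,-2,-2,-2,-1, 1,-2,-1},
    {-1,-1,-3,-2, 0,-3,-2, 1,-1, 2, 5,-2,-2, 0,-1,-1,-1, 1,-1,-1},
    {-2,-3, 1, 0,-3, 0, 1,-3, 0,-3,-2, 6,-2, 0, 0, 1, 0,-3,-4,-2},
    {-1,-3,-1,-1,-4,-2,-2,-3,-1,-3,-2,-2, 7,-1,-2,-1,-1,-2,-4,-3},
    {-1,-3, 0, 2,-3,-2, 0,-3, 1,-2, 0, 0,-1, 5, 1, 0,-1,-2,-2,-1},
    {-1,-3,-2, 0,-3,-2, 0,-3, 2,-2,-1, 0,-2, 1, 5,-1,-1,-3,-3,-2},
    { 1,-1, 0, 0,-2, 0,-1,-2, 0,-2,-1, 1,-1, 0,-1, 4, 1,-2,-3,-2},
    { 0,-1,-1,-1,-2,-2,-2,-1,-1,-1,-1, 0,-1,-1,-1, 1, 5, 0,-2,-2},
    { 0,-1,-3,-2,-1,-3,-3, 3,-2, 1, 1,-3,-2,-2,-3,-2, 0, 4,-3,-1},
    {-3,-2,-4,-3, 1,-2,-2,-3,-3,-2,-1,-4,-4,-2,-3,-3,-2,-3,11, 2},
    {-2,-2,-3,-2, 3,-3, 2,-1,-2,-1,-1,-2,-3,-1,-2,-2,-2,-1, 2, 7}
};

static inline int sub_score(char a, char b, bool prot) {
    if (prot) {
        int ia = aa_code(a), ib = aa_code(b);
        if (ia < 0 || ib < 0) return -4;
        return BL62[ia][ib];
    }
    if (base_code(a) < 0 || base_code(b) < 0) return -2;
    return upcase(a) == upcase(b) ? 2 : -3;
}

struct Anchor { int ps, pe, cs, ce, frame; }; // probe units / contig nt, half-open, frame -1 for dna

struct FillResult { int identities; };

// Global (Needleman-Wunsch, linear gap) alignment of a vs b counting
// identities on the optimal-score path.
static FillResult dp_fill(const std::string& a, const std::string& b, bool prot) {
    const int GAP = prot ? -6 : -4;
    int n = (int)a.size(), m = (int)b.size();
    FillResult res{0};
    if (n == 0 || m == 0) return res;
    if ((double)n * (double)m > 4e6) return res; // degenerate; skip fill
    std::vector<std::vector<int>> S(n + 1, std::vector<int>(m + 1));
    std::vector<std::vector<unsigned char>> B(n + 1, std::vector<unsigned char>(m + 1));
    for (int i = 0; i <= n; ++i) { S[i][0] = i * GAP; B[i][0] = 1; }
    for (int j = 0; j <= m; ++j) { S[0][j] = j * GAP; B[0][j] = 2; }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int d = S[i - 1][j - 1] + sub_score(a[i - 1], b[j - 1], prot);
            int up = S[i - 1][j] + GAP, le = S[i][j - 1] + GAP;
            if (d >= up && d >= le) { S[i][j] = d; B[i][j] = 0; }
            else if (up >= le) { S[i][j] = up; B[i][j] = 1; }
            else { S[i][j] = le; B[i][j] = 2; }
        }
    }
    int i = n, j = m;
    while (i > 0 || j > 0) {
        unsigned char mv = B[i][j];
        if (mv == 0) { if (upcase(a[i - 1]) == upcase(b[j - 1])) res.identities++; --i; --j; }
        else if (mv == 1) --i;
        else --j;
    }
    return res;
}

struct StrandAln {
    std::vector<std::array<int, 4>> blocks; // ps, pe, cs, ce (S-space)
    int identities = 0, covered = 0, aligned_len = 0;
    bool valid = false;
};

// collect maximal exact matches between probe and text, in probe units
static void collect_mems(const std::string& probe, const std::string& text,
                         int k, bool prot, int frame, int scale,
                         std::vector<Anchor>& anchors) {
    int np = (int)probe.size(), nt = (int)text.size();
    if (np < k || nt < k) return;
    // hash of probe k-mers
    std::unordered_map<uint64_t, std::vector<int>> ph;
    uint64_t key = 0, mask = prot ? ((1ULL << (5 * k)) - 1) : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < np; ++i) {
        int c = prot ? aa_code(probe[i]) : base_code(probe[i]);
        if (c < 0 || probe[i] == '*') { run = 0; key = 0; continue; }
        key = ((key << (prot ? 5 : 2)) | (uint64_t)c) & mask;
        if (++run >= k) ph[key].push_back(i - k + 1);
    }
    key = 0; run = 0;
    for (int i = 0; i < nt; ++i) {
        int c = prot ? aa_code(text[i]) : base_code(text[i]);
        if (c < 0 || text[i] == '*' || text[i] == 'X') { run = 0; key = 0; continue; }
        key = ((key << (prot ? 5 : 2)) | (uint64_t)c) & mask;
        if (++run < k) continue;
        auto it = ph.find(key);
        if (it == ph.end()) continue;
        int toff = i - k + 1;
        for (int poff : it->second) {
            // only record at MEM start
            if (poff > 0 && toff > 0 && upcase(probe[poff - 1]) == upcase(text[toff - 1]))
                continue;
            int len = k;
            while (poff + len < np && toff + len < nt &&
                   upcase(probe[poff + len]) == upcase(text[toff + len]) &&
                   text[toff + len] != '*' && text[toff + len] != 'X') ++len;
            Anchor a;
            a.ps = poff; a.pe = poff + len;
            a.cs = frame + scale * toff; a.ce = frame + scale * (toff + len);
            a.frame = frame;
            anchors.push_back(a);
        }
    }
}

static bool splice_ok(const std::string& S, int donor, int acceptor) {
    // donor = first intron base; acceptor = one past last intron base
    if (donor + 2 > (int)S.size() || acceptor - 2 < 0 || acceptor - donor < 4) return false;
    return upcase(S[donor]) == 'G' && upcase(S[donor + 1]) == 'T' &&
           upcase(S[acceptor - 2]) == 'A' && upcase(S[acceptor - 1]) == 'G';
}

static StrandAln align_strand(const std::string& probe, bool prot, const std::string& S) {
    StrandAln out;
    int scale = prot ? 3 : 1;
    std::vector<Anchor> anchors;
    if (prot) {
        for (int f = 0; f < 3; ++f)
            collect_mems(probe, translate_frame(S, f), SEED_AA, true, f, 3, anchors);
    } else {
        collect_mems(probe, S, SEED_NT, false, 0, 1, anchors);
        for (auto& a : anchors) a.frame = -1;
    }
    if (anchors.empty()) return out;
    if ((int)anchors.size() > MAX_ANCHORS) {
        std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
            return (a.pe - a.ps) > (b.pe - b.ps);
        });
        anchors.resize(MAX_ANCHORS);
    }
    std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
        if (a.ps != b.ps) return a.ps < b.ps;
        if (a.cs != b.cs) return a.cs < b.cs;
        return (a.pe - a.ps) > (b.pe - b.ps);
    });

    int n = (int)anchors.size();
    std::vector<double> dp(n);
    std::vector<int> bt(n, -1);
    double best = -1; int best_i = 0;
    for (int i = 0; i < n; ++i) {
        dp[i] = anchors[i].pe - anchors[i].ps;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            const Anchor& aj = anchors[j];
            const Anchor& ai = anchors[i];
            if (aj.ps > ai.ps || (aj.ps == ai.ps && j > i)) break;
            int ov = aj.pe - ai.ps; // probe overlap
            if (ov > 6) continue;
            int ps_i = ai.ps + std::max(0, ov);
            int cs_i = ai.cs + scale * std::max(0, ov);
            if (ps_i >= ai.pe || cs_i >= ai.ce) continue;
            if (cs_i < aj.ce) continue;     // contig order
            int cgap = cs_i - aj.ce;
            int pgap = ps_i - aj.pe;
            if (cgap > MAX_INTRON) continue;
            double pen = 0.5;
            if (cgap >= MIN_INTRON && pgap <= 10)
                pen += splice_ok(S, aj.ce, cs_i) ? 0.0 : 2.0;
            else
                pen += std::abs(cgap - scale * pgap) / 100.0 + pgap / 25.0;
            double gain = (ai.pe - ps_i) - pen;
            if (dp[j] + gain > dp[i]) { dp[i] = dp[j] + gain; bt[i] = j; }
        }
        if (dp[i] > best) { best = dp[i]; best_i = i; }
    }
    // backtrack chain
    std::vector<int> chain;
    for (int i = best_i; i >= 0; i = bt[i]) chain.push_back(i);
    std::reverse(chain.begin(), chain.end());

    // trim probe overlaps along the chain
    std::vector<Anchor> ch;
    for (int idx : chain) {
        Anchor a = anchors[idx];
        if (!ch.empty()) {
            int ov = ch.back().pe - a.ps;
            if (ov > 0) { a.ps += ov; a.cs += scale * ov; }
            if (a.ps >= a.pe || a.cs <= ch.back().ce) continue;
        }
        ch.push_back(a);
    }
    if (ch.empty()) return out;

    // pre-computed frame translations for fills / end extension
    std::array<std::string, 3> trans;
    if (prot) for (int f = 0; f < 3; ++f) trans[f] = translate_frame(S, f);

    // build blocks, filling within-exon gaps
    int ids = 0, covered = 0;
    std::vector<std::array<int, 4>> blocks;
    std::array<int, 4> cur{ch[0].ps, ch[0].pe, ch[0].cs, ch[0].ce};
    ids += ch[0].pe - ch[0].ps;
    for (size_t i = 1; i < ch.size(); ++i) {
        const Anchor& a = ch[i];
        int pgap = a.ps - cur[1];
        int cgap = a.cs - cur[3];
        bool fillable = cgap >= 0 && cgap < MIN_INTRON && pgap >= 0 && pgap <= 60 &&
                        (!prot || (cgap % 3 == 0));
        if (fillable) {
            if (pgap > 0 || cgap > 0) {
                std::string pa = probe.substr(cur[1], pgap);
                std::string ca;
                if (prot) {
                    int f = cur[3] % 3;
                    ca = trans[f].substr((cur[3] - f) / 3, cgap / 3);
                } else ca = S.substr(cur[3], cgap);
                ids += dp_fill(pa, ca, prot).identities;
            }
            cur[1] = a.pe; cur[3] = a.ce;
            ids += a.pe - a.ps;
        } else {
            blocks.push_back(cur);
            cur = {a.ps, a.pe, a.cs, a.ce};
            ids += a.pe - a.ps;
        }
    }
    blocks.push_back(cur);

    // terminal ungapped x-drop extension (same frame/diagonal)
    {
        std::array<int, 4>& b0 = blocks.front();
        int bestp = b0[0], bestc = b0[2], bestids = 0, ids_run = 0;
        double sc = 0, bestsc = 0;
        int p = b0[0] - 1, c = b0[2] - scale;
        while (p >= 0 && c >= 0) {
            char pa = probe[p];
            char ta = prot ? trans[c % 3][(c - c % 3) / 3] : S[c];
            if (prot && (ta == '*' || ta == 'X')) break;
            bool eq = upcase(pa) == upcase(ta);
            sc += eq ? 1.0 : -2.0;
            ids_run += eq ? 1 : 0;
            if (sc > bestsc) { bestsc = sc; bestp = p; bestc = c; bestids = ids_run; }
            if (sc < bestsc - 5) break;
            --p; c -= scale;
        }
        ids += bestids; b0[0] = bestp; b0[2] = bestc;
    }
    {
        std::array<int, 4>& bl = blocks.back();
        int np = (int)probe.size(), nc = (int)S.size();
        int bestp = bl[1], bestc = bl[3], bestids = 0, ids_run = 0;
        double sc = 0, bestsc = 0;
        int p = bl[1], c = bl[3];
        while (p < np && c + scale <= nc) {
            char pa = probe[p];
            char ta = prot ? trans[c % 3][(c - c % 3) / 3] : S[c];
            if (prot && (ta == '*' || ta == 'X')) break;
            bool eq = upcase(pa) == upcase(ta);
            sc += eq ? 1.0 : -2.0;
            ids_run += eq ? 1 : 0;
            if (sc > bestsc) { bestsc = sc; bestp = p + 1; bestc = c + scale; bestids = ids_run; }
            if (sc < bestsc - 5) break;
            ++p; c += scale;
        }
        ids += bestids; bl[1] = bestp; bl[3] = bestc;
    }

    for (auto& b : blocks) { covered += b[1] - b[0]; out.aligned_len += b[3] - b[2]; }
    out.blocks = blocks;
    out.identities = ids;
    out.covered = covered;
    out.valid = true;
    return out;
}

// [[Rcpp::export]]
List cpp_splice_align(std::string probe, bool is_protein, std::string contig) {
    std::string Sf = contig;
    for (auto& c : Sf) c = upcase(c);
    std::string Sr = revcomp(Sf);
    std::string P = probe;
    for (auto& c : P) c = upcase(c);

    StrandAln fwd = align_strand(P, is_protein, Sf);
    StrandAln rev = align_strand(P, is_protein, Sr);
    bool use_rev = false;
    if (rev.valid && (!fwd.valid || rev.identities > fwd.identities ||
                      (rev.identities == fwd.identities && rev.aligned_len > fwd.aligned_len)))
        use_rev = true;
    StrandAln& A = use_rev ? rev : fwd;
    int L = (int)contig.size();

    int nb = A.valid ? (int)A.blocks.size() : 0;
    IntegerMatrix blocks(nb, 4);
    for (int i = 0; i < nb; ++i) {
        blocks(i, 0) = A.blocks[i][0];
        blocks(i, 1) = A.blocks[i][1];
        if (!use_rev) { blocks(i, 2) = A.blocks[i][2]; blocks(i, 3) = A.blocks[i][3]; }
        else { blocks(i, 2) = L - A.blocks[i][3]; blocks(i, 3) = L - A.blocks[i][2]; }
    }
    colnames(blocks) = CharacterVector::create("probe_start", "probe_end", "contig_start", "contig_end");
    double cov = A.valid ? (double)A.covered / (double)probe.size() : 0.0;
    double sim = (A.valid && A.covered > 0) ? (double)A.identities / (double)A.covered : 0.0;
    return List::create(
        _["blocks"] = blocks,
        _["similarity"] = sim,
        _["probe_coverage"] = cov,
        _["aligned_length"] = A.valid ? A.aligned_len : 0,
        _["identities"] = A.valid ? A.identities : 0,
        _["strand"] = use_rev ? "-" : "+");
}
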