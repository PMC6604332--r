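// Chunk-level exact-substring k-mer index over read (or contig) sets.
// DNA postings cover both strands; protein postings cover all six frames,
// with translations broken at stop codons and ambiguous residues so no
// k-mer spans them. Matching = seed (index k-mer) extended to a maximal
// exact match, accepted when the shared substring reaches min_match.

#include <Rcpp.h>
#include <unordered_map>
#include "srwalk_common.h"

using namespace Rcpp;

typedef std::pair<uint64_t, uint64_t> Posting; // key, packed(read, offset, code)

static inline uint64_t pack_post(uint32_t read, uint32_t off, uint32_t code) {
    return ((uint64_t)code << 52) | ((uint64_t)read << 20) | (uint64_t)off;
}
static inline uint32_t post_read(uint64_t p) { return (uint32_t)((p >> 20) & 0xFFFFFFFFULL); }
static inline uint32_t post_off(uint64_t p)  { return (uint32_t)(p & 0xFFFFFULL); }
static inline uint32_t post_code(uint64_t p) { return (uint32_t)(p >> 52); }

struct ChunkIndex {
    int k_dna = 0, k_prot = 0;
    bool has_prot = false;
    std::vector<std::string> seqs;  // subject sequences, as given
    std::vector<Posting> dna;       // sorted by (key, posting)
    std::vector<Posting> prot;
};

static void add_dna_postings(std::vector<Posting>& out, const std::string& s,
                             uint32_t read, int k, uint32_t strand_code) {
    int n = (int)s.size();
    if (n < k) return;
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < n; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) out.push_back({key, pack_post(read, (uint32_t)(i - k + 1), strand_code)});
    }
}

static void add_prot_postings(std::vector<Posting>& out, const std::string& t,
                              uint32_t read, int k, uint32_t frame_code) {
    int n = (int)t.size();
    if (n < k) return;
    uint64_t key = 0, mask = (1ULL << (5 * k)) - 1;
    int run = 0;
    for (int i = 0; i < n; ++i) {
        int c = aa_code(t[i]);
        if (c < 0 || t[i] == '*' || t[i] == 'X') { run = 0; key = 0; continue; }
        key = ((key << 5) | (uint64_t)c) & mask;
        if (++run >= k) out.push_back({key, pack_post(read, (uint32_t)(i - k + 1), frame_code)});
    }
}

// frame codes 0..5 = +1,+2,+3,-1,-2,-3
static std::string frame_translation(const std::string& seq, int frame_code) {
    if (frame_code < 3) return translate_frame(seq, frame_code);
    std::string rc = revcomp(seq);
    return translate_frame(rc, frame_code - 3);
}

// [[Rcpp::export]]
SEXP cpp_chunk_index(CharacterVector seqs, int k_dna, int k_prot, bool with_prot) {
    ChunkIndex* idx = new ChunkIndex();
    idx->k_dna = k_dna; idx->k_prot = k_prot; idx->has_prot = with_prot;
    int n = seqs.size();
    idx->seqs.reserve(n);
    for (int i = 0; i < n; ++i) idx->seqs.push_back(as<std::string>(seqs[i]));
    for (int i = 0; i < n; ++i) {
        const std::string& s = idx->seqs[i];
        add_dna_postings(idx->dna, s, (uint32_t)i, k_dna, 0);
        add_dna_postings(idx->dna, revcomp(s), (uint32_t)i, k_dna, 1);
        if (with_prot) {
            for (int f = 0; f < 6; ++f)
                add_prot_postings(idx->prot, frame_translation(s, f), (uint32_t)i, k_prot, (uint32_t)f);
        }
    }
    std::sort(idx->dna.begin(), idx->dna.end());
    std::sort(idx->prot.begin(), idx->prot.end());
    XPtr<ChunkIndex> ptr(idx, true);
    return ptr;
}

// [[Rcpp::export]]
List cpp_index_counts(SEXP xp) {
    XPtr<ChunkIndex> idx(xp);
    return List::create(_["n_seqs"] = (int)idx->seqs.size(),
                        _["dna"] = (double)idx->dna.size(),
                        _["prot"] = (double)idx->prot.size(),
                        _["k_dna"] = idx->k_dna, _["k_prot"] = idx->k_prot);
}

static uint64_t encode_dna_key(const std::string& s, bool& ok) {
    uint64_t key = 0; ok = true;
    for (char c : s) { int b = base_code(c); if (b < 0) { ok = false; return 0; } key = (key << 2) | (uint64_t)b; }
    return key;
}
static uint64_t encode_prot_key(const std::string& s, bool& ok) {
    uint64_t key = 0; ok = true;
    for (char c : s) { int b = aa_code(c); if (b < 0) { ok = false; return 0; } key = (key << 5) | (uint64_t)b; }
    return key;
}
static std::string decode_dna_key(uint64_t key, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = "ACGT"[key & 3]; key >>= 2; }
    return s;
}
static std::string decode_prot_key(uint64_t key, int k) {
    static const char* AAS = "ACDEFGHIKLMNPQRSTVWY";
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = AAS[key & 31]; key >>= 5; }
    return s;
}

// Postings for one exact k-mer; for tests and invariant checks.
// space: "dna" (code 0='+',1='-') or "prot" (codes 0..5 = +1,+2,+3,-1,-2,-3).
// [[Rcpp::export]]
DataFrame cpp_index_postings(SEXP xp, std::string kmer, std::string space) {
    XPtr<ChunkIndex> idx(xp);
    bool ok; uint64_t key;
    const std::vector<Posting>* v;
    if (space == "dna") {
        if ((int)kmer.size() != idx->k_dna) stop("k-mer length must equal k_dna");
        key = encode_dna_key(kmer, ok); v = &idx->dna;
    } else {
        if ((int)kmer.size() != idx->k_prot) stop("k-mer length must equal k_prot");
        key = encode_prot_key(kmer, ok); v = &idx->prot;
    }
    std::vector<int> read, off, code;
    if (ok) {
        auto lo = std::lower_bound(v->begin(), v->end(), Posting{key, 0});
        for (auto it = lo; it != v->end() && it->first == key; ++it) {
            read.push_back((int)post_read(it->second) + 1);
            off.push_back((int)post_off(it->second));
            code.push_back((int)post_code(it->second));
        }
    }
    return DataFrame::create(_["read"] = read, _["offset"] = off, _["code"] = code);
}

// Posting at global position j (1-based) in the sorted posting array.
// [[Rcpp::export]]
List cpp_index_posting_at(SEXP xp, double j, std::string space) {
    XPtr<ChunkIndex> idx(xp);
    const std::vector<Posting>& v = (space == "dna") ? idx->dna : idx->prot;
    size_t i = (size_t)j - 1;
    if (i >= v.size()) stop("posting index out of range");
    std::string km = (space == "dna") ? decode_dna_key(v[i].first, idx->k_dna)
                                      : decode_prot_key(v[i].first, idx->k_prot);
    return List::create(_["kmer"] = km, _["read"] = (int)post_read(v[i].second) + 1,
                        _["offset"] = (int)post_off(v[i].second),
                        _["code"] = (int)post_code(v[i].second));
}

// Maximal exact run through a seed; query may contain lowercase (compared
// case-insensitively), subject side is compared as stored (uppercase data).
static int extend_match(const std::string& q, int qoff, const std::string& s, int soff, int k) {
    int left = 0;
    while (qoff - left - 1 >= 0 && soff - left - 1 >= 0 &&
           upcase(q[qoff - left - 1]) == upcase(s[soff - left - 1])) ++left;
    int right = 0;
    int qn = (int)q.size(), sn = (int)s.size();
    while (qoff + k + right < qn && soff + k + right < sn &&
           upcase(q[qoff + k + right]) == upcase(s[soff + k + right])) ++right;
    return left + k + right;
}

// Search the chunk for subjects sharing an exact substring of length
// >= min_match with any query. DNA queries search DNA space; protein
// queries search translated space. Lowercase query positions seed nothing.
// Returns 1-based subject ordinals, sorted, unique.
// [[Rcpp::export]]
IntegerVector cpp_chunk_search(SEXP xp, CharacterVector queries, CharacterVector alphabet,
                               int min_match_dna, int min_match_prot) {
    XPtr<ChunkIndex> idx(xp);
    int nsub = (int)idx->seqs.size();
    std::vector<char> matched(nsub, 0);
    std::vector<std::string> rc_cache(nsub);
    std::vector<char> rc_have(nsub, 0);
    // lazy 6-frame translations per subject
    std::vector<std::array<std::string, 6>> tr_cache(idx->has_prot ? nsub : 0);
    std::vector<std::array<char, 6>> tr_have(idx->has_prot ? nsub : 0);
    if (idx->has_prot) for (auto& a : tr_have) a.fill(0);

    for (int qi = 0; qi < queries.size(); ++qi) {
        std::string q = as<std::string>(queries[qi]);
        bool prot = (as<std::string>(alphabet[qi]) == "protein");
        if (prot) {
            if (!idx->has_prot) stop("index was built without protein postings");
            if (min_match_prot < idx->k_prot) stop("min_match below index k");
            int k = idx->k_prot, n = (int)q.size();
            uint64_t key = 0, mask = (1ULL << (5 * k)) - 1;
            int run = 0;
            for (int i = 0; i < n; ++i) {
                char ch = q[i];
                int c = aa_code(ch);
                if (c < 0 || is_lower(ch)) { run = 0; key = 0; continue; }
                key = ((key << 5) | (uint64_t)c) & mask;
                if (++run < k) continue;
                int qoff = i - k + 1;
                auto lo = std::lower_bound(idx->prot.begin(), idx->prot.end(), Posting{key, 0});
                for (auto it = lo; it != idx->prot.end() && it->first == key; ++it) {
                    int r = (int)post_read(it->second);
                    if (matched[r]) continue;
                    int f = (int)post_code(it->second);
                    if (!tr_have[r][f]) {
                        tr_cache[r][f] = frame_translation(idx->seqs[r], f);
                        tr_have[r][f] = 1;
                    }
                    if (extend_match(q, qoff, tr_cache[r][f], (int)post_off(it->second), k) >= min_match_prot)
                        matched[r] = 1;
                }
            }
        } else {
            if (min_match_dna < idx->k_dna) stop("min_match below index k");
            int k = idx->k_dna, n = (int)q.size();
            uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
            int run = 0;
            for (int i = 0; i < n; ++i) {
                char ch = q[i];
                int c = base_code(ch);
                if (c < 0 || is_lower(ch)) { run = 0; key = 0; continue; }
                key = ((key << 2) | (uint64_t)c) & mask;
                if (++run < k) continue;
                int qoff = i - k + 1;
                auto lo = std::lower_bound(idx->dna.begin(), idx->dna.end(), Posting{key, 0});
                for (auto it = lo; it != idx->dna.end() && it->first == key; ++it) {
                    int r = (int)post_read(it->second);
                    if (matched[r]) continue;
                    const std::string* s;
                    if (post_code(it->second) == 0) s = &idx->seqs[r];
                    else {
                        if (!rc_have[r]) { rc_cache[r] = revcomp(idx->seqs[r]); rc_have[r] = 1; }
                        s = &rc_cache[r];
                    }
                    if (extend_match(q, qoff, *s, (int)post_off(it->second), k) >= min_match_dna)
                        matched[r] = 1;
                }
            }
        }
    }
    std::vector<int> out;
    for (int i = 0; i < nsub; ++i) if (matched[i]) out.push_back(i + 1);
    return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_chunk_seqs(SEXP xp, IntegerVector ordinals) {
    XPtr<ChunkIndex> idx(xp);
    CharacterVector out(ordinals.size());
    for (int i = 0; i < ordinals.size(); ++i) {
        int o = ordinals[i] - 1;
        if (o < 0 || o >= (int)idx->seqs.size()) stop("ordinal out of range");
        out[i] = idx->seqs[o];
    }
    return out;
}
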