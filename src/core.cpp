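#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Banded global alignment maximizing the number of matched bases.
// The band is centred on the main diagonal, widened by the length
// difference and a slack of `band` columns on each side, so optimal
// alignments of sequences whose lengths differ by <= band are exact.
// Identity = matches / min(length) (CD-HIT style denominator).
static int banded_matches(const char *a, int n, const char *b, int m, int band) {
    const int NEG = -1000000;
    int dmin = std::min(0, m - n) - band;
    int dmax = std::max(0, m - n) + band;
    std::vector<int> prev(m + 1, NEG), cur(m + 1, NEG);
    for (int j = 0; j <= std::min(m, dmax); ++j) prev[j] = 0;
    for (int i = 1; i <= n; ++i) {
        int jlo = std::max(0, i + dmin);
        int jhi = std::min(m, i + dmax);
        if (jlo > jhi) return 0;
        std::fill(cur.begin(), cur.end(), NEG);
        for (int j = jlo; j <= jhi; ++j) {
            int best = prev[j];                       // gap in b (consume a_i)
            if (j > 0) {
                int diag = prev[j - 1];
                if (diag > NEG) {
                    int v = diag + (a[i - 1] == b[j - 1] ? 1 : 0);
                    if (v > best) best = v;
                }
                if (cur[j - 1] > best) best = cur[j - 1];  // gap in a
            }
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    return prev[m] < 0 ? 0 : prev[m];
}

// [[Rcpp::export]]
int identity_matches_cpp(std::string a, std::string b, int band) {
    return banded_matches(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(), band);
}

// --- bit-parallel helpers -------------------------------------------------
// 2-bit-free representation: one 64-bit occurrence mask per base, valid for
// sequences up to 64 nt (SELEX variable regions are 39-41 nt).
struct PackedSeq {
    uint64_t pm[4];
    int len;
    const char *s;
};

static inline int base_index(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static PackedSeq pack_seq(const char *s) {
    PackedSeq p;
    p.pm[0] = p.pm[1] = p.pm[2] = p.pm[3] = 0;
    p.s = s;
    p.len = (int)std::strlen(s);
    if (p.len <= 64) {
        for (int k = 0; k < p.len; ++k) {
            int b = base_index(s[k]);
            if (b >= 0) p.pm[b] |= (uint64_t)1 << k;
        }
    }
    return p;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcountll(x);
#else
    int c = 0;
    while (x) { x &= x - 1; ++c; }
    return c;
#endif
}

// ungapped matches of two equal-length packed sequences
static inline int hamming_matches(const PackedSeq &a, const PackedSeq &b) {
    return popcount64(a.pm[0] & b.pm[0]) + popcount64(a.pm[1] & b.pm[1]) +
           popcount64(a.pm[2] & b.pm[2]) + popcount64(a.pm[3] & b.pm[3]);
}

// Length of the longest common subsequence, bit-parallel (Crochemore et al.
// style row update). The LCS is an upper bound on the matches of any global
// alignment, banded or not, so it gives a rigorous rejection filter.
static int llcs_bound(const PackedSeq &pat, const char *text, int tlen) {
    uint64_t mask = (pat.len >= 64) ? ~(uint64_t)0
                                    : (((uint64_t)1 << pat.len) - 1);
    uint64_t V = mask;
    for (int j = 0; j < tlen; ++j) {
        int b = base_index(text[j]);
        uint64_t U = (b >= 0) ? (V & pat.pm[b]) : 0;
        V = ((V + U) | (V - U)) & mask;
    }
    return pat.len - popcount64(V);
}

// [[Rcpp::export]]
int llcs_cpp(std::string a, std::string b) {
    if (a.size() > 64) stop("llcs_cpp supports sequences up to 64 nt");
    PackedSeq p = pack_seq(a.c_str());
    return llcs_bound(p, b.c_str(), (int)b.size());
}

// Greedy clustering: sequences are supplied already sorted (abundance
// descending, ties lexicographic). Each joins the first cluster, in
// founding order, whose representative is within `threshold` identity;
// otherwise it founds a new cluster. Returns 1-based cluster index.
// Fast paths (both rigorous): equal-length pairs whose ungapped matches
// already reach the threshold join immediately (ungapped matches lower-bound
// the banded alignment); pairs whose LCS falls below the required match
// count are rejected (LCS upper-bounds it). Everything else is decided by
// the banded DP.
// [[Rcpp::export]]
IntegerVector greedy_assign_cpp(CharacterVector seqs, double threshold, int band) {
    int n = seqs.size();
    IntegerVector assign(n);
    std::vector<PackedSeq> reps;
    reps.reserve(1024);
    for (int i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        PackedSeq q = pack_seq(s);
        int hit = -1;
        for (size_t c = 0; c < reps.size(); ++c) {
            const PackedSeq &r = reps[c];
            if (std::abs(q.len - r.len) > band) continue;
            int minlen = std::min(q.len, r.len);
            int need = (int)std::ceil(threshold * minlen - 1e-9);
            if (q.len <= 64 && r.len <= 64) {
                if (q.len == r.len && hamming_matches(q, r) >= need) { hit = (int)c; break; }
                if (llcs_bound(r, q.s, q.len) < need) continue;
            }
            if (banded_matches(q.s, q.len, r.s, r.len, band) >= need) { hit = (int)c; break; }
        }
        if (hit < 0) {
            reps.push_back(q);
            assign[i] = (int)reps.size();
        } else {
            assign[i] = hit + 1;
        }
    }
    return assign;
}

// All-pairs banded-identity match counts (upper triangle), used by the
// brute-force clustering oracle. Guarded to small inputs by the caller.
// [[Rcpp::export]]
IntegerMatrix identity_matrix_cpp(CharacterVector seqs, int band) {
    int n = seqs.size();
    IntegerMatrix m(n, n);
    std::vector<const char *> s(n);
    std::vector<int> len(n);
    for (int i = 0; i < n; ++i) {
        s[i] = CHAR(STRING_ELT(seqs, i));
        len[i] = (int)std::strlen(s[i]);
    }
    for (int i = 0; i < n; ++i) {
        m(i, i) = len[i];
        for (int j = i + 1; j < n; ++j) {
            int v = banded_matches(s[i], len[i], s[j], len[j], band);
            m(i, j) = v;
            m(j, i) = v;
        }
    }
    return m;
}

// Needleman-Wunsch global alignment score, affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_extend (the Biostrings
// convention), so single-base gaps cost gap_open + gap_extend.
static double gotoh_score(const char *a, int n, const char *b, int m,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
    const double NEG = -1e18;
    std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
    std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
    Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
    for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG; Xp[j] = NEG;
        Yp[j] = -(gap_open + j * gap_extend);
    }
    for (int i = 1; i <= n; ++i) {
        M[0] = NEG; Y[0] = NEG;
        X[0] = -(gap_open + i * gap_extend);
        for (int j = 1; j <= m; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double dbest = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
            M[j] = dbest + s;
            X[j] = std::max(Mp[j] - (gap_open + gap_extend),
                            std::max(Xp[j] - gap_extend,
                                     Yp[j] - (gap_open + gap_extend)));
            Y[j] = std::max(M[j - 1] - (gap_open + gap_extend),
                            std::max(Y[j - 1] - gap_extend,
                                     X[j - 1] - (gap_open + gap_extend)));
        }
        std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    }
    return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// [[Rcpp::export]]
double nw_score_cpp(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_extend) {
    return gotoh_score(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
                       match, mismatch, gap_open, gap_extend);
}

// Best-scoring target for one query representative. Ties broken by
// higher target count, then lexographically smaller target sequence.
// Returns (0-based index, score).
// With `threshold_filter`, targets that provably cannot reach `threshold`
// are skipped via the LCS bound score <= match * LCS (valid whenever
// mismatch <= 0 and gap penalties >= 0; otherwise the filter disables
// itself). Skipped targets score below the threshold, so the matched/lost
// decision and the identity of any match at or above the threshold are
// unchanged; only the reported score of a lost query may then be a bound
// rather than the exact sub-threshold maximum.
// [[Rcpp::export]]
List nw_best_cpp(std::string query, CharacterVector targets, NumericVector counts,
                 double match, double mismatch, double gap_open, double gap_extend,
                 bool threshold_filter = false, double threshold = 0.0) {
    int n = targets.size();
    int best = -1;
    double best_score = -1e18;
    const char *q = query.c_str();
    int lq = (int)query.size();
    bool can_filter = threshold_filter && match > 0 && mismatch <= 0 &&
                      gap_open >= 0 && gap_extend >= 0 && lq <= 64;
    PackedSeq qp;
    if (can_filter) qp = pack_seq(q);
    for (int i = 0; i < n; ++i) {
        const char *t = CHAR(STRING_ELT(targets, i));
        int lt = (int)std::strlen(t);
        if (can_filter) {
            double bound = match * llcs_bound(qp, t, lt);
            if (bound < threshold) {
                if (best < 0 && bound > best_score) best_score = bound;
                continue;
            }
        }
        double s = gotoh_score(q, lq, t, lt, match, mismatch, gap_open, gap_extend);
        bool take = false;
        if (best < 0 || s > best_score + 1e-9) take = true;
        else if (s > best_score - 1e-9 && best >= 0) {
            if (counts[i] > counts[best]) take = true;
            else if (counts[i] == counts[best] &&
                     std::strcmp(t, CHAR(STRING_ELT(targets, best))) < 0) take = true;
        }
        if (take) { best = i; best_score = s; }
    }
    return List::create(_["index"] = best, _["score"] = best_score);
}

// Per-read preparation: mean-Phred quality filter, constant-arm location
// (ungapped comparison scanned over +/- `offset` placements, best = fewest
// mismatches, ties preferring the nominal placement), then length/alphabet
// check of the enclosed variable region.
// reason: 0 pass, 1 quality, 2 arm5_not_found, 3 arm3_not_found,
//         4 length_out_of_range, 5 non_acgt
static int arm_mismatches(const char *read, int rl, const char *arm, int la, int start) {
    int mm = 0;
    for (int k = 0; k < la; ++k) {
        int p = start + k;
        if (p < 0 || p >= rl || read[p] != arm[k]) ++mm;
    }
    return mm;
}

// [[Rcpp::export]]
List prep_reads_cpp(CharacterVector bases, CharacterVector quals,
                    std::string arm5, std::string arm3,
                    int max_mm, int offset, double qual_threshold,
                    int len_lo, int len_hi) {
    int n = bases.size();
    CharacterVector var(n);
    IntegerVector reason(n);
    LogicalVector has_n(n);
    int l5 = (int)arm5.size(), l3 = (int)arm3.size();
    // scan order 0, +1, -1, +2, -2, ... keeping strictly better placements
    std::vector<int> offs;
    offs.push_back(0);
    for (int o = 1; o <= offset; ++o) { offs.push_back(o); offs.push_back(-o); }
    for (int i = 0; i < n; ++i) {
        const char *r = CHAR(STRING_ELT(bases, i));
        const char *q = CHAR(STRING_ELT(quals, i));
        int rl = (int)std::strlen(r);
        var[i] = NA_STRING;
        bool nn = false;
        for (int k = 0; k < rl; ++k) if (r[k] == 'N' || r[k] == 'n') { nn = true; break; }
        has_n[i] = nn;
        if (rl == 0) { reason[i] = 1; continue; }
        double qsum = 0;
        for (int k = 0; k < rl; ++k) qsum += (double)(q[k] - 33);
        if (qsum / rl < qual_threshold - 1e-9) { reason[i] = 1; continue; }
        // 5' arm nominally at read start
        int best5 = max_mm + 1, off5 = 0;
        for (size_t oi = 0; oi < offs.size(); ++oi) {
            int mm = arm_mismatches(r, rl, arm5.c_str(), l5, offs[oi]);
            if (mm < best5) { best5 = mm; off5 = offs[oi]; }
        }
        if (best5 > max_mm) { reason[i] = 2; continue; }
        int vstart = off5 + l5;
        // 3' arm nominally at read end
        int s0 = rl - l3;
        int best3 = max_mm + 1, off3 = 0;
        for (size_t oi = 0; oi < offs.size(); ++oi) {
            int mm = arm_mismatches(r, rl, arm3.c_str(), l3, s0 + offs[oi]);
            if (mm < best3) { best3 = mm; off3 = offs[oi]; }
        }
        if (best3 > max_mm) { reason[i] = 3; continue; }
        int vend = s0 + off3;  // exclusive
        if (vend < vstart) vend = vstart;
        int vlen = vend - vstart;
        var[i] = std::string(r + vstart, r + vend);
        if (vlen < len_lo || vlen > len_hi) { reason[i] = 4; continue; }
        bool clean = true;
        for (int k = vstart; k < vend; ++k) {
            char c = r[k];
            if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { clean = false; break; }
        }
        if (!clean) { reason[i] = 5; continue; }
        reason[i] = 0;
    }
    return List::create(_["var"] = var, _["reason"] = reason, _["has_n"] = has_n);
}

// Per-base substitution errors using R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
CharacterVector mutate_reads_cpp(CharacterVector reads, double error_rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = reads.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(reads[i]);
        for (size_t k = 0; k < s.size(); ++k) {
            if (unif_rand() < error_rate) {
                char cur = s[k];
                char sub = cur;
                while (sub == cur) sub = bases[(int)(unif_rand() * 4) % 4];
                s[k] = sub;
            }
        }
        out[i] = s;
    }
    return out;
}

// Phred+33 quality strings, per-base Normal(mean, sd) rounded and clamped
// to [2, 41]; uses R's RNG.
// [[Rcpp::export]]
CharacterVector make_quals_cpp(IntegerVector lens, double mean, double sd) {
    int n = lens.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        int l = lens[i];
        std::string s(l, '!');
        for (int k = 0; k < l; ++k) {
            int qv = (int)std::lround(::Rf_rnorm(mean, sd));
            if (qv < 2) qv = 2;
            if (qv > 41) qv = 41;
            s[k] = (char)(33 + qv);
        }
        out[i] = s;
    }
    return out;
}
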