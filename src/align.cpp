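#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode A/C/G/T; -1 for anything else
static inline int base2bit(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

// [[Rcpp::export]]
IntegerVector cpp_qual_trunc_len(CharacterVector quals, int min_q) {
    int n = quals.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        const char *q = CHAR(STRING_ELT(quals, i));
        int len = LENGTH(STRING_ELT(quals, i));
        int keep = len;
        for (int j = 0; j < len; ++j) {
            if ((int)q[j] - 33 < min_q) { keep = j; break; }
        }
        out[i] = keep;
    }
    return out;
}

struct Hit { int ref; int pos_ref; int pos_read; };

// gapless identity of read against ref at a fixed diagonal
// offset = position in ref where read position 0 would sit (may be negative)
// returns matches / overlap-length; overlap excludes read bases off the ref ends
static double diag_identity(const std::string &read, const std::string &ref,
                            int offset, int *overlap_out) {
    int m = (int)read.size(), n = (int)ref.size();
    int start = std::max(0, -offset);            // first read pos on the ref
    int stop  = std::min(m, n - offset);         // one past last read pos
    int overlap = stop - start;
    if (overlap_out) *overlap_out = overlap;
    if (overlap <= 0) return 0.0;
    int matches = 0;
    for (int i = start; i < stop; ++i)
        if (read[i] == ref[i + offset]) ++matches;
    return (double)matches / (double)overlap;
}

// banded semi-global alignment (read global, window local) used as a rescue
// when the best gapless diagonal falls below threshold; counts matches on the
// optimal path, identity = matches / read bases aligned to reference bases
static double banded_identity(const std::string &read, const std::string &ref,
                              int offset, int band) {
    int m = (int)read.size(), n = (int)ref.size();
    int lo = std::max(0, offset - band);
    int hi = std::min(n, offset + m + band);
    int w = hi - lo;
    if (w <= 0) return 0.0;
    const int MATCH = 2, MISM = -1, GAP = -2, NEG = -1000000;
    // full DP over read x window (window is small: m + 2*band)
    std::vector<int> S((m + 1) * (w + 1), NEG), M((m + 1) * (w + 1), 0);
    std::vector<signed char> T((m + 1) * (w + 1), 0); // 0 diag,1 up(read gap in ref),2 left
    auto idx = [w](int i, int j) { return i * (w + 1) + j; };
    for (int j = 0; j <= w; ++j) { S[idx(0, j)] = 0; T[idx(0, j)] = 2; } // free leading ref
    for (int i = 1; i <= m; ++i) S[idx(i, 0)] = i * GAP, T[idx(i, 0)] = 1;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= w; ++j) {
            bool eq = read[i - 1] == ref[lo + j - 1];
            int sd = S[idx(i - 1, j - 1)] + (eq ? MATCH : MISM);
            int su = S[idx(i - 1, j)] + GAP;
            int sl = S[idx(i, j - 1)] + ((i == m) ? 0 : GAP); // free trailing ref
            int best = sd, tb = 0;
            if (su > best) { best = su; tb = 1; }
            if (sl > best) { best = sl; tb = 2; }
            S[idx(i, j)] = best;
            T[idx(i, j)] = (signed char)tb;
            M[idx(i, j)] = (tb == 0) ? (M[idx(i - 1, j - 1)] + (eq ? 1 : 0))
                         : (tb == 1) ? M[idx(i - 1, j)] : M[idx(i, j - 1)];
        }
    }
    // best end: read fully consumed, any window column
    int bj = 0, bs = NEG;
    for (int j = 0; j <= w; ++j)
        if (S[idx(m, j)] > bs) { bs = S[idx(m, j)]; bj = j; }
    // traceback to count read bases aligned to ref bases
    int i = m, j = bj, aligned = 0, matches = M[idx(m, bj)];
    while (i > 0) {
        signed char t = T[idx(i, j)];
        if (t == 0) { ++aligned; --i; --j; }
        else if (t == 1) { --i; }
        else { --j; }
        if (j < 0) break;
    }
    if (aligned == 0) return 0.0;
    return (double)matches / (double)aligned;
}

// Seeded alignment of reads against a reference set.
// k-mer index -> candidate (ref, diagonal) pairs -> gapless identity on each
// candidate diagonal, banded rescue if below threshold. Returns all hits with
// identity >= min_identity in long format (1-based indices).
// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector refs,
                     int k, int band, double min_identity,
                     double rescue_margin) {
    int n_ref = refs.size(), n_read = reads.size();
    std::vector<std::string> R(n_ref);
    for (int r = 0; r < n_ref; ++r) R[r] = as<std::string>(refs[r]);

    // index every k-mer of every reference
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
    uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int r = 0; r < n_ref; ++r) {
        const std::string &s = R[r];
        uint64_t h = 0; int run = 0;
        for (int p = 0; p < (int)s.size(); ++p) {
            int b = base2bit(s[p]);
            if (b < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)b) & mask;
            if (++run >= k) index[h].push_back(std::make_pair(r, p - k + 1));
        }
    }

    std::vector<int> out_read, out_ref;
    std::vector<double> out_id;
    std::vector<std::pair<long long, int> > cand; // key = ref * BIG + diag
    for (int q = 0; q < n_read; ++q) {
        std::string rd = as<std::string>(reads[q]);
        int m = (int)rd.size();
        if (m < k) continue;
        cand.clear();
        // seeds at ~12 evenly spaced positions
        int step = std::max(1, (m - k) / 11);
        uint64_t h = 0; int run = 0;
        std::vector<uint64_t> hv(m - k + 1, 0);
        std::vector<bool> ok(m - k + 1, false);
        for (int p = 0; p < m; ++p) {
            int b = base2bit(rd[p]);
            if (b < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)b) & mask;
            if (++run >= k) { hv[p - k + 1] = h; ok[p - k + 1] = true; }
        }
        for (int p = 0; p <= m - k; p += step) {
            if (!ok[p]) continue;
            std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::iterator
                it = index.find(hv[p]);
            if (it == index.end()) continue;
            for (size_t z = 0; z < it->second.size(); ++z) {
                int r = it->second[z].first;
                int diag = it->second[z].second - p; // offset of read start in ref
                cand.push_back(std::make_pair((long long)r * 100000LL + diag + 50000, diag));
            }
        }
        if (cand.empty()) continue;
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        // best identity per reference over its candidate diagonals
        int prev_ref = -1; double best = -1.0; int best_diag = 0;
        cand.push_back(std::make_pair((long long)n_ref * 100000LL, 0)); // sentinel
        for (size_t z = 0; z < cand.size(); ++z) {
            int r = (int)(cand[z].first / 100000LL);
            if (r != prev_ref) {
                if (prev_ref >= 0) {
                    double id = best;
                    // gapped rescue only for near-threshold candidates
                    if (id < min_identity && id >= min_identity - rescue_margin
                        && band > 0)
                        id = std::max(id, banded_identity(rd, R[prev_ref], best_diag, band));
                    if (id >= min_identity) {
                        out_read.push_back(q + 1);
                        out_ref.push_back(prev_ref + 1);
                        out_id.push_back(id);
                    }
                }
                prev_ref = r; best = -1.0; best_diag = 0;
            }
            if (r >= n_ref) break;
            int overlap = 0;
            double id = diag_identity(rd, R[r], cand[z].second, &overlap);
            if (id > best) { best = id; best_diag = cand[z].second; }
        }
    }
    return List::create(_["read"] = wrap(out_read),
                        _["ref"] = wrap(out_ref),
                        _["identity"] = wrap(out_id));
}
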